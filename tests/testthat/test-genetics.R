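test_that("observed heterozygosity matches hand counts", {
  # no heterozygotes anywhere
  g0 <- geno_from(matrix(c(0, 2, 0, 2, 0, 2, 0, 2, 0, 2, 0, 2), 3, 4))
  expect_equal(observed_heterozygosity(g0)$value, 0)
  # all heterozygous
  g1 <- geno_from(matrix(1L, 2, 3))
  expect_equal(observed_heterozygosity(g1)$value, 100)
  # mixed: h = (0.5, 0.5) -> 50
  g2 <- geno_from(rbind(c(1, 1), c(0, 2)))
  r <- observed_heterozygosity(g2)
  expect_equal(r$value, 50)
  expect_equal(r$n_subjects, 2L)
  expect_equal(r$n_loci_used, 2L)
})

test_that("missing calls use per-locus complete-case denominators", {
  codes <- rbind(c(1, NA, NA),
                 c(0, 1, NA),
                 c(2, 1, NA))
  g <- geno_from(codes)
  # locus 1: 1/3 het; locus 2: 2/2; locus 3 dropped entirely
  r <- observed_heterozygosity(g)
  expect_equal(r$value, 100 * mean(c(1 / 3, 1)))
  expect_equal(r$n_loci_used, 2L)
  # all-missing subset errors
  g_allna <- geno_from(matrix(NA_integer_, 2, 2))
  expect_error(observed_heterozygosity(g_allna), "no callable loci")
  expect_error(observed_heterozygosity(g, subject_subset = character(0)),
               "no subjects")
})

test_that("H_O is invariant to homozygote relabeling and equals the pooled
           count on complete data", {
  set.seed(31)
  codes <- matrix(sample(0:2, 200, replace = TRUE), 20, 10)
  g <- geno_from(codes)
  flipped <- geno_from(2L - codes)   # swap which homozygote is 0 vs 2
  expect_equal(observed_heterozygosity(g)$value,
               observed_heterozygosity(flipped)$value)
  # complete data: per-locus average == pooled heterozygote fraction
  pooled <- 100 * sum(codes == 1) / length(codes)
  expect_equal(observed_heterozygosity(g)$value, pooled)
})

test_that("H_O converges to the HWE expectation 2q(1-q)", {
  set.seed(7)
  q <- 0.3
  vals <- replicate(40, {
    codes <- matrix(rbinom(500 * 20, 2, q), 500, 20)
    observed_heterozygosity(geno_from(codes))$value
  })
  expect_lt(abs(mean(vals) - 100 * 2 * q * (1 - q)), 0.5)
})

test_that("per-unit heterozygosity respects partitions and filters", {
  codes <- rbind(c(1, 1), c(1, 1), c(0, 2), c(2, 0))
  g <- geno_from(codes, subject_ids = c("a", "b", "c", "d"))
  # single unit equals the global value
  one <- per_unit_heterozygosity(g, c(a = "U", b = "U", c = "U", d = "U"))
  expect_equal(one$H_O, observed_heterozygosity(g)$value)
  # engineered split: unit A all heterozygous, unit B all homozygous
  two <- per_unit_heterozygosity(g, c(a = "A", b = "A", c = "B", d = "B"))
  expect_equal(two$H_O[two$unit_id == "A"], 100)
  expect_equal(two$H_O[two$unit_id == "B"], 0)
  # filter semantics: excluded subjects contribute nowhere
  filt <- per_unit_heterozygosity(g, c(a = "A", b = "A", c = "B", d = "B"),
                                  subject_filter = c("a", "b"),
                                  units = c("A", "B"))
  expect_equal(filt$H_O[filt$unit_id == "A"], 100)
  expect_true(is.na(filt$H_O[filt$unit_id == "B"]))
  expect_equal(filt$n_subjects[filt$unit_id == "B"], 0L)
  # unknown unit id in membership
  expect_error(per_unit_heterozygosity(g, c(a = "A", b = "Z"),
                                       units = "A"),
               "unknown units")
})

test_that("genotype CSV and VCF readers round-trip codes", {
  dir <- withr::local_tempdir()
  codes <- rbind(c(0, 1, 2), c(1, NA, 0))
  g <- geno_from(codes, subject_ids = c("s1", "s2"))
  csv <- file.path(dir, "g.csv")
  df <- data.frame(subject_id = g$subject_ids, g$codes,
                   check.names = FALSE)
  write.csv(df, csv, row.names = FALSE, na = "-1")
  g2 <- read_genotypes_csv(csv)
  expect_equal(unname(g2$codes), unname(g$codes))
  # minimal VCF with the GT conventions
  vcf <- file.path(dir, "g.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t1/0\t./.",
    "1\t300\trs3\tG\tA\t.\tPASS\t.\tGT\t1/1\t0/0"), vcf)
  gv <- read_genotypes_vcf(vcf)
  expect_equal(unname(gv$codes["s1", ]), c(0L, 1L, 2L))
  expect_equal(unname(gv$codes["s2", ]), c(1L, NA, 0L))
})

test_that("invalid genotype codes and metadata are rejected", {
  expect_error(geno_from(matrix(c(0, 3), 1, 2)), "codes must be")
  expect_error(geno_from(matrix(0L, 2, 2),
                         subject_ids = c("a", "a")), "unique")
  g <- geno_from(matrix(c(0, 1, 2, 1), 2, 2),
                 loci = data.frame(locus_id = c("l1", "l2"),
                                   class = c("intragenic", "intergenic")))
  expect_equal(observed_heterozygosity(g, locus_class = "intergenic")$value,
               50)
  expect_equal(call_rate(g), c(l1 = 1, l2 = 1))
})
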