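#' Construct a genotype matrix
#'
#' Container for biallelic SNP genotypes coded as allele counts:
#' \code{0} and \code{2} are the two homozygotes, \code{1} the
#' heterozygote, and \code{NA} a missing call. Rows are subjects,
#' columns are loci.
#'
#' @param codes integer matrix (subjects x loci) with entries 0, 1, 2 or
#'   NA; a \code{missing_code} (e.g. -1) is converted to NA.
#' @param subject_ids character vector of unique subject identifiers;
#'   defaults to the row names of \code{codes}.
#' @param loci optional data.frame of per-locus metadata with columns
#'   \code{locus_id}, and optionally \code{class} (one of
#'   \code{"intragenic"}, \code{"intergenic"}) and \code{maf} in [0, 1].
#' @param missing_code sentinel value recoded to NA (default -1).
#' @return an object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(codes, subject_ids = rownames(codes),
                            loci = NULL, missing_code = -1L) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  codes[codes %in% missing_code] <- NA_integer_
  bad <- !is.na(codes) & !(codes %in% 0:2)
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or missing")
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(nrow(codes)))
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) stop("subject ids must be unique")
  if (length(subject_ids) != nrow(codes)) {
    stop("length of subject_ids does not match rows of codes")
  }
  if (is.null(loci)) {
    ids <- colnames(codes)
    if (is.null(ids)) ids <- paste0("L", seq_len(ncol(codes)))
    loci <- data.frame(locus_id = ids, stringsAsFactors = FALSE)
  }
  loci <- as.data.frame(loci)
  if (is.null(loci$locus_id)) stop("loci metadata needs a locus_id column")
  loci$locus_id <- as.character(loci$locus_id)
  if (anyDuplicated(loci$locus_id)) stop("locus ids must be unique")
  if (nrow(loci) != ncol(codes)) {
    stop("loci metadata rows must match columns of codes")
  }
  if (!is.null(loci$class) &&
      !all(loci$class %in% c("intragenic", "intergenic", NA))) {
    stop("locus class must be 'intragenic' or 'intergenic'")
  }
  if (!is.null(loci$maf) && any(loci$maf < 0 | loci$maf > 1, na.rm = TRUE)) {
    stop("minor-allele frequencies must lie in [0, 1]")
  }
  dimnames(codes) <- list(subject_ids, loci$locus_id)
  structure(list(codes = codes, subject_ids = subject_ids, loci = loci),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cr <- mean(!is.na(x$codes))
  cat(sprintf("genotype_matrix: %d subjects x %d loci (call rate %.1f%%)\n",
              nrow(x$codes), ncol(x$codes), 100 * cr))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

#' Per-locus call rates
#'
#' @param geno a \code{genotype_matrix}.
#' @return named numeric vector, fraction of non-missing calls per locus.
#' @export
call_rate <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  colMeans(!is.na(geno$codes))
}

#' Read a genotype CSV table
#'
#' Expected layout: a header row of locus ids, one row per subject, the
#' first column holding the subject id. Missing genotypes may be coded
#' as the \code{missing_code}, empty, or NA.
#'
#' @param path file path.
#' @param loci optional locus metadata passed to [genotype_matrix()].
#' @param missing_code sentinel for missing calls (default -1).
#' @return a \code{genotype_matrix}.
#' @export
read_genotypes_csv <- function(path, loci = NULL, missing_code = -1L) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  codes <- as.matrix(tab[, -1L, drop = FALSE])
  genotype_matrix(codes, subject_ids = ids, loci = loci,
                  missing_code = missing_code)
}

#' Read genotypes from a VCF file
#'
#' Maps GT fields of biallelic sites to allele counts: 0/0 -> 0,
#' 0/1 or 1/0 -> 1, 1/1 -> 2, ./. -> missing. Multi-allelic sites are
#' rejected. Requires the \pkg{vcfR} package.
#'
#' @param path VCF file path.
#' @return a \code{genotype_matrix} (subjects = VCF samples).
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt))) stop("multi-allelic sites are not supported")
  gt <- vcfR::extract.gt(v, element = "GT")
  code1 <- function(g) {
    if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1L]]
    if (length(al) != 2L || !all(al %in% c("0", "1"))) {
      stop("unsupported GT field: ", g)
    }
    sum(al == "1")
  }
  codes <- t(apply(gt, c(1L, 2L), code1))
  ids <- vcfR::getID(v)
  if (anyNA(ids)) ids <- paste0("L", seq_along(ids))
  colnames(codes) <- ids
  genotype_matrix(codes, subject_ids = rownames(codes))
}

#' Observed heterozygosity of a group of subjects
#'
#' The observed frequency of heterozygotes averaged over loci,
#' \eqn{H_O = (1/l) \sum_j h_j}, where \eqn{h_j} is the proportion of
#' heterozygous calls at locus \eqn{j} among the non-missing calls of
#' the group, expressed as a percentage in [0, 100]. Loci with no
#' callable genotype in the group are dropped from the average.
#'
#' @param geno a \code{genotype_matrix}.
#' @param subject_subset optional character vector of subject ids (or
#'   logical/integer row index); default all subjects.
#' @param locus_class optional filter, \code{"intragenic"} or
#'   \code{"intergenic"}; default uses the pooled locus set.
#' @return list with \code{value} (percent), \code{n_subjects} and
#'   \code{n_loci_used}, of class \code{heterozygosity_value}.
#' @export
observed_heterozygosity <- function(geno, subject_subset = NULL,
                                    locus_class = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  codes <- geno$codes
  if (!is.null(locus_class)) {
    if (is.null(geno$loci$class)) stop("no locus class metadata available")
    codes <- codes[, geno$loci$class %in% locus_class, drop = FALSE]
  }
  if (!is.null(subject_subset)) {
    if (is.character(subject_subset)) {
      miss <- setdiff(subject_subset, geno$subject_ids)
      if (length(miss)) stop("unknown subject ids: ",
                             paste(miss, collapse = ", "))
      codes <- codes[match(subject_subset, geno$subject_ids), ,
                     drop = FALSE]
    } else {
      codes <- codes[subject_subset, , drop = FALSE]
    }
  }
  if (nrow(codes) == 0L) stop("no subjects")
  n_called <- colSums(!is.na(codes))
  used <- n_called > 0L
  if (!any(used)) stop("no callable loci")
  h_j <- colSums(codes[, used, drop = FALSE] == 1L, na.rm = TRUE) /
    n_called[used]
  structure(list(value = 100 * mean(h_j),
                 n_subjects = nrow(codes),
                 n_loci_used = sum(used)),
            class = "heterozygosity_value")
}

#' @export
print.heterozygosity_value <- function(x, ...) {
  cat(sprintf("H_O = %.4f%% (%d subjects, %d loci)\n",
              x$value, x$n_subjects, x$n_loci_used))
  invisible(x)
}

#' Observed heterozygosity per land unit
#'
#' Applies [observed_heterozygosity()] separately to the members of each
#' land unit, optionally after filtering subjects (e.g. natives only).
#' Units with no filtered member get NA, not zero.
#'
#' @param geno a \code{genotype_matrix}.
#' @param membership named character vector or data.frame
#'   (\code{subject_id}, \code{unit_id}) mapping subjects to land units.
#' @param subject_filter optional character vector of subject ids to
#'   keep, or a predicate function applied to subject ids.
#' @param units optional vector of unit ids fixing the output order;
#'   defaults to the units present in \code{membership}.
#' @return data.frame with one row per unit: \code{unit_id},
#'   \code{H_O}, \code{n_subjects}, \code{n_loci_used}.
#' @export
per_unit_heterozygosity <- function(geno, membership, subject_filter = NULL,
                                    units = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (is.data.frame(membership)) {
    membership <- stats::setNames(as.character(membership$unit_id),
                                  as.character(membership$subject_id))
  }
  ids <- names(membership)
  if (is.null(ids)) stop("membership must map subject ids to unit ids")
  if (!is.null(subject_filter)) {
    keep <- if (is.function(subject_filter)) {
      vapply(ids, subject_filter, FALSE)
    } else {
      ids %in% subject_filter
    }
    membership <- membership[keep]
    ids <- ids[keep]
  }
  miss <- setdiff(ids, geno$subject_ids)
  if (length(miss)) stop("membership refers to unknown subjects: ",
                         paste(utils::head(miss, 3L), collapse = ", "))
  if (is.null(units)) units <- unique(unname(membership))
  unknown <- setdiff(unname(membership), units)
  if (length(unknown)) stop("membership refers to unknown units: ",
                            paste(unknown, collapse = ", "))
  res <- data.frame(unit_id = as.character(units),
                    H_O = NA_real_, n_subjects = 0L,
                    n_loci_used = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(units)) {
    members <- ids[membership == units[i]]
    if (length(members) == 0L) next
    h <- observed_heterozygosity(geno, subject_subset = members)
    res$H_O[i] <- h$value
    res$n_subjects[i] <- h$n_subjects
    res$n_loci_used[i] <- h$n_loci_used
  }
  res
}
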