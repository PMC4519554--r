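# shared fixtures built in code

# binary weights of a path graph 1-2-...-n
path_weights <- function(n) {
  W <- matrix(0, n, n)
  W[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- 1
  spatial_weights(W + t(W))
}

# binary rook-contiguity weights of a k x k lattice
lattice_weights <- function(k) {
  n <- k * k
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    r <- (i - 1L) %/% k
    c0 <- (i - 1L) %% k
    if (c0 < k - 1L) { W[i, i + 1L] <- 1; W[i + 1L, i] <- 1 }
    if (r < k - 1L) { W[i, i + k] <- 1; W[i + k, i] <- 1 }
  }
  spatial_weights(W)
}

# binary weights of an n-cycle (degree-regular, so row standardization
# only rescales: usable for cross-checks against ape::Moran.I)
cycle_weights <- function(n) {
  W <- matrix(0, n, n)
  W[cbind(seq_len(n), c(2:n, 1L))] <- 1
  spatial_weights(W + t(W))
}

unit_square <- function(x0 = 0, y0 = 0, side = 1) {
  matrix(c(x0, y0, x0 + side, y0, x0 + side, y0 + side, x0, y0 + side),
         ncol = 2, byrow = TRUE)
}

# the schematic cohort region with the published contiguity repairs:
# Schwabmuenchen(13)-Bobingen(7), Aichach(2)-Friedberg(4),
# Poettmes(5)-Aichach(2); Altenmuenster(11) falls out as isolate
study_contiguity <- function(region = augsburg_fixture()$region) {
  suppressMessages(build_contiguity(
    region,
    connect_pairs = rbind(c("13", "7"), c("2", "4"), c("5", "2"))))
}

# Moran's I via the raw double sum -- independent of the package's
# quadratic-form implementation
moran_bruteforce <- function(x, w) {
  n <- length(x)
  z <- x - mean(x)
  acc <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) acc <- acc + w$W[i, j] * z[i] * z[j]
  }
  (n / w$S0) * acc / sum(z^2)
}

# exhaustive permutation distribution of Moran's I (n <= 7)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

exhaustive_moran <- function(x, w) {
  perms <- all_permutations(length(x))
  apply(perms, 1L, function(p) moran_bruteforce(x[p], w))
}

# genotype fixture: explicit code matrix
geno_from <- function(codes, ...) {
  genotype_matrix(as.matrix(codes), ...)
}
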