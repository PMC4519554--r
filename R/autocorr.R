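align_values <- function(x, w) {
  if (!is.null(names(x))) {
    miss <- setdiff(w$ids, names(x))
    if (length(miss)) stop("values missing for units: ",
                           paste(miss, collapse = ", "))
    x <- x[w$ids]
  }
  if (length(x) != length(w$ids)) {
    stop("values must match the number of weighted units")
  }
  if (anyNA(x) || any(!is.finite(x))) stop("values must be finite")
  as.numeric(x)
}

moran_stat <- function(z, W, S0) {
  n <- length(z)
  (n / S0) * sum(z * (W %*% z)) / sum(z^2)
}

#' Global Moran's I statistic
#'
#' \eqn{I = (n/S_0) \sum_{ij} w_{ij} z_i z_j / \sum_i z_i^2} with
#' \eqn{z_i = x_i - \bar x}, on binary (non-row-standardized) weights.
#'
#' @param x per-unit values; if named they are aligned to the weight
#'   ids.
#' @param w a \code{spatial_weights} object.
#' @return the statistic (numeric scalar).
#' @export
morans_i <- function(x, w) {
  stopifnot(inherits(w, "spatial_weights"))
  x <- align_values(x, w)
  z <- x - mean(x)
  if (sum(z^2) == 0) stop("zero variance: constant values")
  moran_stat(z, w$W, w$S0)
}

#' Moran's I test under the randomization assumption
#'
#' Analytic one-sided test of global spatial autocorrelation. The
#' variance uses the Cliff-Ord randomization formula, which relaxes
#' the normality assumption through a correction term based on the
#' sample kurtosis \eqn{b_2 = n \sum z_i^4 / (\sum z_i^2)^2}:
#' \deqn{Var(I) = \frac{n[(n^2-3n+3)S_1 - nS_2 + 3S_0^2] -
#'   b_2[(n^2-n)S_1 - 2nS_2 + 6S_0^2]}{(n-1)(n-2)(n-3)S_0^2} -
#'   \frac{1}{(n-1)^2}}
#' with expectation \eqn{E[I] = -1/(n-1)}.
#'
#' @param x per-unit values.
#' @param w a \code{spatial_weights} object.
#' @param alternative \code{"greater"} (default), \code{"less"} or
#'   \code{"two.sided"}.
#' @return object of class \code{moran_result} with fields \code{I},
#'   \code{expected}, \code{variance}, \code{z}, \code{p_analytic}.
#' @export
moran_randomization_test <- function(x, w, alternative = c("greater",
                                                           "less",
                                                           "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(w, "spatial_weights"))
  x <- align_values(x, w)
  n <- length(x)
  if (n < 4L) stop("randomization variance needs at least 4 units")
  zc <- x - mean(x)
  s2 <- sum(zc^2)
  if (s2 == 0) stop("zero variance: constant values")
  I <- moran_stat(zc, w$W, w$S0)
  EI <- -1 / (n - 1)
  b2 <- n * sum(zc^4) / s2^2
  S0 <- w$S0; S1 <- w$S1; S2 <- w$S2
  VI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
           b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  zstat <- (I - EI) / sqrt(VI)
  p <- switch(alternative,
              greater = stats::pnorm(zstat, lower.tail = FALSE),
              less = stats::pnorm(zstat),
              two.sided = 2 * stats::pnorm(abs(zstat), lower.tail = FALSE))
  structure(list(I = I, expected = EI, variance = VI, z = zstat,
                 p_analytic = p, p_permutation = NULL, nsim = NULL,
                 alternative = alternative, n = n),
            class = "moran_result")
}

#' Monte-Carlo permutation test for Moran's I
#'
#' Observed values are randomly reassigned to the areal units
#' \code{nsim} times and the statistic recomputed; the p-value uses
#' the never-zero convention \eqn{p = (1 + m)/(nsim + 1)}, where m
#' counts simulated statistics at least as extreme as the observed one
#' (for the default "greater" alternative, \eqn{I_{sim} \ge I_{obs}}).
#'
#' @param x per-unit values.
#' @param w a \code{spatial_weights} object.
#' @param nsim number of permutations (>= 99; the study default is
#'   10000).
#' @param seed optional integer for reproducibility.
#' @param alternative \code{"greater"} (default), \code{"less"} or
#'   \code{"two.sided"}.
#' @return object of class \code{moran_result} including
#'   \code{p_permutation} and \code{nsim}.
#' @export
moran_permutation_test <- function(x, w, nsim = 10000, seed = NULL,
                                   alternative = c("greater", "less",
                                                   "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(w, "spatial_weights"))
  if (nsim < 99) stop("nsim must be at least 99")
  x <- align_values(x, w)
  n <- length(x)
  z <- x - mean(x)
  if (sum(z^2) == 0) stop("zero variance: constant values")
  I_obs <- moran_stat(z, w$W, w$S0)
  if (!is.null(seed)) set.seed(seed)
  perm <- replicate(nsim, sample.int(n))
  Z <- matrix(z[perm], n, nsim)
  # columnwise Moran statistics in one pass
  I_sim <- (n / w$S0) * colSums(Z * (w$W %*% Z)) / sum(z^2)
  m <- switch(alternative,
              greater = sum(I_sim >= I_obs),
              less = sum(I_sim <= I_obs),
              two.sided = sum(abs(I_sim - mean(I_sim)) >=
                                abs(I_obs - mean(I_sim))))
  p_perm <- (1 + m) / (nsim + 1)
  structure(list(I = I_obs, expected = -1 / (n - 1),
                 variance = stats::var(I_sim), z = NULL,
                 p_analytic = NULL, p_permutation = p_perm, nsim = nsim,
                 alternative = alternative, n = n),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f, n = %d)\n",
              x$I, x$expected, x$n))
  if (!is.null(x$p_analytic)) {
    cat(sprintf("  randomization: Var = %.5f, z = %.3f, p = %.4f (%s)\n",
                x$variance, x$z, x$p_analytic, x$alternative))
  }
  if (!is.null(x$p_permutation)) {
    cat(sprintf("  permutation: p = %.4f (nsim = %d, %s)\n",
                x$p_permutation, x$nsim, x$alternative))
  }
  invisible(x)
}

#' Moran's I test table over several variables
#'
#' Convenience wrapper producing one row per column: the statistic,
#' the analytic randomization p-value and the permutation p-value.
#'
#' @param table data.frame of per-unit variables, rows aligned (or
#'   named) to the weight ids; a \code{unit_id} column is used for
#'   alignment when present.
#' @param w a \code{spatial_weights} object.
#' @param nsim permutations per variable (default 10000).
#' @param seed optional integer seed.
#' @param alternative passed to the two tests.
#' @return data.frame with columns \code{variable}, \code{I},
#'   \code{p_analytic}, \code{p_permutation}.
#' @export
moran_table <- function(table, w, nsim = 10000, seed = NULL,
                        alternative = "greater") {
  table <- as.data.frame(table)
  rows <- if (!is.null(table$unit_id)) {
    match(w$ids, as.character(table$unit_id))
  } else {
    seq_along(w$ids)
  }
  if (anyNA(rows)) stop("table lacks rows for some weighted units")
  vars <- setdiff(names(table)[vapply(table, is.numeric, FALSE)],
                  c("N_ALL", "N_NATIVE", "N_IMG", "N_MAIN_IMG"))
  if (!is.null(seed)) set.seed(seed)
  out <- data.frame(variable = vars, I = NA_real_, p_analytic = NA_real_,
                    p_permutation = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(vars)) {
    v <- table[[vars[i]]][rows]
    if (anyNA(v)) next
    rt <- moran_randomization_test(v, w, alternative = alternative)
    pt <- moran_permutation_test(v, w, nsim = nsim,
                                 alternative = alternative)
    out$I[i] <- rt$I
    out$p_analytic[i] <- rt$p_analytic
    out$p_permutation[i] <- pt$p_permutation
  }
  out
}
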