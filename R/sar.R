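build_design <- function(X, n) {
  if (is.null(X)) {
    Xm <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
    return(Xm)
  }
  X <- as.data.frame(X)
  Xm <- cbind("(Intercept)" = 1, as.matrix(X))
  if (nrow(Xm) != n) stop("design rows must match the response length")
  if (anyNA(Xm)) stop("design matrix contains missing values")
  if (qr(Xm)$rank < ncol(Xm)) stop("singular design matrix")
  Xm
}

# profile pieces at a fixed lambda: GLS beta, sigma2 and log-likelihood
sar_profile <- function(lambda, y, Xm, W, omega) {
  n <- length(y)
  A <- diag(n) - lambda * W
  Ay <- A %*% y
  AX <- A %*% Xm
  qrAX <- qr(AX)
  beta <- qr.coef(qrAX, Ay)
  res <- Ay - AX %*% beta
  sigma2 <- sum(res^2) / n
  logdet <- sum(log(1 - lambda * omega))
  ll <- -n / 2 * log(2 * pi * sigma2) + logdet - n / 2
  list(beta = drop(beta), sigma2 = sigma2, loglik = ll, A = A, AX = AX)
}

#' Fit a simultaneous autoregressive (SAR) error model
#'
#' Maximum-likelihood fit of \eqn{y = X\beta + u}, \eqn{u = \lambda W u
#' + \epsilon}, \eqn{\epsilon \sim N(0, \sigma^2 I)} on binary spatial
#' weights. The spatial parameter is found by bounded scalar search of
#' the profile log-likelihood
#' \eqn{LL(\lambda) = -(n/2)\ln(2\pi\hat\sigma^2(\lambda)) +
#' \ln|I-\lambda W| - n/2}, with the log-determinant computed from the
#' eigenvalues \eqn{\omega_k} of W as \eqn{\sum_k \ln(1-\lambda
#' \omega_k)}; the feasible interval is \eqn{(1/\omega_{min},
#' 1/\omega_{max})}. Covariate p-values are Wald z-tests from the ML
#' covariance conditional on \eqn{\hat\lambda}; the likelihood-ratio
#' test compares against the model with no spatial autocorrelation
#' (\eqn{\lambda = 0}).
#'
#' @param y per-unit response (named vectors are aligned to the weight
#'   ids).
#' @param X data.frame/matrix of covariate columns (no intercept
#'   column; one is added), or NULL for the intercept-only model.
#' @param w a \code{spatial_weights} object.
#' @param lambda optional fixed value of the spatial parameter; when
#'   given the profile search is skipped (lambda = 0 reproduces the
#'   OLS fit).
#' @return object of class \code{sar_fit}: \code{beta}, \code{se},
#'   \code{beta_z}, \code{beta_p}, \code{lambda}, \code{sigma2},
#'   \code{loglik}, \code{loglik_null}, \code{lr_stat}, \code{lr_p},
#'   \code{trend} (\eqn{X\hat\beta}), \code{fitted}
#'   (\eqn{X\hat\beta + \hat\lambda W(y - X\hat\beta)}),
#'   \code{residuals}, \code{interval}.
#' @export
fit_sar_error <- function(y, X = NULL, w, lambda = NULL) {
  stopifnot(inherits(w, "spatial_weights"))
  y <- align_values(y, w)
  n <- length(y)
  Xm <- build_design(X, n)
  if (n < ncol(Xm) + 2L) stop("too few units for this many covariates")
  W <- w$W
  omega <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
  if (max(omega) <= 0 || min(omega) >= 0) stop("degenerate weight spectrum")
  eps <- 1e-6
  lo <- 1 / min(omega) + eps
  hi <- 1 / max(omega) - eps
  if (is.null(lambda)) {
    opt <- stats::optimize(function(l) sar_profile(l, y, Xm, W, omega)$loglik,
                           interval = c(lo, hi), maximum = TRUE,
                           tol = .Machine$double.eps^0.5)
    lambda <- opt$maximum
    if (min(lambda - lo, hi - lambda) < 1e-4 * (hi - lo)) {
      warning("lambda estimate at the feasible-interval boundary")
    }
  } else if (lambda != 0 && (lambda <= lo || lambda >= hi)) {
    stop("fixed lambda outside the feasible interval")
  }
  at <- sar_profile(lambda, y, Xm, W, omega)
  null <- sar_profile(0, y, Xm, W, omega)
  # Wald tests from the ML covariance conditional on lambda-hat
  XtSX <- crossprod(at$AX)
  vcov_beta <- at$sigma2 * solve(XtSX)
  se <- sqrt(diag(vcov_beta))
  zstat <- at$beta / se
  pval <- 2 * stats::pnorm(abs(zstat), lower.tail = FALSE)
  lr_stat <- 2 * (at$loglik - null$loglik)
  lr_p <- stats::pchisq(max(lr_stat, 0), df = 1L, lower.tail = FALSE)
  trend <- drop(Xm %*% at$beta)
  fitted <- trend + lambda * drop(W %*% (y - trend))
  structure(list(beta = at$beta, se = se, beta_z = zstat, beta_p = pval,
                 lambda = lambda, sigma2 = at$sigma2,
                 loglik = at$loglik, loglik_null = null$loglik,
                 lr_stat = lr_stat, lr_p = lr_p,
                 trend = stats::setNames(trend, w$ids),
                 fitted = stats::setNames(fitted, w$ids),
                 residuals = stats::setNames(y - trend, w$ids),
                 interval = c(lo, hi), n = n,
                 covariates = setdiff(colnames(Xm), "(Intercept)"),
                 vcov = vcov_beta),
            class = "sar_fit")
}

#' @export
print.sar_fit <- function(x, ...) {
  cat("SAR error model (maximum likelihood)\n")
  cat(sprintf("  lambda = %.4f, LR test vs lambda=0: p = %.4f\n",
              x$lambda, x$lr_p))
  cat(sprintf("  sigma2 = %.4f, logLik = %.3f (null %.3f)\n",
              x$sigma2, x$loglik, x$loglik_null))
  tab <- data.frame(beta = x$beta, se = x$se, z = x$beta_z, p = x$beta_p)
  print(round(tab, 4))
  invisible(x)
}

#' Format a fitted model as a one-line formula string
#'
#' Intercept followed by "name (coefficient)" terms, the presentation
#' used in reported model tables.
#'
#' @param fit a \code{sar_fit}.
#' @param digits coefficient digits (default 3).
#' @return character scalar.
#' @export
format_sar_formula <- function(fit, digits = 3) {
  terms <- fit$beta[names(fit$beta) != "(Intercept)"]
  paste(c(sprintf("%.*f", digits, fit$beta[["(Intercept)"]]),
          sprintf("%s (%.*f)", names(terms), digits, terms)),
        collapse = " + ")
}

#' Forward search of SAR covariate models
#'
#' Greedy forward selection starting from the intercept model: at each
#' step the candidate with the smallest Wald p-value in the refit is
#' added, up to \code{max_terms} covariates. Every visited model whose
#' included covariates are all significant at \code{alpha} is
#' retained; an empty retained list is a valid outcome.
#'
#' @param y per-unit response.
#' @param data data.frame of candidate covariate columns (rows aligned
#'   or named by \code{unit_id} to the weight ids).
#' @param candidates character vector of column names to search over
#'   (aliases such as EA55_74/BILD_MN are resolved).
#' @param w a \code{spatial_weights} object.
#' @param alpha per-covariate significance threshold (default 0.05).
#' @param max_terms maximum number of covariates (default 4).
#' @return object of class \code{sar_forward} with \code{visited} and
#'   \code{retained} lists; each element has \code{covariates},
#'   \code{fit}, \code{admissible}.
#' @export
forward_search <- function(y, data, candidates, w, alpha = 0.05,
                           max_terms = 4L) {
  stopifnot(inherits(w, "spatial_weights"))
  data <- as.data.frame(data)
  if (!is.null(data$unit_id)) {
    rows <- match(w$ids, as.character(data$unit_id))
    if (anyNA(rows)) stop("data lacks rows for some weighted units")
    data <- data[rows, , drop = FALSE]
  }
  candidates <- resolve_covariate_names(candidates)
  miss <- setdiff(candidates, names(data))
  if (length(miss)) stop("unknown candidate columns: ",
                         paste(miss, collapse = ", "))
  current <- character(0)
  visited <- list()
  repeat {
    if (length(current) >= max_terms) break
    pool <- setdiff(candidates, current)
    if (length(pool) == 0L) break
    trials <- lapply(pool, function(cand) {
      vars <- c(current, cand)
      fit <- try(fit_sar_error(y, data[, vars, drop = FALSE], w),
                 silent = TRUE)
      if (inherits(fit, "try-error")) return(NULL)
      list(cand = cand, vars = vars, fit = fit,
           p_cand = fit$beta_p[[cand]])
    })
    trials <- Filter(Negate(is.null), trials)
    if (length(trials) == 0L) break
    best <- trials[[which.min(vapply(trials, function(t) t$p_cand, 0))]]
    pcov <- best$fit$beta_p[best$vars]
    visited[[length(visited) + 1L]] <-
      list(covariates = best$vars, fit = best$fit,
           admissible = all(pcov < alpha))
    current <- best$vars
  }
  retained <- Filter(function(m) m$admissible, visited)
  structure(list(visited = visited, retained = retained,
                 alpha = alpha, max_terms = max_terms),
            class = "sar_forward")
}

#' @export
print.sar_forward <- function(x, ...) {
  cat(sprintf("forward search: %d visited, %d retained (alpha = %g)\n",
              length(x$visited), length(x$retained), x$alpha))
  for (m in x$retained) {
    cat(sprintf("  %s | lambda = %.3f, LR p = %.3f\n",
                format_sar_formula(m$fit), m$fit$lambda, m$fit$lr_p))
  }
  invisible(x)
}

#' Summarize retained models as a table
#'
#' @param search a \code{sar_forward} object.
#' @return data.frame with one row per retained model: \code{model},
#'   \code{formula}, \code{lambda}, \code{lr_p}, \code{loglik},
#'   \code{n_covariates}.
#' @export
retained_models_table <- function(search) {
  stopifnot(inherits(search, "sar_forward"))
  if (length(search$retained) == 0L) {
    return(data.frame(model = character(0), formula = character(0),
                      lambda = numeric(0), lr_p = numeric(0),
                      loglik = numeric(0), n_covariates = integer(0)))
  }
  do.call(rbind, lapply(seq_along(search$retained), function(i) {
    m <- search$retained[[i]]
    data.frame(model = paste0("m", i),
               formula = format_sar_formula(m$fit),
               lambda = m$fit$lambda, lr_p = m$fit$lr_p,
               loglik = m$fit$loglik,
               n_covariates = length(m$covariates),
               stringsAsFactors = FALSE)
  }))
}

#' Test whether an added covariate improves a model
#'
#' Refits the base model with one extra covariate. The addition
#' "improves" the model only when the extra covariate is significant
#' at \code{alpha} and every base covariate remains so.
#'
#' @param base_covariates character vector of the base model columns.
#' @param extra name of the covariate to add (must not be in the
#'   base).
#' @param y per-unit response.
#' @param data data.frame of covariate columns.
#' @param w a \code{spatial_weights} object.
#' @param alpha significance threshold (default 0.05).
#' @return list: \code{improves}, \code{p_extra},
#'   \code{delta_loglik}, \code{fit} (augmented), \code{base_fit}.
#' @export
evaluate_added_covariate <- function(base_covariates, extra, y, data, w,
                                     alpha = 0.05) {
  data <- as.data.frame(data)
  if (!is.null(data$unit_id)) {
    rows <- match(w$ids, as.character(data$unit_id))
    if (anyNA(rows)) stop("data lacks rows for some weighted units")
    data <- data[rows, , drop = FALSE]
  }
  base_covariates <- resolve_covariate_names(base_covariates)
  extra <- resolve_covariate_names(extra)
  if (extra %in% base_covariates) stop("extra covariate already in base")
  base_fit <- fit_sar_error(y, if (length(base_covariates))
    data[, base_covariates, drop = FALSE] else NULL, w)
  fit <- fit_sar_error(y, data[, c(base_covariates, extra),
                               drop = FALSE], w)
  p_all <- fit$beta_p[c(base_covariates, extra)]
  list(improves = all(p_all < alpha),
       p_extra = fit$beta_p[[extra]],
       delta_loglik = fit$loglik - base_fit$loglik,
       fit = fit, base_fit = base_fit)
}
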