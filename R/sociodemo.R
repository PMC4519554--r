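#' Read a subject table
#'
#' Expected columns: \code{subject_id}, \code{unit_id},
#' \code{birth_land} (ISO-like country code), \code{age},
#' \code{education_years}, \code{education_level}. A subject is a
#' native when \code{birth_land == native_land}; a main immigrant when
#' born in one of \code{main_immigrant_lands}.
#'
#' @param path CSV file path.
#' @param native_land country code marking natives (default "DE").
#' @param main_immigrant_lands codes of the major immigrant group
#'   (default Czech Republic, Romania, Poland, Ukraine).
#' @return data.frame of subject records with logical columns
#'   \code{native} and \code{main_immigrant} added.
#' @export
read_subjects_csv <- function(path, native_land = "DE",
                              main_immigrant_lands = c("CZ", "RO", "PL", "UA")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "unit_id", "birth_land", "age",
            "education_years", "education_level")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("subject table lacks columns: ",
                         paste(miss, collapse = ", "))
  tab$subject_id <- as.character(tab$subject_id)
  tab$unit_id <- as.character(tab$unit_id)
  tab$native <- tab$birth_land == native_land
  tab$main_immigrant <- !tab$native & tab$birth_land %in% main_immigrant_lands
  validate_subjects(tab)
}

validate_subjects <- function(subjects) {
  subjects <- as.data.frame(subjects)
  need <- c("subject_id", "unit_id", "native")
  miss <- setdiff(need, names(subjects))
  if (length(miss)) stop("subject records lack columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(subjects$main_immigrant)) subjects$main_immigrant <- FALSE
  if (any(subjects$main_immigrant & subjects$native)) {
    stop("a native subject cannot belong to the main immigrant group")
  }
  if (!is.null(subjects$age)) {
    out <- !is.na(subjects$age) &
      (subjects$age < 25 | subjects$age > 74)
    if (any(out)) warning(sum(out), " subject(s) with age outside [25, 74];",
                          " kept and banded by value")
  }
  subjects
}

#' Per-land-unit socio-demographic covariates
#'
#' Computes the land-unit covariates used for autocorrelation testing
#' and SAR model building. Age and education variables (AGE25_39,
#' AGE40_54, AGE55_74, AGE_MEAN, EY8_11, EY_MEAN, EDU_MEAN) are
#' computed on natives only; GER_P (percent natives of all subjects)
#' and MAIN_IMP (percent of the major immigrant group among all
#' immigrants) use the full per-unit sample. MAIN_IMP is defined as 0
#' for units without immigrants. Age bands are inclusive:
#' [25, 39], [40, 54], [55, 74].
#'
#' @param subjects data.frame of subject records (see
#'   [read_subjects_csv()]); must contain \code{subject_id},
#'   \code{unit_id}, \code{native}, \code{main_immigrant}, and for
#'   natives \code{age}, \code{education_years}, \code{education_level}.
#' @param units optional unit-id vector fixing the row order.
#' @param rounding \code{"full"} keeps percentages at full precision;
#'   \code{"integer"} rounds the percentage columns GER_P and MAIN_IMP
#'   to whole percent, the presentation used in the study tables.
#' @return data.frame keyed by \code{unit_id} with count columns
#'   (N_ALL, N_NATIVE, N_IMG, N_MAIN_IMG) and the covariates above.
#' @export
compute_covariates <- function(subjects, units = NULL,
                               rounding = c("full", "integer")) {
  rounding <- match.arg(rounding)
  subjects <- validate_subjects(subjects)
  if (anyNA(subjects$unit_id)) stop("every subject needs a unit id")
  if (is.null(units)) units <- unique(subjects$unit_id)
  unknown <- setdiff(subjects$unit_id, units)
  if (length(unknown)) stop("subjects mapped to unknown units: ",
                            paste(unknown, collapse = ", "))
  n <- length(units)
  tab <- data.frame(unit_id = as.character(units),
                    N_ALL = 0L, N_NATIVE = 0L, N_IMG = 0L, N_MAIN_IMG = 0L,
                    GER_P = NA_real_, MAIN_IMP = NA_real_,
                    AGE25_39 = NA_real_, AGE40_54 = NA_real_,
                    AGE55_74 = NA_real_, AGE_MEAN = NA_real_,
                    EY8_11 = NA_real_, EY_MEAN = NA_real_,
                    EDU_MEAN = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    s <- subjects[subjects$unit_id == units[i], , drop = FALSE]
    tab$N_ALL[i] <- nrow(s)
    tab$N_NATIVE[i] <- sum(s$native)
    tab$N_IMG[i] <- sum(!s$native)
    tab$N_MAIN_IMG[i] <- sum(s$main_immigrant)
    if (nrow(s) == 0L) next
    tab$GER_P[i] <- 100 * tab$N_NATIVE[i] / tab$N_ALL[i]
    tab$MAIN_IMP[i] <- if (tab$N_IMG[i] == 0L) 0 else
      100 * tab$N_MAIN_IMG[i] / tab$N_IMG[i]
    nat <- s[s$native, , drop = FALSE]
    if (nrow(nat) == 0L) next
    if (anyNA(nat$age)) stop("missing age for a native subject in unit ",
                             units[i])
    tab$AGE25_39[i] <- 100 * mean(nat$age <= 39)
    tab$AGE40_54[i] <- 100 * mean(nat$age >= 40 & nat$age <= 54)
    tab$AGE55_74[i] <- 100 * mean(nat$age >= 55)
    tab$AGE_MEAN[i] <- mean(nat$age)
    if (!is.null(nat$education_years)) {
      tab$EY8_11[i] <- 100 * mean(nat$education_years <= 11)
      tab$EY_MEAN[i] <- mean(nat$education_years)
    }
    if (!is.null(nat$education_level)) {
      tab$EDU_MEAN[i] <- mean(nat$education_level)
    }
  }
  if (rounding == "integer") {
    tab$GER_P <- round(tab$GER_P)
    tab$MAIN_IMP <- round(tab$MAIN_IMP)
  }
  tab
}

#' Descriptive statistics of a covariate table
#'
#' Mean, standard deviation (n - 1 denominator), median, minimum and
#' maximum of each numeric column, NA values excluded. Columns with
#' fewer than two values get NA for the standard deviation.
#'
#' @param table data.frame (e.g. from [compute_covariates()]).
#' @param columns columns to summarize; default all numeric columns
#'   except counts and unit ids.
#' @return data.frame with one row per variable.
#' @export
descriptive_stats <- function(table, columns = NULL) {
  table <- as.data.frame(table)
  if (is.null(columns)) {
    columns <- setdiff(names(table)[vapply(table, is.numeric, FALSE)],
                       c("N_ALL", "N_NATIVE", "N_IMG", "N_MAIN_IMG"))
  }
  out <- data.frame(variable = columns, mean = NA_real_, sd = NA_real_,
                    median = NA_real_, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(columns)) {
    v <- table[[columns[i]]]
    v <- v[!is.na(v)]
    if (length(v) == 0L) next
    out$mean[i] <- mean(v)
    out$sd[i] <- if (length(v) >= 2L) stats::sd(v) else NA_real_
    out$median[i] <- stats::median(v)
    out$min[i] <- min(v)
    out$max[i] <- max(v)
  }
  out
}

# Model-formula aliases used in reported SAR model tables
covariate_aliases <- c(BILD_MN = "EDU_MEAN", EY_MN = "EY_MEAN",
                       AGE_MN = "AGE_MEAN", EA55_74 = "AGE55_74")

#' Resolve covariate-name aliases
#'
#' Some reported model formulas use alternative tokens for the mean
#' education/age variables (BILD_MN, EY_MN, AGE_MN, EA55_74). This maps
#' them onto the canonical column names.
#'
#' @param names character vector of covariate names.
#' @return character vector of canonical names.
#' @export
resolve_covariate_names <- function(names) {
  hit <- names %in% names(covariate_aliases)
  names[hit] <- covariate_aliases[names[hit]]
  names
}
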