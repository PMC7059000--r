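# Scalar statistics reused across the pipeline, and the cohort demographic
# summaries (sex contingency, age comparison, motor-score screening).

#' Fisher r-to-z transform
#'
#' Variance-stabilizing transform `z = atanh(r)` applied to correlation
#' coefficients before parametric statistics.  Inputs at exactly +/-1 are
#' clipped to +/-(1 - 1e-7) with a warning.
#'
#' @param r correlation value(s) in `[-1, 1]`.
#' @return z value(s).
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r))) stop("non-finite correlation input")
  if (any(abs(r) >= 1)) {
    warning("correlations at +/-1 clipped before atanh")
    r <- clip_r(r)
  }
  atanh(r)
}

#' Inverse Fisher transform
#'
#' @param z Fisher-z value(s).
#' @return correlation value(s) `tanh(z)`.
#' @export
fisher_z_inv <- function(z) {
  if (any(!is.finite(z))) stop("non-finite z input")
  tanh(z)
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Pearson's chi-square with expected counts from the margins, df = 1,
#' without Yates continuity correction (the convention used for the
#' cohort sex comparison).
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return list with `chi2`, `p` and `df`.
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("`tab` must be 2x2")
  if (any(tab < 0)) stop("counts must be non-negative")
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) stop("zero margin in contingency table")
  expected <- outer(rs, cs) / n
  chi2 <- sum((tab - expected)^2 / expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       df = 1L)
}

#' Pooled-variance two-sample t test
#'
#' Classic Student t with pooled variance, two-sided,
#' df = `length(a) + length(b) - 2`.
#'
#' @param a,b numeric samples (each of length >= 2).
#' @return list with `t`, `p` and `df`.
#' @export
two_sample_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each sample needs at least 2 values")
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  if (sp2 <= 0) stop("zero pooled variance")
  tval <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tval, p = 2 * stats::pt(-abs(tval), df = df), df = df)
}

#' Read a cohort demographics table
#'
#' Reads a TSV with at least the columns `id`, `gender`, `age`, `we_fmt`
#' (case-insensitive).  The packaged patient table is available via
#' `system.file("extdata", "patient_demographics.tsv", package = "parcelfc")`.
#'
#' @param path TSV file path.
#' @return data.frame with lower-case column names.
#' @export
read_demographics <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  if ("id" %in% names(tab)) tab$id <- as.character(tab$id)
  tab
}

#' Demographic summary of a patient cohort table
#'
#' Computes the descriptive statistics used for cohort screening: mean age
#' (reported at one decimal), age range, sex counts, the minimum
#' whole-extremity motor score, and the number of subjects passing the
#' `we_fmt > 90` well-recovered inclusion criterion.
#'
#' @param tab data.frame with columns `gender` (F/M), `age`, `we_fmt`.
#' @return list of summaries.
#' @export
demographics_summary <- function(tab) {
  if (nrow(tab) == 0) stop("empty demographics table")
  need <- c("gender", "age", "we_fmt")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(tab$age <= 0)) stop("ages must be positive")
  list(
    n = nrow(tab),
    mean_age = round(mean(tab$age), 1),
    age_range = range(tab$age),
    sex_counts = c(F = sum(tab$gender == "F"), M = sum(tab$gender == "M")),
    min_we_fmt = min(tab$we_fmt),
    n_pass_inclusion = sum(tab$we_fmt > 90)
  )
}

#' Partial correlation controlling for age and sex
#'
#' Pearson correlation between the residuals of the two variables after
#' regressing each on `[1, age, sex]`; the p-value uses a t reference with
#' `n - 4` degrees of freedom.  Used to relate connectivity values to
#' clinical motor scores; note that near-ceiling motor scores carry almost
#' no variance, in which case a clear error is raised.
#'
#' @param x,y numeric vectors (e.g. connectivity values and motor scores).
#' @param age,sex nuisance covariates (sex coded 0/1).
#' @return list with `r_partial`, `p`, `df`.
#' @export
partial_corr <- function(x, y, age, sex) {
  n <- length(x)
  if (length(y) != n || length(age) != n || length(sex) != n)
    stop("all inputs must have equal length")
  if (n < 5) stop("need at least 5 observations")
  if (stats::var(y) == 0)
    stop("scores have zero variance (all values identical, e.g. at ceiling); ",
         "partial correlation is undefined")
  if (stats::var(x) == 0) stop("connectivity values have zero variance")
  X <- cbind(1, age, sex)
  if (qr(X)$rank < ncol(X)) stop("covariate matrix is rank-deficient")
  rx <- stats::lm.fit(X, x)$residuals
  ry <- stats::lm.fit(X, y)$residuals
  r <- stats::cor(rx, ry)
  df <- n - 4
  tval <- r * sqrt(df / (1 - r^2))
  list(r_partial = r, p = 2 * stats::pt(-abs(tval), df = df), df = df)
}
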