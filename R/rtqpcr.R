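#' Delta-delta-Ct relative quantification
#'
#' Fold change of a target transcript in a sample relative to a calibrator
#' sample, both normalized to a reference gene:
#' `fold = efficiency^-((ct_target_sample - ct_ref_sample) -
#' (ct_target_calibrator - ct_ref_calibrator))`.  This implements the
#' normalization used for promoter antisense transcripts (reference mRNA
#' such as cytochrome b or beta-actin; calibrator = untreated cells or the
#' time-0 sample).
#'
#' @param ct_target_sample,ct_ref_sample Ct of target and reference gene in
#'   the sample of interest.
#' @param ct_target_calibrator,ct_ref_calibrator Ct of target and reference
#'   gene in the calibrator sample.
#' @param efficiency Amplification base per cycle.
#' @return Fold change (numeric, vectorized).
#' @examples
#' ddct(20, 18, 22, 18)  # two cycles earlier than calibrator: fold 4
#' @export
ddct <- function(ct_target_sample, ct_ref_sample,
                 ct_target_calibrator, ct_ref_calibrator, efficiency = 2) {
  args <- list(ct_target_sample, ct_ref_sample,
               ct_target_calibrator, ct_ref_calibrator)
  if (any(vapply(args, function(x) length(x) == 0L || anyNA(x), logical(1)))) {
    stopf("all four Ct values are required")
  }
  if (any(efficiency <= 0)) stopf("'efficiency' must be > 0")
  dd <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  efficiency^(-dd)
}

#' Relative levels for a table of Ct measurements
#'
#' Applies [ddct()] over a long-format Ct table, normalizing each target to
#' a reference gene and a calibrator sample (replicates are averaged on the
#' Ct scale first).
#'
#' @param ct_table Data frame with columns `target`, `sample`, `ct` and
#'   optionally `replicate`.
#' @param reference_gene Name (in `target`) of the reference mRNA.
#' @param calibrator Name (in `sample`) of the calibrator sample.
#' @param efficiency Amplification base.
#' @return A data frame of `target`, `sample`, `fold_change`; the
#'   calibrator sample's own fold change is exactly 1.
#' @export
relative_quant <- function(ct_table, reference_gene, calibrator,
                           efficiency = 2) {
  stopifnot(all(c("target", "sample", "ct") %in% names(ct_table)))
  if (!reference_gene %in% ct_table$target) {
    stopf("reference gene '%s' absent from table", reference_gene)
  }
  if (!calibrator %in% ct_table$sample) {
    stopf("calibrator sample '%s' absent from table", calibrator)
  }
  mct <- aggregate(ct ~ target + sample, data = ct_table, FUN = mean)
  ref <- mct[mct$target == reference_gene, ]
  refct <- setNames(ref$ct, ref$sample)
  out <- mct[mct$target != reference_gene, ]
  out$fold_change <- ddct(out$ct, refct[out$sample],
                          mct$ct[match(paste(out$target, calibrator),
                                       paste(mct$target, mct$sample))],
                          refct[calibrator], efficiency)
  rownames(out) <- NULL
  out[, c("target", "sample", "fold_change")]
}

#' Fit a single-exponential decay to a qPCR time course
#'
#' Models relative transcript level as `exp(-k t)` with the intercept
#' constrained to 1 at time 0 and fits `k` by least squares on log levels
#' (`k = -sum(t log y) / sum(t^2)`), matching a multiplicative noise
#' assumption.  Levels are first normalized to the time-0 measurement;
#' non-positive levels are excluded with a flag.
#'
#' @param levels Relative levels at `times`.
#' @param times Times in minutes; must include 0.
#' @param transcript,condition Labels stored with the fit.
#' @param min_points Minimum number of usable (positive) points, including
#'   time 0.
#' @return An object of class `decay_fit` with components `k` (per minute),
#'   `half_life` (minutes; `Inf` when `k = 0`), `times_used`, `residuals`
#'   (log scale), `fitted`, `excluded` (times dropped as non-positive) and
#'   labels.  Methods: `print`, `coef`, `predict`, `residuals`.
#' @examples
#' f <- fit_decay(exp(-log(2) / 30 * c(0, 20, 40, 60)), c(0, 20, 40, 60))
#' f$half_life  # 30
#' @export
fit_decay <- function(levels, times = c(0, 20, 40, 60),
                      transcript = NA_character_, condition = NA_character_,
                      min_points = 3L) {
  if (length(levels) != length(times)) stopf("'levels' and 'times' differ")
  if (!0 %in% times) stopf("'times' must include time 0")
  if (any(times < 0)) stopf("negative time")
  i0 <- which(times == 0)[1]
  if (is.na(levels[i0]) || levels[i0] <= 0) {
    stopf("level at time 0 must be positive")
  }
  y <- levels / levels[i0]
  usable <- !is.na(y) & y > 0
  excluded <- times[!usable]
  if (sum(usable) < min_points) {
    stopf("fewer than %d usable positive time points", min_points)
  }
  t_fit <- times[usable & times > 0]
  y_fit <- y[usable & times > 0]
  k <- -sum(t_fit * log(y_fit)) / sum(t_fit^2)
  fitted <- exp(-k * t_fit)
  resid <- log(y_fit) - log(fitted)
  structure(list(
    k = k,
    half_life = if (k > 0) log(2) / k else if (k == 0) Inf else NA_real_,
    times_used = times[usable], levels_used = y[usable],
    fitted = fitted, residuals = resid, excluded = excluded,
    transcript = transcript, condition = condition
  ), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "exponential decay fit%s: k = %.4g /min, half-life = %.3g min (RMS log-residual %.3g)\n",
    if (is.na(x$transcript)) "" else
      sprintf(" [%s, %s]", x$transcript, x$condition),
    x$k, x$half_life, sqrt(mean(x$residuals^2))))
  if (length(x$excluded)) {
    cat("  excluded non-positive levels at t =",
        paste(x$excluded, collapse = ", "), "min\n")
  }
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) c(k = object$k)

#' @export
residuals.decay_fit <- function(object, ...) object$residuals

#' @export
predict.decay_fit <- function(object, times = object$times_used, ...) {
  exp(-object$k * times)
}

#' Compare turnover between two decay fits
#'
#' Rate ratio `k_a / k_b` with the convention that a ratio below 1 means
#' condition `a` degrades more slowly (e.g. aRNA stabilization by CPT).
#'
#' @param fit_a,fit_b `decay_fit` objects for the same transcript and time
#'   grid.
#' @param tol Relative tolerance for the `"equal"` verdict.
#' @return List with `ratio` (`NA` when `k_b` is 0), `verdict`
#'   (`"slower"`, `"faster"`, `"equal"` or `"undefined"`) and the two rates.
#' @export
compare_turnover <- function(fit_a, fit_b, tol = 1e-9) {
  stopifnot(inherits(fit_a, "decay_fit"), inherits(fit_b, "decay_fit"))
  ka <- fit_a$k; kb <- fit_b$k
  if (kb == 0) {
    return(list(ratio = NA_real_, verdict = "undefined", k_a = ka, k_b = kb))
  }
  ratio <- ka / kb
  verdict <- if (abs(ratio - 1) <= tol) "equal" else
    if (ratio < 1) "slower" else "faster"
  list(ratio = ratio, verdict = verdict, k_a = ka, k_b = kb)
}
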