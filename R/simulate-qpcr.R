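#' Simulate a DRIVE qPCR fixture with planted enrichments
#'
#' Emulates the DRIVE measurement design: each sample is split into an
#' input aliquot, an immunoprecipitated aliquot (IP) and an aliquot treated
#' with RNase H1 before precipitation (the hybrid-specific background).
#' Input-relative recoveries are constructed additively so that
#' `IP - IP_RNaseH` recovers the planted enrichment in expectation, with the
#' RNase H1 aliquot's mean equal to `background`.
#'
#' @param true_enrichment Either a named numeric vector (one enrichment per
#'   amplicon, single condition) or a data frame with columns `amplicon`,
#'   `condition`, `enrichment` (percent-of-input units, >= 0).
#' @param background Mean recovery (percent of input) of the RNase
#'   H1-pretreated aliquot.
#' @param noise_sd Gaussian noise SD (percent of input) added independently
#'   to each aliquot measurement.
#' @param n_reps Number of independent experiments (>= 1).
#' @param condition Condition label used when `true_enrichment` is a vector.
#' @param seed Integer seed.
#' @return A `qpcr_fixture` data frame of class `drive` with columns
#'   `experiment`, `amplicon`, `condition`, `aliquot`
#'   (`input`/`IP`/`IP_RNaseH`), `percent_input`; the planted parameters are
#'   attached as the `truth` attribute.
#' @export
simulate_drive_fixture <- function(true_enrichment, background = 0.5,
                                   noise_sd = 0.1, n_reps = 3L,
                                   condition = "untreated", seed = 1L) {
  if (is.null(dim(true_enrichment))) {
    if (is.null(names(true_enrichment))) {
      stopf("'true_enrichment' vector must be named by amplicon")
    }
    plan <- data.frame(amplicon = names(true_enrichment),
                       condition = condition,
                       enrichment = as.numeric(true_enrichment),
                       stringsAsFactors = FALSE)
  } else {
    plan <- as.data.frame(true_enrichment, stringsAsFactors = FALSE)
    stopifnot(all(c("amplicon", "condition", "enrichment") %in% names(plan)))
  }
  if (any(plan$enrichment < 0)) stopf("enrichments must be >= 0")
  if (background < 0) stopf("'background' must be >= 0")
  n_reps <- as.integer(n_reps)
  if (n_reps < 1L) stopf("'n_reps' must be >= 1")
  with_seed(seed, {
    cells <- plan[rep(seq_len(nrow(plan)), each = n_reps), ]
    cells$experiment <- sprintf("exp%d", rep(seq_len(n_reps), nrow(plan)))
    n <- nrow(cells)
    ip <- pmax(0, cells$enrichment + background + rnorm(n, sd = noise_sd))
    bg <- pmax(0, background + rnorm(n, sd = noise_sd))
    out <- rbind(
      data.frame(experiment = cells$experiment, amplicon = cells$amplicon,
                 condition = cells$condition, aliquot = "input",
                 percent_input = 100, stringsAsFactors = FALSE),
      data.frame(experiment = cells$experiment, amplicon = cells$amplicon,
                 condition = cells$condition, aliquot = "IP",
                 percent_input = ip, stringsAsFactors = FALSE),
      data.frame(experiment = cells$experiment, amplicon = cells$amplicon,
                 condition = cells$condition, aliquot = "IP_RNaseH",
                 percent_input = bg, stringsAsFactors = FALSE)
    )
    out <- out[order(out$experiment, out$amplicon, out$condition), ]
    rownames(out) <- NULL
    structure(out, class = c("qpcr_fixture", "data.frame"),
              experiment_type = "drive",
              truth = list(enrichment = plan, background = background,
                           noise_sd = noise_sd))
  })
}

#' Simulate qPCR decay time courses with known rates
#'
#' Relative transcript levels follow a single-exponential decay
#' `exp(-k * t)` with multiplicative lognormal noise of a given coefficient
#' of variation; the noise factor has mean exactly 1, so the expected level
#' at time `t` equals `exp(-k * t)` (including the time-0 point).
#'
#' @param k_per_min Named numeric vector of decay rates (per minute, >= 0),
#'   one per transcript.
#' @param times Sampling times in minutes; must include 0 and be >= 0.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param n_courses Number of replicate time courses per transcript.
#' @param condition Condition label stored with the fixture.
#' @param seed Integer seed.
#' @return A `qpcr_fixture` data frame of class `decay` with columns
#'   `transcript`, `condition`, `course`, `time_min`, `level`; planted rates
#'   in the `truth` attribute.
#' @export
simulate_decay_fixture <- function(k_per_min, times = c(0, 20, 40, 60),
                                   noise_cv = 0.05, n_courses = 1L,
                                   condition = "FLV", seed = 1L) {
  if (is.null(names(k_per_min))) stopf("'k_per_min' must be named")
  if (any(k_per_min < 0)) stopf("decay rates must be >= 0")
  if (any(times < 0)) stopf("negative time in 'times'")
  if (!0 %in% times) stopf("'times' must include time 0")
  if (noise_cv < 0) stopf("'noise_cv' must be >= 0")
  n_courses <- as.integer(n_courses)
  sdlog <- sqrt(log(1 + noise_cv^2))
  with_seed(seed, {
    grid <- expand.grid(time_min = times,
                        course = seq_len(n_courses),
                        transcript = names(k_per_min),
                        stringsAsFactors = FALSE)
    k <- k_per_min[grid$transcript]
    noise <- if (noise_cv > 0) {
      rlnorm(nrow(grid), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, nrow(grid))
    grid$level <- exp(-k * grid$time_min) * noise
    grid$condition <- condition
    out <- grid[, c("transcript", "condition", "course", "time_min", "level")]
    structure(out, class = c("qpcr_fixture", "data.frame"),
              experiment_type = "decay",
              truth = list(k_per_min = k_per_min, noise_cv = noise_cv))
  })
}

#' Write a qPCR fixture as CSV
#' @param fixture A `qpcr_fixture`.
#' @param path Output CSV path.
#' @export
write_qpcr_csv <- function(fixture, path) {
  utils::write.csv(as.data.frame(fixture), path, row.names = FALSE)
  invisible(path)
}
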