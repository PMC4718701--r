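#' Percent-of-input from qPCR Ct values
#'
#' Converts an IP/input Ct pair to percent of input:
#' `percent = efficiency^(ct_input_adjusted - ct_ip) * 100`, where the input
#' Ct is first corrected for its dilution,
#' `ct_input_adjusted = ct_input - log_efficiency(dilution)`.
#'
#' @param ct_ip,ct_input Ct values of the IP and input aliquots (in
#'   `(0, 45)`).
#' @param input_dilution Input dilution factor (>= 1; 10 means the input
#'   was diluted 1:10 before qPCR).
#' @param efficiency Amplification base per cycle (2 = perfect doubling).
#' @return Percent of input (numeric, vectorized).
#' @examples
#' percent_input(25, 25)        # 100
#' percent_input(30, 20)        # 2^-10 * 100
#' @export
percent_input <- function(ct_ip, ct_input, input_dilution = 1,
                          efficiency = 2) {
  if (any(efficiency <= 0)) stopf("'efficiency' must be > 0")
  if (any(input_dilution < 1)) stopf("'input_dilution' must be >= 1")
  if (any(c(ct_ip, ct_input) <= 0) || any(c(ct_ip, ct_input) >= 45)) {
    stopf("Ct values must lie in (0, 45)")
  }
  ct_in_adj <- ct_input - log(input_dilution, base = efficiency)
  efficiency^(ct_in_adj - ct_ip) * 100
}

#' Subtract the RNase H1 background from an IP recovery
#'
#' The hybrid-specific DRIVE signal is the IP percent-of-input minus the
#' recovery of the same sample pretreated with RNase H1 (which destroys
#' DNA:RNA hybrids).  Negative differences are clipped to zero and flagged.
#'
#' @param ip,ip_rnaseh Percent-of-input of the IP and the RNase
#'   H1-pretreated aliquot of the same (amplicon, condition, replicate).
#' @return Numeric vector of raw enrichments (percent of input), with a
#'   logical `clipped` attribute marking entries floored at zero.
#' @export
subtract_background <- function(ip, ip_rnaseh) {
  if (length(ip_rnaseh) == 0L || anyNA(ip_rnaseh)) {
    stopf("missing RNase H1 aliquot")
  }
  d <- ip - ip_rnaseh
  clipped <- d < 0
  d[clipped] <- 0
  structure(d, clipped = clipped)
}

#' Normalize DRIVE enrichments to a reference amplicon/condition
#'
#' Divides every raw enrichment by the value of the reference cell (by
#' default the 2-min CPT sample of the RPL13A amplicon) of the same
#' experiment, so experiments are made comparable before pooling.  The
#' reference cell itself normalizes to exactly 1.
#'
#' @param table Data frame with columns `experiment`, `amplicon`,
#'   `condition`, `enrichment_raw`.
#' @param reference_amplicon,reference_condition Reference cell.
#' @return The table with an added `enrichment_norm` column.
#' @export
normalize_to_reference <- function(table, reference_amplicon = "RPL13A",
                                   reference_condition = "CPT 2 min") {
  need <- c("experiment", "amplicon", "condition", "enrichment_raw")
  stopifnot(all(need %in% names(table)))
  table$enrichment_norm <- NA_real_
  for (ex in unique(table$experiment)) {
    sel <- table$experiment == ex
    ref <- table$enrichment_raw[sel &
                                table$amplicon == reference_amplicon &
                                table$condition == reference_condition]
    if (length(ref) == 0L || all(is.na(ref))) {
      stopf("reference cell %s/%s absent in experiment %s",
            reference_amplicon, reference_condition, ex)
    }
    refv <- mean(ref, na.rm = TRUE)
    if (refv <= 0) {
      stopf("reference cell %s/%s is not positive in experiment %s",
            reference_amplicon, reference_condition, ex)
    }
    table$enrichment_norm[sel] <- table$enrichment_raw[sel] / refv
  }
  table
}

#' Summarize normalized enrichments over experiments
#'
#' Mean, SEM (`sd/sqrt(n)`) and replicate count per (amplicon, condition)
#' cell; single-replicate cells get SEM 0 and are flagged.
#'
#' @param table A [normalize_to_reference()] result.
#' @return An `enrichment_values` data frame: `amplicon`, `condition`,
#'   `enrichment_norm` (mean), `sem`, `n`, `sem_undefined`.
#' @export
summarize_enrichment <- function(table) {
  stopifnot(all(c("amplicon", "condition", "enrichment_norm") %in%
                names(table)))
  if (nrow(table) == 0L) stopf("empty enrichment table")
  key <- interaction(table$amplicon, table$condition, drop = TRUE)
  agg <- lapply(split(table, key), function(d) {
    n <- nrow(d)
    data.frame(amplicon = d$amplicon[1], condition = d$condition[1],
               enrichment_norm = mean(d$enrichment_norm),
               sem = if (n > 1L) sd(d$enrichment_norm) / sqrt(n) else 0,
               n = n, sem_undefined = n == 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  structure(out, class = c("enrichment_values", "data.frame"))
}

#' Full DRIVE quantification pipeline
#'
#' From a measurement table in long format (one row per aliquot) to
#' summarized normalized enrichments: percent-of-input (if Ct values are
#' supplied), RNase H1 background subtraction, per-experiment normalization
#' to the reference cell, then pooling over experiments.
#'
#' @param measurements Data frame with columns `experiment`, `amplicon`,
#'   `condition`, `aliquot` (`input`/`IP`/`IP_RNaseH`) and either
#'   `percent_input` or `ct` (with optional `dilution` on input rows).
#' @param reference_amplicon,reference_condition Reference cell for
#'   normalization.
#' @param efficiency Amplification base when converting Ct values.
#' @return List with `per_experiment` (raw and normalized enrichments per
#'   experiment cell) and `summary` (an `enrichment_values` table).
#' @export
drive_enrichment <- function(measurements, reference_amplicon = "RPL13A",
                             reference_condition = "CPT 2 min",
                             efficiency = 2) {
  m <- as.data.frame(measurements)
  stopifnot(all(c("experiment", "amplicon", "condition", "aliquot") %in%
                names(m)))
  if (!"percent_input" %in% names(m)) {
    if (!"ct" %in% names(m)) stopf("need 'percent_input' or 'ct' column")
    dil <- if ("dilution" %in% names(m)) m$dilution else 1
    m$percent_input <- NA_real_
    key <- interaction(m$experiment, m$amplicon, m$condition, drop = TRUE)
    for (k in levels(key)) {
      sel <- key == k
      inp <- which(sel & m$aliquot == "input")
      if (length(inp) != 1L) stopf("each sample needs one input aliquot")
      for (al in c("IP", "IP_RNaseH")) {
        i <- which(sel & m$aliquot == al)
        m$percent_input[i] <- percent_input(
          m$ct[i], m$ct[inp],
          input_dilution = if (length(dil) > 1) dil[inp] else dil,
          efficiency = efficiency)
      }
    }
  }
  key <- interaction(m$experiment, m$amplicon, m$condition, drop = TRUE)
  cells <- lapply(split(m, key), function(d) {
    ip <- d$percent_input[d$aliquot == "IP"]
    bg <- d$percent_input[d$aliquot == "IP_RNaseH"]
    if (length(ip) != 1L) stopf("each sample needs one IP aliquot")
    if (length(bg) != 1L) stopf("missing RNase H1 aliquot for %s/%s (%s)",
                                d$amplicon[1], d$condition[1],
                                d$experiment[1])
    raw <- subtract_background(ip, bg)
    data.frame(experiment = d$experiment[1], amplicon = d$amplicon[1],
               condition = d$condition[1],
               enrichment_raw = as.numeric(raw),
               clipped = attr(raw, "clipped"),
               stringsAsFactors = FALSE)
  })
  per_exp <- do.call(rbind, cells)
  rownames(per_exp) <- NULL
  per_exp <- normalize_to_reference(per_exp, reference_amplicon,
                                    reference_condition)
  list(per_experiment = per_exp, summary = summarize_enrichment(per_exp))
}
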