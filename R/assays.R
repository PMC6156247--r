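#' qPCR fold change by the comparative Ct method
#'
#' Reference-normalized cycle thresholds: dCt = Ct(target) - Ct(reference)
#' per sample; fold change = efficiency^-(dCt_treated - dCt_control).
#' Assumes perfect doubling per cycle (efficiency 2) unless told otherwise.
#'
#' @param ct_target_treated,ct_ref_treated Target and reference-gene Ct of
#'   the treated sample (cycles, each in (0, 45)).
#' @param ct_target_control,ct_ref_control Same for the control sample.
#' @param efficiency Amplification efficiency per cycle, default 2.
#' @return Linear fold change (treated vs control).
#' @export
ddct_fold_change <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control,
                             efficiency = 2) {
  cts <- c(ct_target_treated, ct_ref_treated, ct_target_control,
           ct_ref_control)
  if (any(cts <= 0 | cts >= 45))
    stop("Ct values must lie in (0, 45)", call. = FALSE)
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  efficiency^(-ddct)
}

#' ChIP enrichment as percent of input
#'
#' Standard input normalization with the log2 dilution correction: the input
#' Ct is first adjusted for the chromatin fraction used as input
#' (`ct_input - log2(input_fraction)`, i.e. the Ct the input would have
#' shown undiluted), then percent input = 100 x 2^(adjusted input Ct - IP
#' Ct).
#'
#' @param ct_ip IP sample Ct.
#' @param ct_input Input sample Ct.
#' @param input_fraction Fraction of chromatin used as input, in (0, 1].
#' @return Percent of input.
#' @export
percent_input <- function(ct_ip, ct_input, input_fraction) {
  if (any(input_fraction <= 0) || any(input_fraction > 1))
    stop("input_fraction must lie in (0, 1]", call. = FALSE)
  ct_input_adj <- ct_input - log2(input_fraction)
  100 * 2^(ct_input_adj - ct_ip)
}

#' Wound-closure percentage from gap-width measurements
#'
#' Percent healed = 100 x (1 - mean(gap widths at t) / mean(gap widths at
#' t0)). Negative when the gap widened. Unit-invariant (any common length
#' unit) and invariant to the ordering of the measurement list.
#'
#' @param distances_t Gap widths at the later timepoint (>= 0).
#' @param distances_t0 Gap widths at time zero (> 0 on average).
#' @return Percent of wound closed.
#' @export
wound_closure <- function(distances_t, distances_t0) {
  stopifnot(length(distances_t) >= 1, length(distances_t0) >= 1)
  if (any(distances_t < 0) || any(distances_t0 < 0))
    stop("gap widths must be nonnegative", call. = FALSE)
  m0 <- mean(distances_t0)
  if (m0 == 0) stop("t0 gap width is zero; closure undefined", call. = FALSE)
  100 * (1 - mean(distances_t) / m0)
}
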