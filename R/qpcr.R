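#' ChIP-qPCR enrichment relative to input
#'
#' Percent-input quantification:
#' `enrichment = input_dilution * efficiency^(Ct_input - Ct_ip)`. With
#' perfect-doubling chemistry (efficiency 2) each cycle of Ct difference is
#' a two-fold difference in template.
#'
#' @param ct_ip,ct_input Threshold cycles of the immunoprecipitate and the
#'   (diluted) input, vectorized; technical replicates should be averaged
#'   on the Ct scale beforehand (see [mean_ct()]).
#' @param efficiency Amplification factor per cycle, in (1, 2]; default 2.
#' @param input_dilution Fraction of input used (default 1).
#' @return Enrichment as a fraction of input.
#' @export
percent_input <- function(ct_ip, ct_input, efficiency = 2, input_dilution = 1) {
  check_qpcr(c(ct_ip, ct_input), efficiency)
  input_dilution * efficiency^(ct_input - ct_ip)
}

#' Fold enrichment relative to a reference locus
#'
#' Rescales enrichments so the reference locus maps to exactly 1, as when
#' reporting ChIP enrichment relative to a control region.
#'
#' @param enr_target,enr_reference Enrichment values (e.g. from
#'   [percent_input()]); `enr_reference` must be non-zero.
#' @return `enr_target / enr_reference`.
#' @export
relative_to_reference <- function(enr_target, enr_reference) {
  if (any(enr_reference == 0)) abort("reference enrichment must be non-zero")
  enr_target / enr_reference
}

#' Relative expression by the delta-Ct method
#'
#' `level = efficiency^(Ct_reference - Ct_target)`: expression of a target
#' normalized to a reference transcript (the thioredoxin housekeeping gene
#' in the endosperm assays this package models). Equal Cts give 1;
#' the level is monotone decreasing in `Ct_target`.
#'
#' @param ct_target,ct_reference Threshold cycles.
#' @param efficiency Amplification factor per cycle, in (1, 2]; default 2.
#' @return Relative expression level.
#' @export
relative_expression <- function(ct_target, ct_reference, efficiency = 2) {
  check_qpcr(c(ct_target, ct_reference), efficiency)
  efficiency^(ct_reference - ct_target)
}

#' @rdname percent_input
#' @param ct Numeric vector of technical-replicate Ct values.
#' @export
mean_ct <- function(ct) mean(ct, na.rm = TRUE)

check_qpcr <- function(ct, efficiency) {
  if (any(ct <= 0)) abort("Ct values must be positive")
  if (efficiency <= 1 || efficiency > 2) {
    abort("efficiency must be in (1, 2]")
  }
  invisible(TRUE)
}
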