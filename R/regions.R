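#' The 27 cytoarchitectonically defined brain regions
#'
#' The default region family analysed by this package: 13 subcortical regions
#' (basal forebrain cholinergic nuclei, amygdala subnuclei, hippocampal
#' subfields, entorhinal cortex) and 14 neocortical regions (motor, auditory,
#' somatosensory, visual and Broca areas), all defined by post-mortem
#' cytoarchitectonic probabilistic maps. The `hc_mean` column carries the
#' package's default healthy-control baseline gray-matter-density value used
#' by the synthetic cohort generator; these are plausible modulated-VBM
#' magnitudes chosen by the package, not published estimates.
#'
#' @return Data frame with columns `region` (short label), `class`
#'   (`subcortical`/`cortical`) and `hc_mean` (unitless GMD), in the stable
#'   order used throughout the package.
#' @examples
#' head(cyto_regions())
#' @export
cyto_regions <- function() {
  data.frame(
    region = c(
      "Ch4", "Ch123", "CM", "LB", "SF", "ASTR", "CA1", "CA2", "CA3",
      "DG", "SUBC", "EC", "HATA",
      "Motor4a", "Motor4p", "TE1.0", "TE1.1", "TE1.2", "TE3",
      "PSC1", "PSC2", "PSC3a", "PSC3b", "V1", "V2", "BA44", "BA45"
    ),
    class = c(rep("subcortical", 13L), rep("cortical", 14L)),
    hc_mean = c(
      0.48, 0.45, 0.52, 0.55, 0.53, 0.50, 0.55, 0.50, 0.52,
      0.56, 0.54, 0.50, 0.51,
      0.42, 0.44, 0.48, 0.46, 0.47, 0.50,
      0.40, 0.41, 0.39, 0.43, 0.45, 0.46, 0.47, 0.48
    ),
    stringsAsFactors = FALSE
  )
}

#' Reference within-session percent-change tables (MIRIAD cohort)
#'
#' Loads the transcription of the published within-session test-retest
#' summary for the 27-region family in the MIRIAD cohort: per-region mean
#' percent change between the two same-session scans, 95% confidence limits
#' and p-values, for either the Alzheimer's-disease or the healthy-control
#' group. These serve as a fixed, in-package input for exercising the
#' multiple-testing machinery on real published p-values.
#'
#' @param group `"AD"` or `"HC"`.
#' @return Data frame with columns `region`, `mean_pct_change`, `lower`,
#'   `upper`, `p`, `printed_threshold` (the per-rank threshold as printed,
#'   for cross-checking) in the table's printed row order.
#' @export
reference_within_session_table <- function(group = c("AD", "HC")) {
  group <- match.arg(group)
  file <- if (group == "AD") "ad_within_session_reference.csv" else
    "hc_within_session_reference.csv"
  path <- system.file("extdata", file, package = "cytogmd", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
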