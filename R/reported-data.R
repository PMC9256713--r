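# Published reference measurements for the G281 GM rice event and its
# recipient line (Xiushui 110), transcribed from the event's published
# characterization. They serve as validation fixtures for the copy-number
# and calibrator arithmetic and as worked-example inputs; no sequencing
# data are bundled.

#' Published per-element depth table for the G281 rice event
#'
#' Average target depths (ADT) over each transgene element for the GM and
#' wild-type samples, with the general depths and coverage calibrators of
#' the two runs. `SPS` is the single-copy endogenous calibrator gene.
#'
#' @return tibble: `element`, `adt_gm`, `d_gm`, `r_gm`, `adt_wt`, `d_wt`,
#'   `r_wt`.
#' @export
g281_depth_table <- function() {
  tibble(
    element = c("hLF", "EPSPS", "Gt1", "CYP81A6_RNAi", "Ubiquitin",
                "PEPC", "SPS"),
    adt_gm = c(48.93, 53.76, 77.75, 50.86, 43.87, 43.97, 25.11),
    d_gm = 28.91, r_gm = 0.989,
    adt_wt = c(0, 0, 27.05, 0.59, 0.79, 0, 25.14),
    d_wt = 29.28, r_wt = 0.989)
}

#' Published ddPCR replicate counts for the G281 rice event
#'
#' Quantified copies from three droplet-digital-PCR replicates per gene;
#' `SPS` is the endogenous reference.
#'
#' @return tibble: `element`, `rep1`, `rep2`, `rep3`.
#' @export
g281_ddpcr_counts <- function() {
  tibble(element = c("hLF", "EPSPS", "SPS"),
         rep1 = c(37160, 35680, 18980),
         rep2 = c(37760, 35800, 19000),
         rep3 = c(37150, 35320, 19100))
}

#' Published sequencing and mapping counts for the G281 event pair
#'
#' Total trimmed read pairs, pairs with both ends mapped to the host
#' genome, pairs mapped to the transformation plasmid, and chimeric
#' candidate pairs before and after homology filtering, for the GM sample
#' and its wild-type recipient.
#'
#' @return tibble: `sample`, `total_pairs`, `host_mapped_pairs`,
#'   `depth_d`, `plasmid_pairs`, `candidates_unfiltered`,
#'   `candidates_filtered`.
#' @export
g281_mapping_counts <- function() {
  tibble(sample = c("GM", "WT"),
         total_pairs = c(54130964, 54819968),
         host_mapped_pairs = c(53545140, 54233374),
         depth_d = c(28.91, 29.28),
         plasmid_pairs = c(2604, 322),
         candidates_unfiltered = c(332, 262),
         candidates_filtered = c(69, 5))
}
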