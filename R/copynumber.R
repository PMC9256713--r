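# Copy-number estimation from sequencing depth and from ddPCR replicates.
#
# Two depth-based forms are implemented. The raw form subtracts the
# depth- and calibrator-normalized target depths of the transformed and
# wild-type samples:
#
#   CN_raw = ADT_gm / (D_gm * R_gm) - ADT_wt / (D_wt * R_wt)
#
# The calibrated form normalizes each sample's target depth by the depth
# of a single-copy endogenous reference gene (SPS) measured in the same
# sample, so sample-level factors cancel exactly:
#
#   CN_cal = ADT_t,gm / ADT_SPS,gm - ADT_t,wt / ADT_SPS,wt
#
# The two are not equivalent on real data; the calibrated form is the
# default because within-sample normalization absorbs residual library
# and mapping bias that D*R does not capture. The subtraction of the
# wild-type term corrects for host sequence homologous to the target
# element (reads from the native copy inflate ADT in both samples
# equally).

#' Raw depth-based copy number
#'
#' @param adt_gm,adt_wt average target depths in the transformed and
#'   wild-type samples.
#' @param d_gm,d_wt general sequencing depths.
#' @param r_gm,r_wt coverage calibrators.
#' @return copy-number estimate.
#' @export
copy_number_raw <- function(adt_gm, d_gm, r_gm, adt_wt, d_wt, r_wt) {
  if (any(d_gm * r_gm == 0) || any(d_wt * r_wt == 0)) {
    stop("zero depth*calibrator denominator")
  }
  adt_gm / (d_gm * r_gm) - adt_wt / (d_wt * r_wt)
}

#' SPS-calibrated depth-based copy number
#'
#' Per-sample normalization by the single-copy endogenous reference gene;
#' small negative values (wild-type depth exceeding the transformed
#' sample's under noise) are clipped to 0 with a warning.
#'
#' @param adt_t_gm,adt_t_wt target-element depths per sample.
#' @param adt_sps_gm,adt_sps_wt SPS depths per sample.
#' @return copy-number estimate.
#' @export
copy_number_calibrated <- function(adt_t_gm, adt_sps_gm, adt_t_wt,
                                   adt_sps_wt) {
  if (any(adt_sps_gm <= 0)) stop("zero SPS depth in transformed sample")
  if (any(adt_t_wt > 0 & adt_sps_wt <= 0)) {
    stop("zero SPS depth in wild-type sample with nonzero target depth")
  }
  wt_term <- ifelse(adt_t_wt > 0, adt_t_wt / adt_sps_wt, 0)
  cn <- adt_t_gm / adt_sps_gm - wt_term
  if (any(cn < 0)) {
    warning("negative calibrated copy number clipped to 0")
    cn <- pmax(cn, 0)
  }
  cn
}

# display rounding, half-up at `digits` decimals
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Copy-number table from depth statistics of a sample pair
#'
#' Builds a per-element table in both the raw and the SPS-calibrated form.
#' The `adt` tibble of each `depth_stats` must contain an `SPS` row (the
#' single-copy calibrator); without a wild-type sample the wild-type
#' terms are 0 and a warning is emitted.
#'
#' @param gm `depth_stats` of the transformed sample.
#' @param wt optional `depth_stats` of the wild-type sample.
#' @return tibble: `element`, `adt_gm`, `adt_wt`, `copy_raw`,
#'   `copy_number` (calibrated), `rounded`.
#' @export
copy_number_table <- function(gm, wt = NULL) {
  stopifnot(inherits(gm, "depth_stats"))
  sps_gm <- gm$adt$adt[gm$adt$element == "SPS"]
  if (length(sps_gm) != 1) stop("depth_stats must carry an SPS row")
  if (is.null(wt)) {
    warning("no wild-type sample; wild-type terms set to 0")
    wt_adt <- tibble(element = gm$adt$element, adt_wt = 0)
    sps_wt <- 1
    d_wt <- gm$D
    r_wt <- gm$R
  } else {
    wt_adt <- rename(wt$adt, adt_wt = "adt")
    sps_wt <- wt$adt$adt[wt$adt$element == "SPS"]
    d_wt <- wt$D
    r_wt <- wt$R
  }
  gm$adt %>%
    rename(adt_gm = "adt") %>%
    left_join(wt_adt, by = "element") %>%
    mutate(adt_wt = dplyr::coalesce(.data$adt_wt, 0)) %>%
    filter(.data$element != "SPS") %>%
    mutate(
      copy_raw = copy_number_raw(.data$adt_gm, gm$D, gm$R,
                                 .data$adt_wt, d_wt, r_wt),
      copy_number = copy_number_calibrated(.data$adt_gm, sps_gm,
                                           .data$adt_wt, sps_wt),
      rounded = as.integer(round(.data$copy_number)))
}

#' Copy number and dispersion from ddPCR replicate counts
#'
#' The copy number is the ratio of mean quantified target copies to mean
#' quantified endogenous-reference copies; replicate dispersion is the
#' relative standard deviation (sample sd, n-1 denominator, as percent).
#' With fewer than two replicates on a side its RSD is `NA`; the ratio is
#' still returned.
#'
#' @param target numeric vector of quantified target-gene copies.
#' @param reference numeric vector of quantified reference-gene copies.
#' @return one-row tibble: `ratio`, `rsd_target_pct`, `rsd_ref_pct`,
#'   `n_target`, `n_ref`.
#' @export
copy_number_ddpcr <- function(target, reference) {
  stopifnot(length(target) >= 1, length(reference) >= 1,
            all(target >= 0), all(reference >= 0))
  if (mean(reference) <= 0) stop("reference mean must be positive")
  rsd <- function(x) {
    if (length(x) < 2) return(NA_real_)
    stats::sd(x) / mean(x) * 100
  }
  tibble(ratio = mean(target) / mean(reference),
         rsd_target_pct = rsd(target), rsd_ref_pct = rsd(reference),
         n_target = length(target), n_ref = length(reference))
}

#' Read a ddPCR replicate table
#'
#' TSV with an `element` column followed by one column per replicate.
#' One row must be the endogenous reference (default name `SPS`).
#'
#' @param path TSV path.
#' @param reference name of the reference-gene row.
#' @return tibble: `element`, `ratio`, `rsd_target_pct`, `rsd_ref_pct`.
#' @export
read_ddpcr_tsv <- function(path, reference = "SPS") {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  reps <- as.matrix(x[, -1, drop = FALSE])
  ref <- reps[x[[1]] == reference, ]
  if (length(ref) == 0) stop("no reference row '", reference, "'")
  purrr::map_dfr(which(x[[1]] != reference), function(i) {
    tgt <- reps[i, ]
    bind_cols(tibble(element = x[[1]][i]),
              copy_number_ddpcr(tgt[!is.na(tgt)], ref[!is.na(ref)]))
  })
}
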