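# Detection of residual plasmid-backbone sequence from coverage over the
# non-T-DNA region of the transformation plasmid.

#' Scan the plasmid backbone for residual-insertion signal
#'
#' Computes per-base coverage over the plasmid from uniquely mapped read
#' ends (multi-mapped ends are excluded so host/plasmid homology cannot
#' inflate the track) and flags maximal backbone intervals of length at
#' least `min_span` whose coverage reaches `min_depth_frac * D`. Shorter
#' covered stretches are reported as sporadic (logged, not flagged): a few
#' isolated read pairs at ~29x are expected background, whereas a real
#' single-copy residue is covered at about `D` over its whole length.
#'
#' @param pa `pair_alignments` including the plasmid reference.
#' @param pmap the `plasmid_map`.
#' @param D genome sequencing depth (from [depth_stats()]).
#' @param min_depth_frac coverage threshold as a fraction of `D`.
#' @param min_span minimum flagged-interval length (bp).
#' @param read_len read length.
#' @param blacklist optional `blacklist`; its plasmid intervals are
#'   annotated on the report.
#' @return a `backbone_report`: `track` (run-length coverage tibble:
#'   `start`, `end`, `coverage`), `flagged`, `sporadic` tibbles, `verdict`
#'   (`"clean"` / `"residues_detected"`).
#' @export
scan_backbone <- function(pa, pmap, D, min_depth_frac = 0.3,
                          min_span = 200L, read_len = 100L,
                          blacklist = NULL) {
  bb <- pmap$backbone
  prim <- pa$hits %>%
    filter(.data$primary, .data$unique, .data$ref_id == pmap$id)
  if (sum(bb$end - bb$start) == 0) {
    return(structure(list(
      track = tibble(start = integer(0), end = integer(0),
                     coverage = numeric(0)),
      flagged = tibble(start = integer(0), end = integer(0),
                       mean_coverage = numeric(0)),
      sporadic = tibble(start = integer(0), end = integer(0),
                        mean_coverage = numeric(0)),
      verdict = "clean", threshold = min_depth_frac * D,
      note = "empty backbone: T-DNA covers the whole plasmid"),
      class = "backbone_report"))
  }
  cov <- if (nrow(prim) == 0) {
    S4Vectors::Rle(0L, pmap$length)
  } else {
    IRanges::coverage(to_iranges(prim$pos,
                                 pmin(prim$pos + read_len, pmap$length)),
                      width = pmap$length)
  }
  # restrict the track to backbone intervals
  runs <- tibble(start = cumsum(c(0L, S4Vectors::runLength(cov)))[
                   seq_along(S4Vectors::runLength(cov))],
                 end = cumsum(S4Vectors::runLength(cov)),
                 coverage = as.numeric(S4Vectors::runValue(cov)))
  track <- intersect_runs(runs, bb)
  thr <- min_depth_frac * D
  hot <- track %>% filter(.data$coverage >= thr)
  hot_merged <- if (nrow(hot) == 0) {
    tibble(start = integer(0), end = integer(0))
  } else {
    from_iranges(IRanges::reduce(to_iranges(hot$start, hot$end)))
  }
  span_len <- hot_merged$end - hot_merged$start
  mean_cov <- vapply(seq_len(nrow(hot_merged)), function(i) {
    w <- track %>% filter(.data$end > hot_merged$start[i],
                          .data$start < hot_merged$end[i])
    sum(w$coverage * (pmin(w$end, hot_merged$end[i]) -
                        pmax(w$start, hot_merged$start[i]))) /
      span_len[i]
  }, numeric(1))
  flagged <- hot_merged[span_len >= min_span, , drop = FALSE] %>%
    mutate(mean_coverage = mean_cov[span_len >= min_span])
  sporadic <- hot_merged[span_len < min_span, , drop = FALSE] %>%
    mutate(mean_coverage = mean_cov[span_len < min_span])
  structure(list(track = track, flagged = flagged, sporadic = sporadic,
                 verdict = if (nrow(flagged) > 0) "residues_detected"
                           else "clean",
                 threshold = thr,
                 blacklist_plasmid = if (is.null(blacklist)) NULL
                                     else blacklist$plasmid),
            class = "backbone_report")
}

# clip run-length coverage rows to a set of intervals
intersect_runs <- function(runs, iv) {
  purrr::map_dfr(seq_len(nrow(iv)), function(i) {
    runs %>%
      filter(.data$end > iv$start[i], .data$start < iv$end[i]) %>%
      mutate(start = pmax(.data$start, iv$start[i]),
             end = pmin(.data$end, iv$end[i]))
  }) %>% arrange(.data$start)
}

#' @export
print.backbone_report <- function(x, ...) {
  cat("<backbone_report> verdict: ", x$verdict, "\n", sep = "")
  cat("  flagged: ", nrow(x$flagged), " region(s); sporadic: ",
      nrow(x$sporadic), " sub-threshold hit(s)\n", sep = "")
  invisible(x)
}

#' Write the backbone coverage track as bedGraph
#' @param report a `backbone_report`.
#' @param path output path.
#' @param plasmid_id track chromosome name.
#' @return `path`, invisibly.
#' @export
write_backbone_bedgraph <- function(report, path, plasmid_id = "plasmid") {
  utils::write.table(
    data.frame(plasmid_id, report$track$start, report$track$end,
               report$track$coverage),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Coverage plot of the plasmid backbone scan
#'
#' @param report a `backbone_report`.
#' @return a ggplot object: backbone coverage with the flag threshold and
#'   any flagged regions shaded.
#' @export
plot_backbone <- function(report) {
  tr <- report$track
  p <- ggplot2::ggplot(tr) +
    ggplot2::geom_step(ggplot2::aes(x = .data$start,
                                    y = .data$coverage)) +
    ggplot2::geom_hline(yintercept = report$threshold,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "plasmid position (bp)", y = "unique-read coverage",
                  title = paste("backbone scan:", report$verdict)) +
    ggplot2::theme_minimal()
  if (nrow(report$flagged) > 0) {
    p <- p + ggplot2::geom_rect(
      data = report$flagged,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = 0, ymax = Inf),
      fill = "firebrick", alpha = 0.2, inherit.aes = FALSE)
  }
  p
}
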