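# End-to-end characterization: mapping -> blacklist -> junction ->
# assembly -> copy number -> backbone, for a transformed sample with an
# optional wild-type control, producing one report object.

#' Pipeline parameters
#'
#' Defaults are documented on the stage functions they feed; everything a
#' run used is echoed into the report for reproducibility.
#'
#' @param k mapper seed length.
#' @param max_mismatch_frac mapper mismatch tolerance.
#' @param word_size,homology_min_identity,min_block_len homology search.
#' @param margin blacklist expansion (bp; the library insert size).
#' @param blacklist_side apply the blacklist to the host side only
#'   (default) or to both sides (see [filter_native()]).
#' @param cluster_window candidate clustering gap (bp).
#' @param min_abs,min_frac sporadic-cluster thresholds.
#' @param insert_mean library insert size (bp).
#' @param min_overlap,assembly_min_identity greedy assembler.
#' @param junction_min_identity split-alignment identity.
#' @param backbone_min_depth_frac,backbone_min_span backbone scan.
#' @return a named list of parameters.
#' @export
char_params <- function(k = 31L, max_mismatch_frac = 0.1, word_size = 16L,
                        homology_min_identity = 0.9, min_block_len = 50L,
                        margin = 500L, blacklist_side = "host",
                        cluster_window = 500L, min_abs = 3L,
                        min_frac = 0.1, insert_mean = 500,
                        min_overlap = 30L, assembly_min_identity = 0.95,
                        junction_min_identity = 0.9,
                        backbone_min_depth_frac = 0.3,
                        backbone_min_span = 200L) {
  as.list(environment())
}

# junction stage shared between sample and control
junction_stage <- function(pa, bl, D, read_len, p) {
  chim <- extract_chimeric(pa)
  fn <- filter_native(chim, bl, read_len, p$blacklist_side)
  clusters <- cluster_candidates(fn$kept, p$cluster_window, read_len)
  spor <- filter_sporadic(clusters, D, p$min_abs, p$min_frac)
  cand <- consistency_check(spor$candidates, fn$kept, p$insert_mean,
                            read_len)
  list(chimeric = chim, kept = fn$kept, discarded = fn$discarded,
       clusters = clusters, rejected = spor$rejected, candidates = cand,
       surviving = cand %>% filter(.data$verdict == "consistent"))
}

# per-chromosome audit in the style of a filtered/unfiltered count table
audit_table <- function(stage) {
  pre <- stage$chimeric %>% dplyr::count(chrom = .data$host_ref,
                                         name = "not_filtered")
  post <- stage$kept %>% dplyr::count(chrom = .data$host_ref,
                                      name = "filtered")
  reason <- stage$discarded %>%
    group_by(chrom = .data$host_ref) %>%
    summarise(reason = paste(unique(.data$reason), collapse = ";"),
              .groups = "drop")
  pre %>%
    left_join(post, by = "chrom") %>%
    left_join(reason, by = "chrom") %>%
    mutate(filtered = dplyr::coalesce(.data$filtered, 0L),
           reason = dplyr::coalesce(.data$reason, ""))
}

#' Characterize a transformation event from paired-end reads
#'
#' Runs the full pipeline: read mapping against host + plasmid, homology
#' blacklist construction, chimeric-pair extraction and filtering,
#' candidate clustering, junction assembly and integration calling,
#' depth-based copy number (SPS-calibrated when a calibrator interval is
#' given) and the plasmid-backbone scan. A wild-type control, when
#' supplied, is processed identically and used for the copy-number
#' subtraction and as a negative control on candidate clusters.
#'
#' @param gm_reads read tibble for the transformed sample
#'   ([simulate_reads()] / [read_fastq_pair()]).
#' @param host host genome tibble.
#' @param pmap `plasmid_map` of the transformation vector.
#' @param wt_reads optional wild-type read tibble.
#' @param sps optional single-copy calibrator interval: list with `chrom`,
#'   `start`, `end`.
#' @param params a [char_params()] list.
#' @return a `characterization` object.
#' @export
characterize <- function(gm_reads, host, pmap, wt_reads = NULL, sps = NULL,
                         params = char_params()) {
  p <- params
  host <- as_seq_tbl(host)
  read_len <- nchar(gm_reads$seq1[1])
  refs <- ref_set(host, pmap)

  pa_gm <- map_pairs(gm_reads, refs, p$k, p$max_mismatch_frac)
  pa_wt <- if (!is.null(wt_reads)) {
    map_pairs(wt_reads, refs, p$k, p$max_mismatch_frac)
  }

  blocks <- find_homology_blocks(pmap, host, p$word_size,
                                 p$homology_min_identity, p$min_block_len)
  bl <- build_blacklist(blocks, pmap, host, p$margin)

  stats_gm <- depth_stats(pa_gm, pmap, sps, read_len)
  stats_wt <- if (!is.null(pa_wt)) depth_stats(pa_wt, pmap, sps, read_len)

  has_sps <- "SPS" %in% stats_gm$adt$element
  copy_table <- if (has_sps) {
    if (is.null(stats_wt)) {
      withCallingHandlers(copy_number_table(stats_gm, NULL),
                          warning = function(w) {
                            invokeRestart("muffleWarning")
                          })
    } else {
      copy_number_table(stats_gm, stats_wt)
    }
  }
  # event-level copy number: calibrated depth of the whole T-DNA interior
  # (terminal read-length margins trimmed, where junction-spanning reads
  # go unmapped and coverage dips). Averaging over the full ~8 kb insert
  # gives a far steadier estimate than any sub-kilobase element.
  cn_estimate <- if (!is.null(copy_table)) {
    trim <- min(150L, (pmap$tdna[["end"]] - pmap$tdna[["start"]]) %/% 4L)
    iv <- c(pmap$tdna[["start"]] + trim, pmap$tdna[["end"]] - trim)
    adt_tdna <- function(pa_s) {
      prim <- pa_s$hits %>% filter(.data$primary)
      average_target_depth(prim, pmap$id, iv[1], iv[2], read_len)
    }
    sps_of <- function(st) st$adt$adt[st$adt$element == "SPS"]
    t_gm <- adt_tdna(pa_gm)
    t_wt <- if (is.null(pa_wt)) 0 else adt_tdna(pa_wt)
    copy_number_calibrated(t_gm, sps_of(stats_gm), t_wt,
                           if (is.null(stats_wt)) 1 else
                             sps_of(stats_wt))
  } else {
    NA_real_
  }

  gm <- junction_stage(pa_gm, bl, stats_gm$D, read_len, p)
  wt <- if (!is.null(pa_wt)) {
    junction_stage(pa_wt, bl, stats_wt$D, read_len, p)
  }

  calls <- list()
  contigs <- list()
  for (i in seq_len(nrow(gm$surviving))) {
    cl <- gm$surviving[i, ]
    jv <- junction_votes(pa_gm, cl, host, pmap, p$insert_mean,
                         p$min_overlap, p$assembly_min_identity,
                         p$junction_min_identity)
    contigs[[i]] <- jv$contigs
    jn <- jv$junctions
    if (nrow(jn) > 0) {
      calls[[length(calls) + 1]] <-
        call_integration(jn %>% filter(.data$chrom == cl$chrom),
                         cn_estimate)
    }
  }

  backbone <- scan_backbone(pa_gm, pmap, stats_gm$D,
                            p$backbone_min_depth_frac,
                            p$backbone_min_span, read_len, bl)

  structure(list(
    params = p, refs = refs, pmap = pmap,
    alignments = pa_gm, alignments_wt = pa_wt,
    blocks = blocks, blacklist = bl,
    stats_gm = stats_gm, stats_wt = stats_wt,
    copy_table = copy_table, copy_number = cn_estimate,
    gm = gm, wt = wt, audit = audit_table(gm),
    audit_wt = if (!is.null(wt)) audit_table(wt),
    calls = calls, contigs = contigs,
    backbone = backbone), class = "characterization")
}

#' @export
print.characterization <- function(x, ...) {
  cat("== transformation-event characterization ==\n")
  cat(sprintf("GM sample: %d pairs, D = %.2fx, R = %.3f\n",
              x$stats_gm$total_pairs, x$stats_gm$D, x$stats_gm$R))
  if (!is.null(x$stats_wt)) {
    cat(sprintf("WT control: %d pairs, D = %.2fx, R = %.3f\n",
                x$stats_wt$total_pairs, x$stats_wt$D, x$stats_wt$R))
  }
  cat(sprintf("chimeric pairs: %d -> kept %d after homology filtering\n",
              nrow(x$gm$chimeric), nrow(x$gm$kept)))
  cat(sprintf("candidate clusters: %d (of %d) survive depth/consistency filters\n",
              nrow(x$gm$surviving), nrow(x$gm$clusters)))
  for (cl in x$calls) print(cl)
  if (!is.null(x$copy_table)) {
    cat("copy-number table (SPS-calibrated):\n")
    print(x$copy_table %>%
            select("element", "adt_gm", "adt_wt", "copy_number",
                   "rounded"), n = Inf)
  }
  cat("backbone:", x$backbone$verdict, "\n")
  if (!is.null(x$wt)) {
    cat(sprintf("WT control: %d surviving cluster(s)\n",
                nrow(x$wt$surviving)))
  }
  invisible(x)
}

#' @describeIn characterize per-element copy-number table of a run.
#' @param x a `characterization`.
#' @param ... unused.
#' @export
tidy.characterization <- function(x, ...) {
  if (is.null(x$copy_table)) return(tibble())
  x$copy_table
}

#' @describeIn characterize one-row summary of a run.
#' @export
glance.characterization <- function(x, ...) {
  call <- if (length(x$calls) > 0) x$calls[[1]] else NULL
  tibble(
    n_integration_sites = length(x$calls),
    chr = if (is.null(call)) NA_character_ else call$chr,
    locus = if (is.null(call)) NA_integer_ else call$locus,
    deletion_len = if (is.null(call)) NA_integer_ else call$deletion_len,
    arrangement = if (is.null(call)) NA_character_ else call$arrangement,
    copy_number = x$copy_number,
    backbone_verdict = x$backbone$verdict,
    wt_surviving_clusters = if (is.null(x$wt)) NA_integer_ else
      nrow(x$wt$surviving))
}

#' Write a characterization report to a directory
#'
#' Emits `report.json` (machine-readable summary), cluster BED files, the
#' flanking contigs as FASTA, the blacklist, and the backbone coverage
#' bedGraph.
#'
#' @param x a `characterization`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- glance(x)
  jsonlite::write_json(list(
    summary = as.list(g),
    params = x$params,
    depth = list(gm = list(D = x$stats_gm$D, R = x$stats_gm$R),
                 wt = if (!is.null(x$stats_wt)) {
                   list(D = x$stats_wt$D, R = x$stats_wt$R)
                 }),
    copy_table = x$copy_table,
    audit = x$audit,
    calls = lapply(x$calls, function(cl) as.list(tidy(cl))),
    backbone = list(verdict = x$backbone$verdict,
                    flagged = x$backbone$flagged,
                    sporadic = x$backbone$sporadic)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  if (nrow(x$gm$clusters) > 0) {
    write_clusters_bed(x$gm$clusters %>% select(-"members"),
                       file.path(dir, "clusters.bed"))
  }
  ctg <- unlist(x$contigs)
  if (length(ctg) > 0) {
    write_fasta(tibble(id = sprintf("contig_%d", seq_along(ctg)),
                       seq = ctg),
                file.path(dir, "contigs.fasta"))
  }
  write_blacklist(x$blacklist, file.path(dir, "blacklist"))
  write_backbone_bedgraph(x$backbone, file.path(dir, "backbone.bedgraph"),
                          x$pmap$id)
  invisible(dir)
}
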