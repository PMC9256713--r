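# Chimeric-pair extraction, blacklist filtering, candidate clustering and
# sporadic-candidate suppression.
#
# Every filtering stage conserves counts: the input is partitioned into a
# kept and a discarded table, and every discarded row carries a reason
# code, so a Table-2-style audit can be reconstructed at any point.

#' Extract chimeric (host/plasmid) read pairs
#'
#' Normalizes the per-end columns so that the host end and the plasmid end
#' are explicit regardless of which mate hit which reference.
#'
#' @param pa a `pair_alignments` from [map_pairs()] / [read_sam()].
#' @return tibble: `pair_id`, `host_ref`, `host_pos`, `host_strand`,
#'   `host_uniq`, `plasmid_ref`, `plasmid_pos`, `plasmid_strand`,
#'   `plasmid_uniq`, `host_end` (1 or 2: which mate is the host end).
#' @export
extract_chimeric <- function(pa) {
  p <- pa$pairs %>% filter(.data$pair_class == "chimeric_host_plasmid")
  if (nrow(p) == 0) {
    return(tibble(pair_id = character(0), host_ref = character(0),
                  host_pos = integer(0), host_strand = character(0),
                  host_uniq = logical(0), plasmid_ref = character(0),
                  plasmid_pos = integer(0), plasmid_strand = character(0),
                  plasmid_uniq = logical(0), host_end = integer(0)))
  }
  h1 <- !p$plasmid1                      # end 1 is the host end
  uniq1 <- if ("uniq1" %in% names(p)) p$uniq1 else TRUE
  uniq2 <- if ("uniq2" %in% names(p)) p$uniq2 else TRUE
  tibble(pair_id = p$pair_id,
         host_ref = if_else(h1, p$ref1, p$ref2),
         host_pos = if_else(h1, p$pos1, p$pos2),
         host_strand = if_else(h1, p$strand1, p$strand2),
         host_uniq = if_else(h1, uniq1, uniq2),
         plasmid_ref = if_else(h1, p$ref2, p$ref1),
         plasmid_pos = if_else(h1, p$pos2, p$pos1),
         plasmid_strand = if_else(h1, p$strand2, p$strand1),
         plasmid_uniq = if_else(h1, uniq2, uniq1),
         host_end = if_else(h1, 1L, 2L))
}

#' Remove chimeric pairs explained by host/plasmid homology
#'
#' A pair is discarded when its host end's alignment footprint overlaps a
#' blacklisted host interval — the blacklist marks the host neighborhoods
#' (homologous segment +/- one insert) where every physical fragment end
#' of a native-sequence pair must fall. With `side = "both"` the plasmid
#' end is additionally tested against the plasmid-side intervals; that is
#' stricter but unusable for cisgenic events, where the entire donor
#' sequence is plasmid-side homologous and both-side filtering would
#' discard the true junction pairs at the new locus too. The discarded
#' table carries a reason code naming the offending side.
#'
#' @param chim chimeric-pair tibble from [extract_chimeric()].
#' @param bl a `blacklist`.
#' @param read_len aligned read length (footprint width).
#' @param side `"host"` (default) or `"both"`.
#' @return list with `kept` and `discarded` tibbles;
#'   `nrow(kept) + nrow(discarded) == nrow(chim)`.
#' @export
filter_native <- function(chim, bl, read_len = 100L,
                          side = c("host", "both")) {
  side <- match.arg(side)
  if (nrow(chim) == 0) {
    return(list(kept = chim, discarded = mutate(chim,
                                                reason = character(0))))
  }
  host_hit <- vapply(seq_len(nrow(chim)), function(i) {
    iv <- bl$host[bl$host$chrom == chim$host_ref[i], ]
    any(iv$start < chim$host_pos[i] + read_len & chim$host_pos[i] < iv$end)
  }, logical(1))
  plas_hit <- if (side == "both") {
    vapply(seq_len(nrow(chim)), function(i) {
      any(bl$plasmid$start < chim$plasmid_pos[i] + read_len &
            chim$plasmid_pos[i] < bl$plasmid$end)
    }, logical(1))
  } else {
    rep(FALSE, nrow(chim))
  }
  drop <- host_hit | plas_hit
  discarded <- chim[drop, ] %>%
    mutate(reason = dplyr::case_when(
      host_hit[drop] & plas_hit[drop] ~ "native_homology_both_sides",
      host_hit[drop] ~ "native_homology_host_side",
      TRUE ~ "native_homology_plasmid_side"))
  list(kept = chim[!drop, ], discarded = discarded)
}

#' Cluster candidate pairs on the host genome
#'
#' Single-linkage clustering of host-end positions per chromosome: a new
#' cluster starts whenever the gap to the previous position exceeds
#' `cluster_window`. Clusters come back sorted by support, descending.
#'
#' @param kept kept chimeric tibble from [filter_native()].
#' @param cluster_window maximum within-cluster gap (default 500 bp, the
#'   library insert: the physical scale over which junction pairs spread).
#' @param read_len read length (cluster span padding).
#' @return tibble: `chrom`, `start`, `end`, `support`, `unique_support`,
#'   `members` (list of pair ids).
#' @export
cluster_candidates <- function(kept, cluster_window = 500L,
                               read_len = 100L) {
  if (nrow(kept) == 0) {
    return(tibble(chrom = character(0), start = integer(0),
                  end = integer(0), support = integer(0),
                  unique_support = integer(0), members = list()))
  }
  kept %>%
    group_by(chrom = .data$host_ref) %>%
    arrange(.data$host_pos, .by_group = TRUE) %>%
    mutate(cl = cumsum(c(0L, diff(.data$host_pos)) > cluster_window)) %>%
    group_by(.data$chrom, .data$cl) %>%
    summarise(start = min(.data$host_pos),
              end = max(.data$host_pos) + read_len,
              support = n(),
              # host-end uniqueness is what protects against repeat-driven
              # false clusters; the plasmid end of a cisgenic junction pair
              # is never unique (the donor is host-native by construction)
              unique_support = sum(.data$host_uniq),
              members = list(.data$pair_id), .groups = "drop") %>%
    select(-"cl") %>%
    arrange(desc(.data$support))
}

#' Suppress sporadic candidate clusters
#'
#' A cluster survives when its support is at least
#' `max(min_abs, min_frac * depth_D)` and at least `min_abs` of its members
#' are uniquely mapped on both ends. Junction-spanning pairs accumulate in
#' proportion to depth, so isolated one- or two-pair clusters at ~29x are
#' noise or alignment jitter.
#'
#' @param clusters tibble from [cluster_candidates()].
#' @param depth_D genome sequencing depth.
#' @param min_abs absolute minimum support.
#' @param min_frac minimum support as a fraction of depth.
#' @return list with `candidates` and `rejected` (reason-coded) tibbles.
#' @export
filter_sporadic <- function(clusters, depth_D, min_abs = 3L,
                            min_frac = 0.1) {
  stopifnot(depth_D > 0)
  thr <- max(min_abs, min_frac * depth_D)
  ok <- clusters$support >= thr & clusters$unique_support >= min_abs
  list(candidates = clusters[ok, ],
       rejected = clusters[!ok, ] %>%
         mutate(reason = "noise sequences/alignment jitter"))
}

#' Check internal consistency of a candidate cluster
#'
#' A cluster is `contradictory` when its member alignments cannot describe
#' one physical junction: host-end positions spread over more than
#' `3 * insert_mean`; no member is uniquely mapped on both ends; forward-
#' and reverse-strand host ends interleave (implied fragments would overlap
#' impossibly); or plasmid-side positions within one flank scatter more
#' than `3 * insert_mean` (hits across unrelated elements).
#'
#' @param clusters candidate tibble.
#' @param chim the chimeric tibble the clusters were built from.
#' @param insert_mean library insert size.
#' @param read_len read length.
#' @return `clusters` with a `verdict` column
#'   (`"consistent"`/`"contradictory"`).
#' @export
consistency_check <- function(clusters, chim, insert_mean = 500,
                              read_len = 100L) {
  verdict <- vapply(seq_len(nrow(clusters)), function(i) {
    m <- chim %>% filter(.data$pair_id %in% clusters$members[[i]])
    if (clusters$unique_support[i] == 0) return("contradictory")
    if (diff(range(m$host_pos)) > 3 * insert_mean) return("contradictory")
    fwd <- m$host_pos[m$host_strand == "+"]
    rev <- m$host_pos[m$host_strand == "-"]
    if (length(fwd) > 0 && length(rev) > 0 &&
        max(fwd) > min(rev) + insert_mean) {
      return("contradictory")
    }
    for (side_pos in list(fwd, rev)) {
      sp <- m$plasmid_pos[m$host_pos %in% side_pos]
      if (length(sp) > 1 && diff(range(sp)) > 3 * insert_mean) {
        return("contradictory")
      }
    }
    "consistent"
  }, character(1))
  mutate(clusters, verdict = verdict)
}

#' Export candidate clusters as BED (span + support score)
#' @param clusters cluster tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clusters_bed <- function(clusters, path) {
  write_bed(clusters %>%
              mutate(name = sprintf("cluster_%d", row_number()),
                     score = .data$support),
            path)
}
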