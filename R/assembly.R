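# Junction contig assembly, split-alignment junction calling, integration
# calling and T-DNA arrangement inference.
#
# Contigs are assembled by a deterministic greedy overlap-layout assembler
# (longest admissible suffix-prefix overlap first; ties broken by the
# lexicographically smallest merged sequence). Each contig is then split-
# aligned: a host-matching part and a plasmid-matching part on a shared
# breakpoint. Micro-homology at the junction makes the exact split
# ambiguous (a run of bases matching both references scores identically on
# either side); among equal-scoring splits the caller prefers the split
# whose plasmid-side breakpoint sits on a T-DNA terminus — integration
# proceeds from the borders, so that is the biological prior — and
# otherwise the maximal-host split.

#' Assemble reads into contigs (greedy overlap-layout)
#'
#' @param reads character vector of read/contig sequences.
#' @param min_overlap minimum admissible suffix-prefix overlap (bp).
#' @param min_identity minimum identity within an overlap.
#' @return character vector of contigs, longest first.
#' @export
assemble_contigs <- function(reads, min_overlap = 30L, min_identity = 0.95) {
  if (length(reads) == 0) stop("assemble_contigs needs at least one read")
  as.character(cpp_assemble_greedy(reads, as.integer(min_overlap),
                                   min_identity))
}

# top diagonals (by seed count) of query against one subject strand;
# diag d means query[i] pairs with subject[i + d]. The query (contig) is
# the shorter string, so it is the one indexed.
seed_diags <- function(query, subject, w = 16L, top = 4L) {
  hits <- cpp_seed_hits(subject, query, as.integer(w))
  if (nrow(hits) == 0) return(integer(0))
  d <- hits$qpos - hits$spos     # qpos: subject coords; spos: query coords
  tab <- sort(table(d), decreasing = TRUE)
  as.integer(names(tab))[seq_len(min(top, length(tab)))]
}

# per-position cumulative match counts for a set of diagonals:
# rows = diagonals, cols = 0..n (prefix sums)
diag_prefix <- function(query, subject, diags) {
  n <- nchar(query)
  if (length(diags) == 0) return(NULL)
  m <- vapply(diags, function(d) {
    cumsum(c(0L, cpp_diag_matches(query, subject, d)))
  }, integer(n + 1))
  t(m)   # length(diags) x (n+1)
}

#' Split-align one contig into a host part and a plasmid part
#'
#' Tries both contig orientations and both arrangements (host prefix +
#' plasmid suffix = a 5' flank; plasmid prefix + host suffix = a 3'
#' flank). For each candidate breakpoint the host score is the best
#' prefix-match count over candidate host diagonals and the plasmid score
#' the best suffix-match count over candidate plasmid diagonals (both
#' strands); taking the per-side maximum lets a flank tolerate a haplotype
#' indel away from the junction. A call requires `min_overlap` bases at
#' `min_identity` immediately on each side of the breakpoint.
#'
#' @param contig contig sequence.
#' @param host host genome tibble.
#' @param pmap the `plasmid_map`.
#' @param min_overlap minimum anchored bases on each side of the split.
#' @param min_identity minimum identity in the `min_overlap` windows
#'   adjacent to the split.
#' @return tibble of junction calls (possibly 0 rows): `side`
#'   (`"left"` = host 5' flank, `"right"` = host 3' flank), `chrom`,
#'   `host_bp` (left: 0-based exclusive end of retained host; right:
#'   0-based first resumed host base), `plasmid_pos` (0-based first/last
#'   inserted base), `plasmid_strand`, `terminus` (`"start"`, `"end"` or
#'   `"internal"`), `element`, `score`, `contig_len`.
#' @export
call_junction <- function(contig, host, pmap, min_overlap = 30L,
                          min_identity = 0.9) {
  host <- as_seq_tbl(host)
  n <- nchar(contig)
  if (n < 2 * min_overlap) return(empty_junction_tbl())
  L <- pmap$length
  plas_rc <- revcomp(pmap$seq)
  out <- list()
  for (ori in c("+", "-")) {
    ctg <- if (ori == "+") contig else revcomp(contig)
    # candidate host diagonals across chromosomes
    hdiag <- purrr::map_dfr(seq_len(nrow(host)), function(ci) {
      d <- seed_diags(ctg, host$seq[ci], top = 4L)
      if (length(d) == 0) return(tibble())
      tibble(chrom = host$id[ci], diag = d)
    })
    pdiag <- bind_rows(
      tibble(strand = "+", diag = seed_diags(ctg, pmap$seq, top = 4L)),
      tibble(strand = "-", diag = seed_diags(ctg, plas_rc, top = 4L)))
    if (nrow(hdiag) == 0 || nrow(pdiag) == 0) next
    for (chrom in unique(hdiag$chrom)) {
      hd <- hdiag$diag[hdiag$chrom == chrom]
      hseq <- host$seq[host$id == chrom]
      Hpre <- diag_prefix(ctg, hseq, hd)
      Ppre_list <- lapply(seq_len(nrow(pdiag)), function(i) {
        subj <- if (pdiag$strand[i] == "+") pmap$seq else plas_rc
        cumsum(c(0L, cpp_diag_matches(ctg, subj, pdiag$diag[i])))
      })
      Ppre <- do.call(rbind, Ppre_list)
      cl <- best_split(ctg, Hpre, Ppre, hd, pdiag, chrom, pmap,
                       min_overlap, min_identity, n)
      if (!is.null(cl)) out[[length(out) + 1]] <- cl
    }
  }
  if (length(out) == 0) return(empty_junction_tbl())
  bind_rows(out) %>%
    mutate(contig_len = n) %>%
    group_by(.data$side) %>%
    arrange(desc(.data$score), .by_group = TRUE) %>%
    slice(1) %>%
    ungroup()
}

empty_junction_tbl <- function() {
  tibble(side = character(0), chrom = character(0), host_bp = integer(0),
         plasmid_pos = integer(0), plasmid_strand = character(0),
         terminus = character(0), element = character(0),
         score = integer(0), contig_len = integer(0))
}

# evaluate both split forms for one (orientation, chromosome) combination
best_split <- function(ctg, Hpre, Ppre, hd, pdiag, chrom, pmap,
                       min_overlap, min_identity, n) {
  need <- ceiling(min_identity * min_overlap)
  s_range <- seq.int(min_overlap, n - min_overlap)
  hbest <- apply(Hpre, 2, max)            # length n+1
  pbest <- apply(Ppre, 2, max)
  Ptot <- Ppre[, n + 1]
  # a genuine junction must explain more than any single reference can:
  # a contig lying entirely in host-plasmid-shared sequence (e.g. a
  # cisgene donor) scores ~n on one diagonal already and is no junction
  base_single <- max(hbest[n + 1], pbest[n + 1])
  res <- list()
  for (form in c("host_left", "host_right")) {
    if (form == "host_left") {
      total <- hbest[s_range + 1] +
        apply(Ptot - Ppre[, s_range + 1, drop = FALSE], 2, max)
    } else {
      Htot <- Hpre[, n + 1]
      total <- pbest[s_range + 1] +
        apply(Htot - Hpre[, s_range + 1, drop = FALSE], 2, max)
    }
    sc_max <- max(total)
    if (sc_max < 2 * need || sc_max < base_single + need) next
    tie <- s_range[total >= sc_max]       # exact-tie candidate splits
    cands <- purrr::map_dfr(tie, function(s) {
      describe_split(s, form, ctg, Hpre, Ppre, hd, pdiag, chrom, pmap,
                     min_overlap, need, n)
    })
    if (nrow(cands) == 0) next
    # border preference among exact score ties must itself be exact: a
    # breakpoint one base off a terminus is not the terminus
    cands <- cands %>%
      mutate(at_border = .data$plasmid_pos == pmap$tdna[["start"]] |
               .data$plasmid_pos == pmap$tdna[["end"]] - 1L) %>%
      arrange(desc(.data$at_border),
              if (form == "host_left") -.data$s else .data$s) %>%
      slice(1) %>%
      mutate(score = sc_max) %>%
      select(-"at_border", -"s")
    res[[length(res) + 1]] <- cands
  }
  if (length(res) == 0) return(NULL)
  bind_rows(res)
}

# constraints + coordinates for one candidate split position
describe_split <- function(s, form, ctg, Hpre, Ppre, hd, pdiag, chrom,
                           pmap, min_overlap, need, n) {
  L <- pmap$length
  if (form == "host_left") {
    h_win <- Hpre[, s + 1] - Hpre[, s + 1 - min_overlap]
    hi <- which.max(h_win)
    p_win <- Ppre[, s + 1 + min_overlap] - Ppre[, s + 1]
    pi <- which.max(p_win)
    if (h_win[hi] < need || p_win[pi] < need) return(tibble())
    host_bp <- hd[hi] + s                  # exclusive end of host prefix
    pd <- pdiag$diag[pi]
    pstrand <- pdiag$strand[pi]
    ppos <- if (pstrand == "+") (pd + s) %% L else (L - 1L - (pd + s)) %% L
    side <- "left"
  } else {
    p_win <- Ppre[, s + 1] - Ppre[, s + 1 - min_overlap]
    pi <- which.max(p_win)
    h_win <- Hpre[, s + 1 + min_overlap] - Hpre[, s + 1]
    hi <- which.max(h_win)
    if (h_win[hi] < need || p_win[pi] < need) return(tibble())
    host_bp <- hd[hi] + s                  # first resumed host base
    pd <- pdiag$diag[pi]
    pstrand <- pdiag$strand[pi]
    ppos <- if (pstrand == "+") (pd + s - 1L) %% L
            else (L - 1L - (pd + s - 1L)) %% L
    side <- "right"
  }
  terminus <- plasmid_terminus(ppos, pmap)
  tibble(s = s, side = side, chrom = chrom,
         host_bp = as.integer(host_bp), plasmid_pos = as.integer(ppos),
         plasmid_strand = pstrand, terminus = terminus,
         element = element_at(ppos, pmap))
}

plasmid_terminus <- function(pos, pmap, tol = 50L) {
  if (abs(pos - pmap$tdna[["start"]]) <= tol) return("start")
  if (abs(pos - (pmap$tdna[["end"]] - 1L)) <= tol) return("end")
  "internal"
}

# annotated element containing (or within 50 bp of) a plasmid position
element_at <- function(pos, pmap, tol = 50L) {
  el <- pmap$elements
  inside <- el$start <= pos & pos < el$end
  if (any(inside)) {
    # smallest containing element is the most specific annotation
    cand <- el[inside, ]
    return(cand$name[which.min(cand$end - cand$start)])
  }
  d <- pmin(abs(el$start - pos), abs(pos - (el$end - 1L)))
  if (any(d <= tol)) return(el$name[which.min(d)])
  "unannotated"
}

#' Call the integration event from junction calls
#'
#' Junction calls from all contigs are pooled; the modal breakpoint per
#' flank defines the call. With left-flank breakpoint `L` (0-based
#' exclusive end of retained host) and right-flank breakpoint `R` (0-based
#' first resumed host base), the reported locus is the 1-based coordinate
#' of the last retained 5'-flank host base (= `L`) and the deletion length
#' is `R - L`; a genome built with deletion `d` returns exactly `d`. With
#' single-flank evidence the deletion is reported as `NA`, not 0.
#'
#' @param junctions junction-call tibble (rows from [call_junction()],
#'   possibly from many contigs).
#' @param copy_number estimated copy number (used for arrangement
#'   inference); may be `NA`.
#' @return an `integration_call` object.
#' @export
call_integration <- function(junctions, copy_number = NA_real_) {
  if (nrow(junctions) == 0) stop("no junction contigs to call from")
  chroms <- unique(junctions$chrom)
  if (length(chroms) > 1) {
    stop("junctions on different chromosomes: ",
         paste(chroms, collapse = ", "))
  }
  modal <- function(x) {
    if (length(x) == 0) return(NA)
    names(sort(table(x), decreasing = TRUE))[1]
  }
  left <- junctions %>% filter(.data$side == "left")
  right <- junctions %>% filter(.data$side == "right")
  L <- if (nrow(left) > 0) as.integer(modal(left$host_bp)) else NA_integer_
  R <- if (nrow(right) > 0) as.integer(modal(right$host_bp)) else
    NA_integer_
  deletion <- if (!is.na(L) && !is.na(R)) R - L else NA_integer_
  if (!is.na(deletion) && deletion < 0) {
    warning("right breakpoint left of left breakpoint; deletion set NA")
    deletion <- NA_integer_
  }
  call <- structure(list(
    chr = chroms,
    locus = if (!is.na(L)) L else R,       # 1-based last retained base
    deletion_len = deletion,
    element_5p = if (nrow(left) > 0) modal(left$element) else NA_character_,
    element_3p = if (nrow(right) > 0) modal(right$element) else
      NA_character_,
    strand_5p = if (nrow(left) > 0) modal(left$plasmid_strand) else
      NA_character_,
    strand_3p = if (nrow(right) > 0) modal(right$plasmid_strand) else
      NA_character_,
    terminus_5p = if (nrow(left) > 0) modal(left$terminus) else
      NA_character_,
    terminus_3p = if (nrow(right) > 0) modal(right$terminus) else
      NA_character_,
    copy_number = copy_number,
    n_left = nrow(left), n_right = nrow(right),
    junctions = junctions), class = "integration_call")
  call$arrangement <- infer_arrangement(call, copy_number)
  call
}

#' Infer the T-DNA arrangement at an integration site
#'
#' Rules (with `copies` = rounded copy number): one copy with the two
#' flanks on opposite T-DNA termini gives `single`; two copies with both
#' flanks on the same terminus and opposite strands give `head_to_head`
#' (the insert is an inverted repeat, so both host flanks meet the same
#' T-DNA end); two copies with opposite termini on the same strand give
#' `tandem_head_to_tail`; anything else is `unresolved`.
#'
#' @param call an `integration_call` (or list with `terminus_5p`,
#'   `terminus_3p`, `strand_5p`, `strand_3p`).
#' @param copy_number copy-number estimate.
#' @return arrangement label.
#' @export
infer_arrangement <- function(call, copy_number) {
  if (is.na(copy_number) || is.na(call$terminus_5p) ||
      is.na(call$terminus_3p)) {
    return("unresolved")
  }
  copies <- round(copy_number)
  t5 <- call$terminus_5p
  t3 <- call$terminus_3p
  opp_termini <- setequal(c(t5, t3), c("start", "end"))
  same_strand <- identical(call$strand_5p, call$strand_3p)
  if (copies == 1 && opp_termini && same_strand) return("single")
  if (copies == 2 && t5 == t3 && t5 != "internal" && !same_strand) {
    return("head_to_head")
  }
  if (copies == 2 && opp_termini && same_strand) {
    return("tandem_head_to_tail")
  }
  "unresolved"
}

#' @export
print.integration_call <- function(x, ...) {
  cat("<integration_call>\n")
  cat(sprintf("  %s : locus %s (1-based), deletion %s bp\n", x$chr,
              format(x$locus, big.mark = ","),
              ifelse(is.na(x$deletion_len), "unresolved",
                     x$deletion_len)))
  cat(sprintf("  flanks: 5' -> %s (%s, terminus %s) | 3' -> %s (%s, terminus %s)\n",
              x$element_5p, x$strand_5p, x$terminus_5p,
              x$element_3p, x$strand_3p, x$terminus_3p))
  cat(sprintf("  copy number %.2f, arrangement %s\n",
              x$copy_number, x$arrangement))
  cat(sprintf("  evidence: %d left-flank and %d right-flank junction call(s)\n",
              x$n_left, x$n_right))
  invisible(x)
}

#' @export
tidy.integration_call <- function(x, ...) {
  tibble(chr = x$chr, locus = x$locus, deletion_len = x$deletion_len,
         element_5p = x$element_5p, element_3p = x$element_3p,
         strand_5p = x$strand_5p, strand_3p = x$strand_3p,
         copy_number = x$copy_number, arrangement = x$arrangement,
         n_left = x$n_left, n_right = x$n_right)
}

#' Collect the read set for assembling a candidate cluster
#'
#' Takes both mates of every member pair, plus the reads of `one_unmapped`
#' pairs whose mapped end lies on the cluster chromosome within
#' `insert_mean` of the cluster span — the unmapped mates of such pairs
#' are exactly the reads that physically contain the junction (they fail
#' ungapped mapping) and are required for contigs to bridge host and
#' insert.
#'
#' @param pa the `pair_alignments`.
#' @param cluster one row of a cluster tibble.
#' @param insert_mean library insert size.
#' @param what `"all"` (default) or `"orphans"` (only the unmapped mates
#'   of the qualifying `one_unmapped` pairs — the junction-spanning
#'   reads).
#' @param pmap optional `plasmid_map`; when given, plasmid-side orphan
#'   mates must lie within one insert of a T-DNA terminus (where junction
#'   fragments physically end), which keeps unrelated unmapped-mate noise
#'   out of the assembly.
#' @return character vector of read sequences.
#' @export
gather_cluster_reads <- function(pa, cluster, insert_mean = 500,
                                 what = c("all", "orphans"),
                                 pmap = NULL) {
  what <- match.arg(what)
  member <- pa$pairs$pair_id %in% cluster$members[[1]]
  lo <- cluster$start - insert_mean
  hi <- cluster$end + insert_mean
  near <- function(ref, pos) {
    !is.na(ref) & ref == cluster$chrom & pos >= lo & pos <= hi
  }
  # a junction-spanning read is unmapped and its mate sits either on the
  # host flank near the cluster or inside the insert near a T-DNA
  # terminus; both mate configurations occur, one per junction side
  plasmid_ids <- pa$refs$id[pa$refs$is_plasmid]
  near_plasmid <- function(ref, pos) {
    ok <- !is.na(ref) & ref %in% plasmid_ids
    if (is.null(pmap)) return(ok)
    term <- c(pmap$tdna[["start"]], pmap$tdna[["end"]])
    reach <- insert_mean + 100
    ok & (abs(pos - term[1]) <= reach | abs(pos - term[2]) <= reach)
  }
  orphan <- pa$pairs$pair_class == "one_unmapped" &
    (near(pa$pairs$ref1, pa$pairs$pos1) |
       near(pa$pairs$ref2, pa$pairs$pos2) |
       near_plasmid(pa$pairs$ref1, pa$pairs$pos1) |
       near_plasmid(pa$pairs$ref2, pa$pairs$pos2))
  if (what == "orphans") {
    # return only the unmapped end of each orphan pair
    end1_mapped <- !is.na(pa$pairs$ref1)
    return(c(pa$reads$seq1[orphan & !end1_mapped],
             pa$reads$seq2[orphan & end1_mapped]))
  }
  sel <- member | orphan
  c(pa$reads$seq1[sel], pa$reads$seq2[sel])
}

#' Assemble a cluster and collect junction-call votes
#'
#' Junction calls are made on every assembled contig and, in addition, on
#' every raw junction-spanning read (the unmapped mates of nearby
#' `one_unmapped` pairs). Contigs give long, well-anchored splits; the
#' raw reads contribute many independent votes, so a single sequencing
#' error adjacent to the breakpoint in one contig cannot shift the modal
#' breakpoint.
#'
#' @inheritParams gather_cluster_reads
#' @param host host genome tibble.
#' @param pmap the `plasmid_map`.
#' @param min_overlap,assembly_min_identity greedy-assembler settings.
#' @param junction_min_identity split-alignment identity.
#' @return list with `contigs` (character) and `junctions` (tibble of
#'   pooled junction calls).
#' @export
junction_votes <- function(pa, cluster, host, pmap, insert_mean = 500,
                           min_overlap = 30L,
                           assembly_min_identity = 0.95,
                           junction_min_identity = 0.9) {
  reads <- gather_cluster_reads(pa, cluster, insert_mean, pmap = pmap)
  ctg <- assemble_contigs(reads, min_overlap, assembly_min_identity)
  span <- gather_cluster_reads(pa, cluster, insert_mean, "orphans", pmap)
  # a few dozen independent read votes are ample to outvote a stray error
  if (length(span) > 60) span <- span[seq_len(60)]
  # vote on merged contigs and on the raw junction-spanning reads;
  # unmerged singletons in `ctg` duplicate the read set and are skipped
  read_len <- max(nchar(span), 0L, nchar(reads))
  merged <- ctg[nchar(ctg) > read_len]
  jn <- purrr::map_dfr(c(merged, span), call_junction, host = host,
                       pmap = pmap, min_overlap = min_overlap,
                       min_identity = junction_min_identity)
  list(contigs = ctg, junctions = jn)
}
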