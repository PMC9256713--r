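# Plasmid-vs-host homology search and the exclusion blacklist.
#
# A BLAST-like search (exact word seeding, per-diagonal chaining, ungapped
# end extension) finds host segments similar to any part of the plasmid —
# native promoters, RNAi target genes, and the like. Each block, expanded
# by one library-insert on both sides, defines intervals where a chimeric
# pair is uninformative; pairs touching the blacklist on either side are
# removed before candidate clustering.

#' Find homologous blocks between a plasmid and a host genome
#'
#' Exact `word_size`-mer seeds between the (circular) plasmid and each host
#' chromosome are grouped per diagonal and chained into blocks; block ends
#' are extended ungapped under an X-drop rule (+1 match, -2 mismatch,
#' drop 20). Both plasmid strands are searched. Blocks shorter than
#' `min_block_len` or below `min_identity` are dropped.
#'
#' @param pmap a `plasmid_map` (searched as a circle).
#' @param host host genome tibble.
#' @param word_size exact seed length.
#' @param min_identity minimum block identity.
#' @param min_block_len minimum block length (bp).
#' @return tibble: `chrom`, `host_start`, `host_end`, `plasmid_start`,
#'   `plasmid_end`, `strand`, `length`, `identity` (host coords 0-based
#'   half-open; plasmid coords on the forward strand, modulo plasmid
#'   length).
#' @export
find_homology_blocks <- function(pmap, host, word_size = 16L,
                                 min_identity = 0.9, min_block_len = 50L) {
  host <- as_seq_tbl(host)
  L <- pmap$length
  if (word_size > L) stop("word_size exceeds plasmid length")
  # doubled sequence so blocks may span the circular origin
  plas2 <- paste0(pmap$seq, pmap$seq)
  out <- list()
  for (ci in seq_len(nrow(host))) {
    chrom <- host$id[ci]
    hseq <- host$seq[ci]
    for (strand in c("+", "-")) {
      q <- if (strand == "+") plas2 else revcomp(plas2)
      seeds <- as_tibble(cpp_seed_hits(q, hseq, as.integer(word_size)))
      if (nrow(seeds) == 0) next
      seeds <- seeds %>%
        mutate(diag = .data$spos - .data$qpos) %>%
        arrange(.data$diag, .data$qpos)
      # chain seeds on a diagonal when gaps are below the word size
      seeds <- seeds %>%
        group_by(.data$diag) %>%
        mutate(brk = cumsum(c(0L, diff(.data$qpos)) > 3L * word_size)) %>%
        group_by(.data$diag, .data$brk) %>%
        summarise(q0 = min(.data$qpos),
                  q1 = max(.data$qpos) + word_size, .groups = "drop")
      for (i in seq_len(nrow(seeds))) {
        blk <- extend_block(q, hseq, seeds$q0[i], seeds$q1[i],
                            seeds$diag[i])
        if (is.null(blk)) next
        len <- blk$q1 - blk$q0
        if (len < min_block_len || blk$identity < min_identity) next
        if (blk$q0 >= L) next        # duplicate from the doubled copy
        if (strand == "+") {
          ps <- blk$q0 %% L
          pe <- ((blk$q1 - 1L) %% L) + 1L
        } else {
          ps <- (2L * L - blk$q1) %% L
          pe <- ((2L * L - 1L - blk$q0) %% L) + 1L
        }
        out[[length(out) + 1]] <- tibble(
          chrom = chrom,
          host_start = blk$q0 + seeds$diag[i],
          host_end = blk$q1 + seeds$diag[i],
          plasmid_start = ps, plasmid_end = pe, strand = strand,
          length = len, identity = blk$identity)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(0), host_start = integer(0),
                  host_end = integer(0), plasmid_start = integer(0),
                  plasmid_end = integer(0), strand = character(0),
                  length = integer(0), identity = numeric(0)))
  }
  blocks <- bind_rows(out) %>% distinct() %>%
    arrange(.data$chrom, .data$host_start)
  # collapse blocks nested in a longer one on the same chromosome/strand
  blocks %>%
    group_by(.data$chrom, .data$strand) %>%
    filter(!duplicated_nested(.data$host_start, .data$host_end)) %>%
    ungroup()
}

duplicated_nested <- function(start, end) {
  n <- length(start)
  nested <- logical(n)
  for (i in seq_len(n)) {
    nested[i] <- any(start <= start[i] & end >= end[i] &
                       (start < start[i] | end > end[i]))
  }
  nested
}

# ungapped X-drop extension of a seeded run [q0, q1) on a fixed diagonal
extend_block <- function(q, s, q0, q1, diag, match = 1, mismatch = -2,
                         xdrop = 20) {
  qc <- charToRaw(q)
  sc <- charToRaw(s)
  rawN <- charToRaw("N")
  nq <- length(qc)
  ns <- length(sc)
  step <- function(from, dir) {
    best <- from
    score <- 0
    best_score <- 0
    i <- from
    repeat {
      i <- i + dir
      j <- i + diag
      if (i < 0 || i >= nq || j < 0 || j >= ns) break
      hit <- qc[i + 1] == sc[j + 1] && qc[i + 1] != rawN  # N never matches
      score <- score + if (hit) match else mismatch
      if (score > best_score) { best_score <- score; best <- i }
      if (score < best_score - xdrop) break
    }
    best
  }
  e0 <- step(q0, -1L)
  e1 <- step(q1 - 1L, 1L) + 1L
  if (e1 <= e0) return(NULL)
  idx <- (e0 + 1):e1
  matches <- sum(qc[idx] == sc[idx + diag] & qc[idx] != rawN)
  list(q0 = e0, q1 = e1, identity = matches / (e1 - e0))
}

#' Build the exclusion blacklist from homology blocks
#'
#' Every block's host and plasmid intervals are expanded by `margin` on
#' both sides (the library insert size, so any pair with an end generated
#' inside a homologous segment is caught), clipped to reference bounds and
#' merged.
#'
#' @param blocks tibble from [find_homology_blocks()].
#' @param pmap the `plasmid_map` (for plasmid length clipping).
#' @param host host genome tibble (for chromosome length clipping).
#' @param margin expansion in bp (default 500 = insert size).
#' @return a `blacklist`: list of `host` (tibble chrom/start/end) and
#'   `plasmid` (tibble start/end) merged intervals, plus `margin`.
#' @export
build_blacklist <- function(blocks, pmap, host, margin = 500L) {
  stopifnot(margin >= 0)
  host <- as_seq_tbl(host)
  hlen <- setNames(nchar(host$seq), host$id)
  host_iv <- blocks %>%
    mutate(start = pmax(0L, .data$host_start - as.integer(margin)),
           end = pmin(unname(hlen[.data$chrom]),
                      .data$host_end + as.integer(margin))) %>%
    select("chrom", "start", "end")
  host_merged <- host_iv %>%
    group_by(.data$chrom) %>%
    dplyr::group_modify(~ from_iranges(IRanges::reduce(
      to_iranges(.x$start, .x$end)))) %>%
    ungroup()
  plas_iv <- blocks %>%
    mutate(start = pmax(0L, .data$plasmid_start - as.integer(margin)),
           end = pmin(pmap$length, .data$plasmid_end + as.integer(margin)))
  plas_merged <- if (nrow(plas_iv) == 0) {
    tibble(start = integer(0), end = integer(0))
  } else {
    from_iranges(IRanges::reduce(to_iranges(plas_iv$start, plas_iv$end)))
  }
  structure(list(host = host_merged, plasmid = plas_merged,
                 plasmid_id = pmap$id, margin = as.integer(margin)),
            class = "blacklist")
}

#' @export
print.blacklist <- function(x, ...) {
  cat("<blacklist> margin ", x$margin, " bp: ", nrow(x$host),
      " host interval(s), ", nrow(x$plasmid), " plasmid interval(s)\n",
      sep = "")
  invisible(x)
}

#' Test blacklist membership of a position
#'
#' @param bl a `blacklist`.
#' @param ref_id reference name (a host chromosome or the plasmid id).
#' @param pos 0-based position(s).
#' @return logical vector; `FALSE` for unknown references.
#' @export
in_blacklist <- function(bl, ref_id, pos) {
  vapply(pos, function(p) {
    if (identical(ref_id, bl$plasmid_id)) {
      any(bl$plasmid$start <= p & p < bl$plasmid$end)
    } else {
      iv <- bl$host[bl$host$chrom == ref_id, ]
      any(iv$start <= p & p < iv$end)
    }
  }, logical(1))
}

#' Export a blacklist as BED (host) and TSV (plasmid)
#' @param bl a `blacklist`.
#' @param prefix output path prefix (`<prefix>.host.bed`,
#'   `<prefix>.plasmid.tsv`).
#' @return the two paths, invisibly.
#' @export
write_blacklist <- function(bl, prefix) {
  bed <- paste0(prefix, ".host.bed")
  tsv <- paste0(prefix, ".plasmid.tsv")
  write_bed(bl$host, bed)
  utils::write.table(bl$plasmid, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(bed, tsv))
}

#' Import homology blocks from an external tabular search (outfmt-6 style)
#'
#' Accepts a 12-column BLASTN `-outfmt 6` table (query = plasmid, subject =
#' host) as an alternative block source.
#'
#' @param path path to the tab-separated table.
#' @return block tibble compatible with [build_blacklist()].
#' @export
read_blast_blocks <- function(path) {
  x <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(x)[1:12] <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                      "gapopen", "qstart", "qend", "sstart", "send",
                      "evalue", "bitscore")
  tibble(chrom = x$sseqid,
         host_start = pmin(x$sstart, x$send) - 1L,
         host_end = pmax(x$sstart, x$send),
         plasmid_start = x$qstart - 1L,
         plasmid_end = x$qend,
         strand = if_else(x$send >= x$sstart, "+", "-"),
         length = x$length,
         identity = x$pident / 100)
}
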