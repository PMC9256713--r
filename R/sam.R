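# Minimal SAM dialect for interoperability with external aligner runs:
# @SQ headers; FLAG bits 0x1 (paired), 0x4 (unmapped), 0x8 (mate unmapped),
# 0x10 (reverse), 0x40 (first in pair), 0x80 (second in pair); CIGAR is a
# single match-length; pairs are reconstructed by QNAME.

#' Write pair alignments as SAM
#'
#' @param pa a `pair_alignments` object from [map_pairs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(pa, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", pa$refs$id, nchar(pa$refs$seq)),
             con)
  p <- pa$pairs
  rl <- nchar(pa$reads$seq1[1])
  line_for <- function(end) {
    ref <- p[[paste0("ref", end)]]
    pos <- p[[paste0("pos", end)]]
    strand <- p[[paste0("strand", end)]]
    mref <- p[[paste0("ref", 3 - end)]]
    unmapped <- is.na(ref)
    flag <- 1L + ifelse(end == 1, 64L, 128L) +
      ifelse(unmapped, 4L, 0L) +
      ifelse(is.na(mref), 8L, 0L) +
      ifelse(!unmapped & strand == "-", 16L, 0L)
    seqs <- if (end == 1) pa$reads$seq1 else pa$reads$seq2
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
            p$pair_id, flag,
            ifelse(unmapped, "*", ref),
            ifelse(unmapped, 0L, pos + 1L),          # SAM POS is 1-based
            ifelse(unmapped, 0L, 60L),
            ifelse(unmapped, "*", paste0(rl, "M")),
            seqs)
  }
  writeLines(c(line_for(1L), line_for(2L)), con)
  invisible(path)
}

#' Read a minimal SAM file into pair alignments
#'
#' Reconstructs per-pair records by QNAME; both mates must be present.
#' Only FLAG bits 0x1/0x4/0x8/0x10/0x40/0x80 and CIGAR operators M/I/D/S
#' are interpreted; the leftmost position is converted to 0-based.
#'
#' @param path SAM path.
#' @param refs optional [ref_set()]; when given, RNAMEs are validated
#'   against it and plasmid references identified. Otherwise references
#'   are taken from @SQ headers and none is treated as plasmid.
#' @return a `pair_alignments`-shaped list (`pairs`, `reads`, `refs`).
#' @export
read_sam <- function(path, refs = NULL) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  sq_names <- sub(".*\\tSN:([^\\t]+).*", "\\1", sq)
  if (is.null(refs)) {
    refs <- structure(tibble(id = sq_names, seq = NA_character_,
                             is_plasmid = FALSE),
                      class = c("ref_set", "tbl_df", "tbl", "data.frame"))
  }
  f <- strsplit(body, "\t")
  rec <- tibble(
    qname = vapply(f, `[`, "", 1),
    flag = as.integer(vapply(f, `[`, "", 2)),
    rname = vapply(f, `[`, "", 3),
    pos = as.integer(vapply(f, `[`, "", 4)) - 1L,
    cigar = vapply(f, `[`, "", 6),
    seq = vapply(f, `[`, "", 10)
  ) %>%
    mutate(unmapped = bitwAnd(.data$flag, 4L) > 0L,
           end = if_else(bitwAnd(.data$flag, 64L) > 0L, 1L, 2L),
           strand = if_else(bitwAnd(.data$flag, 16L) > 0L, "-", "+"))
  bad <- !rec$unmapped & !(rec$rname %in% refs$id)
  if (any(bad)) stop("unknown RNAME in SAM: ", rec$rname[which(bad)[1]])
  counts <- table(rec$qname)
  if (any(counts != 2)) {
    stop("missing mate for QNAME: ", names(counts)[counts != 2][1])
  }
  # matched reference length from CIGAR M/D ops (I/S consume read only)
  rec$matched_len <- vapply(rec$cigar, function(cg) {
    if (cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDS]", cg))[[1]]
    sum(vapply(ops, function(o) {
      n <- as.integer(sub("[MIDS]$", "", o))
      if (grepl("[MD]$", o)) n else 0L
    }, integer(1)))
  }, integer(1))

  plasmid_of <- function(r) {
    ifelse(is.na(r), NA, refs$is_plasmid[match(r, refs$id)])
  }
  one_end <- function(e) {
    rec %>% filter(.data$end == e) %>%
      mutate(ref = if_else(.data$unmapped, NA_character_, .data$rname),
             pos = if_else(.data$unmapped, NA_integer_, .data$pos),
             strand = if_else(.data$unmapped, NA_character_,
                              .data$strand)) %>%
      select("qname", "ref", "pos", "strand", "seq", "matched_len")
  }
  e1 <- one_end(1L)
  e2 <- one_end(2L)
  ord <- match(e1$qname, e2$qname)
  e2 <- e2[ord, ]
  pairs <- tibble(pair_id = e1$qname,
                  ref1 = e1$ref, plasmid1 = plasmid_of(e1$ref),
                  pos1 = e1$pos, strand1 = e1$strand,
                  ref2 = e2$ref, plasmid2 = plasmid_of(e2$ref),
                  pos2 = e2$pos, strand2 = e2$strand) %>%
    mutate(pair_class = classify_pair(.data$plasmid1, .data$plasmid2))
  reads <- tibble(pair_id = e1$qname, seq1 = e1$seq, seq2 = e2$seq)
  structure(list(pairs = pairs, hits = NULL, reads = reads, refs = refs),
            class = "pair_alignments")
}
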