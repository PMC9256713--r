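# Minimal seed-and-extend paired-end mapper plus depth statistics.
#
# Reads are placed by exact 31-mer seeding (three seed offsets per strand)
# followed by full-length ungapped extension; a read is unmapped when its
# best placement exceeds `max_mismatch_frac` mismatches. Gapped alignment is
# deliberately absent: junctions are resolved by assembly, not CIGARs, and
# reads carrying an indel or a junction simply drop out as unmapped.

#' Build a reference set for mapping
#'
#' @param host host genome (tibble `id`/`seq` or named character vector).
#' @param pmap optional `plasmid_map`; its sequence is appended as an extra
#'   reference flagged as plasmid.
#' @return a `ref_set`: tibble `id`, `seq`, `is_plasmid` with class attr.
#' @export
ref_set <- function(host, pmap = NULL) {
  host <- as_seq_tbl(host)
  refs <- mutate(host, is_plasmid = FALSE)
  if (!is.null(pmap)) {
    refs <- bind_rows(refs, tibble(id = pmap$id, seq = pmap$seq,
                                   is_plasmid = TRUE))
  }
  structure(refs, class = c("ref_set", class(refs)))
}

#' Map reads against a reference set
#'
#' Returns one row per best-tier hit (ties are all reported with
#' `unique = FALSE`). The primary hit per read, used for pair
#' classification, prefers a plasmid reference over a host reference among
#' equal-best hits — multi-copy inserted sequence and host-homologous
#' plasmid elements then accumulate on the plasmid copy, which is what the
#' depth-based copy-number subtraction assumes — then lowest reference
#' index and position.
#'
#' @param reads character vector of read sequences.
#' @param refs a [ref_set()].
#' @param k seed length (default 31).
#' @param max_mismatch_frac maximum mismatch fraction for a mapped read.
#' @return tibble: `read` (index into `reads`), `ref_id`, `is_plasmid`,
#'   `pos` (0-based leftmost), `strand`, `mismatches`, `unique`, `primary`.
#'   Unmapped reads have no rows.
#' @export
map_reads <- function(reads, refs, k = 31L, max_mismatch_frac = 0.1) {
  stopifnot(inherits(refs, "ref_set"))
  if (nrow(refs) == 0) stop("empty reference index")
  hits <- as_tibble(cpp_map_reads(refs$seq, reads, as.integer(k),
                                  max_mismatch_frac))
  if (nrow(hits) == 0) {
    return(tibble(read = integer(0), ref_id = character(0),
                  is_plasmid = logical(0), pos = integer(0),
                  strand = character(0), mismatches = integer(0),
                  unique = logical(0), primary = logical(0)))
  }
  hits %>%
    mutate(ref_id = refs$id[.data$ref],
           is_plasmid = refs$is_plasmid[.data$ref],
           unique = .data$n_best == 1L) %>%
    group_by(.data$read) %>%
    arrange(desc(.data$is_plasmid), .data$ref, .data$pos,
            .by_group = TRUE) %>%
    mutate(primary = row_number() == 1L) %>%
    ungroup() %>%
    select("read", "ref_id", "is_plasmid", "pos", "strand",
           "mismatches", "unique", "primary")
}

#' Map and classify read pairs
#'
#' Maps both ends of every pair and derives the pair class:
#' `both_host`, `both_plasmid`, `chimeric_host_plasmid` (one end host, one
#' end plasmid — junction evidence), `one_unmapped`, `both_unmapped`.
#' Classification uses each end's primary hit and is symmetric in end
#' order.
#'
#' @param reads read tibble from [simulate_reads()] / [read_fastq_pair()].
#' @param refs a [ref_set()].
#' @inheritParams map_reads
#' @return a `pair_alignments` object: list with `pairs` (one row per pair:
#'   `pair_id`, per-end ref/pos/strand/unique, `pair_class`), `hits` (all
#'   best-tier hits, ends keyed by `pair_id` + `end`), `reads` (the input),
#'   and `refs`.
#' @export
map_pairs <- function(reads, refs, k = 31L, max_mismatch_frac = 0.1) {
  n <- nrow(reads)
  all_seq <- c(reads$seq1, reads$seq2)
  hits <- map_reads(all_seq, refs, k, max_mismatch_frac) %>%
    mutate(pair = (.data$read - 1L) %% n + 1L,
           end = (.data$read - 1L) %/% n + 1L,
           pair_id = reads$pair_id[.data$pair]) %>%
    select(-"read")

  prim <- hits %>% filter(.data$primary)
  end_tbl <- function(e) {
    prim %>% filter(.data$end == e) %>%
      select("pair", ref = "ref_id", plasmid = "is_plasmid",
             pos = "pos", strand = "strand", uniq = "unique",
             mm = "mismatches")
  }
  e1 <- end_tbl(1L)
  e2 <- end_tbl(2L)
  pairs <- tibble(pair = seq_len(n), pair_id = reads$pair_id) %>%
    left_join(rename_with_suffix(e1, "1"), by = "pair") %>%
    left_join(rename_with_suffix(e2, "2"), by = "pair") %>%
    mutate(pair_class = classify_pair(.data$plasmid1, .data$plasmid2)) %>%
    select(-"pair")
  structure(list(pairs = pairs, hits = hits, reads = reads, refs = refs,
                 k = k, max_mismatch_frac = max_mismatch_frac),
            class = "pair_alignments")
}

rename_with_suffix <- function(x, suf) {
  nm <- setdiff(names(x), "pair")
  names(x)[match(nm, names(x))] <- paste0(nm, suf)
  x
}

#' Classify a pair from its two ends' reference categories
#'
#' @param plasmid1,plasmid2 logical: is the end's primary hit on a plasmid
#'   reference? `NA` = unmapped.
#' @return character vector of pair classes.
#' @export
classify_pair <- function(plasmid1, plasmid2) {
  dplyr::case_when(
    is.na(plasmid1) & is.na(plasmid2) ~ "both_unmapped",
    is.na(plasmid1) | is.na(plasmid2) ~ "one_unmapped",
    plasmid1 & plasmid2 ~ "both_plasmid",
    !plasmid1 & !plasmid2 ~ "both_host",
    TRUE ~ "chimeric_host_plasmid")
}

#' @export
print.pair_alignments <- function(x, ...) {
  tab <- table(x$pairs$pair_class)
  cat("<pair_alignments> ", nrow(x$pairs), " pairs vs ",
      nrow(x$refs), " references\n", sep = "")
  for (nm in names(tab)) cat("  ", nm, ": ", tab[[nm]], "\n", sep = "")
  invisible(x)
}

#' Coverage calibrator R
#'
#' Fraction of read pairs whose both ends map to the host genome among all
#' trimmed pairs; corrects depth-derived quantities for unmapped data.
#'
#' @param mapped_pairs pairs mapped to the host genome.
#' @param total_pairs total trimmed pairs.
#' @return R in (0, 1].
#' @export
coverage_calibrator <- function(mapped_pairs, total_pairs) {
  if (any(total_pairs <= 0)) stop("total_pairs must be positive")
  stopifnot(all(mapped_pairs <= total_pairs), all(mapped_pairs >= 0))
  mapped_pairs / total_pairs
}

#' General sequencing depth D
#'
#' `D = 2 * read_len * total_pairs / ref_len`, computed from total trimmed
#' pairs (before mapping; R separately corrects for unmapped reads).
#'
#' @param total_pairs total trimmed read pairs.
#' @param read_len read length.
#' @param ref_len host genome length.
#' @return fold coverage.
#' @export
general_depth <- function(total_pairs, read_len, ref_len) {
  stopifnot(read_len > 0, ref_len > 0, total_pairs >= 0)
  2 * read_len * total_pairs / ref_len
}

#' Average sequencing depth over a target interval (ADT)
#'
#' Mean per-base coverage of mapped read ends overlapping the interval.
#'
#' @param aln alignment hit tibble (needs `ref_id`, `pos`, plus the read
#'   length implied by `read_len`); typically `x$hits %>% filter(primary)`.
#' @param ref_id reference the interval lives on.
#' @param start,end 0-based half-open interval.
#' @param read_len aligned read length.
#' @param unique_only count uniquely mapped ends only.
#' @return mean coverage (ADT).
#' @export
average_target_depth <- function(aln, ref_id, start, end, read_len = 100L,
                                 unique_only = FALSE) {
  if (end <= start) stop("zero-length interval")
  a <- aln %>% filter(.data$ref_id == !!ref_id)
  if (unique_only && "unique" %in% names(a)) a <- filter(a, .data$unique)
  if (nrow(a) == 0) return(0)
  w <- max(end, max(a$pos) + read_len)
  cov <- IRanges::coverage(to_iranges(a$pos, a$pos + read_len), width = w)
  unname(IRanges::viewMeans(IRanges::Views(cov, start + 1L, end)))
}

#' Depth statistics for a sample
#'
#' Bundles the genome depth `D`, the coverage calibrator `R`, and per-
#' element average target depths over the plasmid map (plus the host `SPS`
#' calibrator interval when given).
#'
#' @param pa a `pair_alignments`.
#' @param pmap the `plasmid_map`.
#' @param sps optional host calibrator interval: list/row with `chrom`,
#'   `start`, `end` — a single-copy endogenous reference gene.
#' @param read_len read length.
#' @return a `depth_stats` list: `D`, `R`, `adt` tibble (element, adt).
#' @export
depth_stats <- function(pa, pmap, sps = NULL, read_len = 100L) {
  host_len <- sum(nchar(pa$refs$seq[!pa$refs$is_plasmid]))
  total <- nrow(pa$pairs)
  D <- general_depth(total, read_len, host_len)
  R <- coverage_calibrator(sum(pa$pairs$pair_class == "both_host"), total)
  prim <- pa$hits %>% filter(.data$primary)
  adt <- purrr::map_dfr(seq_len(nrow(pmap$elements)), function(i) {
    e <- pmap$elements[i, ]
    tibble(element = e$name,
           adt = average_target_depth(prim, pmap$id, e$start, e$end,
                                      read_len))
  })
  if (!is.null(sps)) {
    adt <- bind_rows(adt, tibble(
      element = "SPS",
      adt = average_target_depth(prim, sps$chrom, sps$start, sps$end,
                                 read_len)))
  }
  structure(list(D = D, R = R, adt = adt, total_pairs = total,
                 read_len = read_len), class = "depth_stats")
}

#' @export
print.depth_stats <- function(x, ...) {
  cat(sprintf("<depth_stats> D = %.2fx, R = %.3f, %d pairs\n",
              x$D, x$R, x$total_pairs))
  print(x$adt, n = Inf)
  invisible(x)
}
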