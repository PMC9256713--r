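# Independent reference implementations used as oracles, plus small
# fixture builders. These deliberately share no code with the package's
# own aligner/assembler: the mapper oracle scans every position of every
# reference on both strands; the assembly oracle re-derives overlaps by
# direct string comparison in R.

# -- brute-force read mapper ------------------------------------------------

chars <- function(s) strsplit(s, "")[[1]]

rc_chr <- function(s) {
  paste(rev(chartr("ACGTN", "TGCAN", chars(s))), collapse = "")
}

# all best placements of `read` over a named list of reference sequences;
# N always counts as a mismatch
bf_map_read <- function(read, refs, max_mismatch_frac = 0.1) {
  len <- nchar(read)
  cap <- floor(max_mismatch_frac * len)
  best <- cap + 1L
  hits <- list()
  for (ref_id in names(refs)) {
    rv <- chars(refs[[ref_id]])
    L <- length(rv)
    if (L < len) next
    for (strand in c("+", "-")) {
      qv <- chars(if (strand == "+") read else rc_chr(read))
      for (pos in 0:(L - len)) {
        seg <- rv[(pos + 1):(pos + len)]
        mm <- sum(seg != qv | qv == "N" | seg == "N")
        if (mm < best) {
          best <- mm
          hits <- list(list(ref_id = ref_id, pos = pos, strand = strand,
                            mm = mm))
        } else if (mm == best && best <= cap) {
          hits[[length(hits) + 1]] <- list(ref_id = ref_id, pos = pos,
                                           strand = strand, mm = mm)
        }
      }
    }
  }
  if (best > cap) return(NULL)
  dplyr::bind_rows(lapply(hits, tibble::as_tibble))
}

# -- reference greedy assembler --------------------------------------------

# longest admissible suffix-prefix overlap of a over b, direct scan
bf_overlap <- function(a, b, min_ov, min_id) {
  la <- nchar(a)
  lb <- nchar(b)
  for (L in seq(min(la, lb), min_ov)) {
    sa <- chars(substr(a, la - L + 1, la))
    sb <- chars(substr(b, 1, L))
    if (sum(sa != sb) <= floor((1 - min_id) * L)) return(L)
  }
  0L
}

# same objective as the package assembler (longest overlap first, ties by
# lexicographically smallest merged sequence), re-derived independently
bf_assemble <- function(reads, min_ov = 30L, min_id = 0.95) {
  seqs <- character(0)
  for (s in reads) {
    if (!(s %in% seqs) && !(rc_chr(s) %in% seqs)) seqs <- c(seqs, s)
  }
  repeat {
    best <- list(len = 0L, merged = NULL, i = 0L, j = 0L)
    n <- length(seqs)
    if (n < 2) break
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        for (b in c(seqs[j], rc_chr(seqs[j]))) {
          L <- bf_overlap(seqs[i], b, min_ov, min_id)
          if (L < min_ov) next
          merged <- paste0(seqs[i], substr(b, L + 1, nchar(b)))
          if (L > best$len ||
              (L == best$len && merged < best$merged)) {
            best <- list(len = L, merged = merged, i = i, j = j)
          }
        }
      }
    }
    if (best$len < min_ov) break
    seqs[best$i] <- best$merged
    seqs <- seqs[-best$j]
  }
  seqs
}

# canonical form of a contig set: per contig, min(seq, revcomp(seq)),
# sorted — assembly output is orientation-free
canon_contigs <- function(x) {
  sort(vapply(x, function(s) min(s, rc_chr(s)), character(1),
              USE.NAMES = FALSE))
}

# approximate containment: does `subject` contain a window matching
# `pattern` (either orientation) with at most max_mm_frac mismatches?
approx_contains <- function(pattern, subject, max_mm_frac = 0.1) {
  lp <- nchar(pattern)
  ls <- nchar(subject)
  if (ls < lp) return(FALSE)
  cap <- floor(max_mm_frac * lp)
  sv <- chars(subject)
  for (pat in c(pattern, rc_chr(pattern))) {
    pv <- chars(pat)
    for (pos in 0:(ls - lp)) {
      if (sum(sv[(pos + 1):(pos + lp)] != pv) <= cap) return(TRUE)
    }
  }
  FALSE
}

# -- fixture builders -------------------------------------------------------

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# host + plasmid pair with planted host-homologous elements, desk scale
small_fixture <- function(host_len = 60000L, seed = 7L,
                          with_homology = TRUE) {
  host <- synth_host(c(chrA = host_len), seed = seed)
  hom <- if (with_homology) {
    tibble::tibble(chrom = "chrA",
                   start = c(round(host_len * 0.15),
                             round(host_len * 0.7)),
                   end = c(round(host_len * 0.15) + 600L,
                           round(host_len * 0.7) + 700L),
                   name = c("promoter_like", "rnai_target_like"))
  }
  pmap <- synth_plasmid(host, hom, seed = seed + 1L)
  list(host = host, pmap = pmap)
}

# noise-free simulation settings (reads are exact genome substrings)
clean_config <- function(depth = 10, seed = 1L) {
  sim_config(depth = depth, err_start = 0, err_end = 0,
             random_read_prob = 0, n_prob = 0, mut_rate = 0, seed = seed)
}
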