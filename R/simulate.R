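# Ground-truthed event genomes and paired-end read simulation.
#
# The simulator emulates a 100 bp paired-end Illumina run: ~500 +/- 10 bp
# inserts, a linear per-cycle substitution-error ramp (0.1% at cycle 1 to
# 4% at cycle 100), a small probability that a read is replaced by random
# sequence, at most one N call per read, and a lightly mutated sample
# haplotype (SNVs + short indels) distinct from the reference.

BASES <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Defaults are the study conditions emulated throughout the package:
#' 100 bp paired-end reads, 500 bp (sd 10) inserts, substitution error
#' ramping linearly from 0.1\% to 4\% along the read, a 5\% chance that one
#' end of a pair is replaced by random sequence, at most one N per read,
#' and a sample haplotype mutated at rate 0.001 with 10\% of mutations
#' being indels (geometric extension 0.3, minimum 1 bp).
#'
#' @param read_len read length in bp.
#' @param insert_mean,insert_sd fragment (outer insert) size distribution.
#' @param depth fold sequencing depth.
#' @param err_start,err_end substitution probability at the first and last
#'   cycle; intermediate cycles interpolate linearly.
#' @param random_read_prob probability that a pair has one end replaced by
#'   uniform random bases.
#' @param max_n_per_read cap on N calls per read.
#' @param n_prob probability that a read carries an N call.
#' @param mut_rate per-base mutation rate applied to the sample haplotype
#'   before fragment sampling.
#' @param indel_frac fraction of haplotype mutations that are indels.
#' @param indel_ext_prob geometric extension probability for indel length.
#' @param min_indel minimum indel length (bp).
#' @param seed RNG seed; every simulation is deterministic given the seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(read_len = 100L, insert_mean = 500, insert_sd = 10,
                       depth = 29, err_start = 0.001, err_end = 0.04,
                       random_read_prob = 0.05, max_n_per_read = 1L,
                       n_prob = 0.01, mut_rate = 0.001, indel_frac = 0.1,
                       indel_ext_prob = 0.3, min_indel = 1L, seed = 1L) {
  stopifnot(err_start >= 0, err_start <= err_end, err_end < 1,
            random_read_prob >= 0, random_read_prob <= 1,
            read_len < insert_mean, depth > 0)
  structure(list(read_len = as.integer(read_len),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 depth = depth, err_start = err_start, err_end = err_end,
                 random_read_prob = random_read_prob,
                 max_n_per_read = as.integer(max_n_per_read),
                 n_prob = n_prob, mut_rate = mut_rate,
                 indel_frac = indel_frac, indel_ext_prob = indel_ext_prob,
                 min_indel = as.integer(min_indel), seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a random host genome
#'
#' Uniform-composition chromosomes used as a stand-in host for simulation
#' studies; real genomes come in through [read_fasta()].
#'
#' @param lengths named integer vector: chromosome name -> length.
#' @param seed RNG seed.
#' @return tibble with `id`, `seq`.
#' @export
synth_host <- function(lengths = c(chr1 = 200000L), seed = 1L) {
  set.seed(seed)
  tibble(id = names(lengths),
         seq = unname(vapply(lengths, function(L) {
           paste(sample(BASES, L, replace = TRUE), collapse = "")
         }, character(1))))
}

#' Construct a synthetic transformation plasmid carrying host-homologous
#' elements
#'
#' Builds a circular plasmid of `total_len` bp whose T-DNA occupies
#' `[tdna_start, tdna_start + tdna_len)`. Segments of the host genome given
#' in `homology` are copied verbatim into the T-DNA interior, emulating
#' native promoters / RNAi targets whose host homology produces
#' false-positive chimeric pairs; the remaining sequence is random. Interior
#' elements are annotated, with non-homologous terminal elements adjacent to
#' the borders so that true junctions fall in unambiguous sequence.
#'
#' @param host host genome tibble (`id`, `seq`).
#' @param homology tibble with `chrom`, `start`, `end`, `name`: host
#'   segments to embed (0-based half-open).
#' @param total_len plasmid length.
#' @param tdna_start,tdna_len T-DNA placement on the plasmid.
#' @param seed RNG seed for the random scaffold.
#' @return a `plasmid_map`.
#' @export
synth_plasmid <- function(host, homology = NULL, total_len = 10000L,
                          tdna_start = 1000L, tdna_len = 8000L, seed = 2L) {
  set.seed(seed)
  host <- as_seq_tbl(host)
  p <- sample(BASES, total_len, replace = TRUE)
  tdna_end <- tdna_start + tdna_len
  stopifnot(tdna_end <= total_len)

  # terminal border elements (random, hence host-unique)
  el <- tibble(name = c("T-DNA", "RB", "UTR_head"),
               start = c(tdna_start, tdna_start, tdna_start + 25L),
               end = c(tdna_end, tdna_start + 25L, tdna_start + 600L),
               strand = "+")
  el <- bind_rows(el, tibble(name = c("LB", "UTR_tail"),
                             start = c(tdna_end - 25L, tdna_end - 600L),
                             end = c(tdna_end, tdna_end - 25L),
                             strand = "+"))
  # place homologous segments in the T-DNA interior, spaced evenly and
  # well clear (> margin + insert) of the borders, so that blacklisting
  # their neighborhoods cannot swallow true junction-spanning pairs
  if (!is.null(homology) && nrow(homology) > 0) {
    hseq <- seq_vec(host)
    interior_start <- tdna_start + 1700L
    interior_end <- tdna_end - 1700L
    gap <- (interior_end - interior_start) %/% max(1L, nrow(homology))
    at <- interior_start
    for (i in seq_len(nrow(homology))) {
      seg <- substr(hseq[[homology$chrom[i]]], homology$start[i] + 1,
                    homology$end[i])
      w <- nchar(seg)
      if (at + w > interior_end) stop("homologous segments overflow T-DNA")
      p[(at + 1):(at + w)] <- strsplit(seg, "")[[1]]
      el <- bind_rows(el, tibble(name = homology$name[i], start = at,
                                 end = at + w, strand = "+"))
      at <- at + gap
    }
  }
  # one annotated payload element in clean (random) interior sequence
  el <- bind_rows(el, tibble(name = "payload", start = tdna_start + 600L,
                             end = tdna_start + 700L, strand = "+"))
  plasmid_map(paste(p, collapse = ""), el, id = "plasmid")
}

#' Build a transgenic event genome with known truth
#'
#' Inserts `copies` copies of the plasmid T-DNA at `site` on `chrom`,
#' deleting `deletion_len` bases of host sequence at the breakpoint. For
#' `head_to_head` the insert is the T-DNA followed by its reverse
#' complement, so both host flanks abut the same T-DNA terminus on opposite
#' strands; `tandem_head_to_tail` concatenates two direct copies.
#'
#' @param host host genome tibble.
#' @param pmap a `plasmid_map`.
#' @param chrom chromosome id receiving the insertion.
#' @param site 0-based host breakpoint (number of retained 5' bases).
#' @param copies 0, 1 or 2.
#' @param arrangement one of `"single"`, `"tandem_head_to_tail"`,
#'   `"head_to_head"`.
#' @param deletion_len host bases deleted at the junction.
#' @return list with `genome` (modified host tibble) and `truth` (an
#'   `event_truth` list, serializable with [write_truth()]).
#' @export
build_event_genome <- function(host, pmap, chrom, site, copies = 2L,
                               arrangement = c("head_to_head", "single",
                                               "tandem_head_to_tail"),
                               deletion_len = 36L) {
  arrangement <- match.arg(arrangement)
  host <- as_seq_tbl(host)
  stopifnot(copies %in% 0:2, deletion_len >= 0)
  hseq <- seq_vec(host)
  if (!chrom %in% names(hseq)) stop("unknown chromosome: ", chrom)
  L <- nchar(hseq[[chrom]])
  if (site + deletion_len > L || site < 0) {
    stop("site + deletion_len outside chromosome ", chrom)
  }
  tdna <- substr(pmap$seq, pmap$tdna[["start"]] + 1, pmap$tdna[["end"]])
  if (copies > 0 && nchar(tdna) == 0) stop("empty T-DNA with copies > 0")
  flank <- substr(hseq[[chrom]], max(1, site - 100), site + 100)
  if (grepl(strrep("N", 100), flank)) {
    warning("insertion site lies in a long N-run; junction unrecoverable")
  }
  insert <- switch(arrangement,
    single = tdna,
    tandem_head_to_tail = paste0(tdna, tdna),
    head_to_head = paste0(tdna, revcomp(tdna)))
  if (copies == 0L) insert <- ""
  if (copies == 1L) insert <- tdna
  out <- hseq
  if (copies > 0L) {
    out[[chrom]] <- paste0(substr(hseq[[chrom]], 1, site), insert,
                           substr(hseq[[chrom]], site + deletion_len + 1, L))
  }
  truth <- structure(list(
    host_chr = chrom, locus = as.integer(site),
    locus_1based = as.integer(site),
    deletion_len = if (copies > 0) as.integer(deletion_len) else 0L,
    copies = as.integer(copies),
    arrangement = if (copies == 2L) arrangement
                  else if (copies == 1L) "single" else "none",
    inserted_seq = insert), class = "event_truth")
  list(genome = tibble(id = names(out), seq = unname(out)), truth = truth)
}

#' Build a cisgenic event genome (native-fragment insertion)
#'
#' Copies a host-native fragment (`donor_chrom`, `[donor_start,
#' donor_end)`) and inserts it, without host deletion, at `site` on
#' `chrom`. Fails if the donor lies within one library-insert of the
#' insertion site, where junctions would be indistinguishable from the
#' native locus.
#'
#' @param host host genome tibble.
#' @param donor_chrom,donor_start,donor_end native donor fragment (0-based
#'   half-open).
#' @param chrom,site insertion point.
#' @param insert_mean library insert size used for the proximity guard.
#' @return list with `genome` and `truth` as in [build_event_genome()].
#' @export
build_cisgenic_genome <- function(host, donor_chrom, donor_start, donor_end,
                                  chrom, site, insert_mean = 500) {
  host <- as_seq_tbl(host)
  hseq <- seq_vec(host)
  if (donor_end <= donor_start) stop("empty donor interval")
  if (donor_chrom == chrom &&
      donor_start - insert_mean < site && site < donor_end + insert_mean) {
    stop("donor fragment overlaps the insertion neighborhood; ",
         "junctions would be indistinguishable")
  }
  frag <- substr(hseq[[donor_chrom]], donor_start + 1, donor_end)
  L <- nchar(hseq[[chrom]])
  out <- hseq
  out[[chrom]] <- paste0(substr(hseq[[chrom]], 1, site), frag,
                         substr(hseq[[chrom]], site + 1, L))
  truth <- structure(list(
    host_chr = chrom, locus = as.integer(site),
    locus_1based = as.integer(site), deletion_len = 0L, copies = 1L,
    arrangement = "single", inserted_seq = frag), class = "event_truth")
  list(genome = tibble(id = names(out), seq = unname(out)), truth = truth)
}

#' Write / read an event truth record as JSON
#' @param truth an `event_truth`.
#' @param path output path.
#' @return `path` invisibly, or the truth list for the reader.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(chr = truth$host_chr, locus_1based = truth$locus_1based,
         deletion_len = truth$deletion_len, copies = truth$copies,
         arrangement = truth$arrangement),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

# mutate one sequence: substitutions + short indels
mutate_seq <- function(seq, cfg) {
  L <- nchar(seq)
  n_mut <- stats::rbinom(1, L, cfg$mut_rate)
  if (n_mut == 0) return(seq)
  pos <- sort(sample.int(L, n_mut))
  is_indel <- runif(n_mut) < cfg$indel_frac
  v <- strsplit(seq, "")[[1]]
  sub_pos <- pos[!is_indel]
  if (length(sub_pos) > 0) {
    cur <- match(v[sub_pos], BASES)
    shift <- sample.int(3, length(sub_pos), replace = TRUE)
    ok <- !is.na(cur)
    v[sub_pos[ok]] <- BASES[(cur[ok] + shift[ok] - 1) %% 4 + 1]
  }
  for (p in rev(pos[is_indel])) {
    len <- cfg$min_indel + stats::rgeom(1, 1 - cfg$indel_ext_prob)
    if (runif(1) < 0.5) {                       # deletion
      drop <- p:min(L, p + len - 1)
      v <- v[-drop]
    } else {                                    # insertion
      v <- append(v, sample(BASES, len, replace = TRUE), after = p)
    }
    L <- length(v)
  }
  paste(v, collapse = "")
}

#' Simulate paired-end reads from a genome
#'
#' The genome is first mutated into a sample haplotype (rate
#' `cfg$mut_rate`); fragments start uniformly, insert sizes are
#' Normal(`insert_mean`, `insert_sd`) truncated to `[2*read_len,
#' chromosome length]`; read 1 is the fragment 5' end and read 2 the
#' reverse complement of its 3' end. Per-cycle substitution probability
#' interpolates linearly from `err_start` to `err_end`; with probability
#' `random_read_prob` one end of a pair is replaced by uniform random
#' bases; each read carries at most `max_n_per_read` N calls. The pair
#' count is `round(depth * genome_len / (2 * read_len))`. Fully
#' deterministic given `cfg$seed`.
#'
#' @param genome tibble with `id`, `seq` (or named character vector).
#' @param cfg a [sim_config()].
#' @param id_prefix read-name prefix.
#' @return tibble with `pair_id`, `seq1`, `qual1`, `seq2`, `qual2`;
#'   attributes `layout` (ground-truth fragment placement on the sample
#'   haplotype) and `haplotype` (the mutated genome reads were drawn
#'   from) support downstream validation.
#' @export
simulate_reads <- function(genome, cfg = sim_config(), id_prefix = "sim") {
  genome <- as_seq_tbl(genome)
  set.seed(cfg$seed)
  rl <- cfg$read_len
  if (min(nchar(genome$seq)) <= cfg$insert_mean + 6 * cfg$insert_sd) {
    stop("genome too short for the configured insert size")
  }
  hap <- genome
  if (cfg$mut_rate > 0) hap$seq <- vapply(hap$seq, mutate_seq, character(1),
                                          cfg = cfg, USE.NAMES = FALSE)
  lens <- nchar(hap$seq)
  total <- sum(lens)
  n <- round(cfg$depth * total / (2 * rl))
  chrom <- sample.int(nrow(hap), n, replace = TRUE, prob = lens)
  ins <- round(rnorm(n, cfg$insert_mean, cfg$insert_sd))
  ins <- pmax(2L * rl, pmin(ins, lens[chrom]))
  start <- floor(runif(n) * (lens[chrom] - ins + 1))   # 0-based
  r1 <- substring(hap$seq[chrom], start + 1, start + rl)
  r2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
    substring(hap$seq[chrom], start + ins - rl + 1, start + ins))))

  reads <- c(r1, r2)                                    # 2n reads
  m <- matrix(unlist(strsplit(reads, ""), use.names = FALSE),
              ncol = rl, byrow = TRUE)
  # per-cycle substitution ramp
  p <- if (rl == 1) cfg$err_start else
    cfg$err_start + (cfg$err_end - cfg$err_start) * (seq_len(rl) - 1) / (rl - 1)
  if (any(p > 0)) {
    mask <- matrix(runif(2 * n * rl), ncol = rl) <
      matrix(p, nrow = 2 * n, ncol = rl, byrow = TRUE)
    idx <- which(mask)
    if (length(idx) > 0) {
      cur <- match(m[idx], BASES)
      shift <- sample.int(3, length(idx), replace = TRUE)
      ok <- !is.na(cur)
      m[idx[ok]] <- BASES[(cur[ok] + shift[ok] - 1) %% 4 + 1]
    }
  }
  # random-sequence replacement: one end per affected pair
  if (cfg$random_read_prob > 0) {
    hit <- which(runif(n) < cfg$random_read_prob)
    if (length(hit) > 0) {
      end2 <- runif(length(hit)) < 0.5
      rows <- ifelse(end2, hit + n, hit)
      m[rows, ] <- sample(BASES, length(rows) * rl, replace = TRUE)
    }
  }
  # N calls, capped at max_n_per_read (one draw per read)
  if (cfg$n_prob > 0 && cfg$max_n_per_read > 0) {
    hit <- which(runif(2 * n) < cfg$n_prob)
    if (length(hit) > 0) {
      m[cbind(hit, sample.int(rl, length(hit), replace = TRUE))] <- "N"
    }
  }
  reads <- do.call(paste0, asplit(m, 2))
  q <- pmin(40L, pmax(2L, as.integer(round(-10 * log10(pmax(p, 1e-4))))))
  qual <- paste(intToUtf8(q + 33L, multiple = TRUE), collapse = "")
  out <- tibble(pair_id = sprintf("%s_%d", id_prefix, seq_len(n)),
                seq1 = reads[seq_len(n)], qual1 = qual,
                seq2 = reads[n + seq_len(n)], qual2 = qual)
  # ground-truth fragment layout on the sample haplotype (not the input
  # reference: indel mutations shift coordinates)
  attr(out, "layout") <- tibble(pair_id = out$pair_id,
                                chrom = hap$id[chrom], start = start,
                                insert = ins)
  attr(out, "haplotype") <- hap
  out
}

#' Merge a spike-in read set into a background read set
#'
#' @param background,spike read tibbles from [simulate_reads()].
#' @param seed RNG seed for the output shuffle.
#' @return merged, shuffled read tibble.
#' @export
spike_reads <- function(background, spike, seed = 1L) {
  if (nrow(spike) > 0 && nchar(spike$seq1[1]) != nchar(background$seq1[1])) {
    stop("read lengths differ between background and spike sets")
  }
  if (any(spike$pair_id %in% background$pair_id)) {
    stop("read ID collision between background and spike sets")
  }
  out <- bind_rows(background, spike)
  set.seed(seed)
  out[sample.int(nrow(out)), ]
}

#' Write / read a paired FASTQ file pair
#'
#' Files are written as `<prefix>_1.fastq` and `<prefix>_2.fastq`.
#'
#' @param reads read tibble from [simulate_reads()].
#' @param prefix output path prefix.
#' @return the two file paths (writer, invisibly) or a read tibble (reader).
#' @export
write_fastq_pair <- function(reads, prefix) {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (end in 1:2) {
    s <- Biostrings::DNAStringSet(reads[[paste0("seq", end)]])
    names(s) <- paste0(reads$pair_id, "/", end)
    qu <- Biostrings::PhredQuality(reads[[paste0("qual", end)]])
    Biostrings::writeXStringSet(
      Biostrings::QualityScaledDNAStringSet(s, qu), paths[end],
      format = "fastq")
  }
  invisible(paths)
}

#' @rdname write_fastq_pair
#' @export
read_fastq_pair <- function(prefix) {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  sets <- lapply(paths, function(p) {
    # the reader warns about dropping (empty) metadata columns; benign
    suppressWarnings(Biostrings::readQualityScaledDNAStringSet(p))
  })
  ids <- sub("/[12]$", "", names(sets[[1]]))
  tibble(pair_id = ids,
         seq1 = unname(as.character(sets[[1]])),
         qual1 = unname(as.character(Biostrings::quality(sets[[1]]))),
         seq2 = unname(as.character(sets[[2]])),
         qual2 = unname(as.character(Biostrings::quality(sets[[2]]))))
}
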