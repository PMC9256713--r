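test_that("event genome construction keeps the length bookkeeping and
           junction structure", {
  fx <- small_fixture(host_len = 30000L, with_homology = FALSE)
  tdna_len <- fx$pmap$tdna[["end"]] - fx$pmap$tdna[["start"]]

  ev <- build_event_genome(fx$host, fx$pmap, "chrA", 12000L, copies = 2,
                           arrangement = "head_to_head",
                           deletion_len = 36L)
  expect_equal(nchar(ev$genome$seq), 30000 - 36 + 2 * tdna_len)
  expect_equal(ev$truth$locus_1based, 12000L)
  expect_equal(ev$truth$deletion_len, 36L)

  # head-to-head: the insert ends with the reverse complement of the
  # T-DNA start, so the 50 bp before the 3' host flank mirror the first
  # 50 bp of T-DNA
  tdna <- substr(fx$pmap$seq, fx$pmap$tdna[["start"]] + 1,
                 fx$pmap$tdna[["end"]])
  ins_end <- 12000 + 2 * tdna_len
  expect_equal(substr(ev$genome$seq, ins_end - 49, ins_end),
               rc_chr(substr(tdna, 1, 50)))

  # copies = 0 leaves the genome untouched
  ev0 <- build_event_genome(fx$host, fx$pmap, "chrA", 12000L, copies = 0)
  expect_identical(ev0$genome$seq, fx$host$seq)
  expect_identical(ev0$truth$inserted_seq, "")

  expect_error(build_event_genome(fx$host, fx$pmap, "chrA", 29990L,
                                  copies = 1, deletion_len = 50L),
               "outside")
})

test_that("cisgenic construction inserts a native fragment and guards
           against self-adjacent donors", {
  fx <- small_fixture(host_len = 30000L, with_homology = FALSE)
  cis <- build_cisgenic_genome(fx$host, "chrA", 5000L, 7052L,
                               "chrA", 20000L)
  expect_equal(nchar(cis$genome$seq), 30000 + 2052)
  expect_equal(cis$truth$deletion_len, 0L)
  expect_error(build_cisgenic_genome(fx$host, "chrA", 5000L, 5000L,
                                     "chrA", 20000L), "empty donor")
  expect_error(build_cisgenic_genome(fx$host, "chrA", 5000L, 7052L,
                                     "chrA", 5400L), "indistinguishable")
})

test_that("read simulation obeys the pair-count formula, insert-size
           distribution and determinism", {
  genome <- tibble::tibble(id = "g", seq = rand_seq(100000, seed = 5))
  cfg <- clean_config(depth = 30, seed = 4)
  reads <- simulate_reads(genome, cfg)
  expect_equal(nrow(reads), 15000)      # round(30 * 1e5 / (2 * 100))

  # mean insert recovered from read placement: with clean reads each pair
  # locates exactly in the genome
  idx <- sample.int(nrow(reads), 300)
  ins <- vapply(idx, function(i) {
    p1 <- as.integer(regexpr(reads$seq1[i], genome$seq, fixed = TRUE))
    p2 <- as.integer(regexpr(rc_chr(reads$seq2[i]), genome$seq,
                             fixed = TRUE))
    (p2 + 100) - p1
  }, numeric(1))
  expect_true(abs(mean(ins) - cfg$insert_mean) <
                3 * cfg$insert_sd / sqrt(length(ins)))

  # determinism: same config, same bytes
  expect_identical(simulate_reads(genome, cfg), reads)

  # with all noise off, every read is an exact (possibly reverse-
  # complemented) substring of the genome
  some <- reads[seq_len(200), ]
  expect_true(all(vapply(some$seq1, grepl, logical(1), x = genome$seq,
                         fixed = TRUE)))
  expect_true(all(vapply(some$seq2, function(s) {
    grepl(rc_chr(s), genome$seq, fixed = TRUE)
  }, logical(1))))
})

test_that("the substitution ramp averages to its analytic mean", {
  genome <- tibble::tibble(id = "g", seq = rand_seq(60000, seed = 6))
  cfg <- sim_config(depth = 10, random_read_prob = 0, n_prob = 0,
                    mut_rate = 0, seed = 8)
  reads <- simulate_reads(genome, cfg)
  lay <- attr(reads, "layout")
  # count read-1 mismatches against the known source fragment
  n_check <- 500
  mism <- vapply(seq_len(n_check), function(i) {
    src <- substr(genome$seq, lay$start[i] + 1, lay$start[i] + 100)
    sum(chars(src) != chars(reads$seq1[i]))
  }, numeric(1))
  p_mean <- (cfg$err_start + cfg$err_end) / 2     # 2.05% per base
  n_bases <- n_check * 100
  expect_true(abs(sum(mism) / n_bases - p_mean) <
                3 * sqrt(p_mean * (1 - p_mean) / n_bases))
  # and the ramp really ramps: last-decile error rate far above first
  first <- vapply(seq_len(n_check), function(i) {
    src <- substr(genome$seq, lay$start[i] + 1, lay$start[i] + 10)
    sum(chars(src) != chars(substr(reads$seq1[i], 1, 10)))
  }, numeric(1))
  last <- vapply(seq_len(n_check), function(i) {
    src <- substr(genome$seq, lay$start[i] + 91, lay$start[i] + 100)
    sum(chars(src) != chars(substr(reads$seq1[i], 91, 100)))
  }, numeric(1))
  expect_gt(sum(last), 5 * sum(first))
})

test_that("spiking merges read sets with disjoint ids, reproducibly", {
  g <- tibble::tibble(id = "g", seq = rand_seq(30000, seed = 2))
  bg <- simulate_reads(g, clean_config(depth = 2, seed = 1), "bg")
  sp <- simulate_reads(g, clean_config(depth = 0.2, seed = 2), "sp")
  merged <- spike_reads(bg, sp, seed = 3)
  expect_equal(nrow(merged), nrow(bg) + nrow(sp))
  expect_identical(spike_reads(bg, sp, seed = 3), merged)
  expect_setequal(merged$pair_id, c(bg$pair_id, sp$pair_id))
  expect_error(spike_reads(bg, bg), "collision")
  # empty spike set: background content unchanged (order aside)
  empty <- sp[0, ]
  expect_setequal(spike_reads(bg, empty, seed = 5)$pair_id, bg$pair_id)
})

test_that("FASTQ pairs round-trip through disk", {
  g <- tibble::tibble(id = "g", seq = rand_seq(20000, seed = 3))
  reads <- simulate_reads(g, sim_config(depth = 1, seed = 2))
  prefix <- withr::local_tempfile()
  write_fastq_pair(reads, prefix)
  back <- read_fastq_pair(prefix)
  expect_equal(back$pair_id, reads$pair_id)
  expect_equal(back$seq1, reads$seq1)
  expect_equal(back$seq2, reads$seq2)
  expect_equal(back$qual1, reads$qual1)
})
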