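test_that("greedy assembly reconstructs a tiled template and matches the
           exhaustive-merge oracle", {
  template <- rand_seq(478, seed = 81)
  starts <- unique(c(seq(1, 478 - 99, by = 20), 478 - 99))
  reads <- vapply(starts, function(s) substr(template, s, s + 99),
                  character(1))
  got <- assemble_contigs(reads)
  expect_equal(length(got), 1)
  expect_equal(min(got, rc_chr(got)), min(template, rc_chr(template)))

  # single read assembles to itself; disjoint reads stay separate
  expect_equal(assemble_contigs("ACGTACGTACGTACGT", min_overlap = 4L),
               "ACGTACGTACGTACGT")
  two <- c(rand_seq(100, seed = 82), rand_seq(100))
  expect_equal(length(assemble_contigs(two)), 2)

  # oracle agreement on random <= 8 read subsets (mixed orientation)
  set.seed(83)
  for (rep in 1:6) {
    tpl <- rand_seq(260)
    st <- sort(sample(160, sample(4:8, 1)))
    rds <- vapply(st, function(s) substr(tpl, s, s + 99), character(1))
    flip <- runif(length(rds)) < 0.5
    rds[flip] <- vapply(rds[flip], rc_chr, character(1))
    expect_equal(canon_contigs(assemble_contigs(rds)),
                 canon_contigs(bf_assemble(rds)),
                 info = paste("rep", rep))
  }
})

test_that("junction split-calling recovers constructed breakpoints,
           orientations and elements", {
  host <- synth_host(c(chrA = 20000L), seed = 84)
  pmap <- synth_plasmid(host, NULL, total_len = 6000L,
                        tdna_start = 1000L, tdna_len = 4000L, seed = 85)
  tdna <- substr(pmap$seq, 1001, 5000)

  # left flank: 200 bp host then 200 bp of T-DNA start
  bp <- 8000L
  contig_l <- paste0(substr(host$seq, bp - 199, bp), substr(tdna, 1, 200))
  jl <- call_junction(contig_l, host, pmap)
  expect_equal(nrow(jl), 1)
  expect_equal(jl$side, "left")
  expect_equal(jl$host_bp, bp)
  expect_equal(jl$plasmid_strand, "+")
  expect_equal(jl$terminus, "start")
  expect_equal(jl$element, "RB")           # element at T-DNA position 0

  # right flank with the plasmid part reverse-complemented (the
  # head-to-head 3' junction): revcomp(T-DNA start) then host resuming
  resume <- 8036L
  contig_r <- paste0(rc_chr(substr(tdna, 1, 200)),
                     substr(host$seq, resume + 1, resume + 200))
  jr <- call_junction(contig_r, host, pmap)
  expect_equal(jr$side, "right")
  expect_equal(jr$host_bp, resume)
  expect_equal(jr$plasmid_strand, "-")
  expect_equal(jr$terminus, "start")

  # pure host or pure plasmid contigs yield no call
  expect_equal(nrow(call_junction(substr(host$seq, 3000, 3400), host,
                                  pmap)), 0)
  expect_equal(nrow(call_junction(substr(pmap$seq, 2000, 2400), host,
                                  pmap)), 0)
})

test_that("integration calling composes breakpoints into locus, deletion
           and arrangement", {
  jn <- tibble::tibble(
    side = c("left", "right", "right"), chrom = "chrA",
    host_bp = c(8000L, 8036L, 8036L),
    plasmid_pos = c(1000L, 1000L, 1000L),
    plasmid_strand = c("+", "-", "-"),
    terminus = "start", element = "RB", score = 300L,
    contig_len = 400L)
  call <- call_integration(jn, copy_number = 1.96)
  expect_equal(call$locus, 8000L)
  expect_equal(call$deletion_len, 36L)
  expect_equal(call$arrangement, "head_to_head")
  expect_equal(call$element_5p, call$element_3p)

  # single-flank evidence: deletion absent, call still emitted
  partial <- call_integration(jn[1, ], copy_number = 2)
  expect_true(is.na(partial$deletion_len))
  expect_equal(partial$locus, 8000L)

  # junctions on two chromosomes are a conflict
  jn2 <- jn
  jn2$chrom <- c("chrA", "chrB", "chrB")
  expect_error(call_integration(jn2), "different chromosomes")

  td <- tidy(call)
  expect_equal(td$arrangement, "head_to_head")
  expect_equal(td$deletion_len, 36L)
})

test_that("arrangement rules cover single, tandem and head-to-head", {
  base <- list(terminus_5p = "start", terminus_3p = "end",
               strand_5p = "+", strand_3p = "+")
  expect_equal(infer_arrangement(base, 1.0), "single")
  expect_equal(infer_arrangement(base, 2.1), "tandem_head_to_tail")
  h2h <- list(terminus_5p = "start", terminus_3p = "start",
              strand_5p = "+", strand_3p = "-")
  expect_equal(infer_arrangement(h2h, 2.0), "head_to_head")
  expect_equal(infer_arrangement(h2h, 1.0), "unresolved")
  expect_equal(infer_arrangement(base, NA), "unresolved")
})

test_that("simulate -> assemble -> call round-trip recovers loci and
           deletions across seeds and arrangements", {
  grid <- expand.grid(seed = 1:5,
                      arrangement = c("single", "head_to_head"),
                      deletion = c(0L, 36L), stringsAsFactors = FALSE)
  # 20 runs; locus must be exact in >= 19, deletion exact whenever both
  # flanks assemble
  ok_locus <- 0L
  n_both <- 0L
  ok_del <- 0L
  flank_try <- 0L
  flank_hit <- 0L
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    host <- synth_host(c(chrA = 50000L), seed = 900 + g$seed)
    pmap <- synth_plasmid(host, NULL, total_len = 8000L,
                          tdna_start = 1000L, tdna_len = 6000L,
                          seed = 901 + g$seed)
    site <- sample(15000:35000, 1)
    ev <- build_event_genome(host, pmap, "chrA", site,
                             copies = if (g$arrangement == "single") 1L
                                      else 2L,
                             arrangement = g$arrangement,
                             deletion_len = g$deletion)
    reads <- simulate_reads(ev$genome,
                            sim_config(depth = 22, seed = 902 + i))
    refs <- ref_set(host, pmap)
    pa <- map_pairs(reads, refs)
    chim <- extract_chimeric(pa)
    cl <- cluster_candidates(chim)
    top <- cl[1, ]
    jv <- junction_votes(pa, top, host, pmap)
    ctg <- jv$contigs
    jn <- jv$junctions[jv$junctions$chrom == "chrA", ]
    if (nrow(jn) == 0) next
    call <- call_integration(jn,
                             copy_number = if (g$arrangement == "single")
                               1 else 2)
    if (!is.na(call$locus) && call$locus == site) {
      ok_locus <- ok_locus + 1L
    }
    if (call$n_left > 0 && call$n_right > 0) {
      n_both <- n_both + 1L
      if (!is.na(call$deletion_len) && call$deletion_len == g$deletion) {
        ok_del <- ok_del + 1L
      }
    }
    # some assembled contig must carry >= 50 bp of true host flank and
    # >= 50 bp of true inserted sequence around the 5' junction
    if (call$n_left > 0) {
      probe <- paste0(substr(host$seq, site - 49, site),
                      substr(ev$truth$inserted_seq, 1, 50))
      flank_try <- flank_try + 1L
      if (any(vapply(ctg[nchar(ctg) >= 100], approx_contains,
                     logical(1), pattern = probe))) {
        flank_hit <- flank_hit + 1L
      }
    }
  }
  expect_gte(ok_locus, 19L)
  expect_gte(n_both, 15L)
  expect_gte(ok_del, n_both - 1L)
  # almost every 5'-flank contig carries >= 50 bp of true host and insert
  # sequence across the junction (a haplotype indel under the probe window
  # defeats the approximate containment occasionally)
  expect_gte(flank_hit / flank_try, 0.8)
})
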