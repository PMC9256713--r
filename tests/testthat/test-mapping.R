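test_that("mapper agrees with the brute-force aligner on a 5 kb fixture", {
  refs_tbl <- tibble::tibble(
    id = c("chrA", "plas"),
    seq = c(rand_seq(5000, seed = 21), rand_seq(1500)))
  refs <- ref_set(refs_tbl[1, ],
                  plasmid_map(refs_tbl$seq[2],
                              data.frame(name = "T-DNA", start = 0L,
                                         end = 1500L, strand = "+"),
                              id = "plas"))
  ref_list <- setNames(refs$seq, refs$id)

  set.seed(31)
  cases <- purrr::map_dfr(1:40, function(i) {
    ref_i <- sample(2, 1)
    L <- nchar(refs$seq[ref_i])
    pos <- sample(L - 100, 1) - 1L
    read <- substr(refs$seq[ref_i], pos + 1, pos + 100)
    n_err <- sample(0:2, 1)
    if (n_err > 0) {
      v <- chars(read)
      at <- sample(100, n_err)
      v[at] <- vapply(v[at], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1))
      read <- paste(v, collapse = "")
    }
    if (runif(1) < 0.5) read <- rc_chr(read)
    tibble::tibble(read = read)
  })
  # a handful of unmappable random reads must stay unmapped in both
  cases <- dplyr::bind_rows(cases,
                            tibble::tibble(read = replicate(3,
                                                            rand_seq(100))))

  got <- map_reads(cases$read, refs)
  for (i in seq_len(nrow(cases))) {
    oracle <- bf_map_read(cases$read[i], ref_list)
    mine <- got[got$read == i, ]
    if (is.null(oracle)) {
      expect_equal(nrow(mine), 0)
    } else {
      expect_equal(nrow(mine), nrow(oracle), info = paste("case", i))
      key <- function(d) {
        sort(paste(d[[1]], d[[2]], d[[3]], d[[4]]))
      }
      expect_equal(key(mine[, c("ref_id", "pos", "strand", "mismatches")]),
                   key(oracle[, c("ref_id", "pos", "strand", "mm")]),
                   info = paste("case", i))
    }
  }
})

test_that("multi-mapped reads are flagged and the primary hit prefers the
           plasmid", {
  core <- rand_seq(400, seed = 41)
  host <- tibble::tibble(
    id = "chrA", seq = paste0(rand_seq(800, seed = 42), core,
                              rand_seq(800)))
  pmap <- plasmid_map(paste0(rand_seq(300), core, rand_seq(300)),
                      data.frame(name = "T-DNA", start = 0L, end = 1000L,
                                 strand = "+"))
  refs <- ref_set(host, pmap)
  read <- substr(core, 101, 200)
  hits <- map_reads(read, refs)
  expect_equal(nrow(hits), 2)
  expect_false(any(hits$unique))
  expect_true(hits$is_plasmid[hits$primary])
})

test_that("pair classification covers all classes and is symmetric", {
  expect_equal(classify_pair(FALSE, TRUE), "chimeric_host_plasmid")
  expect_equal(classify_pair(TRUE, FALSE), "chimeric_host_plasmid")
  expect_equal(classify_pair(FALSE, FALSE), "both_host")
  expect_equal(classify_pair(TRUE, TRUE), "both_plasmid")
  expect_equal(classify_pair(NA, TRUE), "one_unmapped")
  expect_equal(classify_pair(NA, NA), "both_unmapped")
})

test_that("coverage calibrator reproduces the published ratios from raw
           pair counts", {
  # both sequencing runs of the characterized event pair give 0.989
  expect_equal(round(coverage_calibrator(53545140, 54130964), 3), 0.989)
  expect_equal(round(coverage_calibrator(54233374, 54819968), 3), 0.989)
  expect_equal(coverage_calibrator(10, 10), 1)
  expect_error(coverage_calibrator(0, 0), "positive")
})

test_that("general depth follows its formula and scales linearly", {
  expect_equal(general_depth(15000, 100, 100000), 30)
  expect_equal(general_depth(0, 100, 12345), 0)
  expect_equal(general_depth(2 * 7000, 100, 1e6),
               2 * general_depth(7000, 100, 1e6))
})

test_that("average target depth matches arithmetic and a Poisson coverage
           oracle", {
  aln <- tibble::tibble(ref_id = "chrA", pos = 50L)
  expect_equal(average_target_depth(aln, "chrA", 0L, 200L), 0.5)
  expect_equal(average_target_depth(aln[0, ], "chrA", 0L, 200L), 0)
  expect_error(average_target_depth(aln, "chrA", 10L, 10L), "zero-length")

  # simulated 30x: ADT over an interior element within 3 Poisson sigma
  g <- tibble::tibble(id = "chrA", seq = rand_seq(20000, seed = 51))
  reads <- simulate_reads(g, clean_config(depth = 30, seed = 52))
  refs <- ref_set(g)
  pa <- map_pairs(reads, refs)
  prim <- pa$hits[pa$hits$primary, ]
  adt <- average_target_depth(prim, "chrA", 8000L, 9000L)
  expect_lt(abs(adt - 30), 3 * sqrt(30 * 1000) / 1000 * 10)
  expect_gt(adt, 25)
})

test_that("SAM round-trip preserves pair classes and coordinates", {
  fx <- small_fixture(host_len = 20000L, seed = 61,
                      with_homology = FALSE)
  ev <- build_event_genome(fx$host, fx$pmap, "chrA", 9000L, copies = 1,
                           arrangement = "single", deletion_len = 0L)
  reads <- simulate_reads(ev$genome, clean_config(depth = 4, seed = 62))
  refs <- ref_set(fx$host, fx$pmap)
  pa <- map_pairs(reads, refs)
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(pa, path)
  back <- read_sam(path, refs)
  ord <- match(pa$pairs$pair_id, back$pairs$pair_id)
  expect_equal(back$pairs$pair_class[ord], pa$pairs$pair_class)
  expect_equal(back$pairs$pos1[ord], pa$pairs$pos1)
  expect_equal(back$pairs$strand2[ord], pa$pairs$strand2)
  # FLAG 0x4 marks unmapped ends; CIGAR POS is 1-based in the file
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  f <- strsplit(body[1], "\t")[[1]]
  if (f[3] != "*") {
    expect_equal(as.integer(f[4]) - 1L,
                 back$pairs$pos1[back$pairs$pair_id == f[1]])
  }
})
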