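# constructs a chimeric-pair tibble directly; positions/strands as the
# normalized extract_chimeric() output
chim_row <- function(pair_id, host_pos, host_strand = "+",
                     plasmid_pos = 1000L, host_uniq = TRUE,
                     plasmid_uniq = TRUE, chrom = "chrA") {
  tibble::tibble(pair_id = pair_id, host_ref = chrom,
                 host_pos = as.integer(host_pos),
                 host_strand = host_strand, host_uniq = host_uniq,
                 plasmid_ref = "plasmid",
                 plasmid_pos = as.integer(plasmid_pos),
                 plasmid_strand = "+", plasmid_uniq = plasmid_uniq,
                 host_end = 1L)
}

test_that("chimeric extraction pulls exactly the chimeric class", {
  pairs <- tibble::tibble(
    pair_id = sprintf("p%d", 1:5),
    ref1 = c("chrA", "chrA", "plasmid", "chrA", NA),
    plasmid1 = c(FALSE, FALSE, TRUE, FALSE, NA),
    pos1 = c(10L, 20L, 30L, 40L, NA), strand1 = "+",
    uniq1 = TRUE,
    ref2 = c("plasmid", "chrA", "plasmid", "plasmid", "plasmid"),
    plasmid2 = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    pos2 = c(1L, 2L, 3L, 4L, 5L), strand2 = "-", uniq2 = TRUE)
  pairs$pair_class <- classify_pair(pairs$plasmid1, pairs$plasmid2)
  pa <- structure(list(pairs = pairs), class = "pair_alignments")
  chim <- extract_chimeric(pa)
  expect_setequal(chim$pair_id, c("p1", "p4"))
  expect_true(all(chim$host_ref == "chrA"))
  expect_true(all(chim$plasmid_ref == "plasmid"))
})

test_that("native filtering discards on either side, conserves counts,
           and is idempotent", {
  bl <- structure(list(
    host = tibble::tibble(chrom = "chrA", start = 5000L, end = 6000L),
    plasmid = tibble::tibble(start = 2000L, end = 2500L),
    plasmid_id = "plasmid", margin = 500L), class = "blacklist")
  chim <- dplyr::bind_rows(
    chim_row("in_host", 5500, plasmid_pos = 100),
    chim_row("in_plasmid", 9000, plasmid_pos = 2100),
    chim_row("edge_overlap", 4950, plasmid_pos = 100),  # footprint enters
    chim_row("clean", 12000, plasmid_pos = 100))
  fn <- filter_native(chim, bl, side = "both")
  expect_setequal(fn$kept$pair_id, "clean")
  expect_equal(nrow(fn$kept) + nrow(fn$discarded), nrow(chim))
  expect_true(all(nzchar(fn$discarded$reason)))
  expect_equal(
    fn$discarded$reason[fn$discarded$pair_id == "in_plasmid"],
    "native_homology_plasmid_side")
  # idempotence
  fn2 <- filter_native(fn$kept, bl, side = "both")
  expect_equal(fn2$kept, fn$kept)
  expect_equal(nrow(fn2$discarded), 0)
  # empty blacklist keeps everything
  bl0 <- structure(list(host = bl$host[0, ], plasmid = bl$plasmid[0, ],
                        plasmid_id = "plasmid", margin = 500L),
                   class = "blacklist")
  expect_equal(nrow(filter_native(chim, bl0)$kept), nrow(chim))
})

test_that("clustering is single-linkage per chromosome", {
  chim <- dplyr::bind_rows(
    chim_row("a", 1000), chim_row("b", 1100), chim_row("c", 1400),
    chim_row("d", 3000), chim_row("e", 500, chrom = "chrB"))
  cl <- cluster_candidates(chim, cluster_window = 500L)
  expect_equal(nrow(cl), 3)
  big <- cl[cl$support == 3, ]
  expect_equal(big$chrom, "chrA")
  expect_setequal(big$members[[1]], c("a", "b", "c"))
  # {1000, 2000} with window 500 -> two clusters
  cl2 <- cluster_candidates(dplyr::bind_rows(chim_row("x", 1000),
                                             chim_row("y", 2000)),
                            cluster_window = 500L)
  expect_equal(nrow(cl2), 2)
  # 62 pairs within one insert-size neighborhood -> one cluster
  many <- dplyr::bind_rows(lapply(1:62, function(i) {
    chim_row(sprintf("m%d", i), 16439174 + (i %% 50) * 10)
  }))
  cl3 <- cluster_candidates(many, cluster_window = 500L)
  expect_equal(nrow(cl3), 1)
  expect_equal(cl3$support, 62L)
})

test_that("sporadic filtering separates depth-supported clusters from
           jitter", {
  clusters <- dplyr::bind_rows(
    tibble::tibble(chrom = "chr3", start = 100L, end = 800L,
                   support = 62L, unique_support = 60L,
                   members = list(sprintf("p%d", 1:62))),
    tibble::tibble(chrom = "chr4", start = 1L, end = 101L, support = 1L,
                   unique_support = 1L, members = list("q1")),
    tibble::tibble(chrom = "chr6", start = 1L, end = 101L, support = 2L,
                   unique_support = 2L, members = list(c("q2", "q3"))))
  fs <- filter_sporadic(clusters, depth_D = 28.91)
  expect_equal(fs$candidates$chrom, "chr3")
  expect_equal(nrow(fs$rejected), 2)
  expect_true(all(fs$rejected$reason == "noise sequences/alignment jitter"))
  # boundary: an all-unique support-3 cluster passes at min_abs = 3 when
  # depth allows
  b <- tibble::tibble(chrom = "c", start = 1L, end = 101L, support = 3L,
                      unique_support = 3L, members = list(c("a", "b", "c")))
  expect_equal(nrow(filter_sporadic(b, depth_D = 20)$candidates), 1)
  # but support 3 at depth 60 is below the 10%-of-depth bar
  expect_equal(nrow(filter_sporadic(b, depth_D = 60)$candidates), 0)
})

test_that("consistency check flags contradictory geometry and
           multi-mapped-only clusters", {
  mk_cluster <- function(chim) {
    cl <- cluster_candidates(chim, cluster_window = 5000L)
    consistency_check(cl, chim)
  }
  # coherent junction: forward ends left, reverse ends right, tight span
  good <- dplyr::bind_rows(
    lapply(1:6, function(i) chim_row(sprintf("g%d", i), 9500 + i * 50)),
    lapply(1:6, function(i) {
      chim_row(sprintf("h%d", i), 10050 + i * 50, host_strand = "-")
    }))
  expect_equal(mk_cluster(good)$verdict, "consistent")
  # members imply fragments far beyond 3x the insert size
  wide <- dplyr::bind_rows(
    chim_row("w1", 1000), chim_row("w2", 1100), chim_row("w3", 4000))
  expect_equal(mk_cluster(wide)$verdict, "contradictory")
  # a single multi-mapped member is never trustworthy
  multi <- chim_row("m1", 1000, host_uniq = FALSE, plasmid_uniq = FALSE)
  expect_equal(mk_cluster(multi)$verdict, "contradictory")
  # plasmid-side scatter within one flank
  scatter <- dplyr::bind_rows(
    chim_row("s1", 1000, plasmid_pos = 100),
    chim_row("s2", 1050, plasmid_pos = 4000),
    chim_row("s3", 1100, plasmid_pos = 8000))
  expect_equal(mk_cluster(scatter)$verdict, "contradictory")
})
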