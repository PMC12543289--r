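test_that("k-mer counting matches hand enumeration", {
  a <- mk_assembly(s1 = "ACGT")
  cnt <- count_kmers(a, mk_gr("s1", 1, 4), 2)
  expect_equal(sum(cnt), 3)
  expect_equal(unname(cnt[c("AC", "CG", "GT")]), c(1L, 1L, 1L))

  a2 <- mk_assembly(s1 = "AAAA")
  cnt2 <- count_kmers(a2, mk_gr("s1", 1, 4), 2)
  expect_equal(unname(cnt2["AA"]), 3L)
  expect_equal(sum(cnt2), 3)

  # windows containing N are skipped
  a3 <- mk_assembly(s1 = "ACNGT")
  cnt3 <- count_kmers(a3, mk_gr("s1", 1, 5), 2)
  expect_equal(sum(cnt3), 2)
  expect_equal(unname(cnt3[c("AC", "GT")]), c(1L, 1L))

  expect_error(count_kmers(a, mk_gr("s1", 1, 4), 5), "k must be")
})

test_that("windows never span interval boundaries", {
  a <- mk_assembly(s1 = "AAAAAA")
  # two abutting-but-separate windows would create an extra AA if spanned;
  # merge_intervals fuses abutting intervals, so use disjoint ones
  cnt <- count_kmers(a, mk_gr("s1", c(1, 4), c(2, 6)), 2)
  expect_equal(unname(cnt["AA"]), 1L + 2L)
})

test_that("interval counting equals counting on an N-masked sequence", {
  set.seed(31)
  for (i in 1:20) {
    n <- 2000
    s <- random_seq(n)
    iv <- merge_intervals(random_intervals(n, 6))
    keep <- coverage_vec(iv, n)
    masked <- strsplit(s, "")[[1]]
    masked[!keep] <- "N"
    am <- mk_assembly(s1 = paste(masked, collapse = ""))
    ai <- mk_assembly(s1 = s)
    for (k in 2:4) {
      expect_identical(count_kmers(ai, iv, k),
                       count_kmers(am, mk_gr("s1", 1, n), k))
    }
  }
})

test_that("counts are additive over disjoint interval sets", {
  set.seed(13)
  s <- random_seq(5000)
  a <- mk_assembly(s1 = s)
  left <- mk_gr("s1", c(1, 1200), c(1000, 1400))
  right <- mk_gr("s1", c(3000, 4500), c(3500, 4600))
  both <- c(left, right)
  for (k in 2:4) {
    expect_identical(count_kmers(a, both, k),
                     count_kmers(a, left, k) + count_kmers(a, right, k))
  }
})

test_that("normalization divides by the compartment k-mer total", {
  counts <- tibble::tibble(kmer = c("AC", "CG", "GT"), k = 2,
                           count = c(1L, 1L, 1L))
  norm <- normalize_kmer_counts(counts)
  expect_equal(norm$freq, rep(1 / 3, 3))

  one <- normalize_kmer_counts(tibble::tibble(kmer = "AA", k = 2, count = 3L))
  expect_equal(one$freq, 1)

  empty <- tibble::tibble(kmer = kmer_universe(), k = nchar(kmer_universe()),
                          count = 0L)
  expect_error(normalize_kmer_counts(empty), "empty compartment")
})

test_that("frequencies sum to one per k-length, and jointly under all_kmers", {
  set.seed(77)
  a <- mk_assembly(s1 = random_seq(60000))
  cm <- build_compartments(a, mk_gr("s1", 1001, 9000),
                           mk_gr("s1", 30001, 32000))
  counts <- count_compartment_kmers(a, cm)
  for (cp in unique(counts$compartment)) {
    norm <- normalize_kmer_counts(counts[counts$compartment == cp,
                                         c("kmer", "k", "count")])
    sums <- tapply(norm$freq, norm$k, sum)
    expect_true(all(abs(sums - 1) < 1e-12))
  }
  joint <- normalize_kmer_counts(counts[counts$compartment == "coding",
                                        c("kmer", "k", "count")],
                                 scope = "all_kmers")
  expect_lt(abs(sum(joint$freq) - 1), 1e-12)
})

test_that("a zero-total k-length is flagged undefined, not imputed", {
  counts <- tibble::tibble(kmer = c("AA", "AAA"), k = c(2, 3),
                           count = c(10L, 0L))
  norm <- normalize_kmer_counts(counts)
  expect_true(norm$defined[norm$k == 2])
  expect_false(norm$defined[norm$k == 3])
  expect_true(is.na(norm$freq[norm$k == 3]))
})

test_that("enrichment ratios are frequency quotients with zero-flagging", {
  f <- function(ac, cg) tibble::tibble(kmer = c("AC", "CG"), k = 2,
                                       freq = c(ac, cg), defined = TRUE)
  prof <- enrichment_profile(f(0.005, 0.995), f(0.02, 0.98), f(0.02, 0.98))
  expect_equal(prof$E_noncoding[prof$kmer == "AC"], 4)
  expect_equal(prof$E_repeat[prof$kmer == "AC"], 1)

  # identical composition in all compartments
  same <- enrichment_profile(f(0.3, 0.7), f(0.3, 0.7), f(0.3, 0.7))
  expect_true(all(same$E_noncoding == 1 & same$E_repeat == 1))

  # zero denominator -> undefined and excluded downstream
  z <- enrichment_profile(f(0, 1), f(0.5, 0.5), f(0.5, 0.5))
  expect_false(z$defined_nc[z$kmer == "AC"])
  expect_true(is.na(z$E_noncoding[z$kmer == "AC"]))

  expect_error(
    enrichment_profile(f(1, 0),
                       tibble::tibble(kmer = "TT", k = 2, freq = 1,
                                      defined = TRUE),
                       f(1, 0)),
    "mismatched")
})

test_that("uniform sequence with arbitrary labels shows no enrichment", {
  set.seed(404)
  a <- mk_assembly(s1 = random_seq(600000), s2 = random_seq(600000))
  gstart <- round(seq(1, 591000, length.out = 40))
  rstart <- round(seq(3500, 500000, length.out = 10))
  genes <- mk_gr(rep(c("s1", "s2"), each = 40), rep(gstart, 2),
                 rep(gstart, 2) + 5999)
  reps <- mk_gr(rep(c("s1", "s2"), each = 10), rep(rstart, 2),
                rep(rstart, 2) + 1999)
  prof <- genome_enrichment_profile(a, genes, reps)
  frac <- mean(prof$E_noncoding[prof$defined_nc] > 2)
  expect_lt(frac, 0.01)
})

test_that("GC segmentation leaves homogeneous sequence unsplit", {
  set.seed(21)
  a <- mk_assembly(s1 = random_seq(10000, gc = 0.5))
  seg <- gc_segmentation(a)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$start, 1)
  expect_equal(seg$end, 10000)

  two <- mk_assembly(s1 = random_seq(8000, 0.45), s2 = random_seq(8000, 0.55))
  expect_equal(gc_segment_count(two), 2L)
})

test_that("GC segmentation finds a sharp compositional junction", {
  set.seed(22)
  a <- mk_assembly(s1 = paste0(random_seq(10000, gc = 0.2),
                               random_seq(10000, gc = 0.7)))
  seg <- gc_segmentation(a)
  expect_equal(nrow(seg), 2L)
  expect_lt(abs(seg$end[1] - 10000), 50)
  expect_lt(seg$gc[1], 0.25)
  expect_gt(seg$gc[2], 0.65)
  # segments tile the scaffold
  expect_equal(seg$start, c(1, seg$end[1] + 1))
  expect_equal(seg$end[2], 20000)
  expect_true(all(seg$end - seg$start + 1 >= 200))
})

test_that("GC segmentation is deterministic and monotone in the threshold", {
  set.seed(23)
  a <- mk_assembly(s1 = paste0(random_seq(5000, 0.3), random_seq(5000, 0.6),
                               random_seq(5000, 0.4)))
  s1 <- gc_segmentation(a)
  s2 <- gc_segmentation(a)
  expect_identical(s1, s2)
  counts <- vapply(c(400, 100, 25, 5),
                   function(th) gc_segment_count(a, halting_threshold = th),
                   integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("intergenic distances use neighbors and scaffold ends", {
  lens <- c(s1 = 100000)
  d <- intergenic_distances(mk_gr("s1", c(10001, 40001), c(20000, 50000)),
                            lens)
  expect_equal(d$d3[1], 20000)
  expect_equal(d$d5[2], 20000)
  expect_equal(d$d5[1], 10000)
  expect_equal(d$d3[2], 50000)

  single <- intergenic_distances(mk_gr("s1", 1, 1000), lens)
  expect_equal(single$d5, 0)
  expect_equal(single$d3, 99000)

  abut <- intergenic_distances(mk_gr("s1", c(1000, 2001), c(2000, 3000)),
                               lens)
  expect_equal(abut$d3[1], 0)
  expect_equal(abut$d5[2], 0)

  expect_error(intergenic_distances(mk_gr("s1", 99000, 110000), lens),
               "outside")
  expect_error(intergenic_distances(mk_gr("s1", c(100, 150), c(200, 250)),
                                    lens), "overlapping")
})

test_that("compartmentalization applies strict thresholds", {
  mk_d <- function(n_sparse, n_total) {
    tibble::tibble(scaffold = "s1", start = 1, end = 2,
                   d5 = c(rep(6000, n_sparse), rep(100, n_total - n_sparse)),
                   d3 = c(rep(6000, n_sparse), rep(100, n_total - n_sparse)))
  }
  r <- compartmentalization(mk_d(2, 100))
  expect_equal(r$sparse_fraction, 0.02)
  expect_true(r$compartmentalized)

  r1 <- compartmentalization(mk_d(1, 100))
  expect_equal(r1$sparse_fraction, 0.01)
  expect_false(r1$compartmentalized)       # strict >1%

  r0 <- compartmentalization(mk_d(0, 50))
  expect_equal(r0$sparse_fraction, 0)
  expect_false(r0$compartmentalized)

  # sparse requires both flanks above the cutoff, strictly
  edge <- tibble::tibble(scaffold = "s1", start = 1, end = 2,
                         d5 = 5000, d3 = 50000)
  expect_false(compartmentalization(edge)$per_gene$sparse)

  expect_error(compartmentalization(mk_d(0, 0)), "zero genes")
})
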