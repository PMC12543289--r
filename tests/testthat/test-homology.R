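mk_hit <- function(q, s, pident = 90, length = 500, mismatch = 10,
                   gapopen = 1, qstart = 1, qend = 500, sstart = 1,
                   send = 500, evalue = 1e-50, bitscore = 800) {
  tibble::tibble(qseqid = q, sseqid = s, pident = pident, length = length,
                 mismatch = mismatch, gapopen = gapopen, qstart = qstart,
                 qend = qend, sstart = sstart, send = send, evalue = evalue,
                 bitscore = bitscore)
}

test_that("tabular alignment round-trips through the reader", {
  h <- dplyr::bind_rows(mk_hit("a", "b"), mk_hit("b", "a", pident = 85.5))
  f <- tempfile(fileext = ".tsv")
  write.table(h, f, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  r <- read_alignment_table(f)
  expect_equal(r$pident, c(90, 85.5))
  expect_equal(names(r)[1:4],
               c("qseqid", "sseqid", "pident", "length"))
})

test_that("dedupe removes self-hits and score-identical duplicates", {
  h <- dplyr::bind_rows(
    mk_hit("a", "a"),                                   # full self-hit
    mk_hit("a", "b"),
    mk_hit("a", "b"),                                   # duplicate signature
    mk_hit("b", "a"),                                   # reciprocal, kept
    mk_hit("a", "a", qstart = 10, sstart = 300, qend = 200, send = 490)
  )
  d <- dedupe_hits(h)
  expect_equal(nrow(d), 3L)
  # partial within-sequence self-alignment is not a self-hit
  expect_true(any(d$qseqid == "a" & d$sseqid == "a"))
  expect_equal(sum(d$qseqid == "a" & d$sseqid == "b"), 1L)
})

test_that("repeat hits land in cumulative length bins and one identity bin", {
  h <- dplyr::bind_rows(
    mk_hit("a", "b", pident = 97, length = 6000),
    mk_hit("c", "d", pident = 85, length = 150),
    mk_hit("e", "f", pident = 90, length = 100),   # strict >100 fails
    mk_hit("g", "h", pident = 60, length = 5000)   # below pre-filter
  )
  p <- bin_repeat_hits(h)
  get <- function(lb, ib) p$n[p$length_bin == lb & p$identity_bin == ib]
  expect_equal(get(">100", ">95"), 1L)
  expect_equal(get(">1000", ">95"), 1L)
  expect_equal(get(">5000", ">95"), 1L)
  expect_equal(get(">10000", ">95"), 0L)
  expect_equal(get(">100", "80-95"), 1L)
  expect_equal(get(">1000", "80-95"), 0L)
  expect_equal(n_1kb(p), 1L)
})

test_that("repeat binning equals a brute-force reclassification oracle", {
  set.seed(55)
  n <- 200
  h <- mk_hit(paste0("q", 1:n), paste0("s", 1:n),
              pident = round(runif(n, 75, 100), 2),
              length = sample(c(50:200, 900:1100, 4000:6000, 9000:12000),
                              n, replace = TRUE))
  p <- bin_repeat_hits(h)
  # oracle: per-record loop, direct restatement of the category definitions
  oracle <- list()
  for (lb in c(100, 1000, 5000, 10000)) for (ib in c("80-95", ">95")) {
    cnt <- 0L
    for (i in seq_len(n)) {
      if (h$pident[i] < 80) next
      id <- if (h$pident[i] > 95) ">95" else "80-95"
      if (h$length[i] > lb && id == ib) cnt <- cnt + 1L
    }
    oracle[[paste0(">", lb, ib)]] <- cnt
  }
  for (i in seq_len(nrow(p))) {
    expect_identical(p$n[i],
                     oracle[[paste0(p$length_bin[i], p$identity_bin[i])]])
  }
})

test_that("protein hits fall in exactly one length bin", {
  h <- mk_hit(paste0("p", 1:4), paste0("q", 1:4),
              length = c(50, 51, 500, 600))
  b <- bin_protein_hits(h)
  expect_equal(b$n[b$length_bin == "<=50"], 1L)
  expect_equal(b$n[b$length_bin == "50-100"], 1L)
  expect_equal(b$n[b$length_bin == "100-500"], 1L)
  expect_equal(b$n[b$length_bin == ">500"], 1L)
  expect_equal(sum(b$n), nrow(h))
})

test_that("reciprocal best hits require mutual top bitscores", {
  ab <- dplyr::bind_rows(
    mk_hit("a1", "b1", bitscore = 900),
    mk_hit("a1", "b2", bitscore = 500),
    mk_hit("a2", "b2", bitscore = 700)
  )
  ba <- dplyr::bind_rows(
    mk_hit("b1", "a1", bitscore = 880),
    mk_hit("b2", "a3", bitscore = 750),   # b2's best is a3, not a2
    mk_hit("b2", "a2", bitscore = 600)
  )
  r <- reciprocal_best_hits(ab, ba)
  expect_equal(nrow(r), 1L)
  expect_equal(r$a, "a1")
  expect_equal(r$b, "b1")
  expect_false(r$tie)
})

test_that("bitscore ties break by evalue then input order, flagged", {
  ab <- dplyr::bind_rows(
    mk_hit("a1", "b1", bitscore = 900, evalue = 1e-60),
    mk_hit("a1", "b2", bitscore = 900, evalue = 1e-60)
  )
  ba <- mk_hit("b1", "a1", bitscore = 900)
  r <- reciprocal_best_hits(ab, ba)
  expect_equal(r$b, "b1")   # first in input order
  expect_true(r$tie)
})

test_that("reciprocal best hits are symmetric", {
  set.seed(66)
  mk_dir <- function(qs, ss) {
    n <- 30
    mk_hit(sample(qs, n, TRUE), sample(ss, n, TRUE),
           bitscore = round(runif(n, 100, 999)),
           evalue = 10^-round(runif(n, 10, 80)))
  }
  ab <- mk_dir(paste0("a", 1:6), paste0("b", 1:6))
  ba <- mk_dir(paste0("b", 1:6), paste0("a", 1:6))
  r1 <- reciprocal_best_hits(ab, ba)
  r2 <- reciprocal_best_hits(ba, ab)
  expect_setequal(paste(r1$a, r1$b), paste(r2$b, r2$a))
})

test_that("pangenome categories partition the orthogroups", {
  set.seed(8)
  n_sp <- 40
  m <- cbind(
    core = rbinom(n_sp, 1, 1),            # 40/40
    soft = c(rep(1, 34), rep(0, 6)),      # 85%
    shell = c(rep(1, 24), rep(0, 16)),    # 60%
    var = c(rep(1, 20), rep(0, 20)),      # exactly 50% -> variable
    singleton = c(1, rep(0, n_sp - 1))
  )
  p <- pangenome_categories(m)
  expect_equal(as.character(p$category),
               c("core", "softcore", "shell", "variable", "singleton"))
  expect_equal(sum(table(p$category)), ncol(m))
  expect_error(pangenome_categories(matrix(nrow = 0, ncol = 0)), "empty")
})

test_that("focal orthogroup filters are conjunctive", {
  n_sp <- 100
  classes <- rep(paste0("class", 1:20), each = 5)
  counts <- cbind(
    rare = c(rep(1, 4), rep(0, 96)),                  # 4% presence
    multi = c(rep(2, 50), rep(1, 10), rep(0, 40)),    # single-copy 17%
    narrow = c(rep(1, 25), rep(0, 75)),               # 5 classes only
    good = rep(1, 100)
  )
  colnames(counts) <- c("rare", "multi", "narrow", "good")
  classes_narrow <- c(rep("class1", 5), rep("class2", 20), rep("class3", 75))
  f <- select_focal_orthogroups(counts, classes)
  expect_true("good" %in% f)
  expect_false("rare" %in% f)
  expect_false("multi" %in% f)
  f2 <- select_focal_orthogroups(counts, classes_narrow)
  expect_false("narrow" %in% f2)
})

test_that("synteny ratios are 1 on identical genomes, 0.5 on a scrambled pair", {
  orders <- dplyr::bind_rows(lapply(c("sp1", "sp2"), function(sp) {
    tibble::tibble(species = sp, scaffold = "c1", rank = 1:9,
                   gene_id = paste0(sp, "_g", 1:9))
  }))
  og <- tibble::tibble(
    gene_id = c(paste0("sp1_g", 1:9), paste0("sp2_g", 1:9)),
    orthogroup = rep(paste0("OG", 1:9), 2)
  )
  r <- synteny_ratio(orders, og, focal = "OG5", window = 10)
  expect_true(all(r$ratio == 1))
  expect_equal(synteny_summary(r)$mean_synteny, 1)

  # second species: same focal, all neighbors unique to it
  og2 <- og
  og2$orthogroup[10:18] <- c(paste0("X", 1:4), "OG5", paste0("X", 5:8))
  r2 <- synteny_ratio(orders, og2, focal = "OG5", window = 10)
  expect_true(all(r2$ratio == 0.5))
  expect_equal(synteny_summary(r2)$mean_synteny, 0.5)

  expect_error(synteny_ratio(orders, og, focal = "OG99"), "absent")
})

test_that("windows truncate at scaffold boundaries", {
  orders <- tibble::tibble(species = "sp1",
                           scaffold = c(rep("c1", 6), rep("c2", 6)),
                           rank = c(1:6, 1:6),
                           gene_id = paste0("g", 1:12))
  og <- tibble::tibble(gene_id = paste0("g", 1:12),
                       orthogroup = paste0("OG", 1:12))
  # focal 3 genes from the start of c2: upstream window holds 2 genes
  r <- synteny_ratio(orders, og, focal = "OG9", window = 10)
  expect_setequal(r$neighbor, paste0("OG", c(7, 8, 10, 11, 12)))
})

test_that("the pairwise aligner produces usable records from repeat copies", {
  set.seed(12)
  cons <- random_seq(400)
  mutate_at <- function(s, rate) {
    ch <- strsplit(s, "")[[1]]
    i <- which(runif(length(ch)) < rate)
    ch[i] <- sample(c("A", "C", "G", "T"), length(i), replace = TRUE)
    paste(ch, collapse = "")
  }
  seqs <- Biostrings::DNAStringSet(c(r1 = cons, r2 = mutate_at(cons, 0.03),
                                     r3 = mutate_at(cons, 0.10)))
  recs <- align_repeats(seqs)
  expect_true(all(recs$pident >= 80))
  expect_true(any(recs$qseqid == recs$sseqid))   # self-hits present
  d <- dedupe_hits(recs)
  expect_false(any(d$qseqid == d$sseqid & d$qstart == d$sstart &
                     d$qend == d$send))
  p <- bin_repeat_hits(d)
  expect_gt(p$n[p$length_bin == ">100" & p$identity_bin == ">95"], 0)
})
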