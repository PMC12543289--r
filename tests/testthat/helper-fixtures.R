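# in-code fixtures shared across test files

mk_assembly <- function(...) {
  Biostrings::DNAStringSet(c(...))
}

mk_gr <- function(scaffold, start, end, seqlengths = NULL) {
  GenomicRanges::GRanges(scaffold, IRanges::IRanges(start, end),
                         seqlengths = seqlengths)
}

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# random non-degenerate interval set on [1, n]
random_intervals <- function(n, k = 5) {
  s <- sort(sample(n, k))
  e <- pmin(n, s + sample(1:50, k, replace = TRUE))
  mk_gr("s1", s, e)
}

# per-base coverage oracle for interval arithmetic
coverage_vec <- function(gr, n, scaffold = "s1") {
  v <- logical(n)
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == scaffold]
  for (i in seq_along(gr)) {
    v[GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <- TRUE
  }
  v
}

write_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# minimal GFF3 content builder
gff3_lines <- function(rows) {
  c("##gff-version 3", rows)
}

gff3_row <- function(scaffold, type, start, end, id = "x1") {
  paste(scaffold, "test", type, start, end, ".", "+", ".",
        paste0("ID=", id), sep = "\t")
}

# enrichment-profile stub with prescribed threshold counts
mk_profile <- function(n_nc_only, n_both, n_rep_only = 0, n_neutral = 50,
                       fold = 2) {
  n <- n_nc_only + n_both + n_rep_only + n_neutral
  tibble::tibble(
    kmer = paste0("k", seq_len(n)), k = 4,
    f_coding = 0.01, f_noncoding = 0.01, f_repeat = 0.01,
    E_noncoding = c(rep(fold + 1, n_nc_only + n_both),
                    rep(1, n_rep_only + n_neutral)),
    E_repeat = c(rep(1, n_nc_only), rep(fold + 1, n_both + n_rep_only),
                 rep(1, n_neutral)),
    defined_nc = TRUE, defined_rep = TRUE
  )
}
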