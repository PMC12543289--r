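#' The 336 k-mer universe
#'
#' All A/C/G/T words of length 2, 3 and 4: 16 dimers + 64 trimers + 256
#' tetramers = 336 k-mers, the fixed universe of the screen.
#'
#' @param ks Word lengths (default `2:4`).
#' @return Character vector of k-mers, sorted within each length.
#' @export
kmer_universe <- function(ks = 2:4) {
  stopifnot(all(ks %in% 2:4))
  unlist(lapply(ks, function(k) {
    sort(Biostrings::mkAllStrings(c("A", "C", "G", "T"), k))
  }), use.names = FALSE)
}

#' AT content of k-mers
#' @param kmers Character vector.
#' @return Fraction of A/T bases per k-mer.
#' @export
kmer_at_content <- function(kmers) {
  vapply(strsplit(kmers, ""), function(ch) mean(ch %in% c("A", "T")),
         numeric(1))
}

#' Count k-mers of one length over an interval set
#'
#' Counts every window of length `k` lying wholly inside a single interval
#' on the given strand. Windows never span interval boundaries (sequences
#' are extracted per interval before counting), and windows containing any
#' non-A/C/G/T base are skipped — together this reproduces counting on a
#' hard-masked assembly.
#'
#' @param assembly A named [Biostrings::DNAStringSet].
#' @param intervals A `GRanges` within the assembly.
#' @param k Word length, one of 2, 3, 4.
#' @return Named integer vector over the sorted 4^k k-mers of length `k`.
#' @export
count_kmers <- function(assembly, intervals, k) {
  if (!(length(k) == 1 && k %in% 2:4)) stop("k must be one of 2, 3, 4")
  intervals <- merge_intervals(intervals)
  universe <- sort(Biostrings::mkAllStrings(c("A", "C", "G", "T"), k))
  counts <- setNames(integer(length(universe)), universe)
  if (length(intervals) == 0) return(counts)
  sn <- as.character(GenomicRanges::seqnames(intervals))
  bad <- !(sn %in% names(assembly))
  if (any(bad)) stop("interval scaffold(s) absent from assembly: ",
                     paste(unique(sn[bad]), collapse = ", "))
  for (sc in unique(sn)) {
    r <- IRanges::ranges(intervals[sn == sc])
    if (any(IRanges::end(r) > length(assembly[[sc]]))) {
      stop("interval beyond end of scaffold ", sc)
    }
    pieces <- Biostrings::extractAt(assembly[[sc]], r)
    m <- Biostrings::oligonucleotideFrequency(pieces, width = k)
    counts[colnames(m)] <- counts[colnames(m)] + as.integer(colSums(m))
  }
  counts[universe]
}

#' Count the full k-mer universe in every compartment
#'
#' @param assembly A named [Biostrings::DNAStringSet].
#' @param cmap A `CompartmentMap` from [build_compartments()].
#' @param ks Word lengths (default `2:4`).
#' @return Tibble with columns compartment, kmer, k, count.
#' @export
count_compartment_kmers <- function(assembly, cmap, ks = 2:4) {
  stopifnot(inherits(cmap, "CompartmentMap"))
  sets <- list(coding = cmap$coding, noncoding = cmap$noncoding,
               `repeat` = cmap$repeats)
  dplyr::bind_rows(lapply(names(sets), function(cp) {
    dplyr::bind_rows(lapply(ks, function(k) {
      cnt <- count_kmers(assembly, sets[[cp]], k)
      tibble::tibble(compartment = cp, kmer = names(cnt), k = k,
                     count = unname(cnt))
    }))
  }))
}

#' Normalize k-mer counts to frequencies
#'
#' Each k-mer count is divided by the sum of all k-mer counts in its
#' compartment. The default scope `"per_k_length"` normalizes dimers,
#' trimers and tetramers separately (each length sums to 1), which makes
#' same-k-mer enrichment ratios invariant to the k mixture;
#' `"all_kmers"` divides by the grand total instead. A length whose total is
#' zero yields `NA` frequencies flagged `defined = FALSE`.
#'
#' @param counts Tibble with columns kmer, k, count (one compartment).
#' @param scope `"per_k_length"` (default) or `"all_kmers"`.
#' @return Input tibble with added columns freq and defined.
#' @export
normalize_kmer_counts <- function(counts, scope = c("per_k_length", "all_kmers")) {
  scope <- match.arg(scope)
  stopifnot(all(c("kmer", "k", "count") %in% names(counts)))
  if (sum(counts$count) == 0) stop("empty compartment: all k-mer counts are zero")
  grouped <- if (scope == "per_k_length") {
    dplyr::group_by(counts, .data$k)
  } else {
    counts
  }
  out <- dplyr::mutate(grouped,
    total = sum(.data$count),
    defined = .data$total > 0,
    freq = ifelse(.data$total > 0, .data$count / .data$total, NA_real_)
  )
  dplyr::select(dplyr::ungroup(out), -"total")
}

#' Per-k-mer enrichment profile across the three compartments
#'
#' For every k-mer, the non-coding enrichment `E_noncoding` is its frequency
#' in non-coding sequence over its frequency in coding sequence, and the
#' repeat enrichment `E_repeat` is its frequency at repeats over its
#' frequency in non-coding sequence. A ratio is undefined (`NA`, flag
#' `FALSE`) exactly when its denominator is zero or unavailable; undefined
#' ratios are excluded from all downstream threshold counts.
#'
#' @param coding,noncoding,repeat_ Normalized frequency tibbles from
#'   [normalize_kmer_counts()] (columns kmer, k, freq), one per compartment,
#'   over the same k-mer universe.
#' @return Tibble with columns kmer, k, f_coding, f_noncoding, f_repeat,
#'   E_noncoding, E_repeat, defined_nc, defined_rep.
#' @export
enrichment_profile <- function(coding, noncoding, repeat_) {
  key <- function(x) paste(x$kmer, x$k)
  if (!identical(sort(key(coding)), sort(key(noncoding))) ||
      !identical(sort(key(coding)), sort(key(repeat_)))) {
    stop("mismatched k-mer universes across compartments")
  }
  f <- function(x, nm) {
    x <- dplyr::arrange(x, .data$k, .data$kmer)
    tibble::tibble(kmer = x$kmer, k = x$k, !!nm := x$freq)
  }
  out <- dplyr::inner_join(f(coding, "f_coding"), f(noncoding, "f_noncoding"),
                           by = c("kmer", "k"))
  out <- dplyr::inner_join(out, f(repeat_, "f_repeat"), by = c("kmer", "k"))
  dplyr::mutate(out,
    defined_nc = !is.na(.data$f_coding) & .data$f_coding > 0 &
      !is.na(.data$f_noncoding),
    defined_rep = !is.na(.data$f_noncoding) & .data$f_noncoding > 0 &
      !is.na(.data$f_repeat),
    E_noncoding = ifelse(.data$defined_nc,
                         .data$f_noncoding / .data$f_coding, NA_real_),
    E_repeat = ifelse(.data$defined_rep,
                      .data$f_repeat / .data$f_noncoding, NA_real_)
  )
}

#' One-call k-mer enrichment profile for a genome
#'
#' Convenience wrapper: builds compartments, counts the 336-k-mer universe,
#' normalizes per compartment and returns the enrichment profile.
#'
#' @inheritParams build_compartments
#' @param ks Word lengths (default `2:4`).
#' @param scope Normalization scope, see [normalize_kmer_counts()].
#' @return See [enrichment_profile()].
#' @export
genome_enrichment_profile <- function(assembly, genes, repeats,
                                      min_scaffold_len = 50000, ks = 2:4,
                                      scope = "per_k_length") {
  cmap <- build_compartments(assembly, genes, repeats, min_scaffold_len)
  counts <- count_compartment_kmers(assembly, cmap, ks)
  norm <- lapply(split(counts, counts$compartment), function(x) {
    normalize_kmer_counts(dplyr::select(x, -"compartment"), scope = scope)
  })
  enrichment_profile(norm[["coding"]], norm[["noncoding"]], norm[["repeat"]])
}
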