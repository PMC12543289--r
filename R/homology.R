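#' Read a 12-column tabular pairwise alignment file
#'
#' Standard tab-separated alignment table (the BLAST `outfmt 6` dialect,
#' 1-based inclusive coordinates): qseqid, sseqid, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore.
#'
#' @param path Path to the file.
#' @return Tibble of alignment records in input order.
#' @export
read_alignment_table <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  x <- read.table(path, sep = "\t", header = FALSE, col.names = cols,
                  stringsAsFactors = FALSE, comment.char = "#")
  tibble::as_tibble(x)
}

#' Remove self-hits and duplicated overlapping hits
#'
#' Drops records where the query hit itself over its own coordinates
#' (qseqid == sseqid with qstart == sstart and qend == send), then keeps
#' only the first record (input order) among hits to the same target that
#' share an identical alignment score signature: same pident, length,
#' mismatch, gapopen and qstart.
#'
#' @param hits Alignment tibble (see [read_alignment_table()]).
#' @return Filtered tibble, input order preserved.
#' @export
dedupe_hits <- function(hits) {
  self <- hits$qseqid == hits$sseqid &
    hits$qstart == hits$sstart & hits$qend == hits$send
  hits <- hits[!self, , drop = FALSE]
  key <- paste(hits$qseqid, hits$sseqid, hits$pident, hits$length,
               hits$mismatch, hits$gapopen, hits$qstart, sep = "\r")
  hits[!duplicated(key), , drop = FALSE]
}

#' Bin repeat self-alignment hits by length and identity
#'
#' Each deduplicated hit with identity >= 80% increments every cumulative
#' length bin whose threshold its alignment length strictly exceeds
#' (>100, >1,000, >5,000, >10,000 bp) in exactly one identity bin
#' (80-95% or >95%). Hits below 80% identity are ignored (the upstream
#' search is expected to pre-filter at 80%).
#'
#' @param hits Deduplicated alignment tibble.
#' @return Tibble with columns length_bin, identity_bin, n over the full
#'   4 x 2 grid.
#' @export
bin_repeat_hits <- function(hits) {
  hits <- hits[hits$pident >= 80, , drop = FALSE]
  len_bins <- c(100, 1000, 5000, 10000)
  len_labels <- c(">100", ">1000", ">5000", ">10000")
  id_labels <- c("80-95", ">95")
  grid <- tidyr::expand_grid(length_bin = len_labels, identity_bin = id_labels)
  id_bin <- ifelse(hits$pident > 95, ">95", "80-95")
  rows <- lapply(seq_along(len_bins), function(i) {
    sel <- hits$length > len_bins[i]
    tibble::tibble(length_bin = len_labels[i],
                   identity_bin = id_bin[sel])
  })
  tallied <- dplyr::count(dplyr::bind_rows(rows),
                          .data$length_bin, .data$identity_bin)
  out <- dplyr::left_join(grid, tallied, by = c("length_bin", "identity_bin"))
  dplyr::mutate(out, n = ifelse(is.na(.data$n), 0L, .data$n))
}

#' Count of long, near-identical repeat hits (n_1kb)
#'
#' The per-genome summary used downstream of repeat-identity binning: the
#' number of hits longer than 1 kb at more than 95% identity, a proxy for
#' recent, unmutated repeat copies.
#'
#' @param profile Tibble from [bin_repeat_hits()].
#' @return Integer count.
#' @export
n_1kb <- function(profile) {
  as.integer(profile$n[profile$length_bin == ">1000" &
                         profile$identity_bin == ">95"])
}

#' Bin protein self-alignment hits by alignment length
#'
#' Exclusive amino-acid length bins: <=50, 50-100, 100-500, >500 (left-open,
#' right-closed), with the identity distribution summarized per bin.
#'
#' @param hits Deduplicated self-proteome alignment tibble.
#' @return Tibble with columns length_bin, n, median_pident.
#' @export
bin_protein_hits <- function(hits) {
  bins <- cut(hits$length, breaks = c(-Inf, 50, 100, 500, Inf),
              labels = c("<=50", "50-100", "100-500", ">500"))
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(length_bin = bins, pident = hits$pident),
                    .data$length_bin, .drop = FALSE),
    n = dplyr::n(),
    median_pident = stats::median(.data$pident),
    .groups = "drop"
  )
  dplyr::mutate(out, length_bin = as.character(.data$length_bin))
}

#' Reciprocal best hits between two proteomes
#'
#' A pair (a, b) is reported when b is a's top-bitscore subject in the A->B
#' search and a is b's top in B->A. Bitscore ties break by lower evalue,
#' then by input order (flagged in the `tie` column).
#'
#' @param ab,ba Alignment tibbles for the two search directions.
#' @return Tibble with columns a, b, tie (TRUE when either direction's best
#'   hit was an unresolved bitscore+evalue tie broken by input order).
#' @export
reciprocal_best_hits <- function(ab, ba) {
  best <- function(hits) {
    hits$.row <- seq_len(nrow(hits))
    by_q <- split(hits, hits$qseqid)
    rows <- lapply(by_q, function(h) {
      h <- h[h$bitscore == max(h$bitscore), , drop = FALSE]
      h2 <- h[h$evalue == min(h$evalue), , drop = FALSE]
      tie <- nrow(h2) > 1 && length(unique(h2$sseqid)) > 1
      h2 <- h2[which.min(h2$.row), , drop = FALSE]
      tibble::tibble(q = h2$qseqid, s = h2$sseqid, tie = tie)
    })
    dplyr::bind_rows(rows)
  }
  fa <- best(ab)
  fb <- best(ba)
  m <- dplyr::inner_join(fa, fb, by = c(q = "s", s = "q"),
                         suffix = c("_ab", "_ba"))
  out <- tibble::tibble(a = m$q, b = m$s, tie = m$tie_ab | m$tie_ba)
  dplyr::arrange(out, .data$a, .data$b)
}

#' Generate alignment records from repeat sequences
#'
#' Local pairwise alignment of every ordered pair of sequences, emitting
#' 12-column records; used to exercise the repeat-identity metrics on
#' synthetic repeat families without an external search tool.
#'
#' @param seqs Named [Biostrings::DNAStringSet].
#' @param min_pident Report hits at or above this identity (default 80).
#' @param include_self Also emit full-length self-hits (default TRUE, so
#'   that [dedupe_hits()] has something to remove).
#' @return Alignment tibble (see [read_alignment_table()]).
#' @export
align_repeats <- function(seqs, min_pident = 80, include_self = TRUE) {
  stopifnot(is(seqs, "DNAStringSet"), !is.null(names(seqs)))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  rows <- list()
  nm <- names(seqs)
  for (i in seq_along(seqs)) {
    for (j in seq_along(seqs)) {
      if (i == j) {
        if (!include_self) next
        w <- length(seqs[[i]])
        rows[[length(rows) + 1L]] <- tibble::tibble(
          qseqid = nm[i], sseqid = nm[i], pident = 100, length = w,
          mismatch = 0L, gapopen = 0L, qstart = 1L, qend = w,
          sstart = 1L, send = w, evalue = 0, bitscore = 2 * w)
        next
      }
      al <- Biostrings::pairwiseAlignment(seqs[[i]], seqs[[j]],
                                          substitutionMatrix = mat,
                                          gapOpening = 5, gapExtension = 2,
                                          type = "local")
      len <- Biostrings::nchar(al)
      if (len == 0) next
      pid <- Biostrings::pid(al)
      if (pid < min_pident) next
      qr <- Biostrings::pattern(al)
      sr <- Biostrings::subject(al)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        qseqid = nm[i], sseqid = nm[j], pident = round(pid, 2), length = len,
        mismatch = Biostrings::nmismatch(al),
        gapopen = length(Biostrings::indel(qr)[[1]]) +
          length(Biostrings::indel(sr)[[1]]),
        qstart = Biostrings::start(qr), qend = Biostrings::end(qr),
        sstart = Biostrings::start(sr), send = Biostrings::end(sr),
        evalue = 0, bitscore = Biostrings::score(al))
    }
  }
  dplyr::bind_rows(rows)
}
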