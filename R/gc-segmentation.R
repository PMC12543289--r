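#' GC-content segmentation of an assembly
#'
#' Recursive binary segmentation of each scaffold by GC content. At each
#' step the candidate split maximizes a variance-normalized between-part
#' divergence score
#' \deqn{t = \frac{n_L n_R}{n} \frac{(gc_L - gc_R)^2}{p (1 - p)}}
#' where \eqn{p} is the segment's overall GC fraction. The segment is split
#' when the maximal score exceeds `halting_threshold` and both parts are at
#' least `min_segment_len` bp; otherwise it is reported as one segment. On
#' compositionally homogeneous sequence the maximal score stays far below
#' the default threshold of 100, so a homogeneous scaffold yields a single
#' segment. Non-A/C/G/T bases count as non-GC.
#'
#' @param assembly A named [Biostrings::DNAStringSet].
#' @param halting_threshold Stop splitting when the best score is at or
#'   below this value (default 100).
#' @param min_segment_len Minimum reported segment length in bp (default 200).
#' @return Tibble with columns scaffold, start, end, gc (segment GC
#'   fraction); segments tile each scaffold without gaps.
#' @export
gc_segmentation <- function(assembly, halting_threshold = 100,
                            min_segment_len = 200) {
  stopifnot(length(assembly) > 0, halting_threshold > 0, min_segment_len >= 1)
  out <- lapply(names(assembly), function(sc) {
    x <- .gc_indicator(assembly[[sc]])
    segs <- .segment_gc(x, halting_threshold, min_segment_len)
    tibble::tibble(scaffold = sc, start = segs$start, end = segs$end,
                   gc = segs$gc)
  })
  dplyr::bind_rows(out)
}

#' Number of GC segments in an assembly
#' @inheritParams gc_segmentation
#' @return Integer segment count, summed over scaffolds.
#' @export
gc_segment_count <- function(assembly, halting_threshold = 100,
                             min_segment_len = 200) {
  nrow(gc_segmentation(assembly, halting_threshold, min_segment_len))
}

.gc_indicator <- function(seq) {
  ch <- strsplit(as.character(seq), "")[[1]]
  as.integer(ch %in% c("G", "C"))
}

# iterative binary segmentation on a 0/1 indicator vector
.segment_gc <- function(x, threshold, min_len) {
  n <- length(x)
  cs <- cumsum(x)
  starts <- integer(0); ends <- integer(0)
  stack <- list(c(1L, n))
  while (length(stack) > 0) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    cut <- .best_gc_split(cs, i, j, threshold, min_len)
    if (is.na(cut)) {
      starts <- c(starts, i); ends <- c(ends, j)
    } else {
      # right first so output comes back sorted by start
      stack[[length(stack) + 1L]] <- c(cut + 1L, j)
      stack[[length(stack) + 1L]] <- c(i, cut)
    }
  }
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  prev <- ifelse(starts > 1L, cs[pmax(starts - 1L, 1L)], 0L)
  gc <- (cs[ends] - prev) / (ends - starts + 1L)
  list(start = starts, end = ends, gc = gc)
}

# returns absolute cut index (last position of left part) or NA
.best_gc_split <- function(cs, i, j, threshold, min_len) {
  n <- j - i + 1L
  if (n < 2L * min_len) return(NA_integer_)
  tot <- cs[j] - if (i > 1) cs[i - 1L] else 0L
  p <- tot / n
  v <- p * (1 - p)
  if (v == 0) return(NA_integer_)
  t <- as.numeric(seq.int(min_len, n - min_len))   # left part length
  left <- cs[i - 1L + t] - if (i > 1) cs[i - 1L] else 0L
  gcL <- left / t
  gcR <- (tot - left) / (n - t)
  score <- t * (n - t) / n * (gcL - gcR)^2 / v
  best <- which.max(score)
  if (score[best] > threshold) i - 1L + t[best] else NA_integer_
}
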