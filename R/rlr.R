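#' Repeat-linker-repeat layout
#'
#' Coordinates (1-based inclusive) of the two repeat copies and the linker
#' on a repeat-linker-repeat (RLR) construct: two identical repeats of
#' `repeat_len` bp (default 802) flanking a `linker_len` bp linker
#' (default 729), the configuration used to assay RIP in crosses.
#'
#' @param repeat_len Repeat copy length in bp.
#' @param linker_len Linker length in bp.
#' @return Tibble with columns region (repeat1, linker, repeat2), start, end.
#' @export
rlr_layout <- function(repeat_len = 802, linker_len = 729) {
  stopifnot(repeat_len >= 1, linker_len >= 1)
  tibble::tibble(
    region = c("repeat1", "linker", "repeat2"),
    start = c(1L, repeat_len + 1L, repeat_len + linker_len + 1L),
    end = c(repeat_len, repeat_len + linker_len, 2L * repeat_len + linker_len)
  )
}

#' Progeny/parent k-mer frequency ratios on an RLR construct
#'
#' Counts k-mers separately in the duplicated region (both repeat copies
#' pooled; windows never span a region boundary) and in the linker,
#' normalizes counts to frequencies within each region and k-length, and
#' reports the progeny/parent frequency ratio per k-mer and region. A ratio
#' is defined only where the parental frequency is positive.
#'
#' @param parent,progeny Character scalars or `DNAString`s of equal length.
#' @param layout Tibble from [rlr_layout()] matching the parent.
#' @param ks Word lengths (default `2:4`).
#' @return Tibble with columns kmer, k, region (duplicated, linker),
#'   f_parent, f_progeny, ratio, defined.
#' @export
rlr_kmer_ratios <- function(parent, progeny, layout = rlr_layout(), ks = 2:4) {
  parent <- as.character(parent)
  progeny <- as.character(progeny)
  if (nchar(parent) != nchar(progeny)) {
    stop("parent and progeny lengths differ (", nchar(parent), " vs ",
         nchar(progeny), "): align the progeny to the parent first")
  }
  if (max(layout$end) > nchar(parent)) {
    stop("layout extends beyond the sequences")
  }
  regions <- list(
    duplicated = layout[layout$region %in% c("repeat1", "repeat2"), ],
    linker = layout[layout$region == "linker", ]
  )
  one <- function(seq, reg, k) {
    pieces <- Biostrings::DNAStringSet(substring(seq, reg$start, reg$end))
    colSums(Biostrings::oligonucleotideFrequency(pieces, width = k))
  }
  out <- lapply(names(regions), function(rg) {
    dplyr::bind_rows(lapply(ks, function(k) {
      cp <- one(parent, regions[[rg]], k)
      cq <- one(progeny, regions[[rg]], k)
      fp <- if (sum(cp) > 0) cp / sum(cp) else rep(NA_real_, length(cp))
      fq <- if (sum(cq) > 0) cq / sum(cq) else rep(NA_real_, length(cq))
      tibble::tibble(kmer = names(cp), k = k, region = rg,
                     f_parent = unname(fp), f_progeny = unname(fq),
                     defined = !is.na(fp) & fp > 0 & !is.na(fq),
                     ratio = ifelse(!is.na(fp) & fp > 0 & !is.na(fq),
                                    fq / fp, NA_real_))
    }))
  })
  dplyr::bind_rows(out)
}

#' Count substitutions between two equal-length sequences
#'
#' Strict positional comparison; positions where either sequence carries an
#' N are excluded.
#'
#' @param parent,progeny Character scalars or `DNAString`s of equal length.
#' @return Integer substitution count.
#' @export
count_mutations <- function(parent, progeny) {
  a <- strsplit(as.character(parent), "")[[1]]
  b <- strsplit(as.character(progeny), "")[[1]]
  if (length(a) != length(b)) {
    stop("sequences have unequal length (", length(a), " vs ", length(b), ")")
  }
  keep <- a != "N" & b != "N"
  sum(a[keep] != b[keep])
}
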