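#' Merge an interval set
#'
#' Sorts, strips strand and merges overlapping or abutting intervals, the
#' canonical normal form used by every compartment operation.
#'
#' @param gr A [GenomicRanges::GRanges].
#' @return A merged, sorted, strand-free `GRanges`.
#' @export
merge_intervals <- function(gr) {
  stopifnot(is(gr, "GRanges"))
  GenomicRanges::strand(gr) <- "*"
  S4Vectors::mcols(gr) <- NULL
  GenomicRanges::reduce(GenomicRanges::sort(gr))
}

#' Subtract one interval set from another
#'
#' `subtract_intervals(a, b)` returns the parts of `a` not covered by `b`
#' (the `subtractBed` operation used to derive intergenic segments from gene
#' spans).
#'
#' @param a,b [GenomicRanges::GRanges] on the same assembly.
#' @return A merged `GRanges` with `a` minus `b`.
#' @export
subtract_intervals <- function(a, b) {
  a <- merge_intervals(a)
  b <- merge_intervals(b)
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  GenomicRanges::setdiff(a, b, ignore.strand = TRUE)
}

#' Total base pairs covered by an interval set
#' @param gr A `GRanges`.
#' @return Integer, covered bp after merging.
#' @export
total_bp <- function(gr) {
  sum(GenomicRanges::width(merge_intervals(gr)))
}

#' Build the three genomic compartments
#'
#' Segments an assembly into coding (gene spans, introns included),
#' non-coding (everything else) and repeat compartments. Coding and
#' non-coding partition every retained scaffold exactly; repeats may overlap
#' both, so the three compartments are non-exclusive. Scaffolds shorter than
#' `min_scaffold_len` (default 50 kb, the contiguity filter of the screen)
#' are dropped from all three compartments before any counting.
#'
#' @param assembly A named [Biostrings::DNAStringSet] (see [read_fasta()]).
#' @param genes Gene intervals, a `GRanges` (see [read_gene_annotation()]).
#' @param repeats Repeat intervals, a `GRanges`, or `NULL` for none.
#' @param min_scaffold_len Minimum scaffold length retained (bp).
#' @return An object of class `CompartmentMap`: a list with merged `GRanges`
#'   `coding`, `noncoding` and `repeats`, the named vector `seqlengths` of
#'   retained scaffolds, and `min_scaffold_len`.
#' @export
build_compartments <- function(assembly, genes, repeats = NULL,
                               min_scaffold_len = 50000) {
  lens <- scaffold_lengths(assembly)
  keep <- lens >= min_scaffold_len
  if (!any(keep)) {
    stop("no scaffold passes the minimum length threshold of ",
         min_scaffold_len, " bp")
  }
  lens <- lens[keep]
  extents <- GenomicRanges::GRanges(
    seqnames = names(lens),
    ranges = IRanges::IRanges(start = 1, end = unname(lens)),
    seqlengths = lens
  )

  genes <- .restrict_to_scaffolds(merge_intervals(genes), lens, "gene")
  coding <- GenomicRanges::intersect(extents, genes, ignore.strand = TRUE)
  noncoding <- GenomicRanges::setdiff(extents, coding, ignore.strand = TRUE)

  if (is.null(repeats)) {
    repeats <- GenomicRanges::GRanges(seqlengths = lens)
  } else {
    repeats <- .restrict_to_scaffolds(merge_intervals(repeats), lens, "repeat")
  }

  structure(
    list(coding = coding, noncoding = noncoding, repeats = repeats,
         seqlengths = lens, min_scaffold_len = min_scaffold_len),
    class = "CompartmentMap"
  )
}

# keep intervals on retained scaffolds only (warn+skip unknown scaffolds),
# clip intervals extending past a scaffold end (warn)
.restrict_to_scaffolds <- function(gr, lens, what) {
  sn <- as.character(GenomicRanges::seqnames(gr))
  unknown <- !(sn %in% names(lens))
  if (any(unknown)) {
    gr <- gr[!unknown]
    sn <- sn[!unknown]
  }
  beyond <- GenomicRanges::end(gr) > lens[sn] | GenomicRanges::start(gr) < 1
  if (any(beyond)) {
    warning(sum(beyond), " ", what,
            " interval(s) extend beyond scaffold bounds; clipped")
    GenomicRanges::end(gr) <- pmin(GenomicRanges::end(gr), unname(lens[sn]))
    GenomicRanges::start(gr) <- pmax(GenomicRanges::start(gr), 1L)
  }
  gr <- GenomicRanges::GRanges(sn, IRanges::ranges(gr), seqlengths = lens)
  merge_intervals(gr)
}

#' @export
print.CompartmentMap <- function(x, ...) {
  cat("CompartmentMap:", length(x$seqlengths), "scaffold(s) >=",
      x$min_scaffold_len, "bp\n")
  cat("  coding:   ", total_bp(x$coding), "bp\n")
  cat("  noncoding:", total_bp(x$noncoding), "bp\n")
  cat("  repeats:  ", total_bp(x$repeats), "bp\n")
  invisible(x)
}

#' Tabulate a CompartmentMap
#'
#' @param cmap A `CompartmentMap`.
#' @return A tibble with columns scaffold, compartment, start, end
#'   (1-based inclusive).
#' @export
compartment_table <- function(cmap) {
  stopifnot(inherits(cmap, "CompartmentMap"))
  one <- function(gr, label) {
    tibble::tibble(
      scaffold = as.character(GenomicRanges::seqnames(gr)),
      compartment = label,
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr)
    )
  }
  dplyr::bind_rows(one(cmap$coding, "coding"),
                   one(cmap$noncoding, "noncoding"),
                   one(cmap$repeats, "repeat"))
}
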