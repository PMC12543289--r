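#' Per-gene intergenic distances
#'
#' For each gene, the distance in bp to the nearest gene on its 5' (left)
#' and 3' (right) side along the scaffold (strand is ignored). For the first
#' and last gene on a scaffold the open side uses the distance to the
#' scaffold end, which avoids inflating gene-sparse calls on fragmented
#' assemblies.
#'
#' @param genes A `GRanges` of gene spans, non-overlapping within scaffolds
#'   (merge first if needed); abutting genes are allowed and yield gap 0.
#' @param scaffold_lengths Named integer vector of scaffold lengths.
#' @return Tibble with columns scaffold, start, end, d5, d3.
#' @export
intergenic_distances <- function(genes, scaffold_lengths) {
  stopifnot(is(genes, "GRanges"))
  sn <- as.character(GenomicRanges::seqnames(genes))
  if (!all(sn %in% names(scaffold_lengths))) {
    stop("gene(s) on scaffold(s) without a length: ",
         paste(setdiff(sn, names(scaffold_lengths)), collapse = ", "))
  }
  if (any(GenomicRanges::start(genes) < 1 |
          GenomicRanges::end(genes) > scaffold_lengths[sn])) {
    stop("gene interval(s) outside scaffold bounds")
  }
  out <- lapply(unique(sn), function(sc) {
    g <- genes[sn == sc]
    g <- g[order(GenomicRanges::start(g))]
    s <- GenomicRanges::start(g); e <- GenomicRanges::end(g)
    if (any(s[-1] <= e[-length(e)])) {
      stop("overlapping gene intervals on scaffold ", sc)
    }
    L <- scaffold_lengths[[sc]]
    d5 <- s - c(1L, e[-length(e)] + 1L)
    d3 <- c(s[-1] - 1L, L) - e
    tibble::tibble(scaffold = sc, start = s, end = e, d5 = d5, d3 = d3)
  })
  dplyr::bind_rows(out)
}

#' Gene-density compartmentalization of a genome
#'
#' A gene is gene-sparse when flanked on both sides by more than
#' `sparse_threshold` bp of intergenic sequence (default 5 kb); the genome
#' is compartmentalized ("two-speed") when strictly more than
#' `genome_fraction` (default 1%) of its gene pool is gene-sparse.
#'
#' @param distances Tibble from [intergenic_distances()].
#' @param sparse_threshold Flanking distance cutoff in bp (strict `>`).
#' @param genome_fraction Gene-pool fraction cutoff (strict `>`).
#' @return List with `per_gene` (input plus `sparse` flag),
#'   `sparse_fraction` and `compartmentalized`.
#' @export
compartmentalization <- function(distances, sparse_threshold = 5000,
                                 genome_fraction = 0.01) {
  if (nrow(distances) == 0) stop("zero genes: compartmentalization undefined")
  per_gene <- dplyr::mutate(distances,
    sparse = .data$d5 > sparse_threshold & .data$d3 > sparse_threshold)
  frac <- mean(per_gene$sparse)
  list(per_gene = per_gene,
       sparse_fraction = frac,
       compartmentalized = frac > genome_fraction)
}
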