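#' Read a genome assembly from FASTA
#'
#' Sequences are upper-cased on read and IUPAC ambiguity codes other than N
#' are replaced by N, so that downstream k-mer windows containing any
#' ambiguous base drop out of the A/C/G/T k-mer universe (the equivalent of
#' counting on a hard-masked assembly).
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A named [Biostrings::DNAStringSet]. Names are the FASTA ids
#'   truncated at the first whitespace.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate scaffold id(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(Biostrings::width(seqs) == 0)) {
    stop("empty record(s) in FASTA: ",
         paste(ids[Biostrings::width(seqs) == 0], collapse = ", "))
  }
  names(seqs) <- ids
  # map every ambiguity code except N to N; DNAStringSet is already uppercase
  Biostrings::DNAStringSet(Biostrings::chartr("RYSWKMBDHV", "NNNNNNNNNN", seqs))
}

#' Scaffold lengths of an assembly
#' @param assembly A named [Biostrings::DNAStringSet].
#' @return Named integer vector of scaffold lengths (bp).
#' @export
scaffold_lengths <- function(assembly) {
  setNames(Biostrings::width(assembly), names(assembly))
}

#' Read gene intervals from a GFF3 annotation
#'
#' Keeps rows whose `type` equals `feature` (default `"gene"`, so introns and
#' UTRs inside gene spans stay in the coding fraction), merges overlapping
#' spans per scaffold and drops strand: compartment construction is
#' strand-agnostic.
#'
#' @param path Path to a GFF3 file (1-based inclusive coordinates).
#' @param feature Feature type to retain (default `"gene"`).
#' @return A strand-free, merged [GenomicRanges::GRanges].
#' @export
read_gene_annotation <- function(path, feature = "gene") {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == feature]
  merge_intervals(gr)
}

#' Read repeat intervals from GFF3 or BED
#'
#' All feature types are kept (RepeatMasker-derived annotations label rows
#' by repeat family); overlapping repeats are merged. BED input is 0-based
#' half-open and converted on import; GFF3 is 1-based inclusive.
#'
#' @param path Path to the annotation file.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @return A strand-free, merged [GenomicRanges::GRanges].
#' @export
read_repeat_annotation <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("repeat annotation file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- rtracklayer::import(path, format = format)
  merge_intervals(gr)
}
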