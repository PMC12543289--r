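#' Simulate a repeat-linker-repeat cross
#'
#' Builds a parental RLR construct — two identical repeat copies (default
#' 802 bp, drawn from the CpA/TpG-enriched consensus chain) flanking a
#' uniform-composition linker (default 729 bp) — and a set of progeny, each
#' independently RIP-mutated in the two repeat copies only at per-context
#' rate `p`. `p = 0` emulates a RIP-deficient cross (all progeny identical
#' to the parent); positive `p` emulates a wild-type cross.
#'
#' @param parent_seed RNG seed for the whole cross.
#' @param p Per-context mutation probability in the repeat copies.
#' @param n_progeny Number of progeny (default 12).
#' @param repeat_len,linker_len Construct dimensions, see [rlr_layout()].
#' @param cpa_density Fraction of repeat-consensus tokens that are CpA or TpG
#'   dinucleotides (default 0.3, giving paper-scale mutation counts).
#' @return List with `parent` (character), `progeny` (character vector),
#'   `layout` (tibble), `mutation_counts` (per progeny) and `p`.
#' @export
simulate_rlr_cross <- function(parent_seed = 1, p = 0.3, n_progeny = 12,
                               repeat_len = 802, linker_len = 729,
                               cpa_density = 0.3) {
  stopifnot(n_progeny >= 1, p >= 0, p <= 1)
  set.seed(parent_seed)
  layout <- rlr_layout(repeat_len, linker_len)
  rep_ch <- .sim_repeat_consensus(repeat_len, cpa_density)
  linker_ch <- sample(c("A", "C", "G", "T"), linker_len, replace = TRUE)
  parent <- paste(c(rep_ch, linker_ch, rep_ch), collapse = "")
  reps <- layout[layout$region %in% c("repeat1", "repeat2"), c("start", "end")]
  progeny <- character(n_progeny)
  counts <- integer(n_progeny)
  for (i in seq_len(n_progeny)) {
    m <- rip_mutator(parent, reps, p)
    progeny[i] <- m$sequence
    counts[i] <- m$mutation_count
  }
  list(parent = parent, progeny = progeny, layout = layout,
       mutation_counts = counts, p = p)
}
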