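#!/usr/bin/env Rscript

# Homology-derived metrics. Repeat sequence identity is computed on the
# simulated RIP-active genome's own repeat copies: all-vs-all local
# alignment of the extracted copies stands in for the external search, the
# hits are deduplicated, binned by cumulative length and identity class,
# and summarized as n_1kb (hits >1 kb at >95% identity). Pangenome
# categories and microsynteny run on a constructed 12-species orthogroup
# table.

suppressMessages(library(ripscan))
suppressMessages(library(Biostrings))
suppressMessages(library(GenomicRanges))
suppressMessages(library(dplyr))

stopifnot(dir.exists("results/sim/ripped"))
set.seed(7)

## repeat identity -----------------------------------------------------------
for (arm in c("ripped", "clean")) {
  d <- file.path("results/sim", arm)
  assembly <- read_fasta(file.path(d, "assembly.fasta"))
  repeats <- read_repeat_annotation(file.path(d, "repeats.bed"))
  # extract up to 30 copies to keep the quadratic alignment cheap
  take <- repeats[sample(length(repeats), min(30, length(repeats)))]
  seqs <- DNAStringSet(lapply(seq_along(take), function(i) {
    sc <- as.character(seqnames(take))[i]
    subseq(assembly[[sc]], start(take)[i], end(take)[i])
  }))
  names(seqs) <- paste0("rep", seq_along(seqs))
  hits <- dedupe_hits(align_repeats(seqs, include_self = FALSE))
  prof <- bin_repeat_hits(hits)
  write.table(prof, file.path("results", paste0("repeat_identity_", arm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("[%s] %d deduped hits; >100bp/>95%%: %d; n_1kb = %d\n",
              arm, nrow(hits),
              prof$n[prof$length_bin == ">100" & prof$identity_bin == ">95"],
              n_1kb(prof)))
}

## pangenome categories on a constructed species x orthogroup table ----------
n_sp <- 12
m <- cbind(
  sapply(1:3, function(i) rep(1L, n_sp)),                    # core
  sapply(1:2, function(i) c(rep(1L, 10), 0L, 0L)),           # softcore (83%)
  sapply(1:3, function(i) c(rep(1L, 8), rep(0L, 4))),        # shell (67%)
  sapply(1:4, function(i) sample(c(rep(1L, 4), rep(0L, 8)))),# variable
  sapply(1:2, function(i) c(1L, rep(0L, n_sp - 1)))          # singletons
)
colnames(m) <- paste0("OG", seq_len(ncol(m)))
pg <- pangenome_categories(m)
write.table(pg, "results/pangenome_categories.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("pangenome categories:",
    paste(names(table(pg$category)), table(pg$category), collapse = " "),
    "\n")

## microsynteny around a conserved focal orthogroup ---------------------------
orders <- bind_rows(lapply(seq_len(6), function(s) {
  tibble::tibble(species = paste0("sp", s), scaffold = "c1", rank = 1:15,
                 gene_id = paste0("sp", s, "_g", 1:15))
}))
# species 1-4 share the neighborhood; 5-6 have rearranged flanks
og <- bind_rows(lapply(seq_len(6), function(s) {
  ogs <- paste0("OG", 1:15)
  if (s >= 5) ogs[c(1:6, 10:15)] <- paste0("PRIV", s, "_", c(1:6, 10:15))
  tibble::tibble(gene_id = paste0("sp", s, "_g", 1:15), orthogroup = ogs)
}))
ratios <- synteny_ratio(orders, og, focal = "OG8", window = 10)
sm <- synteny_summary(ratios)
write.table(ratios, "results/synteny_ratios.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("focal OG8: mean synteny %.3f over %d neighbor orthogroups\n",
            sm$mean_synteny, sm$n_neighbors))
cat("Wrote results/{repeat_identity_*,pangenome_categories,synteny_ratios}.tsv\n")
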