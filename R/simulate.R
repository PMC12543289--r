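#' Simulation configuration for synthetic annotated genomes
#'
#' Defaults describe the synthetic study condition used throughout the test
#' suite: a 2 Mb genome on 4 scaffolds of 500 kb, 500 non-overlapping genes
#' whose sequence carries two compositional signatures of real coding DNA
#' (TpA suppression and avoidance of A/T homopolymer runs), 5 repeat
#' families of 40 copies each at 2% per-copy neutral divergence, repeat
#' consensus sequences built as a renewal stream of CpA/TpG dinucleotide
#' tokens (the RIP target context) interleaved with uniform single bases,
#' and a gene-sparse block on each scaffold holding ~2% of genes with
#' >5 kb flanks.
#'
#' @param seed Integer RNG seed; the whole simulation is deterministic
#'   given the config.
#' @param n_scaffolds,scaffold_len Assembly shape.
#' @param gc_content Background GC fraction.
#' @param n_genes Total gene count.
#' @param gene_len_mean,gene_len_sd Gene length distribution (bp, normal,
#'   truncated at 300).
#' @param ta_thinning Fraction of TpA dinucleotides retained in coding
#'   sequence relative to the i.i.d. expectation (TpA suppression).
#' @param n_repeat_families,copies_per_family,repeat_len Repeat content.
#' @param repeat_divergence Per-base neutral substitution rate applied to
#'   each repeat copy before RIP.
#' @param rip_rate Per-context C->T (CpA) / G->A (TpG) mutation probability
#'   applied to repeat copies.
#' @param sparse_region_fraction Fraction of each scaffold reserved as a
#'   gene-sparse block.
#' @param sparse_gene_fraction Fraction of genes placed in sparse blocks.
#' @param cpa_density Fraction of repeat-consensus tokens that are CpA or
#'   TpG dinucleotides (RIP target density).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_scaffolds = 4, scaffold_len = 500000,
                       gc_content = 0.5, n_genes = 500,
                       gene_len_mean = 1500, gene_len_sd = 300,
                       ta_thinning = 0.5,
                       n_repeat_families = 5, copies_per_family = 40,
                       repeat_len = 500, repeat_divergence = 0.02,
                       rip_rate = 0, sparse_region_fraction = 0.15,
                       sparse_gene_fraction = 0.02, cpa_density = 0.55) {
  stopifnot(rip_rate >= 0, rip_rate <= 1,
            gc_content > 0, gc_content < 1,
            sparse_region_fraction >= 0, sparse_region_fraction < 1,
            repeat_divergence >= 0, repeat_divergence < 1,
            ta_thinning > 0, ta_thinning <= 1,
            cpa_density > 0, cpa_density < 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Context-specific RIP mutator
#'
#' Applies RIP-style mutations within the given intervals of a sequence:
#' every C immediately followed by A mutates to T with probability `p`, and
#' every G immediately preceded by T mutates to A with probability `p` (the
#' reverse-strand CpA). Contexts are evaluated against the pre-mutation
#' sequence in a single pass, so mutations cannot create or destroy
#' contexts for one another and the expected count is `p` times the number
#' of available contexts. Both bases of the dinucleotide must lie inside an
#' interval.
#'
#' @param sequence Character scalar or `DNAString`.
#' @param intervals Data frame/tibble with columns start, end (1-based
#'   inclusive), or an [IRanges::IRanges].
#' @param p Per-context mutation probability.
#' @return List with `sequence` (mutated character scalar),
#'   `mutation_count`, and `n_contexts` (available CpA/TpG contexts).
#' @export
rip_mutator <- function(sequence, intervals, p) {
  stopifnot(p >= 0, p <= 1)
  if (is(intervals, "IRanges")) {
    intervals <- data.frame(start = IRanges::start(intervals),
                            end = IRanges::end(intervals))
  }
  ch <- strsplit(as.character(sequence), "")[[1]]
  out <- ch
  n_mut <- 0L
  n_ctx <- 0L
  for (r in seq_len(nrow(intervals))) {
    s <- intervals$start[r]; e <- intervals$end[r]
    stopifnot(s >= 1, e <= length(ch), s <= e)
    if (e - s < 1) next
    idx <- s:(e - 1L)
    c_pos <- idx[ch[idx] == "C" & ch[idx + 1L] == "A"]
    g_pos <- idx[ch[idx] == "T" & ch[idx + 1L] == "G"] + 1L
    pos <- c(c_pos, g_pos)
    n_ctx <- n_ctx + length(pos)
    if (length(pos) == 0 || p == 0) next
    hit <- pos[runif(length(pos)) < p]
    out[hit[out[hit] == "C"]] <- "T"
    out[hit[out[hit] == "G"]] <- "A"
    n_mut <- n_mut + length(hit)
  }
  list(sequence = paste(out, collapse = ""),
       mutation_count = n_mut, n_contexts = n_ctx)
}

# sample a background sequence of length n at the given GC
.sim_background <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# coding-like sequence: uniform composition with TpA suppression (thinning
# factor kappa on T->A steps) and no A/T homopolymer runs of 4+, the two
# coding-sequence signatures that differentiate genic from intergenic DNA
# in the simulation
.sim_coding <- function(n, kappa) {
  ch <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  i <- which(ch[-n] == "T" & ch[-1] == "A") + 1L
  res <- i[runif(length(i)) >= kappa]
  ch[res] <- sample(c("C", "G", "T"), length(res), replace = TRUE)
  r <- rle(ch)
  long <- which(r$lengths >= 4 & r$values %in% c("A", "T"))
  if (length(long)) {
    ends <- cumsum(r$lengths)
    for (j in long) {
      pos <- seq(ends[j] - r$lengths[j] + 4, ends[j], by = 4)
      ch[pos] <- sample(setdiff(c("A", "C", "G", "T"), r$values[j]),
                        length(pos), replace = TRUE)
    }
  }
  ch
}

# repeat consensus as a token renewal process: CpA and TpG dinucleotide
# tokens (RIP targets, q/2 each) interleaved with single uniform bases, so
# mutable contexts sit in diverse flanking contexts
.sim_repeat_consensus <- function(n, q) {
  ty <- sample(c("CA", "TG", "S"), n, replace = TRUE,
               prob = c(q / 2, q / 2, 1 - q))
  tok <- ifelse(ty == "S", sample(c("A", "C", "G", "T"), n, replace = TRUE),
                ty)
  strsplit(paste(tok, collapse = ""), "")[[1]][seq_len(n)]
}

# uniform substitutions at the given rate (never to the same base)
.diverge <- function(ch, rate) {
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  ch
}

#' Simulate an annotated genome with optional RIP mutagenesis
#'
#' Builds an i.i.d. background assembly, overwrites gene bodies with
#' coding-biased composition, drops in diverged repeat-family copies in
#' intergenic space, then applies the RIP mutator to every repeat copy at
#' `config$rip_rate`. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return Object of class `SimulatedGenome`: list with `assembly`
#'   (DNAStringSet), `genes` (GRanges), `repeats` (GRanges with family,
#'   copy and realized mutation metadata), `truth` (per-repeat tibble) and
#'   `config`.
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cf <- config
  scaffolds <- paste0("scaffold_", seq_len(cf$n_scaffolds))
  L <- cf$scaffold_len

  # per-scaffold gene allocation
  n_per <- diff(round(seq(0, cf$n_genes, length.out = cf$n_scaffolds + 1)))
  n_sparse_total <- round(cf$n_genes * cf$sparse_gene_fraction)
  sparse_per <- diff(round(seq(0, n_sparse_total,
                               length.out = cf$n_scaffolds + 1)))

  seqs <- list(); gene_rows <- list(); rep_rows <- list(); truth <- list()
  for (si in seq_len(cf$n_scaffolds)) {
    sc <- scaffolds[si]
    ch <- .sim_background(L, cf$gc_content)
    dense_end <- floor(L * (1 - cf$sparse_region_fraction))

    # dense genes
    nd <- n_per[si] - sparse_per[si]
    lens <- pmax(300, round(rnorm(nd, cf$gene_len_mean, cf$gene_len_sd)))
    free <- dense_end - sum(lens)
    if (free < 2 * (nd + 1)) {
      stop("infeasible gene packing on ", sc, ": reduce n_genes or ",
           "gene_len_mean")
    }
    u <- runif(nd + 1)
    gaps <- 2 + floor(u / sum(u) * (free - 2 * (nd + 1)))
    starts <- cumsum(gaps[seq_len(nd)]) + c(0, cumsum(lens)[-nd]) + 1
    ends <- starts + lens - 1

    # sparse genes, >=6 kb apart and >=6 kb from the dense block
    ns <- sparse_per[si]
    if (ns > 0) {
      slens <- pmax(300, round(rnorm(ns, cf$gene_len_mean, cf$gene_len_sd)))
      need <- sum(slens) + (ns + 1) * 6000
      if (need > L - dense_end) {
        stop("sparse block too small on ", sc,
             ": reduce sparse_gene_fraction")
      }
      slack <- (L - dense_end - need) / (ns + 1)
      sgaps <- 6000 + floor(runif(ns + 1) * slack)
      sstarts <- dense_end + cumsum(sgaps[seq_len(ns)]) +
        c(0, cumsum(slens)[-ns]) + 1
      sends <- sstarts + slens - 1
      starts <- c(starts, sstarts); ends <- c(ends, sends)
      lens <- c(lens, slens)
    }
    for (gi in seq_along(starts)) {
      ch[starts[gi]:ends[gi]] <- .sim_coding(lens[gi], cf$ta_thinning)
    }
    gene_rows[[si]] <- tibble::tibble(scaffold = sc, start = starts,
                                      end = ends)

    # repeats into intergenic space (including the sparse block)
    n_rep <- cf$n_repeat_families * cf$copies_per_family
    n_rep_here <- diff(round(seq(0, n_rep,
                                 length.out = cf$n_scaffolds + 1)))[si]
    occupied <- IRanges::reduce(IRanges::IRanges(starts, ends))
    freeiv <- IRanges::setdiff(IRanges::IRanges(1, L), occupied)
    freeiv <- freeiv[IRanges::width(freeiv) >= cf$repeat_len + 20]
    placed <- IRanges::IRanges()
    rstart <- integer(n_rep_here)
    for (ri in seq_len(n_rep_here)) {
      w <- IRanges::width(freeiv) - cf$repeat_len - 10
      pick <- sample(length(freeiv), 1, prob = pmax(w, 1))
      off <- sample(max(w[pick], 1), 1)
      s <- IRanges::start(freeiv)[pick] + 5 + off - 1
      rstart[ri] <- s
      placed <- c(placed, IRanges::IRanges(s, s + cf$repeat_len - 1))
      freeiv <- IRanges::setdiff(freeiv, IRanges::IRanges(s - 5, s + cf$repeat_len + 4))
      freeiv <- freeiv[IRanges::width(freeiv) >= cf$repeat_len + 20]
      if (length(freeiv) == 0 && ri < n_rep_here) {
        stop("infeasible repeat packing on ", sc)
      }
    }
    rep_rows[[si]] <- tibble::tibble(scaffold = sc, start = rstart,
                                     end = rstart + cf$repeat_len - 1)
    seqs[[sc]] <- ch
  }

  genes_df <- dplyr::bind_rows(gene_rows)
  reps_df <- dplyr::bind_rows(rep_rows)

  # assign families round-robin, write diverged copies into the assembly
  consensi <- lapply(seq_len(cf$n_repeat_families), function(i) {
    .sim_repeat_consensus(cf$repeat_len, cf$cpa_density)
  })
  reps_df$family <- rep_len(seq_len(cf$n_repeat_families), nrow(reps_df))
  reps_df$copy_id <- paste0("rep_f", reps_df$family, "_c",
                            seq_len(nrow(reps_df)))
  for (ri in seq_len(nrow(reps_df))) {
    copy <- .diverge(consensi[[reps_df$family[ri]]], cf$repeat_divergence)
    seqs[[reps_df$scaffold[ri]]][reps_df$start[ri]:reps_df$end[ri]] <- copy
  }

  # RIP pass over repeat copies, per scaffold
  mut_counts <- integer(nrow(reps_df)); ctx_counts <- integer(nrow(reps_df))
  for (sc in scaffolds) {
    sel <- which(reps_df$scaffold == sc)
    if (length(sel) == 0) next
    res <- lapply(sel, function(ri) {
      rip_mutator(paste(seqs[[sc]][reps_df$start[ri]:reps_df$end[ri]],
                        collapse = ""),
                  data.frame(start = 1, end = cf$repeat_len), cf$rip_rate)
    })
    for (i in seq_along(sel)) {
      ri <- sel[i]
      seqs[[sc]][reps_df$start[ri]:reps_df$end[ri]] <-
        strsplit(res[[i]]$sequence, "")[[1]]
      mut_counts[ri] <- res[[i]]$mutation_count
      ctx_counts[ri] <- res[[i]]$n_contexts
    }
  }

  assembly <- Biostrings::DNAStringSet(
    vapply(seqs, paste, character(1), collapse = ""))
  names(assembly) <- scaffolds
  lens <- setNames(rep(L, cf$n_scaffolds), scaffolds)
  genes <- GenomicRanges::GRanges(genes_df$scaffold,
                                  IRanges::IRanges(genes_df$start,
                                                   genes_df$end),
                                  seqlengths = lens)
  genes$gene_id <- paste0("gene_", seq_along(genes))
  repeats <- GenomicRanges::GRanges(reps_df$scaffold,
                                    IRanges::IRanges(reps_df$start,
                                                     reps_df$end),
                                    seqlengths = lens)
  repeats$copy_id <- reps_df$copy_id
  repeats$family <- reps_df$family
  repeats$mutations <- mut_counts

  structure(list(
    assembly = assembly, genes = genes, repeats = repeats,
    truth = tibble::tibble(copy_id = reps_df$copy_id,
                           family = reps_df$family,
                           scaffold = reps_df$scaffold,
                           start = reps_df$start, end = reps_df$end,
                           n_contexts = ctx_counts,
                           mutations = mut_counts),
    rip_applied = cf$rip_rate > 0,
    config = cf
  ), class = "SimulatedGenome")
}

#' @export
print.SimulatedGenome <- function(x, ...) {
  cat("SimulatedGenome:", length(x$assembly), "scaffold(s),",
      sum(Biostrings::width(x$assembly)), "bp;",
      length(x$genes), "genes;", length(x$repeats), "repeat copies;",
      sum(x$truth$mutations), "RIP mutations (rate",
      x$config$rip_rate, ")\n")
  invisible(x)
}

#' Write a simulated genome to FASTA + GFF3 + BED + truth TSV
#'
#' Emits `assembly.fasta`, `genes.gff3`, `repeats.bed` and `truth.tsv` into
#' `dir`. Byte-identical output for identical configs (the config seed is
#' recorded in the truth table header).
#'
#' @param sim A `SimulatedGenome`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the four file paths.
#' @export
write_simulated_genome <- function(sim, dir) {
  stopifnot(inherits(sim, "SimulatedGenome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "assembly.fasta")
  gff <- file.path(dir, "genes.gff3")
  bed <- file.path(dir, "repeats.bed")
  tsv <- file.path(dir, "truth.tsv")
  Biostrings::writeXStringSet(sim$assembly, fa)
  g <- sim$genes
  gff_lines <- c("##gff-version 3",
                 paste(as.character(GenomicRanges::seqnames(g)), "ripscan",
                       "gene", GenomicRanges::start(g),
                       GenomicRanges::end(g), ".", "+", ".",
                       paste0("ID=", g$gene_id), sep = "\t"))
  writeLines(gff_lines, gff)
  r <- sim$repeats
  writeLines(paste(as.character(GenomicRanges::seqnames(r)),
                   GenomicRanges::start(r) - 1L, GenomicRanges::end(r),
                   r$copy_id, sep = "\t"), bed)
  con <- file(tsv, "w")
  writeLines(paste0("# seed=", sim$config$seed,
                    " rip_rate=", sim$config$rip_rate), con)
  write.table(sim$truth, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(c(fasta = fa, gff3 = gff, bed = bed, truth = tsv))
}
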