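---
title: "Methods: the compartment-wise k-mer screen for RIP-like signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the compartment-wise k-mer screen for RIP-like signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, parameter choices and numerical
decisions behind ripscan, and what the synthetic-data tests do and do not
establish about real genomes.

## The screen

Repeat-induced point mutation (RIP) and RIP-like defenses mutate duplicated
DNA, in ascomycetes converting C to T where the C is immediately followed
by A (and, on the reverse strand, G to A where the G is preceded by T).
Instead of committing to one mutational motif, the screen measures the
compositional consequence: under an active repeat-directed mutagen,
specific short words become consistently over-represented in repeats and in
non-coding DNA relative to coding DNA, while neutral drift shifts word
frequencies without a consistent compartment bias.

Three compartments are built per assembly: **coding** = merged gene spans
("gene" features, so introns stay coding), **non-coding** = the exact
complement on every retained scaffold, **repeats** = merged annotated
repeat intervals, which may overlap either. Coding and non-coding partition
each scaffold exactly (an invariant the tests enforce to the base pair);
repeats are deliberately non-exclusive. Scaffolds under 50 kb are dropped
before any counting — the screen's default contiguity filter.

All 336 words of length 2-4 are counted per compartment on the given
strand. Counting happens on sequences extracted per interval, so a window
never spans an interval boundary, and windows containing any non-ACGT base
simply match nothing — together this is exactly equivalent to counting on a
hard-masked assembly, an equivalence the test suite checks against literal
N-masking. Reverse-complement collapsing is off by default and available as
an option; the classification thresholds were set without canonicalization
and AT-rich signature words behave similarly either way.

**Normalization scope.** Counts are divided by the compartment total. We
normalize per k-length (dimer, trimer and tetramer frequencies each sum
to 1) rather than over all 336 words jointly: per-length normalization
makes the enrichment ratio of a word invariant to the 2/3/4-mer mixture,
and ratios of the same word under the two schemes differ only by a
constant factor that cancels in compartment comparisons. The literal
all-words scope is kept as an option (`scope = "all_kmers"`).

**Enrichment and classification.** Per word,
`E_nc = f_noncoding/f_coding` and `E_rep = f_repeat/f_noncoding`. A ratio
with zero denominator is undefined, flagged, and excluded from every
downstream count — no pseudo-counts, because smoothing manufactures
enrichment precisely in the sparse tail the screen cares about. With
`n_noncoding` = count of defined words with `E_nc > 2`, `n_both` = count
additionally with `E_rep > 2`, and `ratio = n_both/n_noncoding`:
*recent* requires `ratio > 0.5` and `n_both >= 10`; *trace* is the closed
band `0.3 <= ratio <= 0.5`; everything else is *none*; `n_noncoding == 0`
is *undetermined*. Two corner decisions: the trace band is closed at both
ends (the source description "0.3–0.5" does not state openness), and a
genome with `ratio > 0.5` but `n_both < 10` is called *none* — the 10-word
floor exists to suppress small-count artifacts, so high-ratio/thin-support
cells fail the recent call; the classifier warns and sets
`flag_small_both` so such genomes can be audited.

## Companion metrics

**GC segmentation.** Recursive binary segmentation per scaffold. For a
segment of length $n$ with overall GC fraction $p$, a split into parts of
lengths $n_L, n_R$ with GC fractions $gc_L, gc_R$ scores

$$t = \frac{n_L\,n_R}{n}\,\frac{(gc_L-gc_R)^2}{p(1-p)},$$

the variance-normalized between-part divergence. The best split is taken
while $t$ exceeds the halting threshold (default 100) and both parts are at
least 200 bp. On homogeneous sequence the maximal score behaves like the
supremum of a squared standardized Brownian bridge and stays an order of
magnitude below 100, so homogeneous scaffolds yield one segment; a sharp
20%/70% junction is localized within tens of bp (both are tested). The
procedure is deterministic, and lowering the threshold can only add splits
(monotonicity, also tested). The reference isochore-segmentation tool's
internal constant is not public; the contract here is behavioral, not
bit-exact. Non-ACGT bases count as non-GC.

**Gene density.** Each gene's 5′/3′ distances go to the nearest gene on
the scaffold, with the scaffold end as the neighbor for terminal genes —
treating ends as neighbors avoids inflating gene-sparse calls on
fragmented assemblies, at the cost of slightly undercounting sparseness on
very short scaffolds. Gene-sparse means both flanks strictly exceed 5 kb;
a genome is compartmentalized when strictly more than 1% of genes are
sparse.

**Repeat identity.** Deduplication removes exact self-hits and keeps the
first record among hits sharing the (pident, length, mismatch, gapopen,
qstart) signature — "first" in file order, matching how search output is
usually post-processed. Length bins are cumulative (a 6 kb hit increments
>100, >1,000 and >5,000) with one of two identity bins (80–95, >95);
`n_1kb` (>1 kb at >95%) is the downstream per-genome summary. Records are
generated for tests by `align_repeats()`, a thin wrapper around exact local
pairwise alignment; production input is external tabular search output.

**Synteny.** Windows are the orthogroups of up to 10 genes on each side of
a focal copy, never crossing scaffold boundaries, truncated windows used
as-is. For multi-copy focal genes the per-copy windows are unioned — the
permissive reading; focal genes are mostly single-copy by the selection
filters (>5% presence, >80% single-copy among carriers, ≥10 classes).

**Independent contrasts.** The Felsenstein recursion is implemented
directly (and cross-checked against an independent implementation to
1e-10 in the tests): contrast $(x_L-x_R)/\sqrt{v_L+v_R}$, nodal value the
variance-weighted mean, parent branch inflated by $v_Lv_R/(v_L+v_R)$.
Polytomies are resolved arbitrarily with zero-length branches (warned);
non-positive branch lengths are replaced by $\varepsilon = 10^{-8}$ to
avoid division by zero. Correlation between traits is the through-origin
regression `lm(iy ~ ix - 1)` summarized by adjusted R² and a two-sided
slope p-value, with Benjamini–Hochberg adjustment across pairs. The
zero-preserving log10 transform used for trait tables keeps zeros as 0 —
a deliberate reproduction of the screen's stated handling despite the
mixed scale it creates; `offset = 1` gives the cleaner `log10(x+1)`.

## The synthetic-data generator

The generator's job is to make every pipeline stage testable with known
truth, emulating the features the screen keys on:

* **Background**: i.i.d. uniform sequence at GC 0.5.
* **Coding sequence**: uniform composition with two real coding-DNA
  signatures — TpA suppression (one-pass thinning retaining 50% of TpA
  dinucleotides; TpA is universally under-represented in coding sequence)
  and avoidance of A/T homopolymer runs of length ≥4. These give the
  coding/non-coding contrast a realistic shape: a small set of words
  (poly-A/T words, TpA-containing words) is reliably non-coding-enriched
  even without any RIP, so a mutation-free genome classifies as *none*
  rather than *undetermined*.
* **Repeats**: 5 families × 40 copies of a 500 bp consensus built as a
  renewal stream of CpA/TpG tokens (55% of tokens) interleaved with
  uniform single bases, putting dense RIP targets in diverse flanking
  contexts; copies receive 2% uniform divergence before RIP, giving the
  repeat-identity metrics a realistic 80–100% identity spread.
* **RIP mutator**: within repeat intervals only, each CpA context converts
  C→T and each TpG context G→A, independently with probability `rip_rate`,
  contexts evaluated against the pre-mutation sequence in a single pass.
  Single-pass semantics make the expected count analytic
  (`p × n_contexts`, checked binomially) at the cost of not modeling
  mutation cascades across generations.
* **Architecture**: each 500 kb scaffold reserves its final 15% as a
  gene-sparse block; ~2% of genes are placed there with >6 kb flanks, so
  the compartmentalization call is positive by construction.
* **RLR crosses**: two identical 802 bp repeats flanking a 729 bp linker;
  progeny are RIP-mutated in the repeat copies only. The cross consensus
  uses a lower target density (30% tokens), which yields per-progeny
  mutation counts around 120–160 at rate 0.3 — the order of magnitude the
  real cross experiment reports — and duplicated-region AT-rich k-mer
  ratios in the 10–17× range while linker ratios remain exactly 1.

Default sizes (2 Mb, 500 genes, 200 repeat copies, 20 genomes per
recovery arm, 50 small genomes for conservation checks, 10 kb sequences
for masking equivalence, 100 Brownian replicates on 30–40-tip trees) were
chosen so the full suite runs in minutes on one CPU while keeping counting
noise per tetramer below a few percent.

The generator parameters are the study condition, not a tuning surface:
they were fixed by design analysis — the coding-signature word set must be
non-empty but small, repeats must be a minor fraction (~8%) of non-coding
bp so repeat enrichment is not diluted away, and the token consensus must
spread the post-mutation TpA products over enough distinct words to clear
the 10-word floor — and the acceptance checks were written afterwards
against those frozen values.

**What passing does and does not show.** The synthetic genomes have sharp
compartment boundaries, composition-stationary background, no nested or
fragmented repeats, no GC heterogeneity beyond what segmentation tests
construct, and a one-shot mutagen. Recovery of the planted classification
therefore validates the pipeline's arithmetic and thresholds, not the
screen's biological sensitivity on real assemblies, where annotation
quality, old unannotated repeat relics and assembly artifacts dominate the
error budget. The RLR analysis likewise validates localization of the
signature, not the genetics of the cross.

## Known limitations

* The screen's thresholds (2-fold, 0.5/0.3 ratio bands, 10-word floor) are
  taken as given, not re-estimated; near-threshold genomes flip between
  categories under counting noise.
* Strand-canonical counting, alternative normalization and open/closed
  band conventions are options, but no sensitivity analysis across them is
  bundled.
* `rlr_kmer_ratios()` assumes positionally comparable sequences; progeny
  with indels must be aligned upstream (the mutation counter refuses
  unequal lengths rather than guessing).
* GC segmentation reproduces the reference method's behavior, not its
  exact segment boundaries; its absolute segment counts are comparable
  within ripscan runs only.
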