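#' Phylogenetically independent contrasts
#'
#' Standard Felsenstein recursion on a rooted binary tree: at each internal
#' node the standardized contrast is (xL - xR) / sqrt(vL + vR), the nodal
#' value is the variance-weighted mean of the two daughters, and the branch
#' above the node is inflated by vL * vR / (vL + vR). Polytomies are
#' resolved arbitrarily with zero-length branches (with a warning), and
#' non-positive branch lengths are replaced by `epsilon` to avoid division
#' by zero.
#'
#' @param tree A rooted [ape::phylo] with branch lengths.
#' @param trait Named numeric vector covering every tip label.
#' @param epsilon Replacement for non-positive branch lengths
#'   (default 1e-8).
#' @return Tibble with one row per internal node: node (ape node id),
#'   contrast (standardized), variance (vL + vR), nodal_value.
#' @export
pic_contrasts <- function(tree, trait, epsilon = 1e-8) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (!ape::is.binary(tree) || !ape::is.rooted(tree)) {
    warning("polytomies resolved arbitrarily with zero-length branches")
    tree <- ape::multi2di(tree, random = FALSE)
  }
  if (!ape::is.rooted(tree) || !ape::is.binary(tree)) {
    stop("tree could not be resolved to a rooted binary tree")
  }
  missing <- setdiff(tree$tip.label, names(trait))
  if (length(missing) > 0) {
    stop("missing trait value for tip(s): ", paste(missing, collapse = ", "))
  }
  bl <- tree$edge.length
  bl[is.na(bl) | bl <= 0] <- epsilon

  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  x <- c(unname(trait[tree$tip.label]), rep(NA_real_, nnode))
  v <- numeric(ntip + nnode)   # extra variance accumulated above each node
  edge_above <- integer(ntip + nnode)
  edge_above[tree$edge[, 2]] <- seq_len(nrow(tree$edge))

  contrasts <- numeric(0); variances <- numeric(0)
  nodes <- integer(0); nodal <- numeric(0)
  # postorder over internal nodes
  ord <- rev(unique(tree$edge[ape::postorder(tree), 1]))
  for (nd in rev(ord)) {
    ch <- tree$edge[tree$edge[, 1] == nd, 2]
    stopifnot(length(ch) == 2)
    vL <- bl[edge_above[ch[1]]] + v[ch[1]]
    vR <- bl[edge_above[ch[2]]] + v[ch[2]]
    contrasts <- c(contrasts, (x[ch[1]] - x[ch[2]]) / sqrt(vL + vR))
    variances <- c(variances, vL + vR)
    nodes <- c(nodes, nd)
    x[nd] <- (x[ch[1]] / vL + x[ch[2]] / vR) / (1 / vL + 1 / vR)
    v[nd] <- vL * vR / (vL + vR)
    nodal <- c(nodal, x[nd])
  }
  tibble::tibble(node = nodes, contrast = contrasts, variance = variances,
                 nodal_value = nodal)
}

#' Through-origin regression between two contrast sets
#'
#' Fits `lm(cy ~ cx - 1)` (no intercept, as contrasts have arbitrary sign)
#' and reports the slope, the adjusted R-squared as the correlation
#' measure, and the two-sided p-value of the slope.
#'
#' @param cx,cy Numeric contrast vectors from the same tree in the same
#'   node order (or tibbles from [pic_contrasts()]).
#' @return One-row tibble: slope, adjusted_r2, p_value, n.
#' @export
contrast_regression <- function(cx, cy) {
  if (is.data.frame(cx)) cx <- cx$contrast
  if (is.data.frame(cy)) cy <- cy$contrast
  stopifnot(length(cx) == length(cy))
  if (length(cx) < 3) stop("need at least 3 contrasts")
  fit <- lm(cy ~ cx - 1)
  sm <- summary(fit)
  tibble::tibble(slope = unname(coef(fit)[1]),
                 adjusted_r2 = sm$adj.r.squared,
                 p_value = sm$coefficients[1, 4],
                 n = length(cx))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values (step-up BH).
#' @export
fdr_adjust <- function(pvalues) {
  stopifnot(all(is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)))
  p.adjust(pvalues, method = "BH")
}

#' Contrast correlation between two traits on a tree
#'
#' Convenience wrapper: computes independent contrasts for both traits and
#' regresses one on the other through the origin.
#'
#' @inheritParams pic_contrasts
#' @param x,y Named numeric trait vectors covering every tip.
#' @return One-row tibble, see [contrast_regression()].
#' @export
pic_regression <- function(tree, x, y, epsilon = 1e-8) {
  cx <- pic_contrasts(tree, x, epsilon)
  cy <- pic_contrasts(tree, y, epsilon)
  contrast_regression(cx$contrast, cy$contrast)
}

#' Log10 trait transform with zeros kept as zero
#'
#' The transform used before contrast analyses: log10 of positive values,
#' zeros passed through unchanged. The mixed scale this creates for
#' zero-inflated traits is deliberate, reproducing the screen's stated
#' handling; `log10(x + 1)` is available via `offset = 1` as a cleaner
#' alternative.
#'
#' @param x Non-negative numeric vector.
#' @param offset If positive, use `log10(x + offset)` instead.
#' @return Transformed vector.
#' @export
log10_keep_zero <- function(x, offset = 0) {
  stopifnot(all(is.na(x) | x >= 0))
  if (offset > 0) return(log10(x + offset))
  ifelse(!is.na(x) & x > 0, log10(x), x)
}
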