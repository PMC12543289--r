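#' Simulate correlated Brownian traits on a tree
#'
#' Bivariate Brownian motion along branches: each branch of length t adds a
#' mean-zero bivariate normal increment with covariance
#' `sigma2 * t * [[1, rho], [rho, 1]]`. Serves as the simulation oracle for
#' the contrast analyses: contrasts of either trait are i.i.d. normal with
#' variance `sigma2`, and the through-origin contrast correlation recovers
#' `rho`.
#'
#' @param tree A rooted [ape::phylo] with branch lengths.
#' @param sigma2 Brownian rate (variance per unit branch length).
#' @param rho Trait correlation in \[-1, 1\].
#' @param seed Optional RNG seed.
#' @param root_value Numeric length-2 root state (default c(0, 0)).
#' @return List of two named numeric vectors `x` and `y` over the tips.
#' @export
simulate_brownian_traits <- function(tree, sigma2 = 1, rho = 0, seed = NULL,
                                     root_value = c(0, 0)) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            rho >= -1, rho <= 1, sigma2 >= 0)
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  x <- numeric(nn); y <- numeric(nn)
  root <- ntip + 1L
  x[root] <- root_value[1]; y[root] <- root_value[2]
  # preorder: parents before children
  ord <- rev(ape::postorder(tree))
  for (ei in ord) {
    par <- tree$edge[ei, 1]; chd <- tree$edge[ei, 2]
    t <- tree$edge.length[ei]
    z1 <- rnorm(1); z2 <- rnorm(1)
    dx <- sqrt(sigma2 * t) * z1
    dy <- sqrt(sigma2 * t) * (rho * z1 + sqrt(1 - rho^2) * z2)
    x[chd] <- x[par] + dx
    y[chd] <- y[par] + dy
  }
  list(x = setNames(x[seq_len(ntip)], tree$tip.label),
       y = setNames(y[seq_len(ntip)], tree$tip.label))
}
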