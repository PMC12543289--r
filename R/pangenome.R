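#' Pangenome categories from an orthogroup presence matrix
#'
#' Bins each orthogroup by the fraction of species carrying at least one
#' member: core (>90%), softcore (>80% to 90%), shell (>50% to 80%),
#' variable (50% or less), singleton (exactly one species). Exact 90/80/50%
#' fall to the lower category; the bands are exhaustive and mutually
#' exclusive, with singleton taking precedence.
#'
#' @param counts Species x orthogroup matrix of member counts (or a logical
#'   presence matrix), with orthogroup column names.
#' @return Tibble with columns orthogroup, n_species, frequency, category.
#' @export
pangenome_categories <- function(counts) {
  counts <- as.matrix(counts)
  if (length(counts) == 0 || nrow(counts) == 0 || ncol(counts) == 0) {
    stop("empty presence matrix")
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("OG", seq_len(ncol(counts)))
  }
  present <- counts > 0
  n_sp <- colSums(present)
  freq <- n_sp / nrow(counts)
  category <- ifelse(n_sp == 1, "singleton",
              ifelse(freq > 0.9, "core",
              ifelse(freq > 0.8, "softcore",
              ifelse(freq > 0.5, "shell", "variable"))))
  tibble::tibble(orthogroup = colnames(counts), n_species = unname(n_sp),
                 frequency = unname(freq),
                 category = factor(unname(category),
                                   levels = c("core", "softcore", "shell",
                                              "variable", "singleton")))
}

#' Select focal orthogroups for synteny analysis
#'
#' Conjunctive filters: present in more than `min_presence` of all species,
#' single-copy in more than `min_single_copy` of the carrier genomes, and
#' represented in at least `min_classes` taxonomic classes.
#'
#' @param counts Species x orthogroup matrix of member counts.
#' @param class_labels Taxonomic class per species (named by, or ordered as,
#'   the matrix rows).
#' @param min_presence Presence fraction of all species (strict `>`,
#'   default 0.05).
#' @param min_single_copy Single-copy fraction among carriers (strict `>`,
#'   default 0.8).
#' @param min_classes Minimum classes among carriers (default 10).
#' @return Character vector of focal orthogroup ids.
#' @export
select_focal_orthogroups <- function(counts, class_labels,
                                     min_presence = 0.05,
                                     min_single_copy = 0.8,
                                     min_classes = 10) {
  counts <- as.matrix(counts)
  stopifnot(length(class_labels) == nrow(counts))
  present <- counts > 0
  presence_frac <- colMeans(present)
  single_frac <- vapply(seq_len(ncol(counts)), function(j) {
    carriers <- present[, j]
    if (!any(carriers)) return(0)
    mean(counts[carriers, j] == 1)
  }, numeric(1))
  n_classes <- vapply(seq_len(ncol(counts)), function(j) {
    length(unique(class_labels[present[, j]]))
  }, numeric(1))
  colnames(counts)[presence_frac > min_presence &
                     single_frac > min_single_copy &
                     n_classes >= min_classes]
}

#' Microsynteny ratios around focal orthogroups
#'
#' For each species carrying a focal orthogroup, the window is the set of
#' orthogroups of up to `window` genes upstream and `window` genes
#' downstream of each focal copy on its scaffold (windows never cross
#' scaffold boundaries; truncated windows are used as-is; multi-copy focal
#' genes contribute the union of their windows). For each neighbor
#' orthogroup observed in at least one species' window, the synteny ratio
#' is the number of species with that orthogroup in range over the number
#' of species carrying the focal orthogroup.
#'
#' @param gene_orders Tibble with columns species, scaffold, rank (gene
#'   order within scaffold), gene_id.
#' @param og_map Tibble with columns gene_id, orthogroup (genes without an
#'   orthogroup may be absent or NA).
#' @param focal Character vector of focal orthogroup ids.
#' @param window Genes per direction (default 10).
#' @return Tibble with columns focal, neighbor, n_species_in_range,
#'   n_species_with_focal, ratio.
#' @export
synteny_ratio <- function(gene_orders, og_map, focal, window = 10) {
  stopifnot(all(c("species", "scaffold", "rank", "gene_id")
                %in% names(gene_orders)),
            all(c("gene_id", "orthogroup") %in% names(og_map)))
  go <- dplyr::left_join(gene_orders, og_map, by = "gene_id")
  go <- dplyr::arrange(go, .data$species, .data$scaffold, .data$rank)
  out <- lapply(focal, function(og) {
    hits <- go[!is.na(go$orthogroup) & go$orthogroup == og, , drop = FALSE]
    if (nrow(hits) == 0) stop("focal orthogroup absent everywhere: ", og)
    carriers <- unique(hits$species)
    neighbor_sets <- lapply(carriers, function(sp) {
      gsp <- go[go$species == sp, , drop = FALSE]
      idx <- which(!is.na(gsp$orthogroup) & gsp$orthogroup == og)
      win <- unlist(lapply(idx, function(i) {
        same <- gsp$scaffold == gsp$scaffold[i]
        j <- setdiff(which(same &
                             abs(gsp$rank - gsp$rank[i]) <= window), i)
        j
      }))
      unique(gsp$orthogroup[unique(win)])
    })
    neighbors <- sort(unique(stats::na.omit(unlist(neighbor_sets))))
    if (length(neighbors) == 0) {
      return(tibble::tibble(focal = character(0), neighbor = character(0),
                            n_species_in_range = integer(0),
                            n_species_with_focal = integer(0),
                            ratio = numeric(0)))
    }
    in_range <- vapply(neighbors, function(nb) {
      sum(vapply(neighbor_sets, function(s) nb %in% s, logical(1)))
    }, integer(1))
    tibble::tibble(focal = og, neighbor = neighbors,
                   n_species_in_range = unname(in_range),
                   n_species_with_focal = length(carriers),
                   ratio = unname(in_range) / length(carriers))
  })
  dplyr::bind_rows(out)
}

#' Summarize synteny ratios per focal orthogroup
#'
#' @param ratios Tibble from [synteny_ratio()].
#' @return Tibble with columns focal, mean_synteny, n_neighbors.
#' @export
synteny_summary <- function(ratios) {
  dplyr::summarise(dplyr::group_by(ratios, .data$focal),
                   mean_synteny = mean(.data$ratio),
                   n_neighbors = dplyr::n(), .groups = "drop")
}
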