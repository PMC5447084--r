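#' Alpha-diversity indices per sample
#'
#' For each sample with relative abundances p_i, computes observed
#' richness (number of features with p_i > 0), Shannon entropy
#' (-sum p_i ln p_i, in nats), Gini-Simpson (1 - sum p_i^2), inverse
#' Simpson (1 / sum p_i^2, "effective species"), and Simpson evenness
#' (inverse Simpson / observed richness). Shannon uses the natural log,
#' the convention under which a table of ~4e4 roughly even gene
#' categories gives indices near 10.
#'
#' @param table A `feature_table` of non-negative counts or intensities.
#' @return data.frame with one row per sample: `sample_id`, `observed`,
#'   `shannon`, `gini_simpson`, `inverse_simpson`, `simpson_evenness`.
#'   All-zero samples get `NA` indices with a warning.
#' @export
alpha_diversity <- function(table) {
  v <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  totals <- colSums(v)
  empty <- totals == 0
  if (any(empty)) {
    warning("all-zero sample(s): ", paste(colnames(v)[empty], collapse = ", "))
  }
  comm <- t(v)  # vegan convention: samples in rows
  shannon <- vegan::diversity(comm, index = "shannon")
  gini <- vegan::diversity(comm, index = "simpson")
  invsimp <- vegan::diversity(comm, index = "invsimpson")
  observed <- rowSums(comm > 0)
  out <- data.frame(sample_id = colnames(v),
                    observed = as.integer(observed),
                    shannon = as.numeric(shannon),
                    gini_simpson = as.numeric(gini),
                    inverse_simpson = as.numeric(invsimp),
                    simpson_evenness = as.numeric(invsimp) / observed,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[empty, c("shannon", "gini_simpson", "inverse_simpson",
               "simpson_evenness")] <- NA_real_
  out
}

#' Shared and endemic gene-set overlap between groups
#'
#' For every pair of groups (A, B) reports the shared count |A intersect
#' B| and shared percentage 100 * |A intersect B| / |A union B|; for
#' every group A reports the endemic count |A minus the union of all
#' other groups| and the endemic percentage relative to |A|. These are
#' the conventions under which published shared/endemic gene tables for
#' functional gene arrays are internally consistent.
#'
#' @param sets Named list of >= 2 character vectors of feature ids.
#' @return List with `pairwise` (data.frame: group_a, group_b, shared,
#'   shared_pct) and `endemic` (data.frame: group, size, endemic,
#'   endemic_pct). Percentages are `NA` when a denominator is empty.
#' @export
gene_set_overlap <- function(sets) {
  if (length(sets) < 2) stop("need at least two groups")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must be named")
  }
  sets <- lapply(sets, unique)
  groups <- names(sets)
  cmb <- utils::combn(groups, 2)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
    a <- cmb[1, k]; b <- cmb[2, k]
    shared <- length(intersect(sets[[a]], sets[[b]]))
    uni <- length(union(sets[[a]], sets[[b]]))
    data.frame(group_a = a, group_b = b, shared = shared,
               shared_pct = if (uni > 0) 100 * shared / uni else NA_real_,
               stringsAsFactors = FALSE)
  }))
  endemic <- do.call(rbind, lapply(groups, function(a) {
    others <- unique(unlist(sets[setdiff(groups, a)]))
    own <- sets[[a]]
    end <- length(setdiff(own, others))
    data.frame(group = a, size = length(own), endemic = end,
               endemic_pct = if (length(own) > 0) 100 * end / length(own)
                             else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(pairwise = pairwise, endemic = endemic)
}

#' Average connectivity of a network
#'
#' Two conventions coexist in the co-occurrence network literature and
#' both appear in published topology tables: `"pmen"` counts each edge
#' at both endpoints (avgK = 2L/N, the mean node degree), while
#' `"mutualistic"` reports edges per node (L/N), the convention used for
#' bipartite taxa-function networks.
#'
#' @param n_nodes,n_links Node and edge counts.
#' @param convention `"pmen"` (2L/N) or `"mutualistic"` (L/N).
#' @return Average connectivity.
#' @export
avg_connectivity <- function(n_nodes, n_links,
                             convention = c("pmen", "mutualistic")) {
  convention <- match.arg(convention)
  if (n_nodes <= 0) return(0)
  if (convention == "pmen") 2 * n_links / n_nodes else n_links / n_nodes
}
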