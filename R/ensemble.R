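MEASURES <- c("pearson", "spearman", "bray_curtis", "kld_sym")

# --- vectorised column-wise measure kernels -------------------------------
# U and V are n_samples x B matrices of paired columns; each kernel
# returns B measure values.

col_pearson <- function(U, V) {
  U <- sweep(U, 2, colMeans(U))
  V <- sweep(V, 2, colMeans(V))
  den <- sqrt(colSums(U^2) * colSums(V^2))
  out <- colSums(U * V) / den
  out[!is.finite(out)] <- 0
  out
}

col_rank <- function(M) {
  if (ncol(M) == 1) matrix(rank(M[, 1]), ncol = 1) else apply(M, 2, rank)
}

col_spearman <- function(U, V) col_pearson(col_rank(U), col_rank(V))

col_bray <- function(U, V) {
  den <- colSums(U + V)
  out <- colSums(abs(U - V)) / den
  out[den == 0] <- 0
  out
}

col_kld <- function(U, V, pc_u, pc_v) {
  P <- U + pc_u
  Q <- V + pc_v
  P <- sweep(P, 2, colSums(P), "/")
  Q <- sweep(Q, 2, colSums(Q), "/")
  colSums(P * (log(P) - log(Q))) + colSums(Q * (log(Q) - log(P)))
}

col_measure <- function(measure, U, V, pc_u = 0, pc_v = 0) {
  switch(measure,
         pearson = col_pearson(U, V),
         spearman = col_spearman(U, V),
         bray_curtis = col_bray(U, V),
         kld_sym = col_kld(U, V, pc_u, pc_v),
         stop("unknown measure: ", measure))
}

# Pseudocount for the KL distributions: reciprocal of the vector's total
# (finite, vanishing for deep vectors), per the convention of adding one
# "virtual read" to the feature's sample vector.
kl_pseudocount <- function(x) {
  s <- sum(x)
  if (s > 0) 1 / s else 1e-6
}

#' All four association measures for feature pairs
#'
#' Computes Pearson and Spearman correlation, Bray-Curtis dissimilarity
#' and symmetrised Kullback-Leibler divergence for every cross pair
#' between `table_a` and `table_b` (bipartite mode, e.g. taxa vs
#' functional gene categories) or every within-`table_a` pair. Tables
#' are converted to relative abundance per sample first; the KL
#' divergence uses per-feature distributions across samples with a
#' pseudocount of 1/total.
#'
#' @param table_a,table_b `feature_table`s or matrices sharing sample
#'   ids; `table_b = NULL` gives within-table pairs.
#' @param close_a,close_b Close the respective table to per-sample unit
#'   sum (relative abundance) before measuring. Count tables are
#'   compositional and should be closed (default for `table_a`);
#'   intensity tables that were normalised with a global divisor (lnMR)
#'   are not, and are used as-is (default for `table_b`).
#' @return data.frame: `feature_a`, `feature_b`, one column per measure.
#' @export
pairwise_measures <- function(table_a, table_b = NULL, close_a = TRUE,
                              close_b = FALSE) {
  al <- align_tables(table_a, table_b, close_a, close_b)
  pairs <- al$pairs
  scores <- matrix(NA_real_, nrow(pairs), length(MEASURES),
                   dimnames = list(NULL, MEASURES))
  for (k in seq_len(nrow(pairs))) {
    x <- al$A[pairs$ia[k], ]
    y <- al$B[pairs$ib[k], ]
    xm <- matrix(x, ncol = 1)
    ym <- matrix(y, ncol = 1)
    for (m in MEASURES) {
      scores[k, m] <- col_measure(m, xm, ym, kl_pseudocount(x),
                                  kl_pseudocount(y))
    }
  }
  cbind(pairs[, c("feature_a", "feature_b")], as.data.frame(scores))
}

# Align two tables on shared samples, optionally close each to unit
# column sums, and enumerate pairs. Within-table mode pairs i < j.
align_tables <- function(table_a, table_b = NULL, close_a = TRUE,
                         close_b = FALSE) {
  A <- if (inherits(table_a, "feature_table")) table_a$values else
    as.matrix(table_a)
  cross <- !is.null(table_b)
  B <- if (!cross) A else {
    if (inherits(table_b, "feature_table")) table_b$values else
      as.matrix(table_b)
  }
  shared <- intersect(colnames(A), colnames(B))
  if (length(shared) < 5) {
    stop("need at least 5 shared samples, got ", length(shared))
  }
  A_raw <- A[, shared, drop = FALSE]
  B_raw <- B[, shared, drop = FALSE]
  A <- if (close_a) relative_abundance(A_raw) else A_raw
  if (!cross) {
    B_raw <- A_raw
    B <- A
    close_b <- close_a
  } else {
    B <- if (close_b) relative_abundance(B_raw) else B_raw
  }
  if (cross) {
    grid <- expand.grid(ia = seq_len(nrow(A)), ib = seq_len(nrow(B)))
  } else {
    if (nrow(A) < 2) stop("need at least two features")
    cmb <- utils::combn(nrow(A), 2)
    grid <- data.frame(ia = cmb[1, ], ib = cmb[2, ])
  }
  grid$feature_a <- rownames(A)[grid$ia]
  grid$feature_b <- rownames(B)[grid$ib]
  list(A = A, B = B, A_raw = A_raw, B_raw = B_raw, pairs = grid,
       cross = cross, close_a = close_a, close_b = close_b)
}

#' ReBoot permutation null for one feature pair
#'
#' Each permutation independently shuffles both features' values across
#' samples, renormalises each sample's full composition to unit sum,
#' and recomputes the measure. The permutation operates on the original
#' abundance scale (counts or intensities, before closure): the
#' shuffled feature is re-embedded in each sample's remaining
#' composition and the whole column re-closed, so the null reproduces
#' whatever association is induced purely by the closed-sum constraint
#' -- that is exactly the compositionality correction. Permuting
#' already-closed fractions instead would smuggle each value's source
#' denominator into the target sample and break the correction.
#'
#' @param x,y Abundance vectors of the two features over the same
#'   samples, on the scale of the table they came from.
#' @param n_perm Number of permutations (>= 20 for a usable null).
#' @param seed RNG seed; fixed seed gives an identical null sample.
#' @param measure One of `"pearson"`, `"spearman"`, `"bray_curtis"`,
#'   `"kld_sym"`.
#' @param composition `"shared"` when x and y belong to the same closed
#'   composition (a within-table pair), `"separate"` when each belongs
#'   to its own composition (bipartite pair of two compositional
#'   tables), `"none"` for non-compositional data (plain permutation
#'   null, no renormalisation).
#' @param rest_x,rest_y Per-sample abundance of the rest of the
#'   composition, on the same scale as `x` and `y`. For `"shared"`,
#'   `rest_x` is the combined remainder (defaults to `pmax(1 - x - y,
#'   0)`, the relative-abundance case); for `"separate"`, each defaults
#'   to `pmax(1 - ., 0)`. Pass column totals minus the feature when
#'   working with counts.
#' @return Numeric vector of `n_perm` null measure values.
#' @export
reboot_null <- function(x, y, n_perm = 100, seed = 1, measure = "pearson",
                        composition = c("shared", "separate", "none"),
                        rest_x = NULL, rest_y = NULL) {
  composition <- match.arg(composition)
  measure <- match.arg(measure, MEASURES)
  if (n_perm < 1) stop("n_perm must be >= 1")
  n <- length(x)
  stopifnot(length(y) == n)
  withr_seed(seed, {
    Pi <- vapply(seq_len(n_perm), function(b) x[sample.int(n)], numeric(n))
    Pj <- vapply(seq_len(n_perm), function(b) y[sample.int(n)], numeric(n))
  })
  if (composition == "shared" && is.null(rest_x)) {
    rest_x <- pmax(1 - x - y, 0)
  }
  if (composition == "separate") {
    if (is.null(rest_x)) rest_x <- pmax(1 - x, 0)
    if (is.null(rest_y)) rest_y <- pmax(1 - y, 0)
  }
  renorm <- switch(composition,
    shared = reboot_renormalize(Pi, Pj, TRUE, TRUE, TRUE, rest_x, rest_y),
    separate = reboot_renormalize(Pi, Pj, FALSE, TRUE, TRUE, rest_x, rest_y),
    none = list(U = Pi, V = Pj))
  col_measure(measure, renorm$U, renorm$V, kl_pseudocount(x),
              kl_pseudocount(y))
}

# Renormalise permuted rows within their compositions. Pi, Pj are
# n x B matrices of permuted raw values. `shared` means both features
# sit in one composition whose remainder is rest_x; otherwise rest_x /
# rest_y are each side's own remainder. close_x/close_y flag whether a
# side is compositional at all.
reboot_renormalize <- function(Pi, Pj, shared, close_x, close_y,
                               rest_x, rest_y) {
  if (shared && close_x && close_y) {
    denom <- rest_x + Pi + Pj
    denom[denom == 0] <- 1
    return(list(U = Pi / denom, V = Pj / denom))
  }
  U <- Pi
  V <- Pj
  if (close_x) {
    dx <- rest_x + Pi
    dx[dx == 0] <- 1
    U <- Pi / dx
  }
  if (close_y) {
    dy <- rest_y + Pj
    dy[dy == 0] <- 1
    V <- Pj / dy
  }
  list(U = U, V = V)
}

#' Bootstrap distribution of a measure for one feature pair
#'
#' Resamples samples with replacement and recomputes the measure,
#' yielding the sampling distribution used to judge the stability of an
#' observed association.
#'
#' @inheritParams reboot_null
#' @param n_boot Number of bootstrap resamples (>= 20).
#' @return Numeric vector of `n_boot` bootstrap measure values.
#' @export
bootstrap_dist <- function(x, y, n_boot = 100, seed = 1,
                           measure = "pearson") {
  measure <- match.arg(measure, MEASURES)
  if (n_boot < 1) stop("n_boot must be >= 1")
  n <- length(x)
  withr_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
  })
  U <- matrix(x[idx], n, n_boot)
  V <- matrix(y[idx], n, n_boot)
  col_measure(measure, U, V, kl_pseudocount(x), kl_pseudocount(y))
}

#' Permutation p-value with bootstrap stability guard
#'
#' Two-sided p-value from the z-score of the observed measure against
#' the permutation null's mean and standard deviation, floored at
#' 1/(n_perm + 1) (an observed value can never look more extreme than
#' the resolution of the null sample). If a bootstrap sample is given,
#' the returned p-value carries a logical `stable` attribute: an edge
#' is stable when the central 95% bootstrap interval of the measure
#' excludes the null mean. Stability is a condition on the edge (a
#' measure only counts towards an edge's support when stable), not a
#' modification of the p-value itself -- overwriting p would destroy
#' the uniform-under-null marginals that Brown's combination assumes.
#'
#' @param observed Observed measure value.
#' @param null_sample Permutation null values (non-empty).
#' @param boot_sample Optional bootstrap values for the stability
#'   condition.
#' @return p-value in (0, 1], with a `stable` attribute when a
#'   bootstrap sample was supplied.
#' @export
measure_pvalue <- function(observed, null_sample, boot_sample = NULL) {
  if (!length(null_sample)) stop("empty null sample")
  floor_p <- 1 / (length(null_sample) + 1)
  mu <- mean(null_sample)
  sdv <- stats::sd(null_sample)
  if (is.na(sdv) || sdv == 0) {
    p <- if (isTRUE(all.equal(observed, mu))) 1 else floor_p
  } else {
    p <- 2 * stats::pnorm(-abs(observed - mu) / sdv)
    p <- max(p, floor_p)
    p <- min(p, 1)
  }
  if (!is.null(boot_sample) && length(boot_sample) >= 2) {
    ci <- stats::quantile(boot_sample, c(0.025, 0.975), names = FALSE)
    attr(p, "stable") <- !(mu >= ci[1] && mu <= ci[2])
  }
  p
}

#' Combine dependent p-values by Brown's method
#'
#' Brown's extension of Fisher's method: X = -2 sum(ln p) has mean
#' E = 2k and, under dependence, variance Var = 4k + 2 sum_{i<j}
#' cov(-2 ln p_i, -2 ln p_j). X/c is referred to a chi-square with
#' df = 2 E^2 / Var, where c = Var / (2E). With zero covariances this
#' reduces exactly to Fisher's method.
#'
#' @param p Numeric vector of 2-4 p-values in (0, 1].
#' @param cov_mat Optional k x k covariance matrix of the -2 ln p values
#'   (only off-diagonal entries are used); `NULL` means independence.
#' @return Combined p-value.
#' @export
brown_combine <- function(p, cov_mat = NULL) {
  k <- length(p)
  if (k < 2 || k > 4) stop("expected 2-4 p-values")
  if (any(p <= 0)) {
    warning("p-value(s) of 0 clamped to 1e-15")
    p[p <= 0] <- 1e-15
  }
  if (any(p > 1)) stop("p-values must be <= 1")
  X <- -2 * sum(log(p))
  E <- 2 * k
  cov_sum <- 0
  if (!is.null(cov_mat)) {
    cov_sum <- sum(cov_mat[upper.tri(cov_mat)])
  }
  Var <- 4 * k + 2 * cov_sum
  if (Var <= 0) Var <- 4 * k
  c_scale <- Var / (2 * E)
  df <- 2 * E^2 / Var
  stats::pchisq(X / c_scale, df = df, lower.tail = FALSE)
}

#' Ensemble association inference with ReBoot null and Brown combination
#'
#' For every feature pair (within one table, or across a taxa table and
#' a functional-category table), computes the four association measures,
#' a ReBoot permutation null and a bootstrap sample per measure (all
#' measures share the same permutation stream, so their dependence is
#' observable), per-measure p-values, the empirical covariance of
#' -2 ln p across the shared permutations, and the Brown-combined
#' p-value. `support` counts the measures individually significant at
#' `alpha` AND bootstrap-stable (see [measure_pvalue()]); `sign` is the
#' sign of the dominant (larger absolute) correlation measure.
#'
#' @param table_a,table_b `feature_table`s or matrices; `table_b = NULL`
#'   for within-table pairs, otherwise bipartite pairs (taxa x
#'   functions).
#' @param n_perm ReBoot permutations per pair (default 100).
#' @param n_boot Bootstrap resamples per pair (default 100).
#' @param seed Global seed for the permutation and bootstrap streams.
#' @param alpha Per-measure significance level feeding `support`.
#' @inheritParams pairwise_measures
#' @return data.frame of class `ensemble_edges`: the pair, the four
#'   scores, four p-value columns (`p_<measure>`), `combined_p`,
#'   `support`, `sign`.
#' @export
ensemble_edges <- function(table_a, table_b = NULL, n_perm = 100,
                           n_boot = 100, seed = 1, alpha = 0.05,
                           close_a = TRUE, close_b = FALSE) {
  if (n_perm < 20) stop("n_perm must be >= 20")
  if (n_boot < 20) stop("n_boot must be >= 20")
  al <- align_tables(table_a, table_b, close_a, close_b)
  A <- al$A; B <- al$B
  n <- ncol(A)
  withr_seed(derive_seed(seed, "ensemble"), {
    # one permutation stream per feature (on the raw abundance scale),
    # shared by all pairs and measures it participates in
    perm_a <- lapply(seq_len(nrow(A)), function(i) {
      vapply(seq_len(n_perm), function(b) al$A_raw[i, sample.int(n)],
             numeric(n))
    })
    perm_b <- if (al$cross) {
      lapply(seq_len(nrow(B)), function(i) {
        vapply(seq_len(n_perm), function(b) al$B_raw[i, sample.int(n)],
               numeric(n))
      })
    } else perm_a
    boot_idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
  })
  tot_a <- colSums(al$A_raw)
  tot_b <- colSums(al$B_raw)
  pairs <- al$pairs
  np <- nrow(pairs)
  scores <- matrix(NA_real_, np, 4, dimnames = list(NULL, MEASURES))
  pvals <- matrix(NA_real_, np, 4,
                  dimnames = list(NULL, paste0("p_", MEASURES)))
  combined <- numeric(np)
  support <- integer(np)
  sign_vec <- character(np)
  for (k in seq_len(np)) {
    ia <- pairs$ia[k]; ib <- pairs$ib[k]
    x <- A[ia, ]; y <- B[ib, ]
    pc_x <- kl_pseudocount(x); pc_y <- kl_pseudocount(y)
    rest_x <- if (!al$cross) {
      tot_a - al$A_raw[ia, ] - al$B_raw[ib, ]
    } else {
      tot_a - al$A_raw[ia, ]
    }
    rest_y <- if (al$cross) tot_b - al$B_raw[ib, ] else NULL
    renorm <- reboot_renormalize(perm_a[[ia]], perm_b[[ib]],
                                 shared = !al$cross,
                                 close_x = al$close_a,
                                 close_y = al$close_b,
                                 rest_x = rest_x, rest_y = rest_y)
    Ub <- matrix(x[boot_idx], n, n_boot)
    Vb <- matrix(y[boot_idx], n, n_boot)
    xm <- matrix(x, ncol = 1); ym <- matrix(y, ncol = 1)
    neg2logp <- matrix(NA_real_, n_perm, 4)
    stable <- logical(4)
    for (mi in seq_along(MEASURES)) {
      m <- MEASURES[mi]
      obs <- col_measure(m, xm, ym, pc_x, pc_y)
      null_m <- col_measure(m, renorm$U, renorm$V, pc_x, pc_y)
      boot_m <- col_measure(m, Ub, Vb, pc_x, pc_y)
      scores[k, mi] <- obs
      pk <- measure_pvalue(obs, null_m, boot_m)
      pvals[k, mi] <- as.numeric(pk)
      stable[mi] <- isTRUE(attr(pk, "stable"))
      # p-value of each null draw against its own null, for the
      # empirical dependence of -2 ln p between measures
      sdv <- stats::sd(null_m)
      pb <- if (is.na(sdv) || sdv == 0) rep(1, n_perm) else {
        pmin(pmax(2 * stats::pnorm(-abs(null_m - mean(null_m)) / sdv),
                  1 / (n_perm + 1)), 1)
      }
      neg2logp[, mi] <- -2 * log(pb)
    }
    combined[k] <- brown_combine(pvals[k, ], stats::cov(neg2logp))
    support[k] <- sum(pvals[k, ] < alpha & stable)
    dom <- if (abs(scores[k, "pearson"]) >= abs(scores[k, "spearman"])) {
      scores[k, "pearson"]
    } else scores[k, "spearman"]
    sign_vec[k] <- if (dom < 0) "-" else "+"
  }
  out <- cbind(pairs[, c("feature_a", "feature_b")],
               as.data.frame(scores), as.data.frame(pvals))
  out$combined_p <- combined
  out$support <- support
  out$sign <- sign_vec
  attr(out, "n_perm") <- n_perm
  attr(out, "n_boot") <- n_boot
  attr(out, "alpha") <- alpha
  class(out) <- c("ensemble_edges", class(out))
  out
}

#' Filter ensemble edges to the statistically robust set
#'
#' An edge is retained iff it is supported by at least `min_support`
#' measures, the larger absolute correlation (Pearson or Spearman)
#' exceeds `min_coeff` (the coefficient cutoff applies to correlation
#' measures only -- a "coefficient" is not meaningful for the unbounded
#' KL divergence), and the combined Brown p-value is below `alpha`.
#' With `fdr = TRUE` the combined p is Benjamini-Hochberg adjusted
#' across pairs first; the default is the raw combined p because the
#' permutation floor on per-measure p-values (1/(n_perm + 1)) bounds how
#' small a combined p can get, and stacking a BH adjustment on top of
#' that floor leaves the filter unable to retain any edge at practical
#' permutation counts.
#'
#' @param edges An `ensemble_edges` data.frame.
#' @param min_support Minimum number of individually significant
#'   measures (default 2).
#' @param min_coeff Minimum absolute correlation coefficient
#'   (default 0.8).
#' @param alpha Significance level on the (adjusted) combined p.
#' @param fdr Apply Benjamini-Hochberg adjustment across pairs.
#' @return The edges with `adjusted_p` and logical `retained` columns.
#' @export
filter_edges <- function(edges, min_support = 2, min_coeff = 0.8,
                         alpha = 0.05, fdr = FALSE) {
  edges$adjusted_p <- if (fdr) {
    stats::p.adjust(edges$combined_p, method = "BH")
  } else {
    edges$combined_p
  }
  max_corr <- pmax(abs(edges$pearson), abs(edges$spearman))
  edges$retained <- edges$support >= min_support &
    max_corr > min_coeff &
    edges$adjusted_p < alpha
  edges
}

#' Bipartite taxa-function network from retained edges
#'
#' Builds the undirected bipartite graph of retained associations
#' between taxa and functional gene categories and summarises it with
#' the conventions of mutualistic-network topology tables: node count,
#' edge count, average degree = edges/nodes, and modularity of the
#' greedy module partition.
#'
#' @param edges A filtered `ensemble_edges` data.frame (only rows with
#'   `retained == TRUE` enter the graph; if no `retained` column is
#'   present, all rows are used).
#' @param kind_a,kind_b Node kind labels for the two sides.
#' @return List with `network` (igraph; `kind` vertex attribute,
#'   `weight`/`sign`/`support`/`combined_p` edge attributes) and
#'   `summary` (one-row data.frame: n_nodes, n_edges, average_degree,
#'   modularity).
#' @export
build_bipartite <- function(edges, kind_a = "taxon", kind_b = "function") {
  keep <- if ("retained" %in% colnames(edges)) edges$retained else
    rep(TRUE, nrow(edges))
  e <- edges[keep, , drop = FALSE]
  if (nrow(e) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    summ <- data.frame(n_nodes = 0L, n_edges = 0L, average_degree = 0,
                       modularity = NA_real_)
    return(list(network = g, summary = summ))
  }
  dom <- ifelse(abs(e$pearson) >= abs(e$spearman), e$pearson, e$spearman)
  df <- data.frame(from = e$feature_a, to = e$feature_b,
                   weight = dom, sign = e$sign, support = e$support,
                   combined_p = e$combined_p, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  igraph::V(g)$kind <- ifelse(igraph::V(g)$name %in% e$feature_a,
                              kind_a, kind_b)
  membership <- detect_modules(g)
  igraph::V(g)$module <- as.integer(membership[igraph::V(g)$name])
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  summ <- data.frame(n_nodes = n, n_edges = m,
                     average_degree = avg_connectivity(n, m, "mutualistic"),
                     modularity = network_modularity(g, membership))
  list(network = g, summary = summ)
}
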