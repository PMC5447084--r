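#' Pairwise similarity matrix for network construction
#'
#' Computes the Pearson correlation across samples of transformed
#' abundances. The default transform is ln(relative abundance +
#' pseudocount), which tames the skew of compositional count data before
#' correlation. Zero-variance features cannot be correlated and are
#' excluded with a warning.
#'
#' @param table A `feature_table` (features x samples), prevalence
#'   filtered beforehand.
#' @param transform `"log_relative"` (default) or `"none"` (correlate the
#'   raw values).
#' @param pseudocount Added to relative abundances before the log;
#'   default: half the smallest positive relative abundance.
#' @return A symmetric matrix of class `similarity_matrix` with unit
#'   diagonal, feature ids as dimnames, and a `method` attribute.
#' @export
correlation_matrix <- function(table, transform = c("log_relative", "none"),
                               pseudocount = NULL) {
  transform <- match.arg(transform)
  v <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  if (ncol(v) < 4) stop("need at least 4 samples to correlate")
  if (transform == "log_relative") {
    rel <- relative_abundance(v)
    if (is.null(pseudocount)) {
      pos <- rel[rel > 0]
      pseudocount <- if (length(pos)) min(pos) / 2 else 1e-6
    }
    v <- log(rel + pseudocount)
  }
  sds <- apply(v, 1, stats::sd)
  flat <- sds == 0 | !is.finite(sds)
  if (any(flat)) {
    warning("excluding zero-variance feature(s): ",
            paste(rownames(v)[flat], collapse = ", "))
    v <- v[!flat, , drop = FALSE]
  }
  r <- stats::cor(t(v))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  structure(r, class = c("similarity_matrix", "matrix"),
            method = paste0("pearson/", transform))
}

#' Unfold an eigenvalue spectrum and return nearest-neighbour spacings
#'
#' Rescales a spectrum so that its mean level spacing is one, the
#' prerequisite for comparing nearest-neighbour spacing distributions
#' (NNSD) against the Poisson and Wigner (GOE) reference laws. The
#' empirical cumulative spectral function (rank vs eigenvalue) is fitted
#' with a cubic smoothing spline N(lambda); spacings are the increments
#' of N at consecutive (distinct) eigenvalues, renormalised to mean one.
#' Exact duplicate eigenvalues are collapsed first, as is standard
#' before spacing analysis of degenerate spectra.
#'
#' @param eigenvalues Numeric vector of eigenvalues (any order).
#' @param df Effective degrees of freedom of the smoothing spline fit
#'   of the cumulative spectral function.
#' @return Numeric vector of unfolded spacings with mean 1.
#' @export
unfold_and_nnsd <- function(eigenvalues, df = 10) {
  ev <- sort(as.numeric(eigenvalues))
  if (length(ev) < 5) stop("need at least 5 eigenvalues to unfold")
  span <- ev[length(ev)] - ev[1]
  if (span <= 0) stop("degenerate spectrum: all eigenvalues equal")
  # collapse numerically identical eigenvalues
  keep <- c(TRUE, diff(ev) > 1e-8 * max(span, 1))
  ev <- ev[keep]
  n <- length(ev)
  if (n < 5) stop("fewer than 5 distinct eigenvalues after deduplication")
  df <- max(3, min(df, n - 1))
  fit <- stats::smooth.spline(ev, seq_len(n), df = df)
  nbar <- stats::predict(fit, ev)$y
  d <- diff(nbar)
  d[d < 0] <- 0
  m <- mean(d)
  if (m <= 0) stop("degenerate unfolded spectrum")
  d / m
}

#' Goodness of fit of a spacing sample to Poisson and Wigner laws
#'
#' Chi-square goodness-of-fit of the unfolded spacings against the
#' Poisson law exp(-s) (uncorrelated eigenvalues) and the Wigner surmise
#' (pi/2) s exp(-pi s^2 / 4) (GOE level repulsion), using
#' equal-probability bins with expected count >= 5.
#'
#' @param spacings Unfolded spacings (mean 1), e.g. from
#'   [unfold_and_nnsd()].
#' @return List with `p_poisson`, `p_wigner`, `chisq_poisson`,
#'   `chisq_wigner`, `n_bins`.
#' @export
nnsd_gof <- function(spacings) {
  s <- spacings[is.finite(spacings)]
  n <- length(s)
  n_bins <- max(3L, min(20L, n %/% 5L))
  probs <- seq(0, 1, length.out = n_bins + 1)
  gof <- function(qfun) {
    edges <- qfun(probs)
    edges[1] <- -Inf; edges[n_bins + 1] <- Inf
    obs <- tabulate(findInterval(s, edges, rightmost.closed = TRUE),
                    nbins = n_bins)
    expd <- n / n_bins
    x2 <- sum((obs - expd)^2 / expd)
    list(x2 = x2, p = stats::pchisq(x2, df = n_bins - 1, lower.tail = FALSE))
  }
  pois <- gof(function(p) -log(1 - p))
  wig <- gof(function(p) sqrt(-4 * log(1 - p) / pi))
  list(p_poisson = pois$p, p_wigner = wig$p,
       chisq_poisson = pois$x2, chisq_wigner = wig$x2, n_bins = n_bins)
}

#' Random-matrix-theory threshold scan
#'
#' Scans candidate similarity thresholds and, at each, zeroes
#' correlations below the threshold (in absolute value), restricts to the
#' non-isolated submatrix, and tests the NNSD of the unfolded eigenvalue
#' spectrum against the Poisson and Wigner laws. The chosen threshold is
#' the smallest candidate whose NNSD is consistent with Poisson
#' (p > alpha) and inconsistent with the Wigner surmise (p <= alpha) --
#' the GOE-to-Poisson transition point at which correlated noise has
#' been pruned away and only modular signal remains.
#'
#' @param sim A `similarity_matrix`.
#' @param s_min,s_max,step Candidate threshold grid (defaults 0.30 to
#'   0.99 by 0.01, matching the 2-decimal convention of published
#'   threshold tables).
#' @param alpha Significance level for both spacing tests.
#' @param min_eigen Minimum number of eigenvalues (network size) needed
#'   to attempt a spacing test at a candidate; smaller candidates are
#'   recorded but skipped.
#' @return List of class `threshold_scan`: `scan` (data.frame with
#'   threshold, network_size, total_links, p_poisson, p_wigner),
#'   `chosen_threshold` (NA if no candidate satisfies the criterion) and
#'   `diagnostic`.
#' @export
rmt_threshold <- function(sim, s_min = 0.3, s_max = 0.99, step = 0.01,
                          alpha = 0.05, min_eigen = 20) {
  stopifnot(inherits(sim, "similarity_matrix") || is.matrix(sim))
  grid <- seq(s_min, s_max, by = step)
  rows <- lapply(grid, function(s) {
    a <- unclass(sim)
    off <- abs(a) < s
    diag(off) <- FALSE
    a[off] <- 0
    deg <- rowSums(a != 0) - 1L
    keep <- deg > 0
    size <- sum(keep)
    links <- sum(a[keep, keep, drop = FALSE][upper.tri(a[keep, keep,
                                                         drop = FALSE])] != 0)
    p_pois <- NA_real_; p_wig <- NA_real_
    if (size >= min_eigen) {
      evs <- eigen(a[keep, keep, drop = FALSE], symmetric = TRUE,
                   only.values = TRUE)$values
      sp <- tryCatch(unfold_and_nnsd(evs), error = function(e) NULL)
      if (!is.null(sp) && length(sp) >= 15) {
        g <- nnsd_gof(sp)
        p_pois <- g$p_poisson; p_wig <- g$p_wigner
      }
    }
    data.frame(threshold = s, network_size = size, total_links = links,
               p_poisson = p_pois, p_wigner = p_wig)
  })
  scan <- do.call(rbind, rows)
  ok <- !is.na(scan$p_poisson) & scan$p_poisson > alpha &
    !is.na(scan$p_wigner) & scan$p_wigner <= alpha
  chosen <- if (any(ok)) scan$threshold[which(ok)[1]] else NA_real_
  diagnostic <- if (is.na(chosen)) {
    "no candidate threshold was Poisson-consistent and Wigner-inconsistent"
  } else {
    sprintf("GOE-to-Poisson transition at threshold %.2f", chosen)
  }
  structure(list(scan = scan, chosen_threshold = chosen,
                 diagnostic = diagnostic, alpha = alpha),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat("RMT threshold scan over", nrow(x$scan), "candidates\n")
  cat(" ", x$diagnostic, "\n")
  invisible(x)
}

#' Build a thresholded co-occurrence network
#'
#' Places an edge between features i and j iff |r_ij| >= threshold,
#' weighted by the signed correlation; isolated nodes are removed.
#'
#' @param sim A `similarity_matrix`.
#' @param threshold Similarity cutoff in (0, 1].
#' @return An undirected `igraph` graph with `weight` and `sign` edge
#'   attributes (empty, with a warning, if no pair passes).
#' @export
build_network <- function(sim, threshold) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  a <- unclass(sim)
  a[abs(a) < threshold] <- 0
  diag(a) <- 0
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  if (igraph::ecount(g) == 0) {
    warning("no edges at threshold ", threshold)
    return(g)
  }
  sign_edges(g)
}

#' Detect modules by greedy modularity maximisation
#'
#' Non-overlapping modules from fast-greedy modularity optimisation on
#' absolute edge weights (signed correlations contribute their
#' magnitude). Disconnected components can never be merged profitably,
#' so singleton components end up as their own modules. The algorithm is
#' deterministic for a given graph; `seed` is accepted for interface
#' stability and future stochastic methods.
#'
#' @param net An undirected `igraph` graph.
#' @param seed Unused by the deterministic greedy algorithm.
#' @return Named integer vector: module id per vertex.
#' @export
detect_modules <- function(net, seed = 1) {
  if (igraph::vcount(net) == 0) return(stats::setNames(integer(0), character(0)))
  w <- if ("weight" %in% igraph::edge_attr_names(net)) {
    abs(igraph::E(net)$weight)
  } else NULL
  cl <- igraph::cluster_fast_greedy(igraph::simplify(net), weights = w)
  mem <- stats::setNames(as.integer(igraph::membership(cl)),
                         igraph::V(net)$name)
  # tie rule: if splitting connected components gains nothing (greedy
  # can cut at numerically-zero-Q ties, e.g. complete graphs), fall
  # back to one module per component; compared on the same weights the
  # greedy merge used
  comp <- stats::setNames(igraph::components(net)$membership,
                          igraph::V(net)$name)
  if (igraph::modularity(net, comp[igraph::V(net)$name], weights = w) +
      1e-12 >=
      igraph::modularity(net, mem[igraph::V(net)$name], weights = w)) {
    mem <- as.integer(comp)
    names(mem) <- igraph::V(net)$name
  }
  mem
}

#' Newman-Girvan modularity of a partition
#'
#' Q = sum over modules of (e_mm - a_m^2), where e_mm is the fraction of
#' edges inside module m and a_m the fraction of edge ends attached to
#' it. Computed on the unweighted graph by default; absolute edge
#' weights optionally.
#'
#' @param net An undirected `igraph` graph.
#' @param membership Named module assignment covering every vertex.
#' @param use_weights Weight edges by |weight| instead of counting them.
#' @return Modularity Q in [-0.5, 1].
#' @export
network_modularity <- function(net, membership, use_weights = FALSE) {
  nodes <- igraph::V(net)$name
  missing <- setdiff(nodes, names(membership))
  if (length(missing)) {
    stop("membership missing node(s): ", paste(missing, collapse = ", "))
  }
  w <- if (use_weights) abs(igraph::E(net)$weight) else NULL
  igraph::modularity(net, membership[nodes], weights = w)
}

#' Zi-Pi node role classification
#'
#' Computes, for every node, the within-module degree z-score
#' Zi = (k_i,own - mean(k,own)) / sd(k,own) (mean and sd over the node's
#' module) and the among-module participation coefficient
#' Pi = 1 - sum_m (k_im / k_i)^2. Roles follow the standard cutoffs:
#' module hubs (Zi > 2.5, Pi < 0.62), network hubs (Zi > 2.5,
#' Pi > 0.62), connectors (Zi < 2.5, Pi > 0.62) and peripherals
#' (Zi < 2.5, Pi < 0.62); boundary values fall to the non-hub /
#' non-connector side. Modules of size one, or with zero spread of
#' within-module degree, give Zi = 0.
#'
#' @param net An undirected `igraph` graph.
#' @param membership Named module assignment covering every vertex.
#' @return data.frame: `node`, `module`, `degree`, `zi`, `pi`, `role`.
#' @export
node_roles <- function(net, membership) {
  nodes <- igraph::V(net)$name
  missing <- setdiff(nodes, names(membership))
  if (length(missing)) {
    stop("membership missing node(s): ", paste(missing, collapse = ", "))
  }
  mem <- membership[nodes]
  adj <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  adj[adj != 0] <- 1
  deg <- rowSums(adj)
  mods <- sort(unique(mem))
  # k_im: links from node i into module m
  k_im <- vapply(mods, function(m) {
    rowSums(adj[, mem == m, drop = FALSE])
  }, numeric(length(nodes)))
  if (is.null(dim(k_im))) k_im <- matrix(k_im, nrow = length(nodes))
  k_own <- k_im[cbind(seq_along(nodes), match(mem, mods))]
  zi <- numeric(length(nodes))
  for (m in mods) {
    in_m <- mem == m
    mu <- mean(k_own[in_m])
    sdv <- stats::sd(k_own[in_m])
    zi[in_m] <- if (sum(in_m) < 2 || is.na(sdv) || sdv == 0) 0 else {
      (k_own[in_m] - mu) / sdv
    }
  }
  pi_coef <- ifelse(deg > 0, 1 - rowSums((k_im / pmax(deg, 1))^2), 0)
  role <- classify_role(zi, pi_coef)
  data.frame(node = nodes, module = as.integer(mem),
             degree = as.integer(deg), zi = zi, pi = pi_coef, role = role,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify node roles from (Zi, Pi) coordinates
#'
#' The standard cutoffs: module hubs (Zi > 2.5, Pi < 0.62), network
#' hubs (Zi > 2.5, Pi > 0.62), connectors (Zi < 2.5, Pi > 0.62),
#' peripherals (Zi < 2.5, Pi < 0.62). Values exactly on a boundary fall
#' to the non-hub / non-connector side.
#'
#' @param zi Within-module degree z-score(s).
#' @param pi Participation coefficient(s).
#' @return Character vector of roles.
#' @export
classify_role <- function(zi, pi) {
  ifelse(zi > 2.5,
         ifelse(pi > 0.62, "network_hub", "module_hub"),
         ifelse(pi > 0.62, "connector", "peripheral"))
}

#' Topological summary of a co-occurrence network
#'
#' One row in the format of published pMEN topology tables: network
#' size, total links, number of module hubs, percentages of positive and
#' negative links, avgK (= 2L/N) and modularity.
#'
#' @param net An undirected `igraph` graph with signed `weight` edges.
#' @param membership Module assignment (from [detect_modules()]).
#' @param roles Node roles (from [node_roles()]).
#' @param threshold The similarity threshold used (for the record).
#' @return One-row data.frame.
#' @export
summarize_pmen <- function(net, membership, roles, threshold = NA_real_) {
  n <- igraph::vcount(net)
  l <- igraph::ecount(net)
  w <- if (l > 0) igraph::E(net)$weight else numeric(0)
  data.frame(
    threshold = threshold,
    network_size = n,
    total_links = l,
    n_module_hubs = sum(roles$role == "module_hub"),
    pct_positive = if (l > 0) 100 * mean(w >= 0) else NA_real_,
    pct_negative = if (l > 0) 100 * mean(w < 0) else NA_real_,
    avgK = avg_connectivity(n, l, "pmen"),
    modularity = network_modularity(net, membership),
    row.names = NULL)
}

#' End-to-end phylogenetic molecular ecological network
#'
#' Convenience wrapper: similarity matrix, RMT threshold scan (unless a
#' threshold is supplied), thresholded network, modules, node roles, and
#' the topology summary row.
#'
#' @param table A `feature_table`, already prevalence filtered.
#' @param threshold Optional fixed similarity threshold; if `NULL` the
#'   RMT scan chooses one.
#' @param transform Passed to [correlation_matrix()].
#' @param seed Passed to [detect_modules()].
#' @param ... Passed to [rmt_threshold()].
#' @return List of class `pmen`: `similarity`, `scan` (or NULL),
#'   `threshold`, `network`, `membership`, `roles`, `summary`.
#' @export
pmen <- function(table, threshold = NULL, transform = "log_relative",
                 seed = 1, ...) {
  sim <- correlation_matrix(table, transform = transform)
  scan <- NULL
  if (is.null(threshold)) {
    scan <- rmt_threshold(sim, ...)
    threshold <- scan$chosen_threshold
    if (is.na(threshold)) {
      stop("RMT scan found no threshold; supply one explicitly (",
           scan$diagnostic, ")")
    }
  }
  net <- build_network(sim, threshold)
  membership <- detect_modules(net, seed = seed)
  roles <- node_roles(net, membership)
  summary <- summarize_pmen(net, membership, roles, threshold)
  igraph::V(net)$module <- as.integer(membership[igraph::V(net)$name])
  structure(list(similarity = sim, scan = scan, threshold = threshold,
                 network = net, membership = membership, roles = roles,
                 summary = summary),
            class = "pmen")
}

#' @export
print.pmen <- function(x, ...) {
  cat("pMEN at similarity threshold", format(x$threshold), "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
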