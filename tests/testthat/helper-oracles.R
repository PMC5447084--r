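# Independent oracles and fixture builders shared across tests. These
# deliberately re-derive quantities from first principles (loops, brute
# force, closed forms) rather than calling the implementation under
# test.

# Plain Rand index between two labelings.
rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
    }
  }
  as.numeric(agree / choose(n, 2))
}

# Brute-force Zi/Pi from an adjacency matrix and membership vector,
# written as direct loops over the definitions.
oracle_zi_pi <- function(adj, mem) {
  n <- nrow(adj)
  mods <- sort(unique(mem))
  k_own <- numeric(n)
  for (i in seq_len(n)) {
    k_own[i] <- sum(adj[i, mem == mem[i]])
  }
  zi <- numeric(n)
  for (m in mods) {
    idx <- which(mem == m)
    mu <- mean(k_own[idx])
    sdv <- stats::sd(k_own[idx])
    for (i in idx) {
      zi[i] <- if (length(idx) < 2 || is.na(sdv) || sdv == 0) 0 else {
        (k_own[i] - mu) / sdv
      }
    }
  }
  pi_c <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(adj[i, ])
    if (k == 0) next
    acc <- 0
    for (m in mods) acc <- acc + (sum(adj[i, mem == m]) / k)^2
    pi_c[i] <- 1 - acc
  }
  list(zi = zi, pi = pi_c)
}

# Newman-Girvan modularity from the definition (unweighted), given an
# igraph graph and a membership vector indexed by vertex name.
oracle_modularity <- function(g, mem) {
  el <- igraph::as_edgelist(g, names = TRUE)
  l <- nrow(el)
  if (l == 0) return(0)
  mods <- unique(mem)
  q <- 0
  for (m in mods) {
    inside <- sum(mem[el[, 1]] == m & mem[el[, 2]] == m) / l
    ends <- (sum(mem[el[, 1]] == m) + sum(mem[el[, 2]] == m)) / (2 * l)
    q <- q + inside - ends^2
  }
  q
}

# All set partitions of 1..n as lists of membership vectors (restricted
# growth strings). Bell(8) = 4140, cheap to enumerate.
all_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxblock) {
    k <- length(prefix)
    if (k == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (b in seq_len(maxblock + 1)) {
      recurse(c(prefix, b), max(maxblock, b))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Best modularity over every partition of the graph's vertices.
oracle_best_modularity <- function(g) {
  n <- igraph::vcount(g)
  names <- igraph::V(g)$name
  best <- -Inf
  for (p in all_partitions(n)) {
    mem <- stats::setNames(p, names)
    best <- max(best, oracle_modularity(g, mem))
  }
  best
}

# A small undirected graph from an edge list matrix of vertex names.
graph_from_edges <- function(edges, weights = NULL, isolates = NULL) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]), directed = FALSE,
    vertices = if (is.null(isolates)) NULL else
      data.frame(name = union(unique(c(edges)), isolates)))
  if (!is.null(weights)) igraph::E(g)$weight <- weights
  g
}

# Hand-built 12-node graph with known role structure:
#   module A = a1..a9, a1 the star centre (module hub);
#   c1 bridges modules A, B and D evenly (connector);
#   b1 and d1 small peripheral satellites.
role_fixture <- function() {
  edges <- rbind(
    cbind("a1", paste0("a", 2:9)),     # star inside module A
    c("a2", "a3"),                     # a little within-module flesh
    c("c1", "a4"), c("c1", "b1"), c("c1", "d1"))
  g <- graph_from_edges(edges)
  mem <- stats::setNames(
    c(rep(1L, 9), 2L, 3L, 4L),
    c(paste0("a", 1:9), "c1", "b1", "d1"))
  list(graph = g, membership = mem)
}

# Two disconnected triangles.
two_triangles <- function() {
  graph_from_edges(rbind(
    c("x1", "x2"), c("x2", "x3"), c("x1", "x3"),
    c("y1", "y2"), c("y2", "y3"), c("y1", "y3")))
}

# Feature table helper from a plain matrix with default ids.
ft <- function(m, ...) {
  if (is.null(rownames(m))) rownames(m) <- paste0("f", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  feature_table(m, ...)
}

# Config for the planted 2-block recovery experiments: 500 samples
# (2 x 2 x 5 x 25 factorial), 30 taxa in two blocks of 15, deep
# multinomial sampling.
two_block_config <- function(seed, rho = 0.9) {
  synthetic_config(n_taxa = 30, n_modules = 2, within_module_rho = rho,
                   n_soil_types = 2, n_layers = 2, n_stages = 5,
                   n_replicates = 25, sequencing_depth = 20000, seed = seed)
}

# Scaled-down ensemble experiment config: the 48-sample factorial
# design with 20 taxa and 10 gene categories.
ensemble_config <- function(seed, coupling = 0, rho = 0) {
  synthetic_config(n_taxa = 20, n_gene_categories = 10, n_modules = 4,
                   within_module_rho = rho, coupling_strength = coupling,
                   seed = seed)
}
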