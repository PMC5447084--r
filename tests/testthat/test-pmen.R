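test_that("correlation matrix matches the covariance-formula oracle", {
  set.seed(42)
  m <- matrix(rpois(30, 20) + 1, 3, 10,
              dimnames = list(paste0("f", 1:3), paste0("s", 1:10)))
  tab <- feature_table(m)
  sim <- correlation_matrix(tab)
  # direct textbook computation on the same transform
  rel <- sweep(m, 2, colSums(m), "/")
  pc <- min(rel[rel > 0]) / 2
  lv <- log(rel + pc)
  oracle <- function(x, y) {
    xm <- x - mean(x); ym <- y - mean(y)
    sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
  }
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(sim[i, j], oracle(lv[i, ], lv[j, ]), tolerance = 1e-12)
  }
  expect_equal(diag(unclass(sim)), rep(1, 3), ignore_attr = TRUE)
  expect_identical(unclass(sim), t(unclass(sim)))
})

test_that("self-similarity, antisymmetry and degenerate features", {
  x <- rnorm(20)
  m <- rbind(a = x, b = x, c = -x + 2 * mean(x), d = rep(1, 20))
  colnames(m) <- paste0("s", 1:20)
  expect_warning(sim <- correlation_matrix(m, transform = "none"), "d")
  expect_equal(sim["a", "b"], 1, tolerance = 1e-12)
  expect_equal(sim["a", "c"], -1, tolerance = 1e-12)
  expect_false("d" %in% rownames(sim))
})

test_that("unfolding gives unit mean spacing; uniform spectra are flat", {
  ev <- seq(0.1, 5, length.out = 60)
  sp <- unfold_and_nnsd(ev)
  expect_equal(mean(sp), 1, tolerance = 1e-6)
  expect_lt(stats::var(sp), 1e-3)
  expect_error(unfold_and_nnsd(rep(2, 30)), "degenerate")
})

test_that("NNSD distinguishes GOE from uncorrelated spectra", {
  set.seed(7)
  # GOE: symmetric Gaussian matrix; spacings follow the Wigner surmise
  n <- 300
  g <- matrix(rnorm(n * n), n, n)
  goe <- (g + t(g)) / sqrt(2 * n)
  ev_goe <- eigen(goe, symmetric = TRUE, only.values = TRUE)$values
  # central bulk only, away from the semicircle edges
  bulk <- ev_goe[ev_goe > -1 & ev_goe < 1]
  gof_goe <- nnsd_gof(unfold_and_nnsd(bulk))
  expect_lt(gof_goe$chisq_wigner, gof_goe$chisq_poisson)

  # iid eigenvalues (diagonal of uniforms): Poisson spacings
  set.seed(7)
  ev_pois <- sort(runif(300))
  gof_pois <- nnsd_gof(unfold_and_nnsd(ev_pois))
  expect_lt(gof_pois$chisq_poisson, gof_pois$chisq_wigner)
  expect_gt(gof_pois$p_poisson, 0.05)
})

test_that("RMT scan handles degenerate similarity matrices", {
  ident <- structure(diag(25), dimnames = list(paste0("f", 1:25),
                                               paste0("f", 1:25)),
                     class = c("similarity_matrix", "matrix"))
  scan <- rmt_threshold(ident)
  expect_true(is.na(scan$chosen_threshold))
  expect_true(all(scan$scan$network_size == 0))

  dense <- matrix(0.96, 25, 25,
                  dimnames = list(paste0("f", 1:25), paste0("f", 1:25)))
  diag(dense) <- 1
  scan2 <- rmt_threshold(structure(
    dense, class = c("similarity_matrix", "matrix")))
  expect_true(is.na(scan2$chosen_threshold) ||
              scan2$chosen_threshold >= 0.95)
})

test_that("RMT scan finds the GOE-to-Poisson transition on planted blocks", {
  # count route: multinomial sampling and closure add a band of
  # moderate noise correlations below the signal, so the transition
  # lands strictly between noise and the planted 0.9
  sim <- simulate_dataset(two_block_config(seed = 31))
  cm <- correlation_matrix(sim$otu)
  scan <- rmt_threshold(cm)
  th <- scan$chosen_threshold
  expect_false(is.na(th))
  expect_gt(th, 0.5)
  expect_lt(th, 0.9)
  mem <- detect_modules(build_network(cm, th))
  truth <- sim$truth$module_of[names(mem)]
  expect_gt(rand_index(as.integer(truth), as.integer(mem)), 0.9)

  # latent route: with between-block correlation truly zero, the
  # thresholded graph at the chosen threshold is exactly the two
  # planted blocks as connected components
  cfg <- synthetic_config(n_taxa = 50, n_modules = 2,
                          within_module_rho = 0.9, n_soil_types = 2,
                          n_layers = 2, n_stages = 5, n_replicates = 25,
                          seed = 31)
  lat <- generate_latent(cfg)
  sm <- correlation_matrix(lat$latent, transform = "none")
  scan2 <- rmt_threshold(sm)
  expect_false(is.na(scan2$chosen_threshold))
  net <- build_network(sm, scan2$chosen_threshold)
  comp <- igraph::components(net)
  expect_equal(comp$no, 2)
  truth2 <- lat$truth$module_of[igraph::V(net)$name]
  expect_equal(rand_index(as.integer(truth2), comp$membership), 1)
})

test_that("thresholded network construction is exact on toy matrices", {
  r <- matrix(0.9, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(r) <- 1
  net <- build_network(r, 0.8)
  expect_equal(igraph::vcount(net), 3)
  expect_equal(igraph::ecount(net), 3)
  expect_warning(empty <- build_network(r, 0.95))
  expect_equal(igraph::ecount(empty), 0)

  r2 <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  net2 <- build_network(r2, 0.8)
  mem2 <- detect_modules(net2)
  roles2 <- node_roles(net2, mem2)
  summ <- summarize_pmen(net2, mem2, roles2, 0.8)
  expect_equal(summ$pct_positive, 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(summ$pct_negative, 100 / 3, tolerance = 1e-9)
  expect_equal(summ$avgK, 2)
  # raising the threshold never adds edges
  for (th in c(0.85, 0.91, 0.95)) {
    suppressWarnings(sub <- build_network(r2, th))
    expect_lte(igraph::ecount(sub), igraph::ecount(net2))
  }
})

test_that("module detection recovers obvious and planted structure", {
  tg <- two_triangles()
  mem <- detect_modules(tg)
  expect_equal(length(unique(mem)), 2)
  expect_true(all(tapply(names(mem), mem, function(v) {
    length(unique(substr(v, 1, 1)))
  }) == 1))

  full <- igraph::make_full_graph(5)
  igraph::V(full)$name <- paste0("n", 1:5)
  expect_equal(length(unique(detect_modules(full))), 1)

  # planted 2-block recovery through the count pipeline
  sim <- simulate_dataset(two_block_config(seed = 33))
  cm <- correlation_matrix(sim$otu)
  scan <- rmt_threshold(cm)
  expect_false(is.na(scan$chosen_threshold))
  net <- build_network(cm, scan$chosen_threshold)
  mem2 <- detect_modules(net)
  truth <- sim$truth$module_of[names(mem2)]
  expect_gt(rand_index(as.integer(truth), as.integer(mem2)), 0.9)
})

test_that("modularity closed forms and degree-sum identity hold", {
  tg <- two_triangles()
  mem <- detect_modules(tg)
  expect_equal(network_modularity(tg, mem), 0.5, tolerance = 1e-12)
  one <- stats::setNames(rep(1, 6), igraph::V(tg)$name)
  expect_equal(network_modularity(tg, one), 0, tolerance = 1e-12)
  expect_error(network_modularity(tg, one[-1]), "missing")
  expect_equal(sum(igraph::degree(tg)), 2 * igraph::ecount(tg))
})

test_that("greedy modularity is near the exhaustive optimum on 8 nodes", {
  graphs <- list(
    # two squares joined by a bridge
    graph_from_edges(rbind(c("a", "b"), c("b", "c"), c("c", "d"),
                           c("d", "a"), c("e", "f"), c("f", "g"),
                           c("g", "h"), c("h", "e"), c("a", "e"))),
    # Erdos-Renyi draw, fixed seed
    local({
      set.seed(5)
      g <- igraph::sample_gnp(8, 0.4)
      igraph::V(g)$name <- paste0("v", 1:8)
      g
    }),
    # path graph: weak structure
    graph_from_edges(cbind(paste0("p", 1:7), paste0("p", 2:8))))
  for (g in graphs) {
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
    mem <- detect_modules(g)
    q_greedy <- network_modularity(g, mem)
    q_best <- oracle_best_modularity(g)
    expect_lte(q_best - q_greedy, 0.05)
    # own Q agrees with the from-the-definition oracle
    expect_equal(q_greedy, oracle_modularity(g, mem), tolerance = 1e-12)
  }
})

test_that("Zi/Pi match the brute-force oracle and the role cutoffs", {
  fx <- role_fixture()
  roles <- node_roles(fx$graph, fx$membership)
  adj <- igraph::as_adjacency_matrix(fx$graph, sparse = FALSE)
  oracle <- oracle_zi_pi(adj, fx$membership[rownames(adj)])
  ord <- match(roles$node, rownames(adj))
  expect_equal(roles$zi, oracle$zi[ord], tolerance = 1e-12)
  expect_equal(roles$pi, oracle$pi[ord], tolerance = 1e-12)

  expect_equal(roles$role[roles$node == "a1"], "module_hub")
  expect_equal(roles$role[roles$node == "c1"], "connector")
  expect_true(all(roles$role[roles$node %in% c("b1", "d1")] == "peripheral"))

  # participation identities
  expect_equal(roles$pi[roles$node == "a1"], 0)    # all links inside
  split2 <- graph_from_edges(rbind(c("m", "x"), c("m", "y")))
  mem2 <- c(m = 1L, x = 1L, y = 2L)
  r2 <- node_roles(split2, mem2)
  expect_equal(r2$pi[r2$node == "m"], 0.5)

  # quoted cutoff mapping
  expect_equal(classify_role(3.0, 0.5), "module_hub")
  expect_equal(classify_role(1.0, 0.7), "connector")
  expect_equal(classify_role(3.0, 0.7), "network_hub")
  expect_equal(classify_role(1.0, 0.5), "peripheral")
  # every node gets exactly one role
  expect_true(all(roles$role %in% c("module_hub", "network_hub",
                                    "connector", "peripheral")))
})

test_that("pmen wrapper produces a coherent summary on planted data", {
  sim <- simulate_dataset(two_block_config(seed = 35))
  pm <- pmen(sim$otu)
  expect_s3_class(pm, "pmen")
  expect_equal(pm$summary$avgK,
               2 * pm$summary$total_links / pm$summary$network_size)
  expect_equal(pm$summary$pct_positive + pm$summary$pct_negative, 100)
  expect_gte(pm$summary$modularity, -0.5)
  expect_lte(pm$summary$modularity, 1)
  expect_equal(sort(unique(pm$roles$node)),
               sort(igraph::V(pm$network)$name))
})
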