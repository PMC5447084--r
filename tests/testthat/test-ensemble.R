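test_that("measure identities hold on constructed pairs", {
  m <- rbind(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5),
             c = c(2, 4, 6, 8, 10), d = c(1, 0, 0, 2, 0),
             e = c(0, 1, 1, 0, 3))
  colnames(m) <- paste0("s", 1:5)
  pm <- pairwise_measures(m, close_a = FALSE)
  row <- function(x, y) pm[pm$feature_a == x & pm$feature_b == y, ]

  ident <- row("a", "b")
  expect_equal(ident$pearson, 1, tolerance = 1e-12)
  expect_equal(ident$spearman, 1, tolerance = 1e-12)
  expect_equal(ident$bray_curtis, 0, tolerance = 1e-12)
  expect_equal(ident$kld_sym, 0, tolerance = 1e-12)

  prop <- row("a", "c")
  expect_equal(prop$pearson, 1, tolerance = 1e-12)
  expect_equal(prop$spearman, 1, tolerance = 1e-12)

  disj <- row("d", "e")
  expect_equal(disj$bray_curtis, 1, tolerance = 1e-12)
  expect_gt(disj$kld_sym, 0)
})

test_that("ReBoot null is deterministic and validates inputs", {
  x <- c(0.1, 0.2, 0.05, 0.3, 0.15, 0.2)
  y <- c(0.2, 0.1, 0.25, 0.05, 0.3, 0.1)
  n1 <- reboot_null(x, y, n_perm = 50, seed = 9)
  n2 <- reboot_null(x, y, n_perm = 50, seed = 9)
  expect_identical(n1, n2)
  expect_length(n1, 50)
  expect_error(reboot_null(x, y, n_perm = 0), "n_perm")
})

test_that("ReBoot null is calibrated for independent features", {
  set.seed(14)
  hits <- 0
  reps <- 200
  for (r in seq_len(reps)) {
    x <- runif(30, 0.01, 0.2)
    y <- runif(30, 0.01, 0.2)
    obs <- stats::cor(x, y)
    nl <- reboot_null(x, y, n_perm = 60, seed = r, composition = "none")
    qs <- stats::quantile(nl, c(0.025, 0.975), names = FALSE)
    hits <- hits + (obs >= qs[1] && obs <= qs[2])
  }
  expect_gt(hits / reps, 0.88)
})

test_that("bootstrap distribution is stable for strong associations", {
  set.seed(3)
  x <- sort(runif(100, 0, 0.3))
  y <- x * 0.5 + 0.001
  bt <- bootstrap_dist(x, y, n_boot = 100, seed = 4)
  expect_true(all(bt >= 0.99))
  # bootstrap mean tracks the observed score
  x2 <- runif(100); y2 <- 0.7 * x2 + 0.3 * runif(100)
  bt2 <- bootstrap_dist(x2, y2, n_boot = 100, seed = 5)
  expect_lt(abs(mean(bt2) - stats::cor(x2, y2)), 0.1)
  expect_identical(bootstrap_dist(x, y, n_boot = 30, seed = 8),
                   bootstrap_dist(x, y, n_boot = 30, seed = 8))
})

test_that("permutation p-values follow the z and floor rules", {
  nl <- rnorm(100, 0, 0.1)
  expect_equal(measure_pvalue(mean(nl), nl), 1, ignore_attr = TRUE)
  far <- mean(nl) + 10 * stats::sd(nl)
  expect_equal(as.numeric(measure_pvalue(far, nl)), 1 / 101)
  # degenerate null: point mass
  expect_equal(as.numeric(measure_pvalue(0.5, rep(0.5, 50))), 1)
  expect_equal(as.numeric(measure_pvalue(0.9, rep(0.5, 50))), 1 / 51)
  expect_error(measure_pvalue(0.5, numeric(0)), "empty")

  # stability attribute: wide bootstrap straddling the null mean
  p <- measure_pvalue(far, nl, boot_sample = rnorm(100, mean(nl), 1))
  expect_false(attr(p, "stable"))
  p2 <- measure_pvalue(far, nl, boot_sample = rnorm(100, far, 1e-4))
  expect_true(attr(p2, "stable"))
})

test_that("a planted strong pair is confidently detected", {
  set.seed(21)
  x <- runif(50, 0.01, 0.2)
  y <- 0.95 * scale(x)[, 1] * 0.03 + 0.05 +
    sqrt(1 - 0.95^2) * rnorm(50, 0, 0.03)
  obs <- stats::cor(x, y)
  nl <- reboot_null(x, y, n_perm = 100, seed = 2, composition = "none")
  expect_lte(as.numeric(measure_pvalue(obs, nl)), 0.01)
})

test_that("Brown's method has the stated closed forms and limits", {
  expect_equal(brown_combine(c(1, 1, 1, 1)), 1)

  # independent case equals Fisher exactly
  ps <- list(c(0.05, 0.05), c(0.01, 0.2, 0.6), c(0.3, 0.04, 0.5, 0.9))
  for (p in ps) {
    fisher <- stats::pchisq(-2 * sum(log(p)), df = 2 * length(p),
                            lower.tail = FALSE)
    expect_equal(brown_combine(p), fisher, tolerance = 1e-9)
  }
  expect_equal(round(brown_combine(c(0.05, 0.05)), 4), 0.0175)

  # perfectly dependent duplicated p collapses to the single p
  cov2 <- matrix(4, 2, 2)
  for (p in c(0.01, 0.05, 0.3)) {
    expect_equal(brown_combine(c(p, p), cov2), p, tolerance = 1e-9)
  }

  expect_warning(out <- brown_combine(c(0, 0.05)), "clamped")
  expect_gt(out, 0)
  expect_error(brown_combine(0.5), "2-4")
  expect_error(brown_combine(rep(0.5, 5)), "2-4")
})

test_that("edge filtering applies the support, coefficient and p rules", {
  edges <- data.frame(
    feature_a = paste0("t", 1:4), feature_b = paste0("g", 1:4),
    pearson = c(0.9, 0.85, 0.75, 0.85),
    spearman = c(0.88, 0.8, 0.7, 0.82),
    bray_curtis = 0.2, kld_sym = 0.1,
    p_pearson = 0.01, p_spearman = 0.01, p_bray_curtis = 0.5,
    p_kld_sym = 0.5,
    combined_p = c(0.01, 0.01, 0.01, 0.2),
    support = c(1, 3, 2, 2), sign = "+")
  out <- filter_edges(edges)
  expect_equal(out$retained, c(FALSE, TRUE, FALSE, FALSE))
  # support 1 discarded even with perfect scores; |r| <= 0.8 discarded;
  # high combined p discarded

  # tightening any filter never adds edges
  base <- sum(out$retained)
  for (args in list(list(min_support = 3), list(min_coeff = 0.9),
                    list(alpha = 0.005), list(fdr = TRUE))) {
    tightened <- do.call(filter_edges, c(list(edges), args))
    expect_lte(sum(tightened$retained), base)
  }
})

test_that("ensemble driver flags planted couplings on synthetic data", {
  cfg <- ensemble_config(seed = 51, coupling = 0.9)
  sim <- simulate_dataset(cfg)
  gcn <- lnmr_normalize(sim$geochip)
  ed <- ensemble_edges(sim$otu, gcn, n_perm = 50, n_boot = 50, seed = 52)
  ed <- filter_edges(ed)
  tp <- sim$truth$true_pairs
  tp <- tp[tp$kind == "taxon-function", ]
  key <- paste(ed$feature_a, ed$feature_b)
  planted <- key %in% paste(tp$a, tp$b)
  expect_gt(mean(ed$retained[planted]), 0.5)
  expect_lt(mean(ed$retained[!planted]), 0.05)
  expect_true(all(ed$combined_p > 0 & ed$combined_p <= 1))
  expect_true(all(ed$support %in% 0:4))
  # determinism of the full driver
  ed2 <- ensemble_edges(sim$otu, gcn, n_perm = 50, n_boot = 50, seed = 52)
  expect_equal(ed$combined_p, ed2$combined_p)
})

test_that("ReBoot lowers spurious retention under a dominant taxon", {
  # one taxon with huge, wildly varying counts drives the sample sums;
  # after closure the remaining independent taxa acquire spurious
  # correlations that a naive test endorses
  set.seed(61)
  reps <- 40
  naive_sig <- 0
  reboot_sig <- 0
  n <- 30
  for (r in seq_len(reps)) {
    dom <- exp(rnorm(n, 8, 1.5))
    others <- matrix(rpois(3 * n, 50), 3, n)
    raw <- rbind(dom, others)
    tot <- colSums(raw)
    rel <- sweep(raw, 2, tot, "/")
    x <- rel[2, ]; y <- rel[3, ]
    naive_sig <- naive_sig + (stats::cor.test(x, y)$p.value < 0.05)
    nl <- reboot_null(raw[2, ], raw[3, ], n_perm = 60, seed = r,
                      composition = "shared",
                      rest_x = tot - raw[2, ] - raw[3, ])
    reboot_sig <- reboot_sig +
      (as.numeric(measure_pvalue(stats::cor(x, y), nl)) < 0.05)
  }
  # the naive test endorses nearly every spurious pair; the
  # renormalised null absorbs the closure-induced correlation
  expect_gt(naive_sig, reboot_sig)
  expect_lt(reboot_sig / reps, 0.25)
})

test_that("bipartite network summary uses the edges-per-node convention", {
  edges <- data.frame(
    feature_a = rep("hub", 4), feature_b = paste0("leaf", 1:4),
    pearson = 0.9, spearman = 0.85, bray_curtis = 0.1, kld_sym = 0.1,
    p_pearson = 0.01, p_spearman = 0.01, p_bray_curtis = 0.5,
    p_kld_sym = 0.5, combined_p = 0.01, support = 2, sign = "+",
    retained = TRUE)
  bp <- build_bipartite(edges)
  expect_equal(bp$summary$n_nodes, 5)
  expect_equal(bp$summary$n_edges, 4)
  expect_equal(bp$summary$average_degree, 0.8)
  expect_setequal(unique(igraph::V(bp$network)$kind),
                  c("taxon", "function"))

  none <- build_bipartite(edges[edges$pearson > 1, ])
  expect_equal(none$summary$n_nodes, 0)
  expect_equal(none$summary$average_degree, 0)
})
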