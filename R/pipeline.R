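#' Default pipeline configuration
#'
#' Returns the full configuration list understood by [run_pipeline()],
#' with every stage enabled and the generator defaults. Supply a YAML
#' file or a list overriding any subset of these values.
#'
#' @return Named list of configuration defaults.
#' @export
default_pipeline_config <- function() {
  list(
    out_dir = "meconet_run",
    seed = 1L,
    stages = list(simulate = TRUE, preprocess = TRUE, diversity = TRUE,
                  pmen = TRUE, conet = TRUE),
    simulate = list(),           # overrides for synthetic_config()
    preprocess = list(rarefy_depth = NULL, min_occurrence = 4,
                      snr_threshold = 2),
    pmen = list(threshold = NULL, s_min = 0.3, s_max = 0.99, step = 0.01,
                alpha = 0.05),
    conet = list(n_perm = 100, n_boot = 100, min_support = 2,
                 min_coeff = 0.8, alpha = 0.05, fdr = FALSE)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> preprocess -> diversity -> pmen -> conet on
#' a synthetic dataset, writing each stage's outputs plus a manifest
#' (parameters, per-stage seeds, output paths with MD5 checksums) that
#' makes the run reproducible. Stages can be toggled off; a stage
#' failure aborts with the stage named, keeping partial outputs.
#'
#' @param config A list (see [default_pipeline_config()]) or the path to
#'   a YAML file with the same structure.
#' @return The manifest list, invisibly; also written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)
  if (!is.numeric(cfg$seed) || cfg$seed < 0) {
    stop("seed must be a non-negative integer")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  record <- function(name, path) outputs[[name]] <<- path

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  sim <- NULL
  if (isTRUE(cfg$stages$simulate)) {
    run_stage("simulate", {
      sim_cfg <- do.call(synthetic_config,
                         c(cfg$simulate,
                           list(seed = derive_seed(cfg$seed, "simulate"))))
      sim <- simulate_dataset(sim_cfg)
      record("otu_table", write_feature_table(
        sim$otu, file.path(cfg$out_dir, "otu_table.tsv")))
      record("geochip_table", write_feature_table(
        sim$geochip, file.path(cfg$out_dir, "geochip_table.tsv")))
      record("sample_metadata", write_sample_metadata(
        sim$otu, file.path(cfg$out_dir, "sample_metadata.tsv")))
      record("truth", write_truth(
        sim$truth, file.path(cfg$out_dir, "truth.json")))
    })
  }
  if (is.null(sim)) stop("pipeline currently requires the simulate stage")

  otu <- sim$otu
  geochip <- sim$geochip
  if (isTRUE(cfg$stages$preprocess)) {
    run_stage("preprocess", {
      depth <- cfg$preprocess$rarefy_depth
      if (is.null(depth)) depth <- min(colSums(otu$values))
      otu <- rarefy(otu, depth, seed = derive_seed(cfg$seed, "rarefy"))
      otu <- prevalence_filter(otu, cfg$preprocess$min_occurrence)
      geochip <- lnmr_normalize(geochip)
      record("otu_rarefied", write_feature_table(
        otu, file.path(cfg$out_dir, "otu_rarefied.tsv")))
      record("geochip_normalized", write_feature_table(
        geochip, file.path(cfg$out_dir, "geochip_lnmr.tsv")))
    })
  }

  if (isTRUE(cfg$stages$diversity)) {
    run_stage("diversity", {
      div <- alpha_diversity(otu)
      path <- file.path(cfg$out_dir, "alpha_diversity.tsv")
      utils::write.table(div, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      record("alpha_diversity", path)
    })
  }

  pm <- NULL
  if (isTRUE(cfg$stages$pmen)) {
    run_stage("pmen", {
      pm <- pmen(otu, threshold = cfg$pmen$threshold,
                 seed = derive_seed(cfg$seed, "modules"),
                 s_min = cfg$pmen$s_min, s_max = cfg$pmen$s_max,
                 step = cfg$pmen$step, alpha = cfg$pmen$alpha)
      record("pmen_graphml", export_network(
        pm$network, file.path(cfg$out_dir, "pmen.graphml"), "graphml"))
      roles_path <- file.path(cfg$out_dir, "pmen_node_roles.tsv")
      utils::write.table(pm$roles, roles_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      record("pmen_roles", roles_path)
      summ_path <- file.path(cfg$out_dir, "pmen_summary.tsv")
      utils::write.table(pm$summary, summ_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      record("pmen_summary", summ_path)
    })
  }

  if (isTRUE(cfg$stages$conet)) {
    run_stage("conet", {
      edges <- ensemble_edges(otu, geochip,
                              n_perm = cfg$conet$n_perm,
                              n_boot = cfg$conet$n_boot,
                              seed = derive_seed(cfg$seed, "conet"),
                              alpha = cfg$conet$alpha)
      edges <- filter_edges(edges, cfg$conet$min_support,
                            cfg$conet$min_coeff, cfg$conet$alpha,
                            cfg$conet$fdr)
      edge_path <- file.path(cfg$out_dir, "conet_edges.tsv")
      utils::write.table(edges, edge_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      record("conet_edges", edge_path)
      bp <- build_bipartite(edges)
      if (igraph::vcount(bp$network) > 0) {
        record("conet_graphml", export_network(
          bp$network, file.path(cfg$out_dir, "conet.graphml"), "graphml"))
      }
      summ_path <- file.path(cfg$out_dir, "conet_summary.tsv")
      utils::write.table(bp$summary, summ_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      record("conet_summary", summ_path)
    })
  }

  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    r_version = as.character(getRversion()),
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), "out_dir")],
    outputs = lapply(outputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
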