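#' Configuration for the synthetic mesocosm dataset
#'
#' The generator emulates a factorial mesocosm survey: `n_soil_types`
#' soils sampled at `n_layers` profile depth layers, at `n_stages` plant
#' growth stages, with `n_replicates` mesocosm columns per combination.
#' The defaults (3 x 4 x 2 x 2 = 48 samples) match a typical paddy-soil
#' profile study design. Taxa are partitioned into `n_modules` blocks of
#' co-occurring taxa: the latent log-abundance correlation is
#' `within_module_rho` inside a block and `cross_module_rho` between
#' blocks. A subset of functional gene categories is coupled to specific
#' taxa with correlation `coupling_strength`, planting taxa-function
#' associations that the ensemble inference stage should recover.
#'
#' @param n_soil_types,n_layers,n_stages,n_replicates Design factor
#'   counts, all >= 1.
#' @param n_taxa Number of taxa (features) in the count table.
#' @param n_gene_categories Number of functional gene categories on the
#'   synthetic array.
#' @param n_modules Number of planted co-occurrence modules.
#' @param within_module_rho Latent correlation inside a module, in [0, 1).
#' @param cross_module_rho Latent correlation between modules.
#' @param coupling_strength Correlation between a coupled gene category's
#'   signal and its taxon's latent abundance, in [0, 1).
#' @param n_coupled Number of gene categories coupled to taxa; the rest
#'   are pure background noise. Defaults to half the categories.
#' @param sequencing_depth Reads drawn per sample (multinomial size).
#' @param depth_variability Coefficient of variation of per-sample library
#'   size before rarefaction; 0 gives equal depths.
#' @param background_mean,background_sd Array background signal
#'   parameters (scanner-intensity units).
#' @param latent_sd Standard deviation of latent log-abundances.
#' @param layer_effect Optional shift of latent means per depth layer
#'   step for the first `layer_effect_taxa` taxa (positive: enriched with
#'   depth), reproducing surface- vs depth-enriched contrasts.
#' @param layer_effect_taxa Number of taxa subject to `layer_effect`.
#' @param seed RNG seed making the whole dataset reproducible.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_soil_types = 3, n_layers = 4, n_stages = 2,
                             n_replicates = 2, n_taxa = 40,
                             n_gene_categories = 20, n_modules = 4,
                             within_module_rho = 0.7, cross_module_rho = 0,
                             coupling_strength = 0.6,
                             n_coupled = NULL,
                             sequencing_depth = 10000,
                             depth_variability = 0,
                             background_mean = 1000, background_sd = 200,
                             latent_sd = 1,
                             layer_effect = 0, layer_effect_taxa = 0,
                             seed = 1) {
  cfg <- list(n_soil_types = as.integer(n_soil_types),
              n_layers = as.integer(n_layers),
              n_stages = as.integer(n_stages),
              n_replicates = as.integer(n_replicates),
              n_taxa = as.integer(n_taxa),
              n_gene_categories = as.integer(n_gene_categories),
              n_modules = as.integer(n_modules),
              within_module_rho = within_module_rho,
              cross_module_rho = cross_module_rho,
              coupling_strength = coupling_strength,
              n_coupled = if (is.null(n_coupled)) {
                max(1L, as.integer(n_gene_categories) %/% 2L)
              } else as.integer(n_coupled),
              sequencing_depth = as.integer(sequencing_depth),
              depth_variability = depth_variability,
              background_mean = background_mean,
              background_sd = background_sd,
              latent_sd = latent_sd,
              layer_effect = layer_effect,
              layer_effect_taxa = as.integer(layer_effect_taxa),
              seed = as.integer(seed))
  design <- c(cfg$n_soil_types, cfg$n_layers, cfg$n_stages, cfg$n_replicates)
  if (any(design < 1L)) stop("all design factor counts must be >= 1")
  cfg$n_samples <- prod(design)
  if (cfg$n_taxa < 1L) stop("n_taxa must be >= 1")
  if (cfg$n_modules < 1L || cfg$n_modules > cfg$n_taxa) {
    stop("n_modules must be between 1 and n_taxa")
  }
  if (within_module_rho < 0 || within_module_rho >= 1) {
    stop("within_module_rho must be in [0, 1)")
  }
  if (within_module_rho < cross_module_rho) {
    stop("within_module_rho must be >= cross_module_rho")
  }
  if (coupling_strength < 0 || coupling_strength >= 1) {
    stop("coupling_strength must be in [0, 1)")
  }
  if (background_sd <= 0) stop("background_sd must be positive")
  if (cfg$sequencing_depth < 1L) stop("sequencing_depth must be >= 1")
  if (cfg$n_coupled > cfg$n_gene_categories) {
    stop("n_coupled cannot exceed n_gene_categories")
  }
  structure(cfg, class = "synthetic_config")
}

#' Sample metadata for the factorial design
#'
#' @param config A `synthetic_config`.
#' @return data.frame with columns sample_id, soil_type, layer (letters
#'   A, B, ...), stage, replicate; row names are the sample ids.
#' @export
design_metadata <- function(config) {
  grid <- expand.grid(
    replicate = paste0("R", seq_len(config$n_replicates)),
    stage = paste0("stage", seq_len(config$n_stages)),
    layer = LETTERS[seq_len(config$n_layers)],
    soil_type = paste0("soil", seq_len(config$n_soil_types)),
    stringsAsFactors = FALSE)
  grid <- grid[, c("soil_type", "layer", "stage", "replicate")]
  grid$sample_id <- apply(grid, 1, paste, collapse = ".")
  rownames(grid) <- grid$sample_id
  grid[, c("sample_id", "soil_type", "layer", "stage", "replicate")]
}

# Block correlation matrix with PSD repair by uniform shrinkage of the
# off-diagonal correlations (x 0.95 until the smallest eigenvalue is
# non-negative).
block_correlation <- function(n_taxa, module_of, rho_within, rho_between,
                              max_shrink = 200L) {
  same <- outer(module_of, module_of, "==")
  sigma <- matrix(rho_between, n_taxa, n_taxa)
  sigma[same] <- rho_within
  diag(sigma) <- 1
  shrink <- 0L
  while (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) <
         -1e-10) {
    off <- sigma
    diag(off) <- 0
    sigma <- off * 0.95
    diag(sigma) <- 1
    shrink <- shrink + 1L
    if (shrink > max_shrink) {
      stop("block covariance could not be repaired to positive semi-definite")
    }
  }
  attr(sigma, "shrink_steps") <- shrink
  sigma
}

#' Generate latent log-abundances with planted correlation modules
#'
#' Draws an `n_taxa` x `n_samples` matrix from a multivariate normal
#' whose correlation is `within_module_rho` inside contiguous taxon
#' blocks and `cross_module_rho` outside. Taxa are assigned to modules in
#' contiguous, near-equal blocks. Deterministic for a fixed
#' `config$seed`.
#'
#' @param config A `synthetic_config`.
#' @return List with elements `latent` (matrix, taxa x samples) and
#'   `truth` (class `planted_truth`: `module_of`, `true_pairs` data.frame
#'   with columns `a`, `b`, `kind`, and `latent_means`).
#' @export
generate_latent <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  meta <- design_metadata(config)
  taxa <- sprintf("taxon%03d", seq_len(config$n_taxa))
  module_of <- stats::setNames(
    sort(rep_len(seq_len(config$n_modules), config$n_taxa)), taxa)
  sigma <- block_correlation(config$n_taxa, module_of,
                             config$within_module_rho,
                             config$cross_module_rho)
  withr_seed(config$seed, {
    means <- stats::rnorm(config$n_taxa, mean = 0, sd = 0.5)
    latent <- t(MASS::mvrnorm(n = config$n_samples, mu = rep(0, config$n_taxa),
                              Sigma = sigma * config$latent_sd^2))
  })
  dimnames(latent) <- list(taxa, meta$sample_id)
  latent <- latent + means
  if (config$layer_effect != 0 && config$layer_effect_taxa > 0) {
    step <- match(meta$layer, LETTERS) - 1
    idx <- seq_len(min(config$layer_effect_taxa, config$n_taxa))
    latent[idx, ] <- latent[idx, ] +
      rep(step * config$layer_effect, each = length(idx))
  }
  pairs <- within_module_pairs(module_of)
  truth <- structure(
    list(module_of = module_of, true_pairs = pairs,
         latent_means = stats::setNames(means, taxa)),
    class = "planted_truth")
  list(latent = latent, truth = truth)
}

within_module_pairs <- function(module_of) {
  ids <- names(module_of)
  out <- do.call(rbind, lapply(split(ids, module_of), function(members) {
    if (length(members) < 2) return(NULL)
    cmb <- t(utils::combn(members, 2))
    data.frame(a = cmb[, 1], b = cmb[, 2], kind = "taxon-taxon",
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(a = character(), b = character(), kind = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# Run code under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Small deterministic integer hash for deriving per-unit RNG substreams
# from (seed, label); stays below 2^31.
derive_seed <- function(seed, label) {
  h <- 0
  for (k in utf8ToInt(as.character(label))) h <- (h * 31 + k) %% 2147483647
  as.integer((h + as.numeric(seed) * 7919) %% 2147483647)
}

#' Draw multinomial sequencing counts from latent log-abundances
#'
#' Each sample column becomes a multinomial draw of size `depth` with
#' probabilities proportional to `exp(latent)`, inducing the closed-sum
#' (compositional) structure of amplicon count tables.
#'
#' @param latent Matrix of latent log-abundances (taxa x samples).
#' @param depth Reads per sample; a scalar or per-sample vector, >= 1.
#' @param seed RNG seed.
#' @param metadata Optional sample metadata data.frame to attach.
#' @return A `feature_table` of integer counts; every column sums to its
#'   depth.
#' @export
sample_counts <- function(latent, depth, seed = 1, metadata = NULL) {
  if (any(depth < 1)) stop("depth must be >= 1")
  if (any(!is.finite(latent))) stop("latent matrix must be finite")
  depth <- rep_len(as.integer(depth), ncol(latent))
  probs <- exp(latent)
  counts <- matrix(0L, nrow(latent), ncol(latent), dimnames = dimnames(latent))
  withr_seed(seed, {
    for (j in seq_len(ncol(latent))) {
      counts[, j] <- stats::rmultinom(1, size = depth[j],
                                      prob = probs[, j])[, 1]
    }
  })
  feature_table(counts, sample_metadata = metadata)
}

#' Generate synthetic functional gene array signals
#'
#' Coupled gene categories get a signal that is an affine function of
#' the coupled taxon's standardised latent relative abundance
#' (exp(latent) closed to unit sum per sample, the abundance scale on
#' which association measures operate) plus Gaussian noise, giving a
#' planted taxon-category correlation of `coupling_strength`;
#' uncoupled categories are pure background noise with mean
#' `background_mean` and sd `background_sd`. Negative signals are
#' clipped at zero (scanner intensities are non-negative). Categories
#' are coupled round-robin to taxa `taxon001, taxon002, ...`; the
#' planted pairs are appended to `truth$true_pairs` with kind
#' `"taxon-function"`.
#'
#' @param latent Latent log-abundance matrix from [generate_latent()].
#' @param truth The matching `planted_truth`.
#' @param config A `synthetic_config`.
#' @param metadata Optional sample metadata to attach.
#' @return List with `geochip` (a `feature_table` of signals, annotated
#'   with the category name) and the augmented `truth`.
#' @export
generate_geochip <- function(latent, truth, config, metadata = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$background_sd <= 0) stop("background_sd must be positive")
  rho <- config$coupling_strength
  n_cat <- config$n_gene_categories
  n_s <- ncol(latent)
  cats <- sprintf("category%02d", seq_len(n_cat))
  coupled <- seq_len(config$n_coupled)
  partner <- rep_len(seq_len(nrow(latent)), length(coupled))
  abundance <- relative_abundance(exp(latent))
  z <- t(scale(t(abundance)))  # standardise each taxon across samples
  signal <- matrix(0, n_cat, n_s, dimnames = list(cats, colnames(latent)))
  withr_seed(derive_seed(config$seed, "geochip"), {
    noise <- matrix(stats::rnorm(n_cat * n_s), n_cat, n_s)
  })
  for (g in seq_len(n_cat)) {
    if (g %in% coupled && rho > 0) {
      mix <- rho * z[partner[g], ] + sqrt(1 - rho^2) * noise[g, ]
    } else {
      mix <- noise[g, ]
    }
    signal[g, ] <- config$background_mean + config$background_sd * mix
  }
  signal[signal < 0] <- 0
  if (rho > 0 && length(coupled)) {
    new_pairs <- data.frame(a = rownames(latent)[partner],
                            b = cats[coupled], kind = "taxon-function",
                            stringsAsFactors = FALSE)
    truth$true_pairs <- rbind(truth$true_pairs, new_pairs)
  }
  geochip <- feature_table(signal,
                           feature_annotation = stats::setNames(cats, cats),
                           sample_metadata = metadata)
  list(geochip = geochip, truth = truth)
}

#' Simulate a complete synthetic survey
#'
#' Runs [generate_latent()], [sample_counts()] and [generate_geochip()]
#' under one configuration, returning the OTU-like count table, the
#' array-like signal table, the sample metadata and the planted truth.
#'
#' @param config A `synthetic_config`.
#' @return List with elements `otu`, `geochip`, `metadata`, `truth`,
#'   `latent`.
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  meta <- design_metadata(config)
  lat <- generate_latent(config)
  depth <- config$sequencing_depth
  if (config$depth_variability > 0) {
    withr_seed(derive_seed(config$seed, "depth"), {
      depth <- pmax(1L, as.integer(round(stats::rnorm(
        config$n_samples, config$sequencing_depth,
        config$depth_variability * config$sequencing_depth))))
    })
  }
  otu <- sample_counts(lat$latent, depth,
                       seed = derive_seed(config$seed, "counts"),
                       metadata = meta)
  gc <- generate_geochip(lat$latent, lat$truth, config, metadata = meta)
  list(otu = otu, geochip = gc$geochip, metadata = meta, truth = gc$truth,
       latent = lat$latent)
}

#' Write planted truth to JSON
#'
#' @param truth A `planted_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(module_of = as.list(truth$module_of),
         true_pairs = truth$true_pairs,
         latent_means = as.list(truth$latent_means)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
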