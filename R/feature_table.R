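#' Construct a feature table
#'
#' A `feature_table` holds a non-negative numeric matrix of features
#' (OTUs, taxa, or functional gene categories) by samples, together with
#' optional per-feature annotations (taxonomic lineages or gene categories)
#' and per-sample metadata (soil type, depth layer, growth stage, replicate).
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#'   Must have unique, non-empty row and column names and contain only
#'   finite, non-negative values.
#' @param feature_annotation Optional named character vector mapping
#'   feature ids to a lineage string or gene category. Names must be a
#'   subset of `rownames(values)`.
#' @param sample_metadata Optional data.frame with one row per sample;
#'   row names must match `colnames(values)`.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, feature_annotation = NULL,
                          sample_metadata = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  validate_feature_table_values(values)
  if (!is.null(feature_annotation)) {
    feature_annotation <- unlist(feature_annotation)
    bad <- setdiff(names(feature_annotation), rownames(values))
    if (length(bad)) {
      stop("feature_annotation names not in table: ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  if (!is.null(sample_metadata)) {
    sample_metadata <- as.data.frame(sample_metadata)
    missing <- setdiff(colnames(values), rownames(sample_metadata))
    if (length(missing)) {
      stop("sample_metadata missing rows for samples: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    sample_metadata <- sample_metadata[colnames(values), , drop = FALSE]
  }
  structure(
    list(values = values,
         feature_annotation = feature_annotation,
         sample_metadata = sample_metadata),
    class = "feature_table"
  )
}

validate_feature_table_values <- function(values) {
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("feature table requires feature (row) and sample (column) names")
  }
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup)) {
    stop("duplicated feature id(s): ", paste(unique(dup), collapse = ", "))
  }
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup)) {
    stop("duplicated sample id(s): ", paste(unique(dup), collapse = ", "))
  }
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-finite or negative value at feature '%s', sample '%s'",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
  }
  invisible(values)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$feature_annotation)) {
    cat(sprintf("  annotated features: %d\n", length(x$feature_annotation)))
  }
  if (!is.null(x$sample_metadata)) {
    cat("  sample metadata: ", paste(colnames(x$sample_metadata),
                                     collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Feature and sample ids of a table
#' @param table A `feature_table`.
#' @return Character vector of ids.
#' @export
feature_ids <- function(table) rownames(table$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(table) colnames(table$values)

#' Subset a feature table
#'
#' @param table A `feature_table`.
#' @param features,samples Character, integer, or logical index of
#'   features/samples to keep (default: all).
#' @return A `feature_table`.
#' @export
subset_table <- function(table, features = NULL, samples = NULL) {
  v <- table$values
  if (!is.null(features)) v <- v[features, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  ann <- table$feature_annotation
  if (!is.null(ann)) ann <- ann[intersect(names(ann), rownames(v))]
  meta <- table$sample_metadata
  if (!is.null(meta)) meta <- meta[colnames(v), , drop = FALSE]
  feature_table(v, feature_annotation = ann, sample_metadata = meta)
}

#' Convert a table to relative abundances
#'
#' Divides every sample column by its total so that columns sum to one.
#' All-zero samples are left at zero.
#'
#' @param table A `feature_table` or numeric matrix.
#' @return Object of the same kind with columns closed to unit sum.
#' @export
relative_abundance <- function(table) {
  v <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  tot <- colSums(v)
  tot[tot == 0] <- 1
  out <- sweep(v, 2, tot, "/")
  if (inherits(table, "feature_table")) {
    feature_table(out, table$feature_annotation, table$sample_metadata)
  } else {
    out
  }
}

#' Read a feature table from TSV
#'
#' Reads a tab-delimited table with a header row. The `orientation`
#' argument declares whether rows hold features (the package convention)
#' or samples (the transpose); the returned table always has features in
#' rows. Parsing is strict: duplicate ids, non-numeric cells and negative
#' values are errors that name the offending row or column.
#'
#' @param path Path to a TSV file; first column holds ids.
#' @param orientation `"features"` (rows are features; default) or
#'   `"samples"` (rows are samples).
#' @param feature_annotation,sample_metadata Passed to [feature_table()].
#' @return A `feature_table`.
#' @export
read_feature_table <- function(path, orientation = c("features", "samples"),
                               feature_annotation = NULL,
                               sample_metadata = NULL) {
  orientation <- match.arg(orientation)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expected an id column plus at least one value column")
  ids <- as.character(raw[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicated id(s) in '", path, "': ", paste(dup, collapse = ", "))
  }
  vals <- raw[, -1, drop = FALSE]
  m <- matrix(NA_real_, nrow(vals), ncol(vals),
              dimnames = list(ids, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    col <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(col) & !is.na(vals[[j]]))
    if (length(bad)) {
      stop(sprintf("non-numeric value at row '%s', column '%s'",
                   ids[bad[1]], colnames(vals)[j]))
    }
    m[, j] <- col
  }
  if (orientation == "samples") m <- t(m)
  feature_table(m, feature_annotation = feature_annotation,
                sample_metadata = sample_metadata)
}

#' Write a feature table to TSV
#'
#' @param table A `feature_table`.
#' @param path Output path.
#' @param id_column Name for the leading id column.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, id_column = "feature_id") {
  df <- data.frame(rownames(table$values), table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sample metadata to TSV
#' @param table A `feature_table` with sample metadata.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(table, path) {
  if (is.null(table$sample_metadata)) stop("table has no sample metadata")
  df <- data.frame(sample_id = rownames(table$sample_metadata),
                   table$sample_metadata, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Aggregate features to a taxonomic or functional level
#'
#' Sums feature rows sharing the same label at a given lineage rank.
#' Lineages are `;`-separated strings, optionally with Greengenes-style
#' rank prefixes (`k__`, `p__`, ...). Features whose phylum is in
#' `class_exceptions` (default Proteobacteria) are aggregated at the class
#' rank instead, the usual convention for community-level network
#' analysis where proteobacterial classes are ecologically distinct.
#' Features with no usable annotation are pooled into an
#' `"unclassified"` bucket rather than dropped.
#'
#' @param table A `feature_table` whose `feature_annotation` holds lineages.
#' @param level Rank to aggregate at: one of `"kingdom"`, `"phylum"`,
#'   `"class"`, `"order"`, `"family"`, `"genus"`, `"species"`, or a
#'   1-based rank index.
#' @param class_exceptions Phylum names aggregated at class level instead.
#' @param delim Lineage field delimiter.
#' @return A `feature_table` of aggregated rows; its annotation maps each
#'   output label to itself.
#' @export
aggregate_by_level <- function(table, level = "phylum",
                               class_exceptions = "Proteobacteria",
                               delim = ";") {
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
             "species")
  if (is.character(level)) {
    level_idx <- match(match.arg(level, ranks), ranks)
  } else {
    level_idx <- as.integer(level)
  }
  ann <- table$feature_annotation
  if (is.null(ann)) stop("table has no feature annotation to aggregate by")
  labels <- vapply(rownames(table$values), function(id) {
    lin <- if (id %in% names(ann)) ann[[id]] else NA_character_
    if (is.null(lin) || is.na(lin) || !nzchar(lin)) return("unclassified")
    fields <- strip_rank_prefix(trimws(strsplit(lin, delim, fixed = TRUE)[[1]]))
    pick <- function(i) {
      if (length(fields) >= i && nzchar(fields[i])) fields[i] else NA_character_
    }
    lab <- pick(level_idx)
    phylum <- pick(2L)
    if (!is.na(phylum) && phylum %in% class_exceptions && level_idx == 2L) {
      cls <- pick(3L)
      if (!is.na(cls)) lab <- cls
    }
    if (is.na(lab)) "unclassified" else lab
  }, character(1))
  groups <- rowsum(table$values, group = labels)
  out_ann <- stats::setNames(rownames(groups), rownames(groups))
  feature_table(groups, feature_annotation = out_ann,
                sample_metadata = table$sample_metadata)
}

strip_rank_prefix <- function(x) {
  sub("^[kpcofgsd]__", "", x)
}
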