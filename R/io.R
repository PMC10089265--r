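#' Construct a feature table
#'
#' A feature table is the package's central container: a numeric matrix of
#' samples (rows) by features (columns), tagged with the feature kind
#' (`"otu"` for 16S-derived taxa, `"gene"` for qPCR functional genes) and the
#' measurement units.
#'
#' @param values numeric matrix, samples x features, non-negative. Row names
#'   are sample ids, column names feature ids; both mandatory and unique.
#' @param kind `"otu"` or `"gene"`.
#' @param units `"reads"`, `"relative"` or `"copies_per_gram"`.
#' @return A `feature_table`: the matrix with `kind` and `units` attributes.
#' @examples
#' m <- matrix(c(5, 0, 3, 2), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("OTU_1", "OTU_2")))
#' ft <- feature_table(m, kind = "otu", units = "reads")
#' @export
feature_table <- function(values, kind = c("otu", "gene"),
                          units = c("reads", "relative", "copies_per_gram")) {
  kind <- match.arg(kind)
  units <- match.arg(units)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    invanet_error("invanet_invalid_table", "feature table needs sample row names and feature column names")
  }
  if (anyDuplicated(rownames(values))) {
    invanet_error("invanet_duplicate_id", sprintf(
      "duplicate sample ids: %s",
      paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", ")
    ))
  }
  if (anyDuplicated(colnames(values))) {
    invanet_error("invanet_duplicate_id", sprintf(
      "duplicate feature ids: %s",
      paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", ")
    ))
  }
  if (anyNA(values) || any(values < 0)) {
    invanet_error("invanet_invalid_table", "feature table entries must be non-negative and non-missing")
  }
  structure(values, kind = kind, units = units,
            class = c("feature_table", class(values)))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d %s features [%s]\n",
              nrow(x), ncol(x), attr(x, "kind"), attr(x, "units")))
  invisible(x)
}

ft_kind <- function(x) attr(x, "kind") %||% "otu"
ft_units <- function(x) attr(x, "units") %||% "reads"

# Strip the feature_table class for matrix math while keeping dimnames.
ft_values <- function(x) {
  y <- unclass(x)
  attr(y, "kind") <- NULL
  attr(y, "units") <- NULL
  y
}

#' Read and write feature tables
#'
#' The primary dialect is a tab-separated file whose header row holds feature
#' ids and whose first column holds sample ids. `format = "biom"` accepts a
#' BIOM file (read through the biomformat package; BIOM stores features as
#' rows, which is transposed on ingest).
#'
#' @param path file path.
#' @param kind,units passed to [feature_table()].
#' @param format `"tsv"` or `"biom"`.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, kind = "otu", units = "reads",
                               format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    invanet_error("invanet_missing_file", sprintf("file not found: %s", path))
  }
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      invanet_error("invanet_missing_dependency", "BIOM input requires the biomformat package")
    }
    b <- biomformat::read_biom(path)
    m <- t(as.matrix(biomformat::biom_data(b)))
    return(feature_table(m, kind = kind, units = units))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          row.names = NULL, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    invanet_error("invanet_duplicate_id", sprintf(
      "duplicate sample ids in %s: %s", path,
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  feature_table(m, kind = kind, units = units)
}

#' @rdname read_feature_table
#' @param table a [feature_table()].
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(sample_id = rownames(table),
                   ft_values(table), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table
#'
#' One row per OTU: `otu_id` then the seven ranks phylum..species. Missing or
#' empty ranks are normalised to `"unclassified"`.
#'
#' @param path TSV path with header.
#' @return data.frame with columns otu_id, phylum, class, order, family,
#'   genus, species (and kingdom if present).
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  validate_taxonomy(df)
}

validate_taxonomy <- function(df) {
  if (!"otu_id" %in% names(df)) {
    invanet_error("invanet_invalid_table", "taxonomy table needs an otu_id column")
  }
  if (anyDuplicated(df$otu_id)) {
    invanet_error("invanet_duplicate_id", "duplicate otu_id in taxonomy table")
  }
  rank_cols <- setdiff(names(df), "otu_id")
  for (rc in rank_cols) {
    v <- as.character(df[[rc]])
    v[is.na(v) | !nzchar(v)] <- "unclassified"
    df[[rc]] <- v
  }
  df
}

#' @rdname read_taxonomy
#' @param taxonomy a taxonomy data.frame.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Columns: `sample_id`, `site_id`, `group` (`AP` invaded / `N` native),
#' `lon`, `lat`, and the seven edaphic variables `pH, TC, TN, TP, AN, NN, AP_P`
#' (available phosphorus is named `AP_P` to avoid clashing with the `AP`
#' group label).
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
read_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  validate_metadata(df)
}

edaphic_vars <- function() c("pH", "TC", "TN", "TP", "AN", "NN", "AP_P")

validate_metadata <- function(df) {
  needed <- c("sample_id", "site_id", "group", "lon", "lat")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    invanet_error("invanet_invalid_table",
                  sprintf("metadata lacks columns: %s", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(df$sample_id)) {
    invanet_error("invanet_duplicate_id", "duplicate sample_id in metadata")
  }
  if (!all(df$group %in% c("AP", "N"))) {
    invanet_error("invanet_invalid_table", "group must be 'AP' (invaded) or 'N' (native)")
  }
  tab <- table(df$site_id, df$group)
  if (any(tab > 1)) {
    invanet_error("invanet_invalid_table", "paired design violated: a site_id appears twice within one group")
  }
  df
}

#' @rdname read_metadata
#' @param metadata a metadata data.frame.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a qPCR CT table
#'
#' Samples in rows, assays in columns. Empty cells are non-detects
#' (chip exports leave undetected wells blank) and come back as `NA`.
#'
#' @param path TSV path.
#' @return numeric matrix with `NA` for non-detects.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"))
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    invanet_error("invanet_duplicate_id", "duplicate sample ids in CT table")
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' @rdname read_ct_table
#' @param ct CT matrix.
#' @export
write_ct_table <- function(ct, path) {
  df <- data.frame(sample_id = rownames(ct), ct, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a qPCR panel definition
#'
#' TSV with columns `assay_id`, `category`, `efficiency`. Categories follow
#' the CNPS chip layout: `C_degradation`, `C_fixation`, `C_methane`, `N`,
#' `P`, `S`, plus exactly one `reference_16S` assay.
#'
#' @param path TSV path.
#' @return validated panel data.frame.
#' @seealso [qmec_panel()] for the bundled default panel.
#' @export
read_panel <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  validate_panel(df)
}

panel_categories <- function() {
  c("C_degradation", "C_fixation", "C_methane", "N", "P", "S", "reference_16S")
}

validate_panel <- function(panel) {
  needed <- c("assay_id", "category", "efficiency")
  if (!all(needed %in% names(panel))) {
    invanet_error("invanet_invalid_table",
                  sprintf("panel needs columns: %s", paste(needed, collapse = ", ")))
  }
  if (anyDuplicated(panel$assay_id)) {
    invanet_error("invanet_duplicate_id", "duplicate assay_id in panel")
  }
  bad <- setdiff(unique(panel$category), panel_categories())
  if (length(bad)) {
    invanet_error("invanet_invalid_table",
                  sprintf("unknown panel categories: %s", paste(bad, collapse = ", ")))
  }
  if (sum(panel$category == "reference_16S") != 1L) {
    invanet_error("invanet_invalid_table", "panel must contain exactly one reference_16S assay")
  }
  if (any(!is.finite(panel$efficiency) | panel$efficiency <= 1)) {
    invanet_error("invanet_invalid_table", "amplification efficiencies must be finite and > 1")
  }
  panel
}

#' @rdname read_panel
#' @param panel panel data.frame.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load and cross-validate a full dataset
#'
#' Bundles the OTU table, taxonomy, metadata, CT table, panel and per-sample
#' absolute 16S copy numbers, and checks them against each other: every
#' OTU-table sample must have metadata, every CT assay must be in the panel,
#' every CT sample must be in the OTU table's sample set.
#'
#' @param paths named list with elements `otus`, `taxonomy`, `metadata`,
#'   `ct`, `panel` (file paths). `abs_16s` may be a path to a two-column TSV
#'   (sample_id, copies) or omitted if the metadata carries an `abs_16s`
#'   column.
#' @param format feature-table format (`"tsv"` or `"biom"`).
#' @return An `invanet_dataset` list.
#' @export
load_dataset <- function(paths, format = "tsv") {
  needed <- c("otus", "taxonomy", "metadata", "ct", "panel")
  for (nm in needed) {
    if (is.null(paths[[nm]]) || !file.exists(paths[[nm]])) {
      invanet_error("invanet_missing_file",
                    sprintf("input '%s' missing or not found: %s",
                            nm, paths[[nm]] %||% "<unset>"))
    }
  }
  otus <- read_feature_table(paths$otus, kind = "otu", units = "reads", format = format)
  taxonomy <- read_taxonomy(paths$taxonomy)
  metadata <- read_metadata(paths$metadata)
  ct <- read_ct_table(paths$ct)
  panel <- read_panel(paths$panel)
  abs_16s <- NULL
  if (!is.null(paths$abs_16s)) {
    a <- utils::read.table(paths$abs_16s, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    abs_16s <- stats::setNames(as.numeric(a[[2]]), as.character(a[[1]]))
  } else if ("abs_16s" %in% names(metadata)) {
    abs_16s <- stats::setNames(metadata$abs_16s, metadata$sample_id)
  }
  new_dataset(otus = otus, taxonomy = taxonomy, metadata = metadata,
              ct = ct, panel = panel, abs_16s = abs_16s)
}

new_dataset <- function(otus, taxonomy, metadata, ct, panel, abs_16s,
                        truth = NULL) {
  no_meta <- setdiff(rownames(otus), metadata$sample_id)
  if (length(no_meta)) {
    invanet_error("invanet_missing_metadata", sprintf(
      "samples present in counts but absent from metadata: %s",
      paste(no_meta, collapse = ", ")
    ))
  }
  unknown <- setdiff(colnames(ct), panel$assay_id)
  if (length(unknown)) {
    invanet_error("invanet_unknown_assay", sprintf(
      "CT table assays absent from panel: %s", paste(unknown, collapse = ", ")
    ))
  }
  stray <- setdiff(rownames(ct), metadata$sample_id)
  if (length(stray)) {
    invanet_error("invanet_missing_metadata", sprintf(
      "CT table samples absent from metadata: %s", paste(stray, collapse = ", ")
    ))
  }
  structure(list(otus = otus, taxonomy = taxonomy, metadata = metadata,
                 ct = ct, panel = panel, abs_16s = abs_16s, truth = truth),
            class = "invanet_dataset")
}

#' @export
print.invanet_dataset <- function(x, ...) {
  cat(sprintf("<invanet_dataset> %d samples, %d OTUs, %d qPCR assays, %d sites\n",
              nrow(x$otus), ncol(x$otus), ncol(x$ct),
              length(unique(x$metadata$site_id))))
  invisible(x)
}

#' Write a dataset to a directory as TSV files
#'
#' Inverse of [load_dataset()]; emits `otus.tsv`, `taxonomy.tsv`,
#' `metadata.tsv`, `ct.tsv`, `panel.tsv`, `abs_16s.tsv` (and `truth.json` if
#' the dataset carries synthetic ground truth).
#'
#' @param dataset an `invanet_dataset`.
#' @param dir output directory, created if missing.
#' @return named list of written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    otus = file.path(dir, "otus.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    ct = file.path(dir, "ct.tsv"),
    panel = file.path(dir, "panel.tsv"),
    abs_16s = file.path(dir, "abs_16s.tsv")
  )
  write_feature_table(dataset$otus, paths$otus)
  write_taxonomy(dataset$taxonomy, paths$taxonomy)
  write_metadata(dataset$metadata, paths$metadata)
  write_ct_table(dataset$ct, paths$ct)
  write_panel(dataset$panel, paths$panel)
  utils::write.table(
    data.frame(sample_id = names(dataset$abs_16s), copies = dataset$abs_16s),
    paths$abs_16s, sep = "\t", quote = FALSE, row.names = FALSE
  )
  if (!is.null(dataset$truth)) {
    jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}
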