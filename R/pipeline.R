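#' Run the full analysis pipeline
#'
#' Orchestrates every stage of the survey analysis from one configuration:
#' data (simulated or loaded) -> qPCR quantification -> community diversity
#' (rarefaction, alpha indices, Bray-Curtis/PCoA/ANOSIM, Kruskal-Wallis
#' screens) -> per-group co-occurrence networks (functional molecular
#' ecological network with OTUs + genes, and the gene-gene network) with
#' topology and keystone taxa -> driver importance, keystone-gene
#' regression and RDA -> spatial interpolation and the north-south
#' contrast. One global seed deterministically derives per-stage seeds
#' (`seed * 1000 + stage index`), so identical configurations produce
#' identical reports and stages can be re-run in isolation.
#'
#' @param config a list, or path to a YAML file, with optional blocks:
#'   `simulate` ([synth_config()] arguments), `paths` (for
#'   [load_dataset()]), `seed` (global seed, default 1), `rarefy_depth`,
#'   `anosim_permutations`, `network` ([network_config()] arguments),
#'   `drivers` (`method`, `n_trees`, `n_perm`), `spatial` (`power`,
#'   `grid_rows`, `grid_cols`), `output_dir` (when set, artifacts — TSV
#'   tables, GraphML networks, ASCII rasters and `report.json` — are
#'   written there).
#' @return the report, an `invanet_report` list.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1L
  stage_seed <- function(i) derive_seed(seed, i)
  out_dir <- config$output_dir

  # --- stage 1: data --------------------------------------------------
  dataset <- tryCatch({
    if (!is.null(config$simulate)) {
      cfg <- do.call(synth_config,
                     c(config$simulate,
                       list(seed = config$simulate$seed %||% stage_seed(1L))))
      generate_dataset(cfg)$dataset
    } else if (!is.null(config$paths)) {
      load_dataset(config$paths)
    } else {
      invanet_error("invanet_invalid_config",
                    "config needs a 'simulate' block or input 'paths'")
    }
  }, invanet_error = function(e) {
    invanet_error("invanet_stage_failure",
                  sprintf("stage 'data' failed: %s (check the simulate/paths block)",
                          conditionMessage(e)))
  })
  meta <- dataset$metadata[match(rownames(dataset$otus),
                                 dataset$metadata$sample_id), ]
  groups <- meta$group

  # --- stage 2: qmec --------------------------------------------------
  qm <- tryCatch({
    ct <- qc_filter(dataset$ct, dataset$panel)
    quant <- quantify(ct, dataset$panel, dataset$abs_16s)
    cats <- aggregate_categories(quant, dataset$panel)
    list(quant = quant, categories = cats)
  }, invanet_error = function(e) {
    invanet_error("invanet_stage_failure",
                  sprintf("stage 'qmec' failed: %s (check CT table and panel)",
                          conditionMessage(e)))
  })
  samp <- rownames(dataset$otus)
  gene_abs <- qm$quant$absolute[samp, , drop = FALSE]
  cat_ab <- qm$categories$abundance[samp, , drop = FALSE]

  # --- stage 3: community ---------------------------------------------
  comm <- {
    rare <- rarefy(dataset$otus, depth = config$rarefy_depth,
                   seed = stage_seed(3L))
    alpha <- alpha_diversity(rare)
    dm <- bray_curtis(rare)
    keep <- rownames(rare)
    grp_rare <- groups[match(keep, samp)]
    ord <- pcoa(dm)
    an <- anosim(dm, grp_rare,
                 n_permutations = config$anosim_permutations %||% 999,
                 seed = stage_seed(31L),
                 strata = meta$site_id[match(keep, samp)])
    kw_phylum <- kruskal_wallis_screen(dataset$otus, groups,
                                       taxonomy = dataset$taxonomy,
                                       rank = "phylum", top_n = 10)
    kw_family <- kruskal_wallis_screen(dataset$otus, groups,
                                       taxonomy = dataset$taxonomy,
                                       rank = "family", top_n = 20)
    list(alpha = alpha, ordination = ord, anosim = an,
         kw_phylum = kw_phylum, kw_family = kw_family)
  }

  # --- stage 4: networks + keystones ----------------------------------
  net_args <- config$network %||% list()
  fmen_cfg <- do.call(network_config, c(net_args, list(preset = "fmen")))
  gene_cfg <- do.call(network_config,
                      c(net_args[setdiff(names(net_args), "r_min")],
                        list(preset = "genenet")))
  per_group <- lapply(c(AP = "AP", N = "N"), function(g) {
    rows <- samp[groups == g]
    otus_g <- feature_table(ft_values(dataset$otus)[rows, , drop = FALSE],
                            kind = "otu", units = "reads")
    genes_g <- feature_table(gene_abs[rows, , drop = FALSE],
                             kind = "gene", units = "copies_per_gram")
    fmen <- build_network(otus_g, genes_g, fmen_cfg)
    genenet <- build_network(genes = genes_g, config = gene_cfg)
    ks <- if (any(fmen$nodes$kind == "otu")) {
      keystone_taxa(fmen, k = 5, taxonomy = dataset$taxonomy)
    } else NULL
    list(
      fmen = fmen,
      fmen_topology = if (nrow(fmen$nodes)) topology(fmen) else NULL,
      genenet = genenet,
      genenet_topology = if (nrow(genenet$nodes)) topology(genenet) else NULL,
      keystones = ks
    )
  })
  recovery <- if (!is.null(dataset$truth)) {
    lapply(c(AP = "AP", N = "N"), function(g) {
      ks <- per_group[[g]]$keystones
      if (is.null(ks)) return(NA_integer_)
      sum(ks$keystone %in% dataset$truth$keystones[[g]])
    })
  } else NULL

  # --- stage 5: drivers ------------------------------------------------
  drv_args <- config$drivers %||% list()
  drv <- lapply(c(AP = "AP", N = "N"), function(g) {
    rows <- samp[groups == g]
    ks <- per_group[[g]]$keystones
    rel <- ft_values(dataset$otus)[rows, , drop = FALSE]
    rel <- rel / rowSums(rel)
    edaphic <- as.matrix(meta[match(rows, meta$sample_id), edaphic_vars()])
    rownames(edaphic) <- rows
    preds <- edaphic
    if (!is.null(ks)) {
      ks_rel <- rel[, ks$keystone, drop = FALSE]
      preds <- cbind(ks_rel, edaphic)
    }
    response <- rowSums(gene_abs[rows, , drop = FALSE])
    imp <- importance(preds, response,
                      method = drv_args$method %||% "rf_permutation",
                      n_trees = drv_args$n_trees %||% 500,
                      n_perm = drv_args$n_perm %||% 99,
                      seed = stage_seed(5L))
    reg <- if (!is.null(ks)) {
      keystone_gene_regression(rel[, ks$keystone, drop = FALSE] , response,
                               zero_policy = "pseudo")
    } else NULL
    rd <- rda_genes(cat_ab[rows, , drop = FALSE], edaphic,
                    n_perm = drv_args$n_perm %||% 99, seed = stage_seed(51L))
    list(importance = imp, regression = reg,
         rda = list(proportion_constrained = rd$proportion_constrained,
                    p_value = rd$p_value))
  })

  # --- stage 6: spatial ------------------------------------------------
  sp_args <- config$spatial %||% list()
  spat <- lapply(c(AP = "AP", N = "N"), function(g) {
    rows <- samp[groups == g]
    m <- meta[match(rows, meta$sample_id), ]
    fields <- lapply(colnames(cat_ab), function(cc) {
      idw(data.frame(lon = m$lon, lat = m$lat, value = cat_ab[rows, cc]),
          power = sp_args$power %||% 2)
    })
    names(fields) <- colnames(cat_ab)
    contrast <- north_south_contrast(cat_ab[rows, , drop = FALSE], m$lat,
                                     split_latitude = sp_args$split_latitude)
    list(fields = fields, contrast = contrast)
  })
  # pooled contrast over all samples: twice the stratum size of the
  # per-group versions, hence the better-calibrated gradient readout
  spat$combined <- list(
    fields = NULL,
    contrast = north_south_contrast(cat_ab, meta$lat,
                                    split_latitude = sp_args$split_latitude)
  )

  report <- build_report(seed, config, dataset, qm, comm, per_group,
                         recovery, drv, spat)
  if (!is.null(out_dir)) {
    write_pipeline_artifacts(out_dir, dataset, comm, per_group, spat, report)
  }
  report
}

build_report <- function(seed, config, dataset, qm, comm, per_group,
                         recovery, drv, spat) {
  topo_list <- function(t) if (is.null(t)) NULL else unclass(t)
  structure(list(
    seed = seed,
    parameters = list(
      rarefy_depth = config$rarefy_depth,
      anosim_permutations = config$anosim_permutations %||% 999,
      network = config$network %||% list(),
      drivers = config$drivers %||% list(),
      spatial = config$spatial %||% list()
    ),
    design = list(
      n_samples = nrow(dataset$otus),
      n_sites = length(unique(dataset$metadata$site_id)),
      n_otus = ncol(dataset$otus),
      n_assays = ncol(dataset$ct)
    ),
    qmec = list(
      detected_fraction = mean(qm$quant$detected),
      detected_genes_per_category = as.list(qm$categories$detected_genes)
    ),
    community = list(
      alpha = comm$alpha,
      anosim = comm$anosim,
      proportion_explained = comm$ordination$proportion_explained[1:2],
      kw_phylum = comm$kw_phylum,
      kw_family = comm$kw_family
    ),
    network = lapply(per_group, function(pg) {
      list(fmen_topology = topo_list(pg$fmen_topology),
           genenet_topology = topo_list(pg$genenet_topology),
           keystones = pg$keystones)
    }),
    keystone_recovery = recovery,
    drivers = drv,
    spatial = lapply(spat, function(s) list(contrast = s$contrast))
  ), class = "invanet_report")
}

write_pipeline_artifacts <- function(out_dir, dataset, comm, per_group,
                                     spat, report) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(comm$alpha, file.path(out_dir, "alpha_diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  coords <- data.frame(sample_id = rownames(comm$ordination$coordinates),
                       comm$ordination$coordinates[, 1:2, drop = FALSE])
  utils::write.table(coords, file.path(out_dir, "pcoa_coordinates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (g in names(per_group)) {
    write_network(per_group[[g]]$fmen,
                  file.path(out_dir, sprintf("fmen_%s.graphml", g)))
    write_network(per_group[[g]]$genenet,
                  file.path(out_dir, sprintf("genenet_%s.graphml", g)))
    if (!is.null(per_group[[g]]$keystones)) {
      utils::write.table(per_group[[g]]$keystones,
                         file.path(out_dir, sprintf("keystones_%s.tsv", g)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    for (cc in names(spat[[g]]$fields)) {
      write_ascii_grid(spat[[g]]$fields[[cc]],
                       file.path(out_dir, sprintf("idw_%s_%s.asc", g, cc)))
    }
  }
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  invisible(out_dir)
}

#' Check a pipeline report against the bundled schema
#'
#' Structural validation: required keys and value types per the schema
#' shipped at `inst/schema/report_schema.json`. (A light checker, not a
#' full JSON-Schema engine.)
#'
#' @param report an `invanet_report` (or a list parsed from report.json).
#' @return `TRUE` invisibly; fails with the missing/ill-typed keys named.
#' @export
validate_report <- function(report) {
  schema_path <- system.file("schema", "report_schema.json",
                             package = "invanet")
  schema <- jsonlite::read_json(schema_path)
  problems <- character()
  check <- function(obj, spec, prefix) {
    for (key in names(spec$required)) {
      if (!key %in% names(obj) || is.null(obj[[key]])) {
        problems <<- c(problems, sprintf("%s%s missing", prefix, key))
        next
      }
      want <- spec$required[[key]]
      if (is.character(want) && want == "number" &&
          !is.numeric(unlist(obj[[key]]))) {
        problems <<- c(problems, sprintf("%s%s is not numeric", prefix, key))
      }
      if (is.list(want)) {
        check(obj[[key]], want, paste0(prefix, key, "."))
      }
    }
  }
  check(report, schema, "")
  if (length(problems)) {
    invanet_error("invanet_invalid_report",
                  paste("report fails schema:", paste(problems, collapse = "; ")))
  }
  invisible(TRUE)
}
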