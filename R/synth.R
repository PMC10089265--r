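#' Configuration for the synthetic paired-design generator
#'
#' Describes a survey of `n_sites` sites, each contributing one invaded
#' (`AP`) and one native (`N`) rhizosphere sample, an OTU community, and a
#' CNPS qPCR panel. The generator plants three kinds of recoverable
#' structure:
#'
#' * **Keystones** — `k_planted` OTUs per group load, with weight
#'   `keystone_loading` (lambda), onto a per-sample latent factor that also
#'   drives every functional gene's abundance. In co-occurrence networks
#'   built per group these OTUs become high-degree hubs.
#' * **Group effects** — `group_effect` (delta, log-scale shift) raises
#'   designated responder phyla (Bacteroidetes, Nitrospirae) and lowers
#'   Actinobacteria in invaded samples, and shifts edaphic ammonium (AN)
#'   between groups; in invaded samples AN is additionally negatively
#'   coupled to the gene-driving latent factor.
#' * **Spatial gradient** — `spatial_gradient` (gamma, log units per degree
#'   latitude) tilts the configured gene categories from south to north.
#'
#' @param n_sites number of paired sites (default 22, i.e. 44 samples).
#' @param n_otus number of OTUs in the community.
#' @param panel panel data.frame (default [qmec_panel()]).
#' @param k_planted planted keystones per group.
#' @param keystone_loading lambda in `[0, 1]`.
#' @param group_effect delta, log-scale responder-phylum and AN shift.
#' @param spatial_gradient gamma, log units per degree latitude.
#' @param gradient_categories gene categories carrying the gradient.
#' @param depth_mean,depth_cv sequencing-depth lognormal distribution.
#' @param site_sd per-site random-effect standard deviation (log units).
#' @param otu_noise_sd,gene_noise_sd residual log-scale noise.
#' @param an_coupling strength of the negative AN-gene coupling in invaded
#'   samples.
#' @param bbox study bounding box `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param seed RNG seed; mandatory.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_sites = 22, n_otus = 300, panel = qmec_panel(),
                         k_planted = 5, keystone_loading = 0.9,
                         group_effect = 0.5, spatial_gradient = 1,
                         gradient_categories = c("C_degradation", "C_fixation",
                                                 "C_methane", "P"),
                         depth_mean = 20000, depth_cv = 0.1,
                         site_sd = 0.3, otu_noise_sd = 0.5,
                         gene_noise_sd = 0.5, an_coupling = 0.5,
                         bbox = c(116.36, 117.85, 38.74, 40.04),
                         seed = NULL) {
  if (is.null(seed)) {
    invanet_error("invanet_invalid_config", "synth_config requires an explicit seed")
  }
  cfg <- list(n_sites = as.integer(n_sites), n_otus = as.integer(n_otus),
              panel = validate_panel(panel), k_planted = as.integer(k_planted),
              keystone_loading = keystone_loading, group_effect = group_effect,
              spatial_gradient = spatial_gradient,
              gradient_categories = gradient_categories,
              depth_mean = depth_mean, depth_cv = depth_cv, site_sd = site_sd,
              otu_noise_sd = otu_noise_sd, gene_noise_sd = gene_noise_sd,
              an_coupling = an_coupling, bbox = bbox, seed = as.integer(seed))
  if (cfg$n_sites < 2 || cfg$n_otus < 10) {
    invanet_error("invanet_invalid_config", "need at least 2 sites and 10 OTUs")
  }
  if (cfg$k_planted > cfg$n_otus) {
    invanet_error("invanet_invalid_config", "k_planted cannot exceed n_otus")
  }
  if (cfg$keystone_loading < 0 || cfg$keystone_loading > 1) {
    invanet_error("invanet_invalid_config", "keystone_loading must lie in [0, 1]")
  }
  for (v in c("group_effect", "spatial_gradient", "depth_cv", "site_sd",
              "otu_noise_sd", "gene_noise_sd", "an_coupling")) {
    if (cfg[[v]] < 0) {
      invanet_error("invanet_invalid_config", sprintf("%s must be >= 0", v))
    }
  }
  structure(cfg, class = "synth_config")
}

synth_phyla <- function() {
  list(
    Proteobacteria   = c("Rhizobiales", "Sphingomonadales", "Myxococcales"),
    Bacteroidetes    = c("Chitinophagales", "Sphingobacteriales"),
    Acidobacteria    = c("Acidobacteriales", "Blastocatellales"),
    Actinobacteria   = c("Kineosporiales", "Micrococcales", "Solirubrobacterales"),
    Chloroflexi      = c("Anaerolineales", "SBR1031"),
    Gemmatimonadetes = c("Gemmatimonadales", "Longimicrobiales"),
    Nitrospirae      = "Nitrospirales",
    Verrucomicrobia  = "Chthoniobacterales",
    Planctomycetes   = "Planctomycetales",
    Armatimonadetes  = "Armatimonadales",
    Firmicutes       = "Bacillales"
  )
}

responder_phyla <- function() {
  c(Bacteroidetes = 1, Nitrospirae = 1, Actinobacteria = -1)
}

#' Generate a synthetic paired-design dataset
#'
#' Draws a full dataset — OTU counts, taxonomy, sample metadata with edaphic
#' variables and coordinates, qPCR CT table, panel and absolute 16S copies —
#' from a latent-factor log-abundance model (Gaussian copula on log
#' abundances, multinomial counts at a drawn depth), together with the
#' ground truth needed to score recovery.
#'
#' Per sample `s` with latent factor `f_s ~ N(0,1)`, site effect
#' `u_{site(s),j} ~ N(0, site_sd^2)` shared by the two paired samples, the
#' log relative abundance of OTU `j` is
#' `alpha_j + lambda f_s [j in keystones(group_s)] + delta dir(phylum_j) [group_s = AP]
#'  + u_{site(s),j} + noise`; counts are multinomial at the sample's drawn
#' depth. Gene log absolute abundances share the same `lambda f_s` plus the
#' latitude gradient for configured categories. CT values are produced by
#' inverting the quantification chain ([invert_quantification()]), so
#' [quantify()] recovers the planted gene abundances exactly.
#'
#' @param cfg a [synth_config()].
#' @return list with elements `dataset` (an `invanet_dataset`) and `truth`
#'   (planted keystone ids per group, the parameters used, per-sample latent
#'   factors, planted gene abundances).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$seed, {
    n_sites <- cfg$n_sites
    n <- 2L * n_sites
    site_ids <- sprintf("site%02d", seq_len(n_sites))
    groups <- rep(c("AP", "N"), n_sites)
    sample_sites <- rep(site_ids, each = 2L)
    sample_ids <- paste(sample_sites, groups, sep = "_")

    lon <- stats::runif(n_sites, cfg$bbox[1], cfg$bbox[2])
    lat <- stats::runif(n_sites, cfg$bbox[3], cfg$bbox[4])

    # --- taxonomy -----------------------------------------------------
    phyla_pool <- synth_phyla()
    phylum_w <- c(0.30, 0.15, 0.12, 0.12, 0.08, 0.06, 0.04, 0.04, 0.03, 0.03, 0.03)
    otu_ids <- sprintf("OTU_%d", seq_len(cfg$n_otus))
    phylum <- sample(names(phyla_pool), cfg$n_otus, replace = TRUE,
                     prob = phylum_w)
    ord <- vapply(phylum, function(p) {
      pool <- phyla_pool[[p]]
      pool[sample.int(length(pool), 1L)]
    }, character(1))
    taxonomy <- data.frame(
      otu_id = otu_ids, phylum = phylum, class = "unclassified", order = ord,
      family = "unclassified", genus = "unclassified",
      species = "unclassified", stringsAsFactors = FALSE
    )

    # --- planted structure --------------------------------------------
    ks_all <- sample(otu_ids, 2L * cfg$k_planted)
    keystones <- list(AP = ks_all[seq_len(cfg$k_planted)],
                      N = ks_all[cfg$k_planted + seq_len(cfg$k_planted)])
    alpha <- stats::rnorm(cfg$n_otus, 0, 1.2)
    names(alpha) <- otu_ids
    # keystones get a moderate baseline so they survive prevalence filtering
    alpha[ks_all] <- 0.5
    f <- stats::rnorm(n)
    names(f) <- sample_ids

    # --- OTU counts ----------------------------------------------------
    dir <- responder_phyla()
    shift <- rep(0, cfg$n_otus)
    for (p in names(dir)) shift[phylum == p] <- dir[[p]] * cfg$group_effect
    u_site <- matrix(stats::rnorm(n_sites * cfg$n_otus, 0, cfg$site_sd),
                     n_sites, cfg$n_otus, dimnames = list(site_ids, otu_ids))
    L <- matrix(rep(alpha, each = n), n, cfg$n_otus,
                dimnames = list(sample_ids, otu_ids))
    for (g in c("AP", "N")) {
      rows <- groups == g
      L[rows, keystones[[g]]] <- L[rows, keystones[[g]]] +
        cfg$keystone_loading * f[rows]
    }
    L[groups == "AP", ] <- sweep(L[groups == "AP", , drop = FALSE], 2, shift, `+`)
    L <- L + u_site[sample_sites, ] +
      matrix(stats::rnorm(n * cfg$n_otus, 0, cfg$otu_noise_sd), n, cfg$n_otus)
    depth <- pmax(100L, round(stats::rlnorm(n, log(cfg$depth_mean),
                                            cfg$depth_cv)))
    counts <- matrix(0, n, cfg$n_otus, dimnames = list(sample_ids, otu_ids))
    for (i in seq_len(n)) {
      p_i <- exp(L[i, ] - max(L[i, ]))
      counts[i, ] <- stats::rmultinom(1, depth[i], p_i)[, 1]
    }
    otus <- feature_table(counts, kind = "otu", units = "reads")

    # --- functional genes ---------------------------------------------
    panel <- cfg$panel
    gene_assays <- panel$assay_id[panel$category != "reference_16S"]
    gene_cat <- stats::setNames(panel$category, panel$assay_id)[gene_assays]
    n_genes <- length(gene_assays)
    beta <- stats::rnorm(n_genes, 16, 1)
    lat_c <- lat[match(sample_sites, site_ids)] - mean(cfg$bbox[3:4])
    grad <- as.numeric(gene_cat %in% cfg$gradient_categories)
    G <- outer(rep(1, n), beta) +
      cfg$keystone_loading * matrix(f, n, n_genes) +
      cfg$spatial_gradient * outer(lat_c, grad) +
      matrix(stats::rnorm(n * n_genes, 0, cfg$gene_noise_sd), n, n_genes)
    gene_abs <- exp(G)
    dimnames(gene_abs) <- list(sample_ids, gene_assays)

    # --- qPCR chain ----------------------------------------------------
    abs_16s <- stats::setNames(stats::rlnorm(n, log(1e9), 0.3), sample_ids)
    ct_16s <- stats::setNames(stats::rnorm(n, 20, 0.5), sample_ids)
    ct <- invert_quantification(gene_abs, panel, abs_16s, ct_16s = ct_16s)

    # --- metadata -------------------------------------------------------
    f_std <- (f - mean(f)) / stats::sd(f)
    an <- 8 + cfg$group_effect * (groups == "AP") -
      cfg$an_coupling * f_std * (groups == "AP") +
      stats::rnorm(n, 0, 1)
    metadata <- data.frame(
      sample_id = sample_ids, site_id = sample_sites, group = groups,
      lon = lon[match(sample_sites, site_ids)],
      lat = lat[match(sample_sites, site_ids)],
      pH = stats::rnorm(n, 8.1, 0.3),
      TC = stats::rlnorm(n, log(15), 0.3),
      TN = stats::rlnorm(n, log(1.2), 0.3),
      TP = stats::rlnorm(n, log(0.8), 0.25),
      AN = pmax(0.1, an),
      NN = stats::rlnorm(n, log(10), 0.4),
      AP_P = stats::rlnorm(n, log(12), 0.5),
      stringsAsFactors = FALSE
    )

    truth <- list(
      keystones = keystones,
      lambda = cfg$keystone_loading,
      delta = cfg$group_effect,
      gamma = cfg$spatial_gradient,
      responder_phyla = as.list(responder_phyla()),
      gradient_categories = cfg$gradient_categories,
      latent = as.list(f),
      gene_abundance = gene_abs,
      seed = cfg$seed
    )
    dataset <- new_dataset(otus = otus, taxonomy = taxonomy,
                           metadata = metadata, ct = ct, panel = panel,
                           abs_16s = abs_16s, truth = truth)
    list(dataset = dataset, truth = truth)
  })
}

#' Invert the qPCR quantification chain
#'
#' Given planted absolute gene abundances, produces the CT table that
#' [quantify()] maps back to those abundances (to floating-point precision).
#' The reference 16S assay is assigned CT `ct_16s`; each gene's relative
#' copies follow from the absolute ratio, and its CT from inverting
#' \eqn{N_0 = E^{(threshold - CT)}}. Abundances of zero become non-detects
#' (CT above the detection threshold, encoded `NA` as on chip exports).
#'
#' @param abs_abundance samples x genes matrix of absolute copies (>= 0).
#' @param panel panel data.frame (supplies efficiencies and the reference).
#' @param abs_16s named per-sample absolute 16S copies (> 0).
#' @param ct_16s CT assigned to the reference assay (scalar or per sample).
#' @param threshold detection-threshold CT.
#' @return CT matrix (samples x assays) including the reference column.
#' @export
invert_quantification <- function(abs_abundance, panel, abs_16s,
                                  ct_16s = 20, threshold = 31) {
  panel <- validate_panel(panel)
  if (any(abs_abundance < 0, na.rm = TRUE)) {
    invanet_error("invanet_invalid_argument", "absolute abundances must be non-negative")
  }
  if (any(abs_16s <= 0)) {
    invanet_error("invanet_invalid_argument", "absolute 16S copies must be positive")
  }
  samples <- rownames(abs_abundance)
  ref_assay <- panel$assay_id[panel$category == "reference_16S"]
  eff <- stats::setNames(panel$efficiency, panel$assay_id)
  e_ref <- eff[[ref_assay]]
  ct_ref <- rep_len(ct_16s, length(samples))
  rel_16s <- e_ref^(threshold - ct_ref)
  genes <- colnames(abs_abundance)
  rel <- abs_abundance * (rel_16s / abs_16s[samples])
  e_g <- matrix(eff[genes], length(samples), length(genes), byrow = TRUE)
  ct_g <- threshold - log(rel) / log(e_g)
  ct_g[abs_abundance == 0] <- NA_real_
  ct <- cbind(ct_g, ct_ref)
  colnames(ct) <- c(genes, ref_assay)
  rownames(ct) <- samples
  ct
}
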