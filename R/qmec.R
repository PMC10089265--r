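#' Efficiency-based quality filter for qPCR assays
#'
#' Removes, for all samples, every assay whose amplification efficiency lies
#' outside the acceptance band: assays with efficiency below 1.8 or above
#' 2.2 are eliminated; the bounds themselves are retained. Removals are
#' reported via a message.
#'
#' @param ct CT matrix (samples x assays), `NA` = non-detect.
#' @param panel panel data.frame supplying per-assay `efficiency`.
#' @param e_min,e_max acceptance band for the fold-amplification per cycle.
#' @return the CT matrix restricted to retained assays.
#' @export
qc_filter <- function(ct, panel, e_min = 1.8, e_max = 2.2) {
  panel <- validate_panel(panel)
  eff <- stats::setNames(panel$efficiency, panel$assay_id)
  unknown <- setdiff(colnames(ct), names(eff))
  if (length(unknown)) {
    invanet_error("invanet_unknown_assay", sprintf(
      "assays absent from panel: %s", paste(unknown, collapse = ", ")
    ))
  }
  e <- eff[colnames(ct)]
  drop <- e < e_min | e > e_max
  if (any(drop)) {
    message(sprintf("qc_filter: removed %d assay(s) with efficiency outside [%g, %g]: %s",
                    sum(drop), e_min, e_max,
                    paste(colnames(ct)[drop], collapse = ", ")))
  }
  if (all(drop)) {
    warning("qc_filter: no assays pass the efficiency filter")
  }
  ct[, !drop, drop = FALSE]
}

#' Convert CT values to relative copy numbers
#'
#' A cycle threshold of 31 is the chip's detection threshold: CT values above
#' it (or missing) are non-detects and quantify to zero. Detected wells map
#' to relative copies \eqn{N_0 = E^{(31 - CT)}}, where `E` is the assay's
#' amplification efficiency (fold amplification per cycle; 2 means perfect
#' doubling). A CT exactly at the threshold therefore maps to one relative
#' copy.
#'
#' @param ct numeric vector (or matrix) of CT values; `NA` = non-detect.
#' @param efficiency amplification efficiency, scalar or one per column.
#' @param threshold detection-threshold CT.
#' @return relative copy numbers, same shape as `ct`.
#' @export
ct_to_relative <- function(ct, efficiency = 2, threshold = 31) {
  stopifnot_scalar_number(threshold, "threshold")
  if (threshold <= 0) {
    invanet_error("invanet_invalid_argument", "detection threshold must be positive")
  }
  if (any(efficiency <= 1, na.rm = TRUE)) {
    invanet_error("invanet_invalid_argument", "amplification efficiency must exceed 1")
  }
  if (is.matrix(ct)) {
    eff <- if (length(efficiency) == 1L) {
      matrix(efficiency, nrow(ct), ncol(ct))
    } else {
      matrix(efficiency, nrow(ct), ncol(ct), byrow = TRUE)
    }
  } else {
    eff <- efficiency
  }
  rel <- eff^(threshold - ct)
  rel[is.na(ct) | ct > threshold] <- 0
  rel
}

#' Absolute quantification of functional genes
#'
#' Runs the full quantification chain: CT values are converted to relative
#' copies per assay ([ct_to_relative()]), then referenced against the 16S
#' rRNA assay and scaled by the externally measured absolute 16S copy number
#' of each sample:
#' \deqn{abs_{gene} = N_{0,gene} \times abs_{16S} / N_{0,16S}.}
#'
#' @param ct CT matrix (samples x assays) including the reference assay.
#' @param panel panel data.frame with per-assay `category` and `efficiency`.
#' @param abs_16s named numeric vector of absolute 16S copies per sample.
#' @param threshold detection-threshold CT.
#' @return A `quant_result`: list with `relative` and `absolute` matrices
#'   (samples x functional assays), logical `detected` matrix, the
#'   efficiencies used, and `flagged_samples` (samples whose 16S reference
#'   was a non-detect; their absolute abundances are `NA`).
#' @export
quantify <- function(ct, panel, abs_16s, threshold = 31) {
  panel <- validate_panel(panel)
  ref_assay <- panel$assay_id[panel$category == "reference_16S"]
  if (!ref_assay %in% colnames(ct)) {
    invanet_error("invanet_unknown_assay",
                  sprintf("reference assay %s missing from CT table", ref_assay))
  }
  missing_abs <- setdiff(rownames(ct), names(abs_16s))
  if (length(missing_abs)) {
    invanet_error("invanet_invalid_argument", sprintf(
      "absolute 16S copies missing for samples: %s",
      paste(missing_abs, collapse = ", ")
    ))
  }
  if (any(abs_16s[rownames(ct)] <= 0, na.rm = TRUE)) {
    invanet_error("invanet_invalid_argument", "absolute 16S copy numbers must be positive")
  }
  eff <- stats::setNames(panel$efficiency, panel$assay_id)[colnames(ct)]
  rel <- ct_to_relative(ct, efficiency = eff, threshold = threshold)
  rel_16s <- rel[, ref_assay]
  flagged <- rownames(ct)[rel_16s == 0]
  if (length(flagged)) {
    warning(sprintf("16S reference non-detect in sample(s) %s; absolute abundances undefined there",
                    paste(flagged, collapse = ", ")))
  }
  gene_assays <- setdiff(colnames(ct), ref_assay)
  rel_genes <- rel[, gene_assays, drop = FALSE]
  scale <- abs_16s[rownames(ct)] / rel_16s
  scale[rel_16s == 0] <- NA_real_
  abs_genes <- rel_genes * scale
  structure(list(
    relative = rel_genes,
    absolute = abs_genes,
    detected = rel_genes > 0,
    efficiency = eff[gene_assays],
    reference_assay = ref_assay,
    flagged_samples = flagged
  ), class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("<quant_result> %d samples x %d assays (%.1f%% detected)\n",
              nrow(x$absolute), ncol(x$absolute),
              100 * mean(x$detected)))
  invisible(x)
}

#' Aggregate gene abundances into element-cycle categories
#'
#' Sums absolute copies per sample within each CNPS category
#' (C degradation, C fixation, methane metabolism, N, P, S) and counts the
#' detected genes per category.
#'
#' @param quant a `quant_result` from [quantify()].
#' @param panel panel data.frame.
#' @return list with `abundance` (samples x categories matrix) and
#'   `detected_genes` (categories -> number of genes detected in at least
#'   one sample).
#' @export
aggregate_categories <- function(quant, panel) {
  panel <- validate_panel(panel)
  cat_of <- stats::setNames(panel$category, panel$assay_id)
  assays <- colnames(quant$absolute)
  uncat <- setdiff(assays, names(cat_of))
  if (length(uncat)) {
    invanet_error("invanet_unknown_assay", sprintf(
      "uncategorized assays: %s", paste(uncat, collapse = ", ")
    ))
  }
  cats <- setdiff(panel_categories(), "reference_16S")
  ab <- matrix(0, nrow(quant$absolute), length(cats),
               dimnames = list(rownames(quant$absolute), cats))
  for (cc in cats) {
    members <- assays[cat_of[assays] == cc]
    if (length(members)) {
      ab[, cc] <- rowSums(quant$absolute[, members, drop = FALSE])
    }
  }
  detected <- vapply(cats, function(cc) {
    members <- assays[cat_of[assays] == cc]
    if (!length(members)) return(0L)
    sum(colSums(quant$detected[, members, drop = FALSE]) > 0)
  }, integer(1))
  list(abundance = ab, detected_genes = detected)
}
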