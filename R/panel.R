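#' The bundled CNPS qPCR panel
#'
#' Default panel definition for the high-throughput element-cycling chip:
#' 71 functional assays — 35 carbon-cycling (21 degradation, 10 fixation,
#' 4 methane metabolism), 22 nitrogen-cycling, 9 phosphorus-cycling and
#' 5 sulfur-cycling genes — plus one 16S rRNA reference assay. Assay ids are
#' the customary gene symbols for each pathway. Amplification efficiency
#' defaults to 2 (perfect doubling per cycle) for every assay; real chips
#' supply per-assay values, which [qc_filter()] screens against the 1.8-2.2
#' acceptance band.
#'
#' @param efficiency default amplification efficiency applied to all assays.
#' @return panel data.frame with columns `assay_id`, `category`,
#'   `efficiency`.
#' @export
qmec_panel <- function(efficiency = 2) {
  genes <- list(
    C_degradation = c(
      "amyA", "amyX", "apu", "sga", "abfA", "manB", "xylA", "xylB", "cex",
      "cdh", "chiA", "naglu", "exg", "pgu", "lig", "mnp", "glx", "pox",
      "bglX", "pel", "cda"
    ),
    C_fixation = c(
      "cbbL_R", "cbbL_G", "rbcL", "accA", "acsA", "acsB", "aclB", "korA",
      "prkB", "frdA"
    ),
    C_methane = c("mcrA", "pmoA", "mmoX", "mxaF"),
    N = c(
      "amoA_AOA", "amoA_AOB", "hao", "nxrA", "narG", "napA", "nirK", "nirS",
      "norB", "nosZ", "nrfA", "nifH", "nasA", "nirA", "nirB", "gdh", "ureC",
      "glnA", "nmo", "hzsB", "hdh", "anfG"
    ),
    P = c("phoD", "phoX", "phoN", "ppx", "ppk", "pqqC", "phnK", "phnX", "opd"),
    S = c("dsrA", "dsrB", "soxY", "aprA", "sqr"),
    reference_16S = "16S_rRNA"
  )
  panel <- data.frame(
    assay_id = unlist(genes, use.names = FALSE),
    category = rep(names(genes), lengths(genes)),
    efficiency = efficiency,
    stringsAsFactors = FALSE
  )
  validate_panel(panel)
}
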