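#' Write an ecological network to GraphML
#'
#' Serialises an [eco_network()] so that Gephi, Cytoscape or igraph can open
#' it. Node attributes `kind` and `mean_abundance` and edge attributes `rho`,
#' `p_raw`, `q` and `sign` are declared as GraphML keys. Numeric attributes
#' are written with 17 significant digits, so [read_network()] reproduces the
#' network exactly.
#'
#' @param net an [eco_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "eco_network"))
  num <- function(x) sprintf("%.17g", x)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
    "  <key id=\"kind\" for=\"node\" attr.name=\"kind\" attr.type=\"string\"/>",
    "  <key id=\"mean_abundance\" for=\"node\" attr.name=\"mean_abundance\" attr.type=\"double\"/>",
    "  <key id=\"rho\" for=\"edge\" attr.name=\"rho\" attr.type=\"double\"/>",
    "  <key id=\"p_raw\" for=\"edge\" attr.name=\"p_raw\" attr.type=\"double\"/>",
    "  <key id=\"q\" for=\"edge\" attr.name=\"q\" attr.type=\"double\"/>",
    "  <key id=\"sign\" for=\"edge\" attr.name=\"sign\" attr.type=\"string\"/>",
    "  <graph id=\"G\" edgedefault=\"undirected\">"
  )
  n <- net$nodes
  node_lines <- sprintf(
    paste0("    <node id=\"%s\"><data key=\"kind\">%s</data>",
           "<data key=\"mean_abundance\">%s</data></node>"),
    esc(n$id), esc(n$kind), num(n$mean_abundance)
  )
  e <- net$edges
  edge_lines <- if (nrow(e)) sprintf(
    paste0("    <edge source=\"%s\" target=\"%s\">",
           "<data key=\"rho\">%s</data><data key=\"p_raw\">%s</data>",
           "<data key=\"q\">%s</data><data key=\"sign\">%s</data></edge>"),
    esc(e$from), esc(e$to), num(e$rho), num(e$p_raw), num(e$q), esc(e$sign)
  ) else character()
  lines <- c(lines, node_lines, edge_lines, "  </graph>", "</graphml>")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  if (!file.exists(path)) {
    invanet_error("invanet_missing_file", sprintf("file not found: %s", path))
  }
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, ".//graph/node")
  data_of <- function(el, key) {
    xml2::xml_text(xml2::xml_find_first(el, sprintf("./data[@key='%s']", key)))
  }
  node_df <- data.frame(
    id = xml2::xml_attr(nodes, "id"),
    kind = vapply(nodes, data_of, character(1), key = "kind"),
    mean_abundance = as.numeric(vapply(nodes, data_of, character(1),
                                       key = "mean_abundance")),
    stringsAsFactors = FALSE
  )
  edges <- xml2::xml_find_all(doc, ".//graph/edge")
  edge_df <- data.frame(
    from = xml2::xml_attr(edges, "source"),
    to = xml2::xml_attr(edges, "target"),
    rho = as.numeric(vapply(edges, data_of, character(1), key = "rho")),
    p_raw = as.numeric(vapply(edges, data_of, character(1), key = "p_raw")),
    q = as.numeric(vapply(edges, data_of, character(1), key = "q")),
    sign = vapply(edges, data_of, character(1), key = "sign"),
    stringsAsFactors = FALSE
  )
  eco_network(node_df, edge_df)
}
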