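#' Export a sub-network to XGMML or GraphML
#'
#' Writes a well-formed XML graph file. Node attributes carry the molecular
#' role, module membership and (when supplied) the normalized fold change;
#' edge attributes carry the common-linkage weight and, when available, the
#' edge provenance. GraphML files round-trip through
#' [igraph::read_graph()] losslessly for topology and attributes.
#'
#' @param subnet A non-empty `subnetwork`.
#' @param file Output path.
#' @param format `"xgmml"` or `"graphml"`.
#' @param module Optional `deg_module` used to mark module membership.
#' @param fc_norm Optional named numeric vector of normalized fold changes.
#' @param roles Optional named character vector gene -> role (e.g. from
#'   [network_roles()]).
#' @param provenance Optional named character vector keyed by
#'   `edge_key(from, to)`.
#' @return The output path, invisibly.
#' @export
export_network <- function(subnet, file,
                           format = c("xgmml", "graphml"),
                           module = NULL, fc_norm = NULL, roles = NULL,
                           provenance = NULL) {
  if (!format[1L] %in% c("xgmml", "graphml")) {
    stop("unknown format '", format[1L],
         "'; supported formats: xgmml, graphml", call. = FALSE)
  }
  format <- match.arg(format)
  stopifnot(inherits(subnet, "subnetwork"))
  if (length(subnet$nodes) == 0L) {
    stop("cannot export an empty sub-network", call. = FALSE)
  }
  nodes <- subnet$nodes
  node_role <- if (is.null(roles)) rep("other", length(nodes)) else
    unname(ifelse(nodes %in% names(roles), roles[nodes], "other"))
  in_module <- if (is.null(module)) nodes %in% subnet$covered_genes else
    nodes %in% module$gene
  nfc <- if (is.null(fc_norm)) rep(NA_real_, length(nodes)) else
    unname(fc_norm[nodes])
  ed <- subnet$edges
  eprov <- if (is.null(provenance)) rep("reference", nrow(ed)) else
    unname(ifelse(edge_key(ed$from, ed$to) %in% names(provenance),
                  provenance[edge_key(ed$from, ed$to)], "reference"))

  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      ed[c("from", "to")], directed = FALSE,
      vertices = data.frame(name = nodes, role = node_role,
                            in_module = as.character(in_module),
                            norm_fc = ifelse(is.na(nfc), "", nfc),
                            stringsAsFactors = FALSE))
    igraph::E(g)$cl <- ed$cl
    igraph::E(g)$provenance <- eprov
    igraph::write_graph(g, file, format = "graphml")
    return(invisible(file))
  }

  doc <- xml2::xml_new_root(
    "graph",
    label = sprintf("%s_%s", subnet$regulator, subnet$module_id),
    directed = "0",
    xmlns = "http://www.cs.rpi.edu/XGMML")
  for (i in seq_along(nodes)) {
    nd <- xml2::xml_add_child(doc, "node", id = nodes[i], label = nodes[i])
    xml2::xml_add_child(nd, "att", name = "role", type = "string",
                        value = node_role[i])
    xml2::xml_add_child(nd, "att", name = "in_module", type = "boolean",
                        value = tolower(as.character(in_module[i])))
    if (!is.na(nfc[i])) {
      xml2::xml_add_child(nd, "att", name = "norm_fc", type = "real",
                          value = format(nfc[i], digits = 10))
    }
  }
  for (i in seq_len(nrow(ed))) {
    eg <- xml2::xml_add_child(doc, "edge", source = ed$from[i],
                              target = ed$to[i],
                              label = paste(ed$from[i], ed$to[i], sep = "-"))
    xml2::xml_add_child(eg, "att", name = "cl", type = "real",
                        value = format(ed$cl[i], digits = 10))
    xml2::xml_add_child(eg, "att", name = "provenance", type = "string",
                        value = eprov[i])
  }
  xml2::write_xml(doc, file)
  invisible(file)
}
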