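ROLE_LEVELS <- c("receptor", "transcription_factor", "transporter", "other")
TISSUE_CLASSES <- c("TE", "GE", "TEn")

# Normalize free-text role labels (case-insensitive, spaces/dashes tolerated).
normalize_roles <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[ -]+", "_", x)
  x[x %in% c("tf", "transcriptionfactor")] <- "transcription_factor"
  x[!x %in% ROLE_LEVELS] <- "other"
  x
}

new_interactome <- function(graph) {
  stopifnot(igraph::is_igraph(graph))
  structure(list(graph = graph), class = "interactome")
}

#' Load a reference interactome from an edge list and a role table
#'
#' Reads a tab-separated edge list (two or more columns; extra columns and
#' `#` comment lines are ignored), collapses duplicate edges, drops
#' self-loops, and attaches a molecular role to every node. The network is
#' undirected throughout: any orientation implied by the column order of the
#' edge file is discarded. Typical reference interactomes at full scale
#' comprise on the order of 6000 proteins and 63000 interactions.
#'
#' @param edge_file Path to a TSV with gene identifiers in the first two
#'   columns. Lines starting with `#` are skipped.
#' @param role_file Optional path to a two-column TSV `gene<TAB>role`. Role
#'   names are case-insensitive; recognised roles are `receptor`,
#'   `transcription_factor` (also `TF`), `transporter`; anything else maps to
#'   `other`. Genes absent from the file default to `other`.
#' @return An `interactome` object: an undirected [igraph][igraph::igraph]
#'   graph with vertex attribute `role` and edge attribute `provenance`
#'   (all `"reference"` after loading).
#' @examples
#' ef <- tempfile(); writeLines(c("a\tb", "b\ta", "c\tc", "b\td"), ef)
#' rf <- tempfile(); writeLines("a\treceptor", rf)
#' net <- load_network(ef, rf)
#' network_size(net)  # duplicate b-a collapsed, self-loop c-c dropped
#' @export
load_network <- function(edge_file, role_file = NULL) {
  ed <- read_tsv_pairs(edge_file, 2L, what = "edge")
  a <- ed$fields[, 1L]
  b <- ed$fields[, 2L]
  keep <- a != b                       # drop self-loops
  if (!any(keep)) {
    stop("edge file ", edge_file, " contains no usable (non-self-loop) edges",
         call. = FALSE)
  }
  df <- unique(data.frame(from = pmin(a[keep], b[keep]),
                          to = pmax(a[keep], b[keep]),
                          stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  igraph::E(g)$provenance <- "reference"

  roles <- stats::setNames(rep("other", igraph::vcount(g)),
                           igraph::V(g)$name)
  if (!is.null(role_file)) {
    rf <- read_tsv_pairs(role_file, 2L, what = "role")
    rn <- normalize_roles(rf$fields[, 2L])
    hit <- rf$fields[, 1L] %in% names(roles)
    roles[rf$fields[hit, 1L]] <- rn[hit]
  }
  igraph::V(g)$role <- unname(roles[igraph::V(g)$name])
  new_interactome(g)
}

#' @export
print.interactome <- function(x, ...) {
  g <- x$graph
  cat(sprintf("Interactome: %d nodes, %d edges (undirected)\n",
              igraph::vcount(g), igraph::ecount(g)))
  tab <- table(factor(igraph::V(g)$role, levels = ROLE_LEVELS))
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  prov <- table(igraph::E(g)$provenance)
  if (length(prov)) {
    cat("  provenance:",
        paste(sprintf("%s=%d", names(prov), prov), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Nodes, edges, roles and size of an interactome
#'
#' Small accessors used throughout the pipeline.
#'
#' @param net An `interactome`.
#' @return `network_nodes`: character vector of gene identifiers.
#'   `network_edges`: two-column data frame (`from`, `to`) plus `provenance`.
#'   `network_roles`: named character vector gene -> role.
#'   `network_size`: named integer vector `c(nodes, edges)`.
#' @export
network_nodes <- function(net) igraph::V(net$graph)$name

#' @rdname network_nodes
#' @export
network_edges <- function(net) {
  el <- igraph::as_edgelist(net$graph)
  data.frame(from = el[, 1L], to = el[, 2L],
             provenance = igraph::E(net$graph)$provenance,
             stringsAsFactors = FALSE)
}

#' @rdname network_nodes
#' @export
network_roles <- function(net) {
  stats::setNames(igraph::V(net$graph)$role, igraph::V(net$graph)$name)
}

#' @rdname network_nodes
#' @export
network_size <- function(net) {
  c(nodes = igraph::vcount(net$graph), edges = igraph::ecount(net$graph))
}

#' Expand the reference network with module-incident supplementary edges
#'
#' Supplementary interaction sources (BioGRID-style gene-gene pairs) are used
#' to improve the coverage of a DEG module: only edges incident to at least
#' one module gene are added, tagged `"supplementary"`. Genes introduced by
#' expansion get role `other`; expansion never enlarges the typed-regulator
#' list and never changes the provenance of an existing reference edge.
#'
#' @param net An `interactome`.
#' @param extra_edges Path to a supplementary edge list (same TSV dialect as
#'   [load_network()]).
#' @param module_genes Character vector of module gene identifiers; only
#'   supplementary edges touching at least one of them are added.
#' @return The expanded `interactome`.
#' @export
expand_network <- function(net, extra_edges, module_genes) {
  ed <- read_tsv_pairs(extra_edges, 2L, what = "supplementary edge")
  a <- ed$fields[, 1L]
  b <- ed$fields[, 2L]
  keep <- a != b & (a %in% module_genes | b %in% module_genes)
  if (!any(keep)) {
    return(net)
  }
  a <- pmin(ed$fields[keep, 1L], ed$fields[keep, 2L])
  b <- pmax(ed$fields[keep, 1L], ed$fields[keep, 2L])
  new <- unique(data.frame(from = a, to = b, stringsAsFactors = FALSE))

  g <- net$graph
  have <- edge_key(igraph::as_edgelist(g)[, 1L], igraph::as_edgelist(g)[, 2L])
  if (igraph::ecount(g) == 0L) have <- character(0)
  new <- new[!edge_key(new$from, new$to) %in% have, , drop = FALSE]
  if (nrow(new) == 0L) {
    return(net)
  }
  missing_nodes <- setdiff(unique(c(new$from, new$to)), igraph::V(g)$name)
  if (length(missing_nodes) > 0L) {
    g <- igraph::add_vertices(g, length(missing_nodes), name = missing_nodes,
                              role = "other")
  }
  g <- igraph::add_edges(g, rbind(new$from, new$to), provenance = "supplementary")
  new_interactome(g)
}

#' Read a tissue-specificity table
#'
#' Parses a three-column TSV `gene<TAB>tissue<TAB>class` with class one of
#' `TE` (tissue enriched: at least 5-fold greater expression in one tissue
#' than all others), `GE` (group enriched: at least 5-fold greater in a small
#' group of tissues), `TEn` (tissue enhanced: 5-fold above the all-tissue
#' mean). A gene may carry classes in several tissues; absence of an entry
#' means the gene is not specific in that tissue.
#'
#' @param path Path to the TSV.
#' @return A `tissue_table`: data frame with columns `gene`, `tissue`,
#'   `class`, plus attribute `tissues`.
#' @export
read_tissue_table <- function(path) {
  tt <- read_tsv_pairs(path, 3L, what = "tissue")
  cls <- tt$fields[, 3L]
  bad <- which(!cls %in% TISSUE_CLASSES)
  if (length(bad) > 0L) {
    stop("tissue table ", path, ": line ", tt$lineno[bad[1L]],
         " has class '", cls[bad[1L]], "' (expected TE, GE or TEn)",
         call. = FALSE)
  }
  df <- unique(data.frame(gene = tt$fields[, 1L], tissue = tt$fields[, 2L],
                          class = cls, stringsAsFactors = FALSE))
  tissue_table(df)
}

#' @rdname read_tissue_table
#' @param entries Data frame with columns `gene`, `tissue`, `class`.
#' @export
tissue_table <- function(entries) {
  stopifnot(all(c("gene", "tissue", "class") %in% names(entries)),
            all(entries$class %in% TISSUE_CLASSES))
  structure(entries[c("gene", "tissue", "class")],
            tissues = sort(unique(entries$tissue)),
            class = c("tissue_table", "data.frame"))
}

#' Prune an interactome to one tissue
#'
#' Removes every gene classified tissue-enriched (TE) or group-enriched (GE)
#' in some tissue other than the selected one, unless that gene is itself
#' TE, GE or TEn in the selected tissue. Tissue-enhanced-elsewhere genes and
#' genes without any tissue annotation are kept. Edges incident to a removed
#' gene are dropped with it.
#'
#' Genes that are group-enriched both in the selected tissue and elsewhere
#' are kept (their selected-tissue class protects them) and reported via a
#' message, since group enrichment does not identify which tissues form the
#' group.
#'
#' @param net An `interactome`.
#' @param tt A `tissue_table` from [read_tissue_table()].
#' @param tissue Name of the tissue the analysis is restricted to.
#' @return The pruned `interactome` (node and edge sets are subsets of the
#'   input's).
#' @export
prune_to_tissue <- function(net, tt, tissue) {
  stopifnot(inherits(tt, "tissue_table"))
  tissues <- attr(tt, "tissues")
  if (!tissue %in% tissues) {
    stop("unknown tissue '", tissue, "'; valid tissues: ",
         paste(tissues, collapse = ", "), call. = FALSE)
  }
  specific_elsewhere <- unique(tt$gene[tt$tissue != tissue &
                                         tt$class %in% c("TE", "GE")])
  protected <- unique(tt$gene[tt$tissue == tissue])
  ambiguous <- intersect(
    tt$gene[tt$tissue == tissue & tt$class == "GE"],
    tt$gene[tt$tissue != tissue & tt$class == "GE"])
  if (length(ambiguous) > 0L) {
    message("keeping ", length(ambiguous),
            " gene(s) group-enriched both in '", tissue,
            "' and elsewhere: ", paste(ambiguous, collapse = ", "))
  }
  drop <- setdiff(specific_elsewhere, protected)
  drop <- intersect(drop, igraph::V(net$graph)$name)
  if (length(drop) == 0L) {
    return(net)
  }
  new_interactome(igraph::delete_vertices(net$graph, drop))
}
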