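#' Construct a DEG module
#'
#' A DEG module is a set of differentially expressed genes that are
#' co-expressed and functionally related; it is the unit of input to the
#' scoring pipeline. Each gene carries a signed log fold change and a
#' p-value for one comparison (e.g. a time point against baseline, or
#' against the preceding time point).
#'
#' @param genes Character vector of gene identifiers (one entry per gene).
#' @param logFC Numeric vector of signed log fold changes.
#' @param pvalue Numeric vector of p-values in `[0, 1]`.
#' @param module_id Label for the module.
#' @param comparison Label for the contrast the module belongs to.
#' @return A `deg_module`: data frame with columns `gene`, `logFC`,
#'   `pvalue` and attributes `module_id`, `comparison`.
#' @export
deg_module <- function(genes, logFC, pvalue, module_id = "module1",
                       comparison = "contrast1") {
  stopifnot(length(genes) > 0L,
            length(logFC) == length(genes),
            length(pvalue) == length(genes))
  if (anyDuplicated(genes)) {
    stop("duplicate gene entries in DEG module '", module_id, "'",
         call. = FALSE)
  }
  if (any(pvalue < 0 | pvalue > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  structure(data.frame(gene = as.character(genes), logFC = as.numeric(logFC),
                       pvalue = as.numeric(pvalue), stringsAsFactors = FALSE),
            module_id = module_id, comparison = comparison,
            class = c("deg_module", "data.frame"))
}

#' @export
print.deg_module <- function(x, ...) {
  cat(sprintf("DEG module '%s' (%s): %d genes, logFC range [%.3g, %.3g]\n",
              attr(x, "module_id"), attr(x, "comparison"), nrow(x),
              min(x$logFC), max(x$logFC)))
  invisible(x)
}

#' Read DEG modules from a TSV file
#'
#' Expects a header line and columns `gene`, `logFC`, `pvalue`, optionally
#' `module_id` (several modules per file). Column matching is
#' case-insensitive; `log_fc`/`lfc` and `p_value`/`pval` synonyms are
#' accepted.
#'
#' @param path Path to the TSV.
#' @param module_id Module label when the file has no `module_id` column;
#'   defaults to the file name without extension.
#' @param comparison Comparison label attached to every module read.
#' @return A named list of `deg_module` objects.
#' @export
read_deg_modules <- function(path, module_id = NULL, comparison = "contrast1") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  nm <- tolower(gsub("[._]", "", names(df)))
  pick <- function(alts, what) {
    i <- which(nm %in% alts)[1L]
    if (is.na(i)) {
      stop("DEG module file ", path, " lacks a ", what, " column",
           call. = FALSE)
    }
    df[[i]]
  }
  gene <- as.character(pick(c("gene", "genes", "symbol", "id"), "gene"))
  lfc <- as.numeric(pick(c("logfc", "lfc", "foldchange", "log2fc"), "logFC"))
  pv <- as.numeric(pick(c("pvalue", "pval", "p"), "pvalue"))
  mid_i <- which(nm == "moduleid")[1L]
  if (!is.na(mid_i)) {
    ids <- as.character(df[[mid_i]])
    out <- lapply(split(seq_len(nrow(df)), ids), function(ix) {
      deg_module(gene[ix], lfc[ix], pv[ix],
                 module_id = ids[ix[1L]], comparison = comparison)
    })
    return(out)
  }
  module_id <- module_id %||% tools::file_path_sans_ext(basename(path))
  out <- list(deg_module(gene, lfc, pv, module_id = module_id,
                         comparison = comparison))
  names(out) <- module_id
  out
}

#' Multi-source shortest hop distances
#'
#' Breadth-first-search distances (unweighted hop counts) from the nearest
#' source to every reachable node of the interactome. Sources not present in
#' the network are skipped with a warning; unreachable nodes are absent from
#' the result.
#'
#' @param net An `interactome`.
#' @param sources Character vector of source gene identifiers.
#' @return Named numeric vector: reachable node -> hop distance (0 for the
#'   sources themselves).
#' @export
bfs_distances <- function(net, sources) {
  sources <- unique(as.character(sources))
  present <- sources %in% igraph::V(net$graph)$name
  if (any(!present)) {
    warning("dropping ", sum(!present),
            " source gene(s) absent from the network: ",
            paste(utils::head(sources[!present], 5L), collapse = ", "),
            if (sum(!present) > 5L) ", ..." else "", call. = FALSE)
  }
  sources <- sources[present]
  if (length(sources) == 0L) {
    stop("no source gene maps into the network", call. = FALSE)
  }
  d <- igraph::distances(net$graph, v = sources,
                         to = igraph::V(net$graph), weights = NA)
  dmin <- apply(d, 2L, min)
  dmin[is.finite(dmin)]
}

#' Select the closest regulator molecules for a DEG module
#'
#' Finds the regulators (nodes of the configured molecular role, receptors
#' by default) nearest to the differentially expressed genes of a module.
#' In the default `"per_gene"` scope each module gene nominates the
#' role-labelled nodes at its minimal positive hop distance; the union over
#' genes is returned, together with every role-labelled node that is itself
#' a module member (distance 0, a differentially expressed regulator).
#' `scope = "global"` instead takes the single minimal positive distance
#' from the module as a whole (multi-source BFS).
#'
#' @param net An `interactome`.
#' @param module A `deg_module`.
#' @param role Regulator role, one of `receptor`, `transcription_factor`,
#'   `transporter` (default `receptor`).
#' @param scope `"per_gene"` (default) or `"global"`; see Details.
#' @return A `regulator_set`: list with `regulators` (character vector),
#'   `distances` (named numeric, 0 for in-module regulators), `role`, and
#'   `unmapped` (module genes absent from the network, reported for the run
#'   audit).
#' @export
select_regulators <- function(net, module, role = "receptor",
                              scope = c("per_gene", "global")) {
  scope <- match.arg(scope)
  role <- normalize_roles(role)
  stopifnot(inherits(module, "deg_module"))
  g <- net$graph
  nodes <- igraph::V(g)$name
  mg <- intersect(module$gene, nodes)
  unmapped <- setdiff(module$gene, nodes)
  if (length(mg) == 0L) {
    stop("no module gene maps into the network", call. = FALSE)
  }
  if (length(mg) < 0.5 * nrow(module)) {
    warning("fewer than 50% of module genes map to network nodes; ",
            "check that the module and the network share one gene namespace",
            call. = FALSE)
  }
  role_nodes <- nodes[igraph::V(g)$role == role]
  in_module <- intersect(role_nodes, mg)

  dist_of <- stats::setNames(rep(NA_real_, 0), character(0))
  if (length(role_nodes) > 0L) {
    d <- igraph::distances(g, v = mg, to = role_nodes, weights = NA)
    if (scope == "global") {
      dmin <- apply(d, 2L, min)
      pos <- dmin[dmin > 0 & is.finite(dmin)]
      if (length(pos) > 0L) {
        dist_of <- pos[pos == min(pos)]
      }
    } else {
      picks <- list()
      for (i in seq_len(nrow(d))) {
        row <- d[i, ]
        pos <- row[row > 0 & is.finite(row)]
        if (length(pos) == 0L) next
        picks[[length(picks) + 1L]] <- pos[pos == min(pos)]
      }
      if (length(picks) > 0L) {
        all <- unlist(picks)
        dist_of <- vapply(split(all, names(all)), min, numeric(1))
      }
    }
  }
  dist_of <- c(dist_of[setdiff(names(dist_of), in_module)],
               stats::setNames(rep(0, length(in_module)), in_module))
  if (length(dist_of) == 0L) {
    stop("no regulator found: no '", role,
         "' node reachable from the module and none inside it",
         call. = FALSE)
  }
  structure(list(regulators = sort(names(dist_of)),
                 distances = dist_of[sort(names(dist_of))],
                 role = role, unmapped = unmapped),
            class = "regulator_set")
}

#' @export
print.regulator_set <- function(x, ...) {
  cat(sprintf("Regulator set (%s): %d regulator(s), distances %s\n",
              x$role, length(x$regulators),
              paste(sprintf("%s=%g", names(x$distances), x$distances),
                    collapse = ", ")))
  if (length(x$unmapped)) {
    cat("  unmapped module genes:", paste(x$unmapped, collapse = ", "), "\n")
  }
  invisible(x)
}
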