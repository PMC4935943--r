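#' Common linkage index of a gene pair
#'
#' Edge weight quantifying interaction strength as the shared neighborhood
#' relative to the two endpoints' total neighbor counts:
#' \deqn{CL_{ij} = (D_{ij} + I_{ij}) / (n_i + n_j)}
#' where \eqn{D_{ij}} is 1 when i and j interact directly (0 otherwise),
#' \eqn{I_{ij}} is the number of common neighbors, and \eqn{n_k} the degree
#' of node k. For a pair that does not interact directly the index is
#' defined to be 0, regardless of shared neighbors. On edges the index is
#' strictly positive, and since each endpoint counts the other endpoint and
#' every common neighbor among its neighbors, it can never exceed 1/2.
#'
#' @param net An `interactome`.
#' @param i,j Distinct gene identifiers present in the network.
#' @param method `"cl"` (default, the formula above) or `"jaccard"`, which
#'   divides by the size of the neighborhood union
#'   \eqn{n_i + n_j - I_{ij}} instead.
#' @return A number in `[0, 1]`.
#' @examples
#' ef <- tempfile()
#' writeLines(c("a\tb", "a\tc", "b\tc", "b\td"), ef)
#' g1 <- load_network(ef)
#' common_linkage_index(g1, "a", "b")  # (1 + 1)/(2 + 3) = 0.4
#' common_linkage_index(g1, "b", "d")  # (1 + 0)/(3 + 1) = 0.25
#' common_linkage_index(g1, "a", "d")  # not connected -> 0
#' @export
common_linkage_index <- function(net, i, j, method = c("cl", "jaccard")) {
  method <- match.arg(method)
  g <- net$graph
  nodes <- igraph::V(g)$name
  if (!i %in% nodes || !j %in% nodes) {
    stop("unknown node: ", paste(setdiff(c(i, j), nodes), collapse = ", "),
         call. = FALSE)
  }
  if (i == j) {
    stop("common linkage index is defined for distinct nodes", call. = FALSE)
  }
  ni <- igraph::neighbors(g, i)$name
  if (!j %in% ni) {
    return(0)
  }
  nj <- igraph::neighbors(g, j)$name
  I <- length(intersect(ni, nj))
  denom <- if (method == "cl") length(ni) + length(nj) else
    length(ni) + length(nj) - I
  (1 + I) / denom
}

#' Label every edge of the network with its common linkage weight
#'
#' @param net An `interactome`.
#' @param method Passed to [common_linkage_index()].
#' @return A `weighted_interactome`: the same network with an additional
#'   edge attribute `cl`, strictly positive on every edge.
#' @export
weight_edges <- function(net, method = c("cl", "jaccard")) {
  method <- match.arg(method)
  g <- net$graph
  if (igraph::ecount(g) == 0L) {
    stop("cannot weight an empty network", call. = FALSE)
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  deg <- igraph::degree(g)
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)), as.integer)
  I <- vapply(seq_len(nrow(el)), function(e) {
    length(intersect(adj[[el[e, 1L]]], adj[[el[e, 2L]]]))
  }, numeric(1))
  denom <- deg[el[, 1L]] + deg[el[, 2L]]
  if (method == "jaccard") denom <- denom - I
  igraph::E(g)$cl <- (1 + I) / denom
  out <- new_interactome(g)
  class(out) <- c("weighted_interactome", class(out))
  out
}

#' @export
print.weighted_interactome <- function(x, ...) {
  NextMethod()
  w <- igraph::E(x$graph)$cl
  cat(sprintf("  CL weights: min %.4g, median %.4g, max %.4g\n",
              min(w), stats::median(w), max(w)))
  invisible(x)
}

# Compare two node sequences: TRUE when a is lexicographically smaller.
path_lex_less <- function(a, b) {
  n <- min(length(a), length(b))
  for (k in seq_len(n)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  length(a) < length(b)
}

# Hop-bounded maximum-product search from one source to every node.
# Dynamic program over hop counts: best[[h]][[v]] is the best walk of at
# most h edges from source to v, as list(score, nodes). Because every CL
# weight is <= 1/2, extending a walk strictly decreases its score, so the
# optimum is always a simple path and the hop-minimal tie-break is safe.
# Returns a list over node names of list(score, nodes, length) or NULL.
max_product_paths <- function(wnet, source, max_len = 9L) {
  g <- wnet$graph
  nodes <- igraph::V(g)$name
  nv <- length(nodes)
  src <- match(source, nodes)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$cl
  # symmetric directed copies for relaxation
  from <- c(el[, 1L], el[, 2L])
  to <- c(el[, 2L], el[, 1L])
  ww <- c(w, w)

  score <- rep(-Inf, nv)
  best_path <- vector("list", nv)
  best_len <- rep(NA_integer_, nv)
  score[src] <- 1
  best_path[[src]] <- src
  best_len[src] <- 0L

  frontier_score <- score
  frontier_path <- best_path
  for (h in seq_len(max_len)) {
    new_score <- rep(-Inf, nv)
    new_path <- vector("list", nv)
    active <- which(frontier_score > -Inf)
    if (length(active) == 0L) break
    sel <- from %in% active
    for (e in which(sel)) {
      u <- from[e]; v <- to[e]
      cand <- frontier_score[u] * ww[e]
      if (cand > new_score[v] ||
          (cand == new_score[v] &&
           path_lex_less(nodes[c(frontier_path[[u]], v)],
                         nodes[new_path[[v]]]))) {
        new_score[v] <- cand
        new_path[[v]] <- c(frontier_path[[u]], v)
      }
    }
    for (v in which(new_score > -Inf)) {
      if (new_score[v] > score[v] ||
          (new_score[v] == score[v] && h < best_len[v]) ||
          (new_score[v] == score[v] && h == best_len[v] &&
           path_lex_less(nodes[new_path[[v]]], nodes[best_path[[v]]]))) {
        score[v] <- new_score[v]
        best_path[[v]] <- new_path[[v]]
        best_len[v] <- h
      }
    }
    frontier_score <- new_score
    frontier_path <- new_path
  }
  out <- stats::setNames(vector("list", nv), nodes)
  for (v in seq_len(nv)) {
    if (is.finite(score[v]) && score[v] > -Inf && v != src) {
      out[[v]] <- list(score = score[v], nodes = nodes[best_path[[v]]],
                       length = best_len[v])
    }
  }
  out
}

#' Highest-product path between a regulator and a target gene
#'
#' Returns the path of at most `max_len` edges whose product of common
#' linkage weights is maximal. Ties are broken by fewer edges, then by the
#' lexicographically smallest node sequence, making the result
#' deterministic. Targets farther than `max_len` hops (by default, hop
#' distance 10 or more) yield `NULL`: longer paths are rare and unlikely to
#' carry signal.
#'
#' @param wnet A `weighted_interactome` from [weight_edges()].
#' @param source,target Distinct gene identifiers in the network.
#' @param max_len Maximum number of edges in a retained path (default 9).
#' @return A `path_record` — list with `regulator`, `target`, `nodes`
#'   (ordered), `score` (product of edge CL weights) and `length` (edge
#'   count) — or `NULL` when no path of at most `max_len` edges exists.
#' @export
best_path <- function(wnet, source, target, max_len = 9L) {
  nodes <- igraph::V(wnet$graph)$name
  missing <- setdiff(c(source, target), nodes)
  if (length(missing) > 0L) {
    stop("unknown node: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (source == target) {
    stop("source and target must differ", call. = FALSE)
  }
  hit <- max_product_paths(wnet, source, max_len)[[target]]
  if (is.null(hit)) {
    return(NULL)
  }
  structure(list(regulator = source, target = target, nodes = hit$nodes,
                 score = hit$score, length = hit$length),
            class = "path_record")
}

#' @export
print.path_record <- function(x, ...) {
  cat(sprintf("Path %s -> %s (%d edges, score %.4g): %s\n",
              x$regulator, x$target, x$length, x$score,
              paste(x$nodes, collapse = " - ")))
  invisible(x)
}

#' Build the minimal sub-network of a regulator for a DEG module
#'
#' Merges the highest-product paths (each at most `max_len` edges) from the
#' regulator to every module gene present in the network, and optionally
#' extends the merged network with the 1-neighbors of its nodes (every
#' adjacent node plus the connecting edge). Module genes with no retained
#' path are recorded as uncovered.
#'
#' @param wnet A `weighted_interactome`.
#' @param regulator Gene identifier of the regulator seeding the search; an
#'   in-module (distance 0) regulator seeds paths from itself to the other
#'   module genes.
#' @param module A `deg_module`.
#' @param extend Add the 1-neighbor extension (default `TRUE`).
#' @param max_len Maximum path length in edges (default 9).
#' @return A `subnetwork`: list with `regulator`, `module_id`, `nodes`,
#'   `edges` (data frame `from`, `to`, `cl`), `paths` (list of
#'   `path_record`), `covered_genes`, `extended`, `path_nodes` (nodes lying
#'   on retained paths, before extension).
#' @export
build_subnetwork <- function(wnet, regulator, module, extend = TRUE,
                             max_len = 9L) {
  g <- wnet$graph
  nodes <- igraph::V(g)$name
  if (!regulator %in% nodes) {
    stop("unknown regulator node: ", regulator, call. = FALSE)
  }
  stopifnot(inherits(module, "deg_module"))
  targets <- setdiff(intersect(module$gene, nodes), regulator)
  all_best <- max_product_paths(wnet, regulator, max_len)
  paths <- Filter(Negate(is.null), all_best[targets])
  covered <- names(paths)
  if (regulator %in% module$gene) covered <- c(regulator, covered)

  path_nodes <- unique(c(if (length(paths) > 0L || regulator %in% module$gene)
    regulator, unlist(lapply(paths, `[[`, "nodes"))))
  ekeys <- unique(unlist(lapply(paths, function(p) {
    n <- p$nodes
    edge_key(n[-length(n)], n[-1L])
  })))

  sub_nodes <- path_nodes
  if (isTRUE(extend) && length(path_nodes) > 0L) {
    nb <- unique(unlist(lapply(
      igraph::adjacent_vertices(g, path_nodes), function(v) v$name)))
    ext_nodes <- setdiff(nb, path_nodes)
    # connecting edges: any edge between a path node and an extension node
    el <- igraph::as_edgelist(g)
    touch <- (el[, 1L] %in% path_nodes & el[, 2L] %in% ext_nodes) |
      (el[, 2L] %in% path_nodes & el[, 1L] %in% ext_nodes)
    ekeys <- unique(c(ekeys, edge_key(el[touch, 1L], el[touch, 2L])))
    sub_nodes <- c(path_nodes, ext_nodes)
  }

  edges <- data.frame(from = character(0), to = character(0),
                      cl = numeric(0), stringsAsFactors = FALSE)
  if (length(ekeys) > 0L) {
    el <- igraph::as_edgelist(g)
    keys <- edge_key(el[, 1L], el[, 2L])
    hit <- match(ekeys, keys)
    edges <- data.frame(from = pmin(el[hit, 1L], el[hit, 2L]),
                        to = pmax(el[hit, 1L], el[hit, 2L]),
                        cl = igraph::E(g)$cl[hit], stringsAsFactors = FALSE)
  }
  structure(list(regulator = regulator,
                 module_id = attr(module, "module_id"),
                 nodes = sort(unique(sub_nodes)),
                 edges = edges,
                 paths = paths,
                 path_nodes = sort(path_nodes),
                 covered_genes = sort(unique(covered)),
                 extended = isTRUE(extend)),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf(
    "Sub-network of %s for module '%s': %d nodes, %d edges, %d module gene(s) covered%s\n",
    x$regulator, x$module_id, length(x$nodes), nrow(x$edges),
    length(x$covered_genes), if (x$extended) " (1-neighbor extended)" else ""))
  invisible(x)
}
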