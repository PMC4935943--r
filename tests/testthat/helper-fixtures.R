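# Fixture builders and independent oracles used across the suite.

# Write a TSV edge list to a temp file and load it.
make_network <- function(edges, roles = NULL) {
  ef <- withr::local_tempfile(fileext = ".tsv",
                              .local_envir = parent.frame())
  writeLines(vapply(edges, function(e) paste(e, collapse = "\t"),
                    character(1)), ef)
  rf <- NULL
  if (!is.null(roles)) {
    rf <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
    writeLines(paste(names(roles), roles, sep = "\t"), rf)
  }
  load_network(ef, rf)
}

# The worked 4-node graph: edges a-b, a-c, b-c, b-d.
g1_network <- function(roles = NULL) {
  make_network(list(c("a", "b"), c("a", "c"), c("b", "c"), c("b", "d")),
               roles = roles)
}

# Oracle: hop distances by hand-rolled breadth-first search over an edge
# data frame (independent of igraph).
oracle_bfs <- function(edges_df, sources) {
  adj <- list()
  addnb <- function(a, b) {
    adj[[a]] <<- c(adj[[a]], b)
  }
  for (i in seq_len(nrow(edges_df))) {
    addnb(edges_df$from[i], edges_df$to[i])
    addnb(edges_df$to[i], edges_df$from[i])
  }
  nodes <- unique(c(edges_df$from, edges_df$to, sources))
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  dist[sources] <- 0
  queue <- sources
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (u in adj[[v]]) {
      if (dist[u] > dist[v] + 1) {
        dist[u] <- dist[v] + 1
        queue <- c(queue, u)
      }
    }
  }
  dist[is.finite(dist)]
}

# Oracle: best path by exhaustive enumeration of simple paths of at most
# max_len edges, scored by the product of CL weights taken in path order,
# with the tie-break: highest score, fewer edges, lexicographically
# smallest node sequence.
oracle_best_path <- function(wnet, source, target, max_len = 9L) {
  g <- wnet$graph
  ps <- igraph::all_simple_paths(g, from = source, to = target,
                                 cutoff = max_len)
  if (length(ps) == 0L) return(NULL)
  el <- igraph::as_edgelist(g)
  wkey <- setNames(igraph::E(g)$cl,
                   paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]),
                         sep = "|"))
  best <- NULL
  for (p in ps) {
    nm <- p$name
    a <- nm[-length(nm)]; b <- nm[-1]
    sc <- 1
    for (k in seq_along(a)) {
      sc <- sc * wkey[[paste(min(a[k], b[k]), max(a[k], b[k]), sep = "|")]]
    }
    cand <- list(nodes = nm, score = sc, length = length(a))
    if (is.null(best) || cand$score > best$score ||
        (cand$score == best$score && cand$length < best$length) ||
        (cand$score == best$score && cand$length == best$length &&
         paste(cand$nodes, collapse = "\r") <
         paste(best$nodes, collapse = "\r"))) {
      best <- cand
    }
  }
  best
}

# Oracle: upper-tail hypergeometric probability by direct enumeration with
# binomial coefficients.
oracle_hyper <- function(k, t, r, N) {
  if (k == 0) return(1)
  i <- k:min(t, r)
  sum(choose(r, i) * choose(N - r, t - i)) / choose(N, t)
}

# Random connected-ish graph as an edge list (for property tests).
random_edges <- function(n, p = 0.35) {
  nodes <- sprintf("n%02d", seq_len(n))
  comb <- t(combn(nodes, 2))
  keep <- runif(nrow(comb)) < p
  # splice in a random spanning path so source/target are usually connected
  ord <- sample(nodes)
  path <- cbind(ord[-n], ord[-1])
  el <- unique(rbind(comb[keep, , drop = FALSE], t(apply(path, 1, sort))))
  data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE)
}

edges_to_network <- function(edges_df) {
  make_network(split(as.matrix(edges_df[c("from", "to")]),
                     seq_len(nrow(edges_df))))
}

# One full synthetic run: returns the NAS-ranked annotation table and the
# planted pathway name.
run_synthetic <- function(seed, effect = 2.0, noise_sd = 0.15) {
  sc <- synthetic_scenario(seed = seed, planted_effect = effect,
                           noise_sd = noise_sd)
  nw <- generate_network(sc)
  md <- generate_module(sc, nw$network)
  regs <- select_regulators(nw$network, md$module)
  wn <- weight_edges(nw$network)
  subs <- lapply(regs$regulators,
                 function(r) build_subnetwork(wn, r, md$module))
  subs <- Filter(function(s) length(s$covered_genes) > 0, subs)
  ann <- annotate_subnetworks(subs, md$module, md$collection)
  list(ranked = rank_results(ann), planted = md$planted,
       n_candidates = length(md$collection))
}
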