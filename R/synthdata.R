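#' Define a synthetic benchmark scenario
#'
#' Fixes every parameter of the deterministic fixture generator: a connected
#' preferential-attachment interactome with molecular roles and tissue
#' classes, a canonical-pathway collection with one planted (truly active)
#' pathway plus size-matched decoy pathways, and a DEG module containing the
#' planted genes at elevated fold change. The generator emulates the
#' degree heterogeneity of signaling networks and a clean planted signal;
#' all randomness flows through the single `seed`.
#'
#' @param seed Integer seed driving every random draw.
#' @param n_nodes,n_edges Size of the interactome (the graph is connected,
#'   so `n_edges >= n_nodes - 1`).
#' @param role_fractions Named proportions of `receptor`,
#'   `transcription_factor`, `transporter` nodes (the rest are `other`);
#'   must sum to at most 1.
#' @param n_pathways Number of candidate pathways (1 planted +
#'   `n_pathways - 1` decoys).
#' @param pathway_size Genes per candidate pathway; the DEG module is the
#'   union of all candidate pathways' genes, so candidate sets are
#'   exchangeable when no signal is planted.
#' @param planted_effect Mean log fold change of the planted genes (decoys
#'   are centered at 0).
#' @param noise_sd Standard deviation of fold-change noise.
#' @param tissue_profile List with `tissues` (names; the first is the
#'   analysis tissue) and per-gene class probabilities `p_te`, `p_ge`,
#'   `p_ten` in each non-analysis tissue.
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(seed = 1L, n_nodes = 80L, n_edges = 200L,
                               role_fractions = c(receptor = 0.10,
                                                  transcription_factor = 0.08,
                                                  transporter = 0.04),
                               n_pathways = 4L, pathway_size = 6L,
                               planted_effect = 2.0, noise_sd = 0.15,
                               tissue_profile = list(
                                 tissues = c("adipose", "liver", "brain"),
                                 p_te = 0.03, p_ge = 0.03, p_ten = 0.06)) {
  stopifnot(n_edges >= n_nodes - 1L,
            sum(role_fractions) <= 1,
            n_pathways >= 1L,
            n_pathways * pathway_size <= n_nodes)
  structure(list(seed = as.integer(seed), n_nodes = as.integer(n_nodes),
                 n_edges = as.integer(n_edges),
                 role_fractions = role_fractions,
                 n_pathways = as.integer(n_pathways),
                 pathway_size = as.integer(pathway_size),
                 planted_effect = planted_effect, noise_sd = noise_sd,
                 tissue_profile = tissue_profile),
            class = "synthetic_scenario")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Generate a synthetic interactome and tissue table
#'
#' Builds a connected graph by preferential attachment: a random recursive
#' tree with degree-proportional parent choice, then extra edges sampled
#' with probability proportional to current degree, giving the heavy-tailed
#' degree distribution typical of signaling networks. Roles are assigned by
#' the scenario's fractions (rounded); tissue classes are sampled per gene
#' and non-analysis tissue. The same seed reproduces the output exactly.
#'
#' @param scenario A `synthetic_scenario`.
#' @return List with `network` (an `interactome`) and `tissue_table`.
#' @export
generate_network <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  n <- scenario$n_nodes
  m <- scenario$n_edges
  genes <- sprintf("G%04d", seq_len(n))
  with_seed(scenario$seed, {
    deg <- integer(n)
    from <- integer(m); to <- integer(m)
    # preferential-attachment tree keeps the graph connected
    for (v in 2:n) {
      w <- deg[seq_len(v - 1L)] + 1
      u <- sample.int(v - 1L, 1L, prob = w)
      from[v - 1L] <- u; to[v - 1L] <- v
      deg[u] <- deg[u] + 1L; deg[v] <- deg[v] + 1L
    }
    seen <- new.env(hash = TRUE)
    for (e in seq_len(n - 1L)) {
      assign(edge_key(genes[from[e]], genes[to[e]]), TRUE, envir = seen)
    }
    e <- n - 1L
    guard <- 0L
    while (e < m) {
      uv <- sample.int(n, 2L, prob = deg + 1)
      guard <- guard + 1L
      if (guard > 100L * m) {
        stop("infeasible edge count for ", n, " nodes", call. = FALSE)
      }
      if (uv[1L] == uv[2L]) next
      key <- edge_key(genes[uv[1L]], genes[uv[2L]])
      if (!is.null(seen[[key]])) next
      assign(key, TRUE, envir = seen)
      e <- e + 1L
      from[e] <- uv[1L]; to[e] <- uv[2L]
      deg[uv[1L]] <- deg[uv[1L]] + 1L; deg[uv[2L]] <- deg[uv[2L]] + 1L
    }
    g <- igraph::graph_from_data_frame(
      data.frame(from = genes[from], to = genes[to],
                 stringsAsFactors = FALSE),
      directed = FALSE, vertices = genes)
    igraph::E(g)$provenance <- "reference"

    roles <- rep("other", n)
    pool <- sample.int(n)   # random order, then carve role blocks
    offset <- 0L
    for (r in names(scenario$role_fractions)) {
      cnt <- round(scenario$role_fractions[[r]] * n)
      if (cnt > 0L) {
        roles[pool[offset + seq_len(cnt)]] <- r
        offset <- offset + cnt
      }
    }
    igraph::V(g)$role <- roles

    tp <- scenario$tissue_profile
    rows <- list()
    for (tis in tp$tissues[-1L]) {
      cls <- sample(c("TE", "GE", "TEn", "none"), n, replace = TRUE,
                    prob = c(tp$p_te, tp$p_ge, tp$p_ten,
                             1 - tp$p_te - tp$p_ge - tp$p_ten))
      hit <- cls != "none"
      if (any(hit)) {
        rows[[tis]] <- data.frame(gene = genes[hit], tissue = tis,
                                  class = cls[hit],
                                  stringsAsFactors = FALSE)
      }
    }
    # the analysis tissue protects a slice of genes, including some that
    # would otherwise be pruned
    prot <- sample(genes, max(1L, round(0.1 * n)))
    rows[["analysis"]] <- data.frame(
      gene = prot, tissue = tp$tissues[1L],
      class = sample(c("TE", "GE", "TEn"), length(prot), replace = TRUE),
      stringsAsFactors = FALSE)
    tt <- tissue_table(do.call(rbind, rows))
    list(network = new_interactome(g), tissue_table = tt)
  })
}

#' Generate a DEG module and pathway collection with planted signal
#'
#' Samples `n_pathways * pathway_size` genes from the network and partitions
#' them at random into equal candidate pathways; the first is the planted
#' pathway (named `PLANTED_PW` at a seeded random position of the name
#' order), the rest are decoys (sharing no gene with the planted set). The
#' DEG module is the union of all candidate genes; planted genes draw their
#' log fold change from `N(planted_effect, noise_sd)`, decoy genes from
#' `N(0, noise_sd)`.
#'
#' @param scenario A `synthetic_scenario`.
#' @param net The `interactome` from [generate_network()].
#' @return List with `module` (a `deg_module`), `collection` (a
#'   `gene_set_collection`), and `planted` (the planted pathway's name).
#' @export
generate_module <- function(scenario, net) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  genes <- network_nodes(net)
  need <- scenario$n_pathways * scenario$pathway_size
  if (need > length(genes)) {
    stop("planted design needs ", need, " genes but the network has only ",
         length(genes), call. = FALSE)
  }
  with_seed(scenario$seed + 1000000L, {
    chosen <- sample(genes, need)
    groups <- split(chosen, rep(seq_len(scenario$n_pathways),
                                each = scenario$pathway_size))
    labels <- sprintf("CANDIDATE_PW_%02d", seq_len(scenario$n_pathways))
    planted_pos <- sample.int(scenario$n_pathways, 1L)
    labels[planted_pos] <- "PLANTED_PW"
    names(groups) <- labels

    lfc <- stats::rnorm(need, mean = 0, sd = scenario$noise_sd)
    planted_genes <- groups[[planted_pos]]
    lfc[chosen %in% planted_genes] <-
      stats::rnorm(length(planted_genes), mean = scenario$planted_effect,
                   sd = scenario$noise_sd)
    pv <- stats::runif(need, min = 1e-8, max = 0.009)
    module <- deg_module(chosen, lfc, pv,
                         module_id = sprintf("synthetic_seed%d", scenario$seed),
                         comparison = "synthetic")
    list(module = module,
         collection = gene_set_collection(groups, source_db = "other"),
         planted = "PLANTED_PW")
  })
}

#' Write a scenario's fixtures to disk in the pipeline's file dialects
#'
#' Emits the exact TSV/GMT formats consumed by [load_network()],
#' [read_tissue_table()], [read_deg_modules()] and [read_gmt()], so that
#' end-to-end runs exercise the parsers.
#'
#' @param scenario A `synthetic_scenario`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written file paths (`edges`,
#'   `roles`, `tissue`, `module`, `gmt`), invisibly; the planted pathway's
#'   name is attached as attribute `planted`.
#' @export
write_scenario_files <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nw <- generate_network(scenario)
  md <- generate_module(scenario, nw$network)

  paths <- c(edges = file.path(dir, "edges.tsv"),
             roles = file.path(dir, "roles.tsv"),
             tissue = file.path(dir, "tissue.tsv"),
             module = file.path(dir, "module.tsv"),
             gmt = file.path(dir, "pathways.gmt"))
  ed <- network_edges(nw$network)
  writeLines(paste(ed$from, ed$to, sep = "\t"), paths[["edges"]])
  rl <- network_roles(nw$network)
  writeLines(paste(names(rl), rl, sep = "\t"), paths[["roles"]])
  tt <- nw$tissue_table
  writeLines(paste(tt$gene, tt$tissue, tt$class, sep = "\t"),
             paths[["tissue"]])
  writeLines(c("gene\tlogFC\tpvalue",
               paste(md$module$gene, md$module$logFC, md$module$pvalue,
                     sep = "\t")), paths[["module"]])
  writeLines(vapply(md$collection, function(s) {
    paste(c(s$name, "synthetic candidate pathway", s$genes),
          collapse = "\t")
  }, character(1)), paths[["gmt"]])
  structure(invisible(paths), planted = md$planted)
}
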