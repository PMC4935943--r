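#' Validate a pipeline run configuration
#'
#' Collects every input path and tunable parameter of an end-to-end run.
#' Defaults follow the method's published operating point: paths of at most
#' 9 edges, a hop-distance cap of 10, receptors as the regulator class, a
#' 0.05 significance level, and the 1-neighbor extension enabled.
#'
#' @param edge_file,role_file Reference network files (see
#'   [load_network()]).
#' @param module_files Character vector of DEG-module TSV paths.
#' @param gmt_files Named character vector of GMT paths; names give the
#'   source database of each file (`KEGG`, `BioCarta`, `PID`, `Reactome`,
#'   `other`).
#' @param extra_edges Optional supplementary edge list for network
#'   expansion.
#' @param tissue_file,tissue Optional tissue table and selected tissue; both
#'   or neither.
#' @param regulator_role Molecular role of the upstream regulators.
#' @param regulator_scope `"per_gene"` or `"global"` (see
#'   [select_regulators()]).
#' @param max_path_len Maximum edges per retained path (must be smaller than
#'   `distance_cap`).
#' @param distance_cap Hop-distance cap beyond which module genes are
#'   considered unreachable.
#' @param extend_1neighbor Apply the 1-neighbor extension to sub-networks.
#' @param alpha Significance level in `(0, 1)`.
#' @param universe `"collection"` or an integer universe size for the
#'   hypergeometric test.
#' @param cl_method `"cl"` or `"jaccard"` edge weighting.
#' @param select_by `"dice"` or `"logp"` cross-sub-network selection.
#' @param out_dir Optional output directory for the results TSV, audit JSON
#'   and exported sub-networks.
#' @return A validated `run_config` list.
#' @export
run_config <- function(edge_file, role_file, module_files, gmt_files,
                       extra_edges = NULL, tissue_file = NULL, tissue = NULL,
                       regulator_role = "receptor",
                       regulator_scope = "per_gene",
                       max_path_len = 9L, distance_cap = 10L,
                       extend_1neighbor = TRUE, alpha = 0.05,
                       universe = "collection", cl_method = "cl",
                       select_by = "dice", out_dir = NULL) {
  if (!(max_path_len < distance_cap)) {
    stop("config invalid: max_path_len (", max_path_len,
         ") must be smaller than distance_cap (", distance_cap, ")",
         call. = FALSE)
  }
  if (!(alpha > 0 && alpha < 1)) {
    stop("config invalid: alpha must lie in (0, 1)", call. = FALSE)
  }
  if (xor(is.null(tissue_file), is.null(tissue))) {
    stop("config invalid: tissue_file and tissue must be given together",
         call. = FALSE)
  }
  if (is.null(names(gmt_files))) {
    names(gmt_files) <- rep("other", length(gmt_files))
  }
  required <- c(edge_file, role_file, module_files, unname(gmt_files),
                extra_edges, tissue_file)
  missing <- required[!file.exists(required)]
  if (length(missing) > 0L) {
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(edge_file = edge_file, role_file = role_file,
                 module_files = module_files, gmt_files = gmt_files,
                 extra_edges = extra_edges, tissue_file = tissue_file,
                 tissue = tissue, regulator_role = regulator_role,
                 regulator_scope = regulator_scope,
                 max_path_len = as.integer(max_path_len),
                 distance_cap = as.integer(distance_cap),
                 extend_1neighbor = isTRUE(extend_1neighbor),
                 alpha = alpha, universe = universe,
                 cl_method = cl_method, select_by = select_by,
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full sub-network discovery and ranking pipeline
#'
#' Executes, per DEG module: load, optional expansion, optional tissue
#' pruning, closest-regulator selection, common-linkage edge weighting,
#' minimal sub-network construction per regulator, pathway annotation
#' (Dice + hypergeometric p), NAS scoring, ranking and consolidation. The
#' run is deterministic given identical inputs.
#'
#' @param config A `run_config`.
#' @return A `pipeline_result` list with `results` (full annotation table),
#'   `ranked` (the same table ordered by NAS), `consolidated` (selected
#'   results merged by pathway name), `subnetworks`, `regulators`, `errors`
#'   (per-module error messages, if any) and `audit` (input hashes and
#'   parameters). When `config$out_dir` is set, `results.tsv`,
#'   `consolidated.tsv` and `audit.json` are written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  net <- load_network(config$edge_file, config$role_file)

  modules <- list()
  for (mf in config$module_files) {
    modules <- c(modules, read_deg_modules(mf))
  }
  if (length(modules) == 0L) {
    stop("empty module set: no DEG module could be read", call. = FALSE)
  }
  collection <- NULL
  for (i in seq_along(config$gmt_files)) {
    col <- read_gmt(config$gmt_files[[i]],
                    source_db = names(config$gmt_files)[i])
    collection <- if (is.null(collection)) col else
      combine_collections(collection, col)
  }

  all_results <- list()
  all_subnets <- list()
  all_regs <- list()
  errors <- character(0)
  for (mod in modules) {
    mid <- attr(mod, "module_id")
    res <- tryCatch({
      mnet <- net
      if (!is.null(config$extra_edges)) {
        mnet <- expand_network(mnet, config$extra_edges, mod$gene)
      }
      if (!is.null(config$tissue)) {
        tt <- read_tissue_table(config$tissue_file)
        mnet <- prune_to_tissue(mnet, tt, config$tissue)
      }
      regs <- select_regulators(mnet, mod, role = config$regulator_role,
                                scope = config$regulator_scope)
      wnet <- weight_edges(mnet, method = config$cl_method)
      subnets <- lapply(regs$regulators, function(r) {
        build_subnetwork(wnet, r, mod, extend = config$extend_1neighbor,
                         max_len = config$max_path_len)
      })
      subnets <- Filter(function(s) length(s$covered_genes) > 0L, subnets)
      if (length(subnets) == 0L) {
        stop("no regulator reaches any module gene within ",
             config$max_path_len, " edges", call. = FALSE)
      }
      ann <- annotate_subnetworks(subnets, mod, collection,
                                  universe = config$universe,
                                  select_by = config$select_by)
      list(ann = ann, subnets = subnets, regs = regs)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[mid] <- conditionMessage(res)
    } else {
      all_results[[mid]] <- res$ann
      all_subnets[[mid]] <- res$subnets
      all_regs[[mid]] <- res$regs
    }
  }
  if (length(all_results) == 0L) {
    stop("pipeline failed for every module:\n  ",
         paste(names(errors), errors, sep = ": ", collapse = "\n  "),
         call. = FALSE)
  }
  results <- do.call(rbind, unname(all_results))
  ranked <- rank_results(results)
  consolidated <- consolidate(results)

  audit <- list(
    package_version = as.character(utils::packageVersion("nasfinder")),
    r_version = R.version.string,
    parameters = config[setdiff(names(config),
                                c("edge_file", "role_file", "module_files",
                                  "gmt_files", "extra_edges", "tissue_file",
                                  "out_dir"))],
    inputs = lapply(
      c(list(edge_file = config$edge_file, role_file = config$role_file),
        as.list(stats::setNames(config$module_files,
                                paste0("module_", seq_along(config$module_files)))),
        as.list(stats::setNames(unname(config$gmt_files),
                                paste0("gmt_", seq_along(config$gmt_files))))),
      function(p) list(path = p, md5 = unname(tools::md5sum(p)))),
    module_errors = as.list(errors))

  out <- structure(list(results = results, ranked = ranked,
                        consolidated = consolidated,
                        subnetworks = all_subnets, regulators = all_regs,
                        errors = errors, audit = audit),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(
      ranked[c("module_id", "regulator", "pathway", "source_db", "dice",
               "p_value", "nas", "selected")],
      file.path(config$out_dir, "results.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(consolidated,
                       file.path(config$out_dir, "consolidated.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(audit, file.path(config$out_dir, "audit.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "Pipeline result: %d module(s), %d annotation row(s), %d consolidated pathway(s)\n",
    length(x$subnetworks), nrow(x$results), nrow(x$consolidated)))
  if (length(x$errors)) {
    cat("  failed modules:",
        paste(names(x$errors), collapse = ", "), "\n")
  }
  top <- x$ranked[!duplicated(x$ranked$pathway), , drop = FALSE]
  top <- utils::head(top, 5L)
  if (nrow(top)) {
    cat("  top pathways by NAS:\n")
    for (i in seq_len(nrow(top))) {
      cat(sprintf("    %-30s NAS %.3f  p %.3g  (via %s)\n", top$pathway[i],
                  top$nas[i], top$p_value[i], top$regulator[i]))
    }
  }
  invisible(x)
}
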