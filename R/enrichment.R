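GENESET_SOURCES <- c("KEGG", "BioCarta", "PID", "Reactome", "other")

#' Read a gene-set collection in GMT format
#'
#' Standard GMT: one reference gene set per line,
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' line are collapsed.
#'
#' @param file Path to the GMT file.
#' @param source_db Label of the originating pathway database (`KEGG`,
#'   `BioCarta`, `PID`, `Reactome` or `other`); recorded on every set.
#' @return A `gene_set_collection`: named list of gene sets, each a list
#'   with `name`, `source_db`, `description`, `genes`.
#' @export
read_gmt <- function(file, source_db = "other") {
  source_db <- match.arg(source_db, GENESET_SOURCES)
  if (!file.exists(file)) {
    stop("file not found: ", file, call. = FALSE)
  }
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop("malformed GMT ", file, ": line ", i,
           " has fewer than 3 fields", call. = FALSE)
    }
    genes <- unique(trimws(f[-(1:2)]))
    genes <- genes[nzchar(genes)]
    sets[[f[1L]]] <- list(name = f[1L], source_db = source_db,
                          description = f[2L], genes = genes)
  }
  structure(sets, class = "gene_set_collection")
}

#' @rdname read_gmt
#' @param sets Named list of character vectors (set name -> genes), used to
#'   build a collection in code.
#' @export
gene_set_collection <- function(sets, source_db = "other") {
  source_db <- match.arg(source_db, GENESET_SOURCES)
  stopifnot(length(sets) == 0L || !is.null(names(sets)))
  out <- lapply(names(sets), function(nm) {
    g <- unique(as.character(sets[[nm]]))
    if (length(g) == 0L) stop("empty gene set: ", nm, call. = FALSE)
    list(name = nm, source_db = source_db, description = "", genes = g)
  })
  names(out) <- names(sets)
  structure(out, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("Gene-set collection: %d set(s), %d distinct genes\n",
              length(x), length(unique(unlist(lapply(x, `[[`, "genes"))))))
  invisible(x)
}

#' Combine collections from several databases
#'
#' @param ... `gene_set_collection` objects.
#' @return One `gene_set_collection`; names must be unique within a source
#'   database (a set name may recur across databases and is then suffixed
#'   with the database label).
#' @export
combine_collections <- function(...) {
  parts <- list(...)
  out <- list()
  for (p in parts) {
    stopifnot(inherits(p, "gene_set_collection"))
    for (s in p) {
      key <- if (s$name %in% names(out)) paste(s$name, s$source_db, sep = ".")
      else s$name
      out[[key]] <- s
    }
  }
  structure(out, class = "gene_set_collection")
}

#' Sorensen-Dice similarity of two gene sets
#'
#' \deqn{S(T, R) = 2 |T \cap R| / (|T| + |R|)}
#' The index ranges between 0 and 1 and accounts for the over-representation
#' of small gene sets; it equals 1 exactly when the sets coincide.
#'
#' @param target Character vector, the target set T (module genes inside the
#'   minimal sub-network).
#' @param reference Character vector, a canonical-pathway gene set (must be
#'   non-empty).
#' @return A number in `[0, 1]`.
#' @export
dice_similarity <- function(target, reference) {
  target <- unique(as.character(target))
  reference <- unique(as.character(reference))
  if (length(target) == 0L && length(reference) == 0L) {
    stop("Dice similarity undefined for two empty sets", call. = FALSE)
  }
  if (length(reference) == 0L) {
    stop("reference gene set is empty", call. = FALSE)
  }
  2 * length(intersect(target, reference)) /
    (length(target) + length(reference))
}

#' Upper-tail hypergeometric p-value of a gene-set overlap
#'
#' Probability of observing `k` or more shared genes when `t` genes are
#' drawn without replacement from a universe of `N` genes containing `r`
#' reference-set members. Used only for ranking; no multiple-testing
#' correction is applied.
#'
#' @param k Observed overlap size.
#' @param t Size of the target set (number of draws).
#' @param r Size of the reference set (successes in the universe).
#' @param N Universe size.
#' @return P(X >= k), a number in `(0, 1]`.
#' @export
hypergeom_pvalue <- function(k, t, r, N) {
  stopifnot(length(k) == 1L, length(t) == 1L, length(r) == 1L,
            length(N) == 1L)
  if (k < 0 || t < 0 || r < 0 || N < 0 || k > min(t, r) ||
      t > N || r > N) {
    stop("inconsistent hypergeometric counts: k=", k, " t=", t, " r=", r,
         " N=", N, call. = FALSE)
  }
  if (k == 0) {
    return(1)
  }
  stats::phyper(k - 1, m = r, n = N - r, k = t, lower.tail = FALSE)
}

#' DAVID-style enrichment score of a functional group
#'
#' The enrichment score of a group of functional terms is the negative
#' base-10 logarithm of the geometric mean of the member terms' p-values,
#' so a group of terms at p = 0.05 scores
#' \eqn{-\log_{10} 0.05 \approx 1.3}.
#'
#' @param p_values Numeric vector of term p-values in `(0, 1]`.
#' @return The enrichment score (non-negative).
#' @export
functional_group_score <- function(p_values) {
  if (length(p_values) == 0L) {
    stop("empty p-value list", call. = FALSE)
  }
  if (any(p_values <= 0)) {
    stop("p-values must be strictly positive", call. = FALSE)
  }
  -mean(log10(p_values))
}

#' Filter functional groups into DEG-module gene lists
#'
#' Keeps the groups whose enrichment score exceeds `min_score` (default 1, a
#' slightly more permissive cut than the conventional 1.3 that corresponds
#' to p = 0.05) and, within each kept group, retains only the genes attached
#' to terms with p-value below `term_alpha`.
#'
#' @param groups A list of data frames, one per functional group, each with
#'   columns `term`, `p` and `genes` (list column or comma-separated
#'   string).
#' @param min_score Minimum enrichment score for a group to be kept.
#' @param term_alpha Term-level p-value cut for gene retention.
#' @return Named list (group index) of character gene vectors, one per kept
#'   group.
#' @export
filter_functional_groups <- function(groups, min_score = 1, term_alpha = 0.05) {
  out <- list()
  for (i in seq_along(groups)) {
    gr <- groups[[i]]
    stopifnot(all(c("term", "p", "genes") %in% names(gr)))
    if (functional_group_score(gr$p) <= min_score) next
    keep <- gr$p < term_alpha
    genes <- unlist(lapply(gr$genes[keep], function(g) {
      if (is.character(g) && length(g) == 1L) {
        strsplit(g, ",", fixed = TRUE)[[1L]]
      } else {
        as.character(g)
      }
    }))
    genes <- unique(trimws(genes))
    if (length(genes) > 0L) {
      out[[names(groups)[i] %||% paste0("group", i)]] <- genes
    }
  }
  out
}

#' Annotate sub-networks against a canonical-pathway collection
#'
#' For every (sub-network, reference set) pair the Dice similarity, the
#' hypergeometric p-value of the overlap between the target set T (module
#' genes inside the sub-network) and the reference set, and the network
#' activity score are computed. Per sub-network the reference set with the
#' lowest p-value is flagged `chosen` (ties: highest Dice, then name
#' order); per regulator the sub-network whose chosen annotation has the
#' highest Dice is flagged `selected` (ties: greatest NAS). The full table
#' is returned so downstream ranking can consider every candidate pathway.
#'
#' @param subnets List of `subnetwork` objects (typically one per
#'   regulator).
#' @param module The `deg_module` the sub-networks were built for.
#' @param collection A `gene_set_collection`.
#' @param universe Universe size for the hypergeometric test; the default
#'   `"collection"` uses the number of distinct genes in the collection.
#'   P-values are used only for ranking, so any consistent universe
#'   preserves the order.
#' @param fc_norm Named numeric vector of min-max normalized fold changes
#'   (from [normalize_fold_changes()]), covering the module genes. Computed
#'   from the module when omitted.
#' @param select_by Cross-sub-network similarity used for the `selected`
#'   flag: `"dice"` (default, the named similarity score) or `"logp"`
#'   (smaller p wins).
#' @return An `enrichment_results` data frame with columns `module_id`,
#'   `regulator`, `pathway`, `source_db`, `dice`, `p_value`, `nas`, `cdr`,
#'   `ngr`, `mnf`, `chosen`, `selected`.
#' @export
annotate_subnetworks <- function(subnets, module, collection,
                                 universe = "collection", fc_norm = NULL,
                                 select_by = c("dice", "logp")) {
  select_by <- match.arg(select_by)
  stopifnot(inherits(module, "deg_module"),
            inherits(collection, "gene_set_collection"),
            length(collection) > 0L)
  if (is.null(fc_norm)) {
    fc_norm <- normalize_fold_changes(
      stats::setNames(module$logFC, module$gene))
  }
  N <- if (identical(universe, "collection")) {
    length(unique(unlist(lapply(collection, `[[`, "genes"))))
  } else {
    as.integer(universe)
  }
  targets <- lapply(subnets, function(s) {
    intersect(intersect(module$gene, s$covered_genes), s$nodes)
  })
  if (all(lengths(targets) == 0L)) {
    stop("no mappable gene: every sub-network target set is empty",
         call. = FALSE)
  }
  rows <- list()
  for (si in seq_along(subnets)) {
    s <- subnets[[si]]
    T_set <- targets[[si]]
    if (length(T_set) == 0L) next
    # universe must accommodate the target set even under the collection
    # default (module genes need not all appear in the collection)
    N_eff <- max(N, length(T_set),
                 max(vapply(collection, function(r) length(r$genes),
                            numeric(1))))
    for (r in collection) {
      k <- length(intersect(T_set, r$genes))
      nasrec <- compute_nas(T_set, r$genes, fc_norm)
      rows[[length(rows) + 1L]] <- data.frame(
        subnet = si, module_id = s$module_id, regulator = s$regulator,
        pathway = r$name, source_db = r$source_db,
        dice = dice_similarity(T_set, r$genes),
        p_value = hypergeom_pvalue(k, length(T_set), length(r$genes), N_eff),
        nas = nasrec$nas, cdr = nasrec$cdr, ngr = nasrec$ngr,
        mnf = nasrec$mnf, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)

  # per sub-network: lowest p, tie -> highest Dice, then name order
  res$chosen <- FALSE
  for (key in unique(res$subnet)) {
    ix <- which(res$subnet == key)
    ord <- order(res$p_value[ix], -res$dice[ix], res$pathway[ix])
    res$chosen[ix[ord[1L]]] <- TRUE
  }
  # per regulator: among its chosen annotations the highest similarity,
  # tie -> greatest NAS (one sub-network per regulator here, but the rule
  # is applied over however many candidates are present)
  res$selected <- FALSE
  ch <- which(res$chosen)
  for (reg in unique(res$regulator[ch])) {
    ix <- ch[res$regulator[ch] == reg]
    ord <- if (select_by == "dice") {
      order(-res$dice[ix], -res$nas[ix], res$pathway[ix])
    } else {
      order(res$p_value[ix], -res$nas[ix], res$pathway[ix])
    }
    res$selected[ix[ord[1L]]] <- TRUE
  }
  class(res) <- c("enrichment_results", "data.frame")
  res
}

#' Consolidate selected results sharing a pathway name
#'
#' When several regulators' selected sub-networks are annotated with the
#' same canonical pathway, they are merged into one consolidated pathway
#' record listing the member regulators and carrying the maximum NAS and
#' minimum p-value among the members. The per-member table is kept alongside
#' so no information is lost.
#'
#' @param results An `enrichment_results` table; only rows with
#'   `selected == TRUE` are consolidated (all rows if the flag is absent).
#' @return Data frame with columns `module_id`, `pathway`, `source_db`,
#'   `n_members`, `members` (comma-separated regulators), `nas`
#'   (max), `p_value` (min).
#' @export
consolidate <- function(results) {
  if (is.null(results) || nrow(results) == 0L) {
    return(data.frame(module_id = character(0), pathway = character(0),
                      source_db = character(0), n_members = integer(0),
                      members = character(0), nas = numeric(0),
                      p_value = numeric(0), stringsAsFactors = FALSE))
  }
  sel <- if ("selected" %in% names(results)) results[results$selected, ,
                                                     drop = FALSE] else results
  if (nrow(sel) == 0L) return(consolidate(NULL))
  key <- paste(sel$module_id, sel$pathway, sep = "\r")
  out <- do.call(rbind, lapply(split(seq_len(nrow(sel)), key), function(ix) {
    data.frame(module_id = sel$module_id[ix[1L]],
               pathway = sel$pathway[ix[1L]],
               source_db = sel$source_db[ix[1L]],
               n_members = length(ix),
               members = paste(sort(sel$regulator[ix]), collapse = ","),
               nas = max(sel$nas[ix]),
               p_value = min(sel$p_value[ix]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(-out$nas, out$p_value, out$pathway), , drop = FALSE]
}
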