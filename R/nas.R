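#' Min-max normalize signed fold changes into [0, 1]
#'
#' A fold change v (taken with sign) is mapped to
#' \eqn{(v - v_{min}) / (v_{max} - v_{min})}, where \eqn{v_{min}} and
#' \eqn{v_{max}} are the minimum and maximum fold changes over the
#' comparison. The extremes are taken over all differentially expressed
#' genes of the comparison so that the resulting activity scores are
#' comparable across modules of one contrast. This scaling favors positive
#' fold changes, i.e. activation. When every fold change is identical the
#' map is degenerate and all values are set to 0.5 (neutral activity) with
#' a warning.
#'
#' @param fcs Named numeric vector of signed (log) fold changes.
#' @return Named numeric vector in `[0, 1]` with attributes `v_min` and
#'   `v_max`.
#' @export
normalize_fold_changes <- function(fcs) {
  if (length(fcs) == 0L) {
    stop("empty fold-change mapping", call. = FALSE)
  }
  v_min <- min(fcs)
  v_max <- max(fcs)
  if (v_max == v_min) {
    warning("all fold changes equal (v_max = v_min); mapping every gene ",
            "to neutral activity 0.5", call. = FALSE)
    out <- stats::setNames(rep(0.5, length(fcs)), names(fcs))
  } else {
    out <- (fcs - v_min) / (v_max - v_min)
  }
  attr(out, "v_min") <- v_min
  attr(out, "v_max") <- v_max
  out
}

#' Network activity score of a target set against a reference signature
#'
#' \deqn{NAS = (MNF \times CDR) / NGR}
#' where CDR is the number of common molecules between the target set and
#' the reference gene signature, NGR the signature size, and MNF the mean
#' min-max-normalized fold change of the CDR genes (0 when the overlap is
#' empty). NAS lies in `[0, 1]` and expresses how strongly the reference
#' signature is influenced by the experimental condition.
#'
#' @param target_set Character vector of genes (module genes inside the
#'   minimal sub-network).
#' @param reference Character vector, non-empty reference gene signature, or
#'   a single gene-set record from a `gene_set_collection`.
#' @param norm_fc Named numeric vector of normalized fold changes covering
#'   `target_set` (see [normalize_fold_changes()]).
#' @return A `nas_record`: list with `cdr`, `ngr`, `mnf`, `nas`, `v_min`,
#'   `v_max`.
#' @export
compute_nas <- function(target_set, reference, norm_fc) {
  if (is.list(reference) && !is.null(reference$genes)) {
    reference <- reference$genes
  }
  reference <- unique(as.character(reference))
  if (length(reference) == 0L) {
    stop("reference gene signature is empty", call. = FALSE)
  }
  target_set <- unique(as.character(target_set))
  common <- intersect(target_set, reference)
  miss <- setdiff(common, names(norm_fc))
  if (length(miss) > 0L) {
    stop("normalized fold changes missing for: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  }
  cdr <- length(common)
  ngr <- length(reference)
  mnf <- if (cdr == 0L) 0 else mean(norm_fc[common])
  structure(list(cdr = cdr, ngr = ngr, mnf = mnf,
                 nas = mnf * cdr / ngr,
                 v_min = attr(norm_fc, "v_min") %||% NA_real_,
                 v_max = attr(norm_fc, "v_max") %||% NA_real_),
            class = "nas_record")
}

#' @export
print.nas_record <- function(x, ...) {
  cat(sprintf("NAS = (MNF %.4g x CDR %d) / NGR %d = %.4g\n",
              x$mnf, x$cdr, x$ngr, x$nas))
  invisible(x)
}

#' Rank enrichment results by network activity score
#'
#' Orders an annotation table by descending NAS; ties are broken by
#' ascending p-value, then by pathway name.
#'
#' @param results An `enrichment_results` data frame (see
#'   [annotate_subnetworks()]).
#' @return The same table, reordered.
#' @export
rank_results <- function(results) {
  if (is.null(results) || nrow(results) == 0L) {
    return(results)
  }
  out <- results[order(-results$nas, results$p_value, results$pathway), ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}
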