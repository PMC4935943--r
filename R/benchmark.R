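BENCH_SCENARIOS <- c(top10 = 10L, top100 = 100L, all = NA_integer_)

#' Build a truth table of positive/negative pathway annotations
#'
#' Every reference pathway evaluated in a benchmark must be annotated as a
#' positive or negative result for each experimental dataset (for instance,
#' pathways containing the perturbed gene are positives).
#'
#' @param dataset Character vector of dataset labels.
#' @param pathway Character vector of pathway names.
#' @param label Character vector, each `"positive"` or `"negative"`.
#' @return A `truth_table` data frame.
#' @export
truth_table <- function(dataset, pathway, label) {
  stopifnot(length(dataset) == length(pathway),
            length(pathway) == length(label),
            all(label %in% c("positive", "negative")))
  structure(unique(data.frame(dataset = as.character(dataset),
                              pathway = as.character(pathway),
                              label = label, stringsAsFactors = FALSE)),
            class = c("truth_table", "data.frame"))
}

#' @rdname truth_table
#' @param path TSV file `dataset<TAB>pathway<TAB>label`.
#' @export
read_truth_table <- function(path) {
  tt <- read_tsv_pairs(path, 3L, what = "truth")
  bad <- which(!tt$fields[, 3L] %in% c("positive", "negative"))
  if (length(bad) > 0L) {
    stop("truth table ", path, ": line ", tt$lineno[bad[1L]],
         " has label '", tt$fields[bad[1L], 3L],
         "' (expected positive/negative)", call. = FALSE)
  }
  truth_table(tt$fields[, 1L], tt$fields[, 2L], tt$fields[, 3L])
}

#' Read a tool's ranked pathway output
#'
#' @param path TSV file `pathway<TAB>p_value`, one row per pathway, most
#'   significant first (re-sorted by p-value on read).
#' @return Data frame `pathway`, `p_value` sorted by ascending p.
#' @export
read_ranked_output <- function(path) {
  rk <- read_tsv_pairs(path, 2L, what = "ranked output")
  p <- suppressWarnings(as.numeric(rk$fields[, 2L]))
  if (anyNA(p)) {
    stop("ranked output ", path, ": line ",
         rk$lineno[which(is.na(p))[1L]], " has a non-numeric p-value",
         call. = FALSE)
  }
  df <- data.frame(pathway = rk$fields[, 1L], p_value = p,
                   stringsAsFactors = FALSE)
  df[order(df$p_value), , drop = FALSE]
}

#' Confusion counts of a ranked pathway list against a truth table
#'
#' Within the scenario's window (the 10 or 100 top-ranked results, or all
#' results), a positive pathway with p-value below `alpha` is a true
#' positive, a negative pathway below `alpha` a false positive, a positive
#' at or above `alpha` a false negative and a negative at or above `alpha` a
#' true negative. Labelled pathways outside the window (including pathways
#' the tool did not report at all) are treated as not called: positives
#' count as false negatives, negatives as true negatives — the only reading
#' under which the top-k scenarios differ from `all`.
#'
#' @param ranked Data frame `pathway`, `p_value`, sorted by significance.
#' @param truth A `truth_table`.
#' @param dataset Dataset label selecting the truth rows.
#' @param scenario One of `"top10"`, `"top100"`, `"all"`.
#' @param alpha Significance cut (default 0.05).
#' @return Named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusion_counts <- function(ranked, truth, dataset,
                             scenario = c("all", "top10", "top100"),
                             alpha = 0.05) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(truth, "truth_table"))
  tt <- truth[truth$dataset == dataset, , drop = FALSE]
  if (nrow(tt) == 0L) {
    stop("no truth annotations for dataset '", dataset, "'", call. = FALSE)
  }
  labels <- stats::setNames(tt$label, tt$pathway)
  if (nrow(ranked) > 0L) {
    if (is.unsorted(ranked$p_value)) {
      stop("ranked list must be sorted by significance", call. = FALSE)
    }
    unknown <- setdiff(ranked$pathway, names(labels))
    if (length(unknown) > 0L) {
      stop("pathway without truth annotation in dataset '", dataset, "': ",
           unknown[1L], call. = FALSE)
    }
  }
  k <- BENCH_SCENARIOS[[scenario]]
  window <- if (is.na(k)) ranked else utils::head(ranked, k)

  counts <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
  called <- character(0)
  if (nrow(window) > 0L) {
    lab <- labels[window$pathway]
    sig <- window$p_value < alpha
    counts["tp"] <- sum(lab == "positive" & sig)
    counts["fp"] <- sum(lab == "negative" & sig)
    counts["fn"] <- sum(lab == "positive" & !sig)
    counts["tn"] <- sum(lab == "negative" & !sig)
    called <- window$pathway
  }
  outside <- labels[setdiff(names(labels), called)]
  counts["fn"] <- counts["fn"] + sum(outside == "positive")
  counts["tn"] <- counts["tn"] + sum(outside == "negative")
  counts
}

#' The four standard benchmark measures from confusion counts
#'
#' Precision tp/(tp+fp); recall (sensitivity) tp/(tp+fn); specificity
#' tn/(tn+fp); accuracy (tp+tn)/(positives+negatives). A 0/0 ratio yields
#' `NaN`, the undefined marker excluded from z-score aggregation.
#'
#' @param counts Named vector with elements `tp`, `fp`, `tn`, `fn`.
#' @return Named numeric vector `c(precision, recall, specificity,
#'   accuracy)`.
#' @export
performance_metrics <- function(counts) {
  stopifnot(all(c("tp", "fp", "tn", "fn") %in% names(counts)),
            all(counts >= 0))
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  tn <- counts[["tn"]]; fn <- counts[["fn"]]
  ratio <- function(num, den) if (den == 0) NaN else num / den
  c(precision = ratio(tp, tp + fp),
    recall = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    accuracy = ratio(tp + tn, tp + tn + fp + fn))
}

#' Cross-tool z-score aggregation of benchmark measures
#'
#' For each measure (and dataset), each tool's value is standardized
#' against the mean and sample standard deviation over tools; a tool's
#' cumulative quality score is the mean of its z-scores across the four
#' measures and all datasets. A tool that beats the across-tool average on
#' every measure obtains a positive mean z. Undefined measures (`NaN`) are
#' excluded; when a measure shows zero variance across tools every tool
#' receives z = 0 for it (reported via a message).
#'
#' @param table Data frame with columns `tool`, `measure`, `value` and
#'   optionally `dataset` (assumed single dataset when absent).
#' @param pooled Standardize over tools pooling all datasets together
#'   instead of per dataset (default `FALSE`: per dataset, then averaged).
#' @return List with `z` (data frame `tool`, `dataset`, `measure`, `z`) and
#'   `cumulative` (named numeric, mean z per tool, descending).
#' @export
zscore_aggregate <- function(table, pooled = FALSE) {
  stopifnot(all(c("tool", "measure", "value") %in% names(table)))
  if (!"dataset" %in% names(table)) {
    table$dataset <- "dataset1"
  }
  if (length(unique(table$tool)) < 2L) {
    stop("z-score aggregation needs at least 2 tools", call. = FALSE)
  }
  grp <- if (pooled) table$measure else
    paste(table$dataset, table$measure, sep = "\r")
  zs <- rep(NA_real_, nrow(table))
  for (g in unique(grp)) {
    ix <- which(grp == g & is.finite(table$value))
    if (length(ix) < 2L) next
    x <- table$value[ix]
    s <- stats::sd(x)
    if (s == 0) {
      message("zero variance across tools for ",
              sub("\r", " / ", g, fixed = TRUE), "; z set to 0")
      zs[ix] <- 0
    } else {
      zs[ix] <- (x - mean(x)) / s
    }
  }
  z <- data.frame(tool = table$tool, dataset = table$dataset,
                  measure = table$measure, z = zs,
                  stringsAsFactors = FALSE)
  z <- z[!is.na(z$z), , drop = FALSE]
  cumulative <- sort(vapply(split(z$z, z$tool), mean, numeric(1)),
                     decreasing = TRUE)
  list(z = z, cumulative = cumulative)
}

#' Run a full benchmark over tools, datasets and scenarios
#'
#' @param outputs Nested list `outputs[[tool]][[dataset]]`, each a ranked
#'   data frame (`pathway`, `p_value`).
#' @param truth A `truth_table` covering every (dataset, pathway).
#' @param scenarios Scenarios to evaluate (default all three).
#' @param alpha Significance cut.
#' @return List with `metrics` (long data frame of counts and measures) and
#'   `zscores` (one [zscore_aggregate()] result per scenario).
#' @export
run_benchmark <- function(outputs, truth,
                          scenarios = c("top10", "top100", "all"),
                          alpha = 0.05) {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  rows <- list()
  for (tool in names(outputs)) {
    for (ds in names(outputs[[tool]])) {
      for (sc in scenarios) {
        cc <- confusion_counts(outputs[[tool]][[ds]], truth, ds, sc, alpha)
        m <- performance_metrics(cc)
        rows[[length(rows) + 1L]] <- data.frame(
          tool = tool, dataset = ds, scenario = sc,
          tp = cc[["tp"]], fp = cc[["fp"]], tn = cc[["tn"]], fn = cc[["fn"]],
          measure = names(m), value = unname(m), stringsAsFactors = FALSE)
      }
    }
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  zscores <- lapply(stats::setNames(scenarios, scenarios), function(sc) {
    zscore_aggregate(metrics[metrics$scenario == sc,
                             c("tool", "dataset", "measure", "value")])
  })
  list(metrics = metrics, zscores = zscores)
}

#' Bar chart of cumulative z-scores per tool
#'
#' @param zres Result of [zscore_aggregate()] (or one element of
#'   [run_benchmark()]'s `zscores`).
#' @param ... Passed to [graphics::barplot()].
#' @export
plot_zscores <- function(zres, ...) {
  graphics::barplot(zres$cumulative, las = 2,
                    ylab = "mean z-score across measures",
                    main = "Cumulative benchmark quality", ...)
  invisible(zres$cumulative)
}
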