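make_truth <- function(...) {
  df <- data.frame(...)
  truth_table(df$dataset, df$pathway, df$label)
}

test_that("confusion counts apply the four definitions at alpha 0.05", {
  truth <- make_truth(dataset = "d1", pathway = c("P", "N"),
                      label = c("positive", "negative"))
  ranked <- data.frame(pathway = c("P", "N"), p_value = c(0.01, 0.20),
                       stringsAsFactors = FALSE)
  cc <- confusion_counts(ranked, truth, "d1", "top10")
  expect_equal(cc, c(tp = 1L, fp = 0L, tn = 1L, fn = 0L))
})

test_that("labelled pathways outside the scenario window are not called", {
  paths <- sprintf("P%02d", 1:50)
  truth <- make_truth(dataset = "d1", pathway = paths,
                      label = c(rep("negative", 49), "positive"))
  ranked <- data.frame(pathway = paths,
                       p_value = seq(0.001, 0.049, length.out = 50),
                       stringsAsFactors = FALSE)
  # the positive is ranked 50th: under top10 it is a false negative
  cc <- confusion_counts(ranked, truth, "d1", "top10")
  expect_equal(cc[["fn"]], 1L)
  expect_equal(cc[["tp"]], 0L)
  expect_equal(cc[["fp"]], 10L)
  expect_equal(cc[["tn"]], 39L)
  # under "all" it is significant, hence a true positive
  cc_all <- confusion_counts(ranked, truth, "d1", "all")
  expect_equal(cc_all[["tp"]], 1L)
  expect_equal(sum(cc_all), nrow(truth))
})

test_that("an empty ranked list leaves every labelled pathway uncalled", {
  truth <- make_truth(dataset = "d1", pathway = c("A", "B", "C"),
                      label = c("positive", "positive", "negative"))
  cc <- confusion_counts(data.frame(pathway = character(0),
                                    p_value = numeric(0)),
                         truth, "d1", "all")
  expect_equal(cc, c(tp = 0L, fp = 0L, tn = 1L, fn = 2L))
})

test_that("unlabelled pathways in a ranked list are reported by name", {
  truth <- make_truth(dataset = "d1", pathway = "A", label = "positive")
  ranked <- data.frame(pathway = c("A", "MYSTERY"), p_value = c(0.01, 0.02),
                       stringsAsFactors = FALSE)
  expect_error(confusion_counts(ranked, truth, "d1", "all"), "MYSTERY")
})

test_that("the four measures follow their formulas, with NaN for 0/0", {
  m <- performance_metrics(c(tp = 8, fp = 2, fn = 2, tn = 8))
  expect_equal(unname(m), rep(0.8, 4))
  perfect <- performance_metrics(c(tp = 5, fp = 0, fn = 0, tn = 7))
  expect_equal(unname(perfect), rep(1, 4))
  none <- performance_metrics(c(tp = 0, fp = 0, fn = 3, tn = 2))
  expect_true(is.nan(none[["precision"]]))
  expect_equal(none[["recall"]], 0)
})

test_that("z-scores standardize across tools and sum to zero per measure", {
  tab <- data.frame(tool = c("t1", "t2", "t3"), measure = "precision",
                    value = c(0.5, 0.7, 0.9), stringsAsFactors = FALSE)
  z <- zscore_aggregate(tab)
  expect_equal(unname(z$cumulative[c("t1", "t2", "t3")]), c(-1, 0, 1))
  expect_equal(sum(z$z$z), 0, tolerance = 1e-12)

  same <- tab; same$value <- 0.5
  expect_message(z0 <- zscore_aggregate(same), "zero variance")
  expect_true(all(z0$z$z == 0))

  expect_error(zscore_aggregate(tab[1, ]), "at least 2")
})

test_that("a tool above average on every measure gets a positive mean z", {
  set.seed(13)
  measures <- c("precision", "recall", "specificity", "accuracy")
  tab <- expand.grid(tool = c("good", "mid", "poor"), measure = measures,
                     dataset = c("d1", "d2"), stringsAsFactors = FALSE)
  tab$value <- ifelse(tab$tool == "good", runif(nrow(tab), 0.8, 0.95),
                      ifelse(tab$tool == "mid", runif(nrow(tab), 0.5, 0.6),
                             runif(nrow(tab), 0.2, 0.4)))
  z <- zscore_aggregate(tab)
  expect_gt(z$cumulative[["good"]], 0)
  expect_lt(z$cumulative[["poor"]], 0)
  # per (dataset, measure) group the z-scores still sum to ~0
  grp <- paste(z$z$dataset, z$z$measure)
  expect_true(all(abs(tapply(z$z$z, grp, sum)) < 1e-10))
})

test_that("run_benchmark evaluates every tool, dataset and scenario", {
  truth <- make_truth(dataset = rep(c("d1", "d2"), each = 4),
                      pathway = rep(c("P1", "P2", "N1", "N2"), 2),
                      label = rep(c("positive", "positive", "negative",
                                    "negative"), 2))
  mk <- function(p) {
    df <- data.frame(pathway = c("P1", "P2", "N1", "N2"), p_value = p,
                     stringsAsFactors = FALSE)
    df[order(df$p_value), , drop = FALSE]
  }
  outputs <- list(
    sharp = list(d1 = mk(c(0.01, 0.02, 0.2, 0.3)),
                 d2 = mk(c(0.01, 0.03, 0.4, 0.5))),
    blunt = list(d1 = mk(c(0.01, 0.2, 0.01, 0.3)),
                 d2 = mk(c(0.2, 0.3, 0.01, 0.02))))
  bench <- run_benchmark(outputs, truth)
  expect_equal(sort(unique(bench$metrics$scenario)),
               c("all", "top10", "top100"))
  expect_equal(nrow(bench$metrics), 2 * 2 * 3 * 4)
  expect_gt(bench$zscores$all$cumulative[["sharp"]],
            bench$zscores$all$cumulative[["blunt"]])
})

test_that("truth tables and ranked outputs read from disk validate labels", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("d1\tP1\tpositive", "d1\tN1\tnegative"), tf)
  tt <- read_truth_table(tf)
  expect_equal(nrow(tt), 2)
  writeLines(c("d1\tP1\tmaybe"), tf)
  expect_error(read_truth_table(tf), "maybe")

  rf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("P2\t0.2", "P1\t0.01"), rf)
  rk <- read_ranked_output(rf)
  expect_equal(rk$pathway, c("P1", "P2"))  # re-sorted by p
  writeLines(c("P1\tnot-a-number"), rf)
  expect_error(read_ranked_output(rf), "line 1")
})
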