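test_that("GMT parsing deduplicates genes and flags malformed lines", {
  gf <- withr::local_tempfile(fileext = ".gmt")
  writeLines("P1\tdesc\tg1\tg2\tg2", gf)
  col <- read_gmt(gf, source_db = "KEGG")
  expect_length(col, 1)
  expect_setequal(col$P1$genes, c("g1", "g2"))
  expect_equal(col$P1$source_db, "KEGG")

  writeLines(character(0), gf)
  expect_length(read_gmt(gf), 0)

  writeLines("P1\tonly-two-fields", gf)
  expect_error(read_gmt(gf), "line 1")
})

test_that("Dice similarity follows its formula and attains its bounds", {
  expect_equal(dice_similarity(c("g1", "g2"), c("g1", "g2")), 1)
  expect_equal(dice_similarity(c("g1", "g2", "g3"),
                               c("g2", "g3", "g4", "g5")), 4 / 7)
  expect_equal(dice_similarity("a", "b"), 0)
  expect_error(dice_similarity(character(0), character(0)), "empty")
  expect_error(dice_similarity("a", character(0)), "empty")
})

test_that("Dice is symmetric, maximal only at equality, monotone in overlap", {
  set.seed(21)
  pool <- sprintf("g%02d", 1:20)
  for (rep in 1:25) {
    A <- sample(pool, sample(1:8, 1))
    B <- sample(pool, sample(1:8, 1))
    expect_equal(dice_similarity(A, B), dice_similarity(B, A))
    expect_equal(dice_similarity(A, B) == 1, setequal(A, B))
    extra_in <- setdiff(B, A)
    if (length(extra_in) > 0) {
      expect_gte(dice_similarity(c(A, extra_in[1]), B),
                 dice_similarity(A, B))
    }
    extra_out <- setdiff(pool, union(A, B))
    if (length(extra_out) > 0) {
      expect_lte(dice_similarity(c(A, extra_out[1]), B),
                 dice_similarity(A, B))
    }
  }
})

test_that("hypergeometric p-values match brute-force enumeration", {
  expect_equal(hypergeom_pvalue(0, 3, 4, 10), 1)
  expect_equal(hypergeom_pvalue(2, 3, 4, 10), 1 / 3)
  expect_equal(hypergeom_pvalue(5, 5, 5, 5), 1)
  expect_error(hypergeom_pvalue(4, 3, 4, 10), "inconsistent")

  for (N in c(5, 9, 15)) {
    for (t in 0:N) {
      for (r in 0:N) {
        for (k in 0:min(t, r)) {
          expect_equal(hypergeom_pvalue(k, t, r, N),
                       oracle_hyper(k, t, r, N),
                       tolerance = 1e-12,
                       label = sprintf("k=%d t=%d r=%d N=%d", k, t, r, N))
        }
      }
    }
  }
})

test_that("functional group scoring reproduces the 1.3 <-> 0.05 equivalence", {
  expect_equal(functional_group_score(rep(0.05, 3)), -log10(0.05))
  expect_equal(round(functional_group_score(rep(0.05, 3)), 3), 1.301)
  expect_equal(functional_group_score(1.0), 0)
  expect_equal(functional_group_score(c(0.1, 0.001)), 2)
  expect_error(functional_group_score(c(0.05, 0)), "positive")
  expect_error(functional_group_score(numeric(0)), "empty")
})

test_that("functional group filter keeps score > 1 groups, p < 0.05 genes", {
  groups <- list(
    keep = data.frame(term = c("t1", "t2"), p = c(0.01, 0.2),
                      genes = c("g1,g2", "g3"),
                      stringsAsFactors = FALSE),
    weak = data.frame(term = "t3", p = 0.5, genes = "g4",
                      stringsAsFactors = FALSE))
  out <- filter_functional_groups(groups)
  expect_named(out, "keep")
  expect_setequal(out$keep, c("g1", "g2"))  # t2 at p=0.2 contributes none
})

test_that("annotation applies the stated selection and tie-break rules", {
  net <- make_network(list(c("r", "g1"), c("g1", "g2"), c("g2", "g3")),
                      roles = c(r = "receptor"))
  w <- weight_edges(net)
  mod <- deg_module(c("g1", "g2", "g3"), c(2, 1, 0.5),
                    c(0.01, 0.01, 0.01))
  sn <- build_subnetwork(w, "r", mod, extend = FALSE)

  # the reference with the lowest overlap p-value is chosen per sub-network
  col <- gene_set_collection(list(
    hit = c("g1", "g2", "g3"),
    padded = c("g1", "g2", "g3", "x1", "x2", "x3"),
    miss = c("y1", "y2")))
  ann <- annotate_subnetworks(list(sn), mod, col, universe = 20)
  expect_equal(ann$pathway[ann$chosen], "hit")

  # equal p-values (certain overlaps in a tiny universe): higher Dice wins
  col_tie <- gene_set_collection(list(lean = "g1", broad = c("g1", "g2")))
  ann_tie <- annotate_subnetworks(list(sn), mod, col_tie, universe = 3)
  expect_equal(unique(ann_tie$p_value), 1)  # both overlaps are certain
  expect_equal(ann_tie$pathway[ann_tie$chosen], "broad")
  expect_gt(ann_tie$dice[ann_tie$pathway == "broad"],
            ann_tie$dice[ann_tie$pathway == "lean"])

  # two sub-networks for one regulator with equal Dice: greatest NAS wins
  sn1 <- build_subnetwork(w, "r", deg_module("g1", 2, 0.01), extend = FALSE)
  sn2 <- build_subnetwork(w, "r", deg_module("g2", 1, 0.01), extend = FALSE)
  col2 <- gene_set_collection(list(pair = c("g1", "g2")))
  ann2 <- annotate_subnetworks(list(sn1, sn2), mod, col2, universe = 20)
  expect_equal(length(unique(ann2$dice)), 1)   # Dice ties across sub-networks
  expect_equal(sum(ann2$selected), 1)
  expect_equal(ann2$nas[ann2$selected], max(ann2$nas))
  expect_gt(max(ann2$nas), min(ann2$nas))      # the tie-break was decisive
})

test_that("annotation errors when every target set is empty", {
  net <- make_network(list(c("r", "x"), c("x", "y")),
                      roles = c(r = "receptor"))
  w <- weight_edges(net)
  mod <- deg_module(c("zz", "qq"), c(1, 2), c(0.01, 0.01))
  sn <- structure(list(regulator = "r", module_id = "m", nodes = c("r", "x"),
                       edges = data.frame(), paths = list(),
                       path_nodes = character(0),
                       covered_genes = character(0), extended = FALSE),
                  class = "subnetwork")
  col <- gene_set_collection(list(P = "zz"))
  expect_error(annotate_subnetworks(list(sn), mod, col), "no mappable gene")
})

test_that("consolidation merges same-name selections and keeps extremes", {
  res <- data.frame(
    module_id = "m1",
    regulator = c("r1", "r2", "r3", "r4"),
    pathway = c("CARDIACEGF", "CARDIACEGF", "CARDIACEGF", "OTHER"),
    source_db = "BioCarta",
    dice = c(0.5, 0.4, 0.3, 0.2),
    p_value = c(0.01, 0.002, 0.05, 0.04),
    nas = c(0.3, 0.6, 0.1, 0.2),
    selected = TRUE, stringsAsFactors = FALSE)
  out <- consolidate(res)
  expect_equal(nrow(out), 2)
  card <- out[out$pathway == "CARDIACEGF", ]
  expect_equal(card$n_members, 3)
  expect_equal(card$nas, 0.6)
  expect_equal(card$p_value, 0.002)
  expect_equal(card$members, "r1,r2,r3")

  distinct <- res; distinct$pathway <- paste0("P", 1:4)
  expect_equal(nrow(consolidate(distinct)), 4)
  expect_equal(nrow(consolidate(res[0, ])), 0)
})
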