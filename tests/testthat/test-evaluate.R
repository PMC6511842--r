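make_gs <- function(n_bg = 100, n_gp = 20, n_gn = 30) {
  bg <- paste0("g", seq_len(n_bg))
  gold_standard(bg, bg[seq_len(n_gp)], bg[n_gp + seq_len(n_gn)])
}

test_that("miRNA eligibility applies the strict GP count and fraction rule", {
  bg600 <- paste0("g", 1:600)
  expect_true(eligible_mirna(gold_standard(bg600, bg600[1:31], bg600[40:60])))
  expect_false(eligible_mirna(gold_standard(bg600, bg600[1:30], bg600[40:60])))
  bg1000 <- paste0("g", 1:1000)
  expect_false(eligible_mirna(gold_standard(bg1000, bg1000[1:40],
                                            bg1000[50:70])))
})

test_that("prediction scoring reproduces the defining identities", {
  gs <- make_gs()
  whole <- score_predictions(gs$background, gs)
  expect_equal(whole$sensitivity, 1)
  expect_equal(whole$specificity, 0)
  expect_equal(whole$gain, 0)

  perfect <- score_predictions(gs$positives, gs)
  expect_equal(perfect$gain, 1)

  # GP = 10 with 7 hits, GN = 20 with 4 predicted
  gs2 <- gold_standard(paste0("g", 1:50), paste0("g", 1:10),
                       paste0("g", 11:30))
  pred <- c(paste0("g", 1:7), paste0("g", 11:14))
  m <- score_predictions(pred, gs2)
  expect_equal(m$sensitivity, 0.7)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$gain, 0.5, tolerance = 1e-12)
})

test_that("genes outside the background do not change the score", {
  gs <- make_gs()
  pred <- c(gs$positives[1:5], gs$negatives[1:3])
  m1 <- score_predictions(pred, gs)
  m2 <- suppressWarnings(score_predictions(c(pred, "alien1", "alien2"), gs))
  expect_equal(m1, m2)
  expect_error(score_predictions("g1", gold_standard("g1", character(0)[0],
                                                     character(0))),
               "non-empty")
})

test_that("degree filtering keeps genes by induced-subgraph degree", {
  path <- tempfile()
  writeLines(c("a\tb\t200", "b\tc\t200", "a\tc\t200"), path)
  triangle <- read_edge_list(path, 150)
  expect_setequal(network_degree_filter(c("a", "b", "c"), triangle, 2),
                  c("a", "b", "c"))
  writeLines(c("a\tb\t200", "b\tc\t200"), path)
  path_net <- read_edge_list(path, 150)
  expect_equal(network_degree_filter(c("a", "b", "c"), path_net, 2), "b")
  expect_equal(network_degree_filter(c("a", "b", "c"), path_net, 0),
               c("a", "b", "c"))
  # degree counts only interactions among predicted genes
  expect_equal(network_degree_filter(c("a", "c"), path_net, 1), character(0))
})

test_that("degree filtering shrinks monotonically in k", {
  set.seed(77)
  genes <- paste0("g", 1:40)
  edges <- t(combn(genes, 2))
  keep <- runif(nrow(edges)) < 0.15
  path <- tempfile()
  writeLines(paste(edges[keep, 1], edges[keep, 2], 200, sep = "\t"), path)
  net <- read_edge_list(path, 150)
  prev <- genes
  for (k in 0:6) {
    cur <- network_degree_filter(genes, net, k)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("pooled condition curves filter, order and accumulate correctly", {
  gs <- make_gs()
  labels <- c(t1 = "breast tumor vs normal", t2 = "breast cancer line",
              n1 = "liver control", n2 = "kidney treatment")
  bics <- list(
    list(conditions = c("t1", "t2", "n1", "n2"), genes = gs$positives[1:8]),   # 0.5
    list(conditions = c("t1", "t2"), genes = gs$positives[9:12]),              # 1.0
    list(conditions = c("n1", "n2", "t1", "n1", "n2"), genes = gs$negatives)   # 0.2
  )
  curve <- pooled_condition_curve(bics, labels, "breast", 0.3, gs)
  expect_equal(nrow(curve), 2L)  # the 0.2 bicluster is filtered out
  expect_equal(curve$condition_fraction, c(1.0, 0.5))
  expect_equal(curve$tpr, c(4 / 20, 12 / 20))
  expect_equal(curve$fpr, c(0, 0))

  # pool equal to GP gives the (1, 0) point
  one <- pooled_condition_curve(
    list(list(conditions = "t1", genes = gs$positives)), labels, "breast",
    0.3, gs)
  expect_equal(one$tpr, 1)
  expect_equal(one$fpr, 0)

  # monotone in both coordinates for nested random pools
  set.seed(3)
  many <- lapply(1:6, function(i)
    list(conditions = sample(names(labels), 3, TRUE),
         genes = sample(gs$background, sample(5:30, 1))))
  cv <- pooled_condition_curve(many, labels, "breast", 0.1, gs)
  if (nrow(cv) > 1) {
    expect_true(all(diff(cv$tpr) >= 0))
    expect_true(all(diff(cv$fpr) >= 0))
  }
})

test_that("gold standards enforce disjointness and background containment", {
  bg <- paste0("g", 1:10)
  expect_error(gold_standard(bg, c("g1", "g2"), c("g2", "g3")), "both")
  expect_warning(gs <- gold_standard(bg, c("g1", "outside"), "g3"), "dropped")
  expect_equal(gs$positives, "g1")
})
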