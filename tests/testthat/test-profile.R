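test_that("quantization thresholds are inclusive and symmetric", {
  fc <- matrix(c(0.40, log2(1.3), -1.2, 0.1, NA, -log2(1.3)), nrow = 2,
               dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
  q <- quantize(fc, log2(1.3))
  expect_equal(q["g1", "c1"], 1L)      # 0.40 > log2(1.3) ~ 0.3785
  expect_equal(q["g2", "c1"], 1L)      # exactly at threshold counts
  expect_equal(q["g2", "c3"], -1L)     # exactly at -threshold
  expect_equal(q["g2", "c2"], 0L)      # missing -> neutral
  q2 <- quantize(fc, 1.0)
  expect_equal(q2["g1", "c2"], -1L)    # -1.2 at 2.0 FC threshold
  expect_error(quantize(fc, 0), "positive")
})

test_that("raising the threshold never turns a neutral call into a regulated one", {
  set.seed(11)
  fc <- matrix(rnorm(300), 30, 10,
               dimnames = list(paste0("g", 1:30), paste0("c", 1:10)))
  lo <- quantize(fc, log2(1.3))
  hi <- quantize(fc, log2(2.0))
  expect_true(all(lo[hi != 0] == hi[hi != 0]))
})

test_that("hypergeometric enrichment matches an exhaustive-summation oracle", {
  # closed-form cases: N=100, K=10, n=10
  set.seed(23)
  genes <- paste0("g", 1:100)
  bg <- genes[1:10]
  # condition 1: all 10 regulated genes inside the background
  # condition 2: exactly 1 of 10 inside
  # condition 3: none regulated
  tern <- matrix(0L, 100, 3, dimnames = list(genes, c("c1", "c2", "c3")))
  tern[1:10, 1] <- 1L
  tern[c(1, 11:19), 2] <- 1L
  q <- structure(tern, fc_threshold = log2(1.3),
                 class = c("ternary_matrix", "matrix"))
  sel <- enriched_conditions(q, bg, "up", fdr_cutoff = 0.05)
  all_tab <- attr(sel, "all_conditions")
  expect_equal(all_tab$p[1], 1 / choose(100, 10), tolerance = 1e-12)
  expect_equal(all_tab$p[2], 1 - choose(90, 10) / choose(100, 10),
               tolerance = 1e-12)
  expect_equal(all_tab$p[3], 1)
  expect_equal(sel$condition, "c1")

  # random cases against the brute-force tail sum
  for (i in 1:25) {
    N <- sample(20:200, 1)
    K <- sample(5:(N - 5), 1)
    n <- sample(1:(N - 1), 1)
    tern <- matrix(0L, N, 1,
                   dimnames = list(paste0("g", 1:N), "c"))
    reg <- sample(N, n)
    tern[reg, 1] <- 1L
    q <- structure(tern, fc_threshold = 1,
                   class = c("ternary_matrix", "matrix"))
    bgi <- paste0("g", sample(N, K))
    tab <- attr(enriched_conditions(q, bgi, "up"), "all_conditions")
    k <- sum(paste0("g", reg) %in% bgi)
    expect_equal(tab$p, hyper_upper_tail(k, N, K, n), tolerance = 1e-12)
  }
})

test_that("selected condition sets shrink as the FDR cutoff decreases", {
  set.seed(31)
  N <- 150
  genes <- paste0("g", 1:N)
  bg <- sample(genes, 30)
  tern <- matrix(0L, N, 40, dimnames = list(genes, paste0("c", 1:40)))
  for (j in 1:40) {
    n <- sample(5:40, 1)
    # half the conditions lean into the background set
    pool <- if (j <= 20) c(bg, sample(genes, 20)) else genes
    tern[unique(sample(pool, n)), j] <- 1L
  }
  q <- structure(tern, fc_threshold = 1,
                 class = c("ternary_matrix", "matrix"))
  cuts <- c(0.2, 0.1, 0.05, 0.01)
  sel <- lapply(cuts, function(f) enriched_conditions(q, bg, "up", f)$condition)
  for (i in 2:length(cuts))
    expect_true(all(sel[[i]] %in% sel[[i - 1]]))
})

test_that("MIR profiles binarize by direction and never overlap", {
  genes <- paste0("g", 1:60)
  conds <- paste0("c", 1:8)
  set.seed(5)
  tern <- matrix(sample(c(-1L, 0L, 1L), 60 * 8, TRUE, c(.25, .4, .35)), 60, 8,
                 dimnames = list(genes, conds))
  # make background genes strongly up in conditions 1-4, down in 5-8
  bg <- genes[1:20]
  tern[1:20, 1:4] <- 1L
  tern[1:20, 5:8] <- -1L
  q <- structure(tern, fc_threshold = log2(1.3),
                 class = c("ternary_matrix", "matrix"))
  up <- build_mir_profile(q, bg, "up", 0.05)
  down <- build_mir_profile(q, bg, "down", 0.05)
  expect_setequal(colnames(up$values), bg)
  expect_true(all(up$values %in% 0:1))
  # up cell is 1 iff ternary +1; down iff -1; never both
  common <- intersect(rownames(up$values), rownames(down$values))
  if (length(common))
    expect_true(all(up$values[common, ] * down$values[common, ] == 0))
  for (cd in rownames(up$values))
    expect_equal(unname(up$values[cd, ]),
                 unname(as.integer(tern[bg, cd] == 1L)))
  for (cd in rownames(down$values))
    expect_equal(unname(down$values[cd, ]),
                 unname(as.integer(tern[bg, cd] == -1L)))
})

test_that("background genes absent from the matrix are dropped with a message", {
  genes <- paste0("g", 1:30)
  tern <- matrix(0L, 30, 2, dimnames = list(genes, c("c1", "c2")))
  tern[1:5, 1] <- 1L   # condition c1 regulates exactly the background genes
  q <- structure(tern, fc_threshold = 1,
                 class = c("ternary_matrix", "matrix"))
  expect_message(prof <- build_mir_profile(q, c(genes[1:5], "missing"), "up"),
                 "dropped")
  expect_false("missing" %in% colnames(prof$values))
  expect_equal(rownames(prof$values), "c1")
})

test_that("zero enriched conditions give an empty profile with a warning", {
  genes <- paste0("g", 1:50)
  tern <- matrix(0L, 50, 3, dimnames = list(genes, paste0("c", 1:3)))
  q <- structure(tern, fc_threshold = 1,
                 class = c("ternary_matrix", "matrix"))
  expect_warning(prof <- build_mir_profile(q, genes[1:10], "up"), "empty")
  expect_equal(nrow(prof$values), 0L)
  fit <- pbe(prof)
  expect_length(fit$biclusters, 0L)
})
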