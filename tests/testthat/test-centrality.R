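test_that("degree centrality and the maximum-degree node set", {
  expect_equal(unname(degree_centrality(make_adj(matrix(0, 6, 6)))),
               rep(0, 6))

  one <- matrix(0, 6, 6); one[1, 2] <- one[2, 1] <- 96
  d <- degree_centrality(make_adj(one))
  expect_equal(unname(d), c(96, 96, 0, 0, 0, 0))
  md <- max_degree(make_adj(one))
  expect_equal(md$score, 96)
  expect_setequal(md$nodes, c("PE", "YSE"))

  complete <- matrix(40, 6, 6); diag(complete) <- 0
  expect_equal(unname(degree_centrality(make_adj(complete))), rep(200, 6))

  md0 <- max_degree(make_adj(matrix(0, 6, 6)))
  expect_equal(md0$score, 0)
  expect_length(md0$nodes, 0)

  set.seed(11)
  for (rep in 1:50) {
    A <- rand_weight_matrix()
    expect_equal(unname(degree_centrality(A)),
                 unname(apply(A, 1, sum)))  # brute-force row sums
    expect_equal(max_degree(make_adj(A))$score, max(apply(A, 1, sum)))
  }
})

test_that("eigenvector centrality matches closed forms and dense eigen", {
  # complete equal-weight graph: uniform Perron vector
  complete <- matrix(70, 6, 6); diag(complete) <- 0
  v <- eigenvector_centrality(make_adj(complete))
  expect_equal(unname(v), rep(1 / sqrt(6), 6), tolerance = 1e-9)

  # single link: mass splits evenly over the 2x2 block
  one <- matrix(0, 6, 6); one[1, 2] <- one[2, 1] <- 88
  v <- eigenvector_centrality(make_adj(one))
  expect_equal(unname(v), c(1 / sqrt(2), 1 / sqrt(2), 0, 0, 0, 0),
               tolerance = 1e-9)

  expect_equal(unname(eigenvector_centrality(make_adj(matrix(0, 6, 6)))),
               rep(0, 6))

  set.seed(12)
  for (rep in 1:200) {
    A <- rand_weight_matrix(density = stats::runif(1, 0.2, 1))
    v <- eigenvector_centrality(A)
    if (all(A == 0)) next
    expect_equal(sum(v^2), 1, tolerance = 1e-9)
    expect_true(all(v >= 0))
    e <- eigen(A, symmetric = TRUE)
    ref <- e$vectors[, 1]
    if (sum(ref) < 0) ref <- -ref
    expect_lt(max(abs(unname(v) - ref)), 1e-8)
  }
})

test_that("spectral radius matches closed forms and spectral bounds", {
  one <- matrix(0, 6, 6); one[1, 2] <- one[2, 1] <- 88
  expect_equal(spectral_radius(make_adj(one)), 88, tolerance = 1e-8)

  # equal-weight complete graph: eigenvalues of w(J - I) are (K-1)w and -w
  complete <- matrix(70, 6, 6); diag(complete) <- 0
  expect_equal(spectral_radius(make_adj(complete)), 350, tolerance = 1e-8)

  expect_equal(spectral_radius(make_adj(matrix(0, 6, 6))), 0)

  set.seed(13)
  for (rep in 1:100) {
    A <- rand_weight_matrix()
    rho <- spectral_radius(A)
    expect_equal(rho, max(eigen(A, symmetric = TRUE,
                                only.values = TRUE)$values),
                 tolerance = 1e-8)
    d <- rowSums(A)
    expect_lte(rho, max(d) + 1e-8)
    expect_gte(rho, mean(d) - 1e-8)
  }
})

test_that("score normalization uses the shared 100*(K-1) bound", {
  expect_equal(normalize_score(500, "degree"), 1)
  expect_equal(normalize_score(0, "eigen"), 0)
  expect_equal(normalize_score(95, "degree"), 0.19)
  expect_error(normalize_score(-1, "degree"), class = "dynetox_bad_score")
})

test_that("critical nodes honor the tie tolerance and empty-set rule", {
  s <- stats::setNames(c(96, 96, 0, 0, 0, 0), labels6)
  expect_setequal(critical_nodes(s), c("PE", "YSE"))
  expect_length(critical_nodes(stats::setNames(rep(0, 6), labels6)), 0)

  # a gap larger than tol excludes the runner-up; within tol it ties
  s <- stats::setNames(c(99, 99 - 1e-8, 0, 0, 0, 0), labels6)
  expect_equal(critical_nodes(s, tol = 1e-9), "PE")
  s <- stats::setNames(c(99, 99 - 1e-10, 0, 0, 0, 0), labels6)
  expect_setequal(critical_nodes(s, tol = 1e-9), c("PE", "YSE"))
})

test_that("critical-node tables flag >=3-way ties and round-trip CSV", {
  p1 <- matrix(1, 6, 6); p1[1, 2] <- p1[2, 1] <- 0.01
  # three-node equal-weight triangle: a 3-way tie, flagged omitted
  p2 <- matrix(1, 6, 6)
  for (i in 1:3) for (j in 1:3) if (i != j) p2[i, j] <- 0.02
  mats <- list(make_assoc(p1, "g", 2), make_assoc(p2, "g", 3),
               make_assoc(matrix(1, 6, 6), "g", 4))
  net <- build_dynamic_network(mats)
  tbl <- critical_node_table(net)
  expect_equal(nrow(tbl), 6)  # 3 timepoints x 2 kinds

  two <- tbl[tbl$dpf == 2 & tbl$kind == "degree", ]
  expect_equal(two$nodes, "PE,YSE")
  expect_false(two$omitted)

  tri <- tbl[tbl$dpf == 3, ]
  expect_true(all(tri$omitted))
  expect_equal(tri$n_nodes, c(3L, 3L))
  expect_equal(tri$nodes, rep("PE,YSE,CM", 2))  # retained internally

  empty <- tbl[tbl$dpf == 4, ]
  expect_true(all(empty$nodes == ""))

  f <- withr::local_tempfile(fileext = ".csv")
  write_critical_node_table(tbl, f)
  raw <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_equal(raw$nodes[raw$dpf == 4], rep("-", 2))
  expect_equal(raw$nodes[raw$dpf == 3], rep("omitted", 2))
  back <- read_critical_node_table(f)
  expect_equal(back$group, tbl$group)
  expect_equal(back$omitted, tbl$omitted)
  expect_equal(back$nodes[!back$omitted], tbl$nodes[!tbl$omitted])
})

test_that("importance summary pools kinds, splits ties, and rounds", {
  tbl <- structure(data.frame(
    group = "g", dpf = c(2, 3, 4, 5, 2, 3, 4, 5),
    kind = rep(c("degree", "eigen"), each = 4),
    nodes = c("PE", "PE,YSE", "SD", "", "PE", "PE,YSE", "PE", ""),
    n_nodes = c(1, 2, 1, 0, 1, 2, 1, 0),
    omitted = FALSE, stringsAsFactors = FALSE
  ), class = c("critical_node_table", "data.frame"))
  imp <- summarize_importance(tbl)
  # single-node cells: PE, SD, PE, PE -> PE 75%, SD 25%
  expect_equal(unname(imp$unique_pct[c("PE", "SD")]), c(75, 25))
  expect_equal(sum(imp$unique_pct), 100)
  expect_equal(imp$n_unique_cells, 4)
  # appearances: PE 5, YSE 2, SD 1 of 8
  expect_equal(unname(imp$with_ties_pct[c("PE", "YSE", "SD")]),
               100 * c(5, 2, 1) / 8)
  expect_equal(imp$n_appearances, 8)
  # half-away-from-zero reporting
  expect_equal(unname(imp$with_ties_pct_rounded[c("PE", "YSE", "SD")]),
               c(63, 25, 13))

  solo <- tbl[2, ]; solo$nodes <- "PE"; solo$n_nodes <- 1
  imp <- summarize_importance(solo)
  expect_equal(unname(imp$unique_pct["PE"]), 100)

  none <- tbl; none$nodes <- ""; none$n_nodes <- 0
  expect_warning(imp <- summarize_importance(none), "no populated cells")
  expect_equal(sum(imp$unique_pct), 0)
  expect_equal(imp$n_unique_cells, 0)
  expect_equal(imp$n_appearances, 0)
})
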