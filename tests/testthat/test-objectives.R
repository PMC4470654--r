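test_that("penalty transform hits the documented endpoints and is decreasing", {
  expect_equal(confidence_to_penalty(0.9), 1)
  expect_equal(round(confidence_to_penalty(0.999), 2), 0.33)
  expect_equal(confidence_to_penalty(0.99), 0.5)
  s <- seq(0.901, 0.999, by = 0.001)
  expect_true(all(diff(confidence_to_penalty(s)) < 0))
  expect_error(confidence_to_penalty(1))
  expect_error(confidence_to_penalty(0.85))
  # literal printed form, kept for comparison only
  expect_equal(confidence_to_penalty(0.9, form = "literal"), 2)
  expect_equal(confidence_to_penalty(0.999, form = "literal"), 4)
})

test_that("shortest distances match exhaustive path enumeration on the toy graph", {
  toy <- make_toy_fixture()
  net <- build_ppi_network(toy$ppi, toy$target)
  ed <- data.frame(a = toy$ppi$protein_a, b = toy$ppi$protein_b,
                   w = confidence_to_penalty(toy$ppi$confidence))
  for (p in c("PA", "PB", "PC", "PD", "PE", "PG", "PT")) {
    expect_equal(shortest_distance(net, p), oracle_shortest(ed, p, "PT"),
                 info = p)
  }
  expect_equal(shortest_distance(net, "PT"), 0)
  # disconnected and unknown proteins share the fallback
  expect_equal(shortest_distance(net, "PF"), net$fallback_distance)
  expect_equal(shortest_distance(net, "NOT_A_NODE"), net$fallback_distance)
  # fallback is worse than any connected protein
  expect_gt(net$fallback_distance,
            max(shortest_distance(net, c("PA", "PB", "PC", "PD", "PE", "PG"))))
})

test_that("distances satisfy the triangle property through intermediate nodes", {
  toy <- make_toy_fixture()
  net <- build_ppi_network(toy$ppi, toy$target)
  nodes <- c("PA", "PB", "PC", "PD", "PE", "PG")
  d <- igraph::distances(net$graph, weights = igraph::E(net$graph)$weight)
  for (a in nodes) for (b in nodes) {
    expect_lte(shortest_distance(net, a),
               d[a, b] + shortest_distance(net, b) + 1e-12)
  }
})

test_that("relevance averages distinct-protein distances", {
  # P at one 0.999 edge (1/3), Q--R--T with two 0.9-boundary-adjacent edges
  ed <- ppi_edges(c("P", "Q", "R"), c("T", "R", "T"),
                  c(0.999, 0.901, 0.901))
  net <- build_ppi_network(ed, "T")
  cand <- data.frame(site_id = c("P_1", "Q_1", "P_2"),
                     protein_id = c("P", "Q", "P"))
  toy_mat <- phospho_matrix(
    matrix(c(1, 0, 1, 0, 1, 0, 1, 0, 1, 0, 1, 0), nrow = 3),
    data.frame(site_id = cand$site_id, protein_id = cand$protein_id),
    c("a", "b", "c", "d")
  )
  labels <- c(a = 1L, b = 1L, c = -1L, d = -1L)
  ctx <- objective_context(cand, toy_mat, labels, net)
  dP <- 1 / (-log10(1 - 0.999))
  dQ <- 2 / (-log10(1 - 0.901))
  expect_equal(relevance_objective(c(1L, 1L, 0L), ctx), mean(c(dP, dQ)))
  # a duplicated protein counts once; site order is irrelevant
  expect_equal(relevance_objective(c(1L, 1L, 1L), ctx), mean(c(dP, dQ)))
  expect_equal(relevance_objective(c(1L, 0L, 0L), ctx),
               relevance_objective(c(0L, 0L, 1L), ctx))
  # adding a protein at distance 0 cannot increase the mean
  ctx0 <- ctx
  ctx0$protein_dist[3] <- 0
  expect_lte(relevance_objective(c(1L, 1L, 1L), ctx0),
             relevance_objective(c(1L, 1L, 0L), ctx0))
})

test_that("sigmoid calibration pins the hyperplane to p = 0.5", {
  set.seed(31)
  for (rep in 1:5) {
    f <- rnorm(12, sd = runif(1, 0.5, 3))
    c <- sample(rep(c(1L, -1L), 6))
    m <- fit_sigmoid(f, c)
    expect_equal(m$B, 0)
    expect_equal(predict(m, 0), 0.5)
  }
})

test_that("sigmoid slope matches a grid-search oracle and orients correctly", {
  f <- c(-1.2, -1.0, -0.8, 0.9, 1.0, 1.3)
  c <- c(1, 1, 1, -1, -1, -1)
  m <- fit_sigmoid(f, c)
  res <- c == -1
  n1 <- sum(res); n0 <- sum(!res)
  t <- ifelse(res, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  nll <- function(A) {
    p <- pmin(pmax(1 / (1 + exp(A * f)), 1e-15), 1 - 1e-15)
    -sum(t * log(p) + (1 - t) * log(1 - p))
  }
  grid <- seq(-50, 50, by = 1e-3)
  expect_equal(m$A, grid[which.min(vapply(grid, nll, numeric(1)))],
               tolerance = 1e-3)
  # resistant samples (positive f here) must get p > 0.5
  expect_true(all(predict(m, f[res]) > 0.5))
  expect_true(all(predict(m, f[!res]) < 0.5))
  expect_warning(fit_sigmoid(rep(1, 6), c), "identical")
})

test_that("separation matches an independently assembled LOOCV on the fixture", {
  toy <- make_toy_fixture()
  idx <- match(c("PA_S1", "PG_S7"), toy$matrix$sites$site_id)
  X <- t(toy$matrix$values[idx, , drop = FALSE])  # complete rows
  lab <- toy$labels[toy$matrix$samples]
  expect_equal(separation_loocv(X, lab), oracle_separation(X, lab),
               tolerance = 1e-3)
  # single-site signature too
  X1 <- X[, 1, drop = FALSE]
  expect_equal(separation_loocv(X1, lab), oracle_separation(X1, lab),
               tolerance = 1e-3)
})

test_that("separation stays in [-1, 0] across random signatures", {
  set.seed(19)
  for (rep in 1:8) {
    n <- sample(6:10, 1)
    X <- matrix(rnorm(n * 3), n)
    X[sample(length(X), 2)] <- NA
    lab <- sample(rep(c(1L, -1L), length.out = n))
    s <- separation_loocv(X, lab)
    expect_gte(s, -1)
    expect_lte(s, 0)
  }
})

test_that("degenerate folds are scored worst instead of failing", {
  # one resistant sample: its fold has a single class
  X <- matrix(c(1, 1.1, 0.9, -1), 4)
  lab <- c(1L, 1L, 1L, -1L)
  s <- separation_loocv(X, lab)
  expect_gte(s, -1)
  expect_lte(s, 0)
})

test_that("evaluation is memoized and total for the empty chromosome", {
  toy <- make_toy_fixture()
  net <- build_ppi_network(toy$ppi, toy$target)
  cand <- select_candidates(toy$matrix, toy$labels, k = 4, min_fold = 1)
  ctx <- objective_context(cand, toy$matrix, toy$labels, net)
  bits <- c(1L, 1L, rep(0L, nrow(cand) - 2))
  first <- evaluate_objectives(bits, ctx)
  # the cache, not the SVM, answers the second call
  key <- paste(bits, collapse = "")
  sentinel <- c(size = -99, separation = -99, relevance = -99)
  ctx$cache[[key]] <- sentinel
  expect_identical(evaluate_objectives(bits, ctx), sentinel)

  zero <- evaluate_objectives(rep(0L, nrow(cand)), ctx)
  expect_equal(unname(zero), c(0, 0, net$fallback_distance))
  expect_equal(first[["size"]], 2)
})

test_that("the objective triple on the fixture matches a hand-assembled one", {
  toy <- make_toy_fixture()
  net <- build_ppi_network(toy$ppi, toy$target)
  cand <- select_candidates(toy$matrix, toy$labels, k = 5, min_fold = 1)
  ctx <- objective_context(cand, toy$matrix, toy$labels, net)
  sel <- which(cand$site_id %in% c("PA_S1", "PG_S7"))
  bits <- integer(nrow(cand)); bits[sel] <- 1L
  got <- evaluate_objectives(bits, ctx)
  idx <- match(c("PA_S1", "PG_S7"), toy$matrix$sites$site_id)
  X <- t(toy$matrix$values[idx, , drop = FALSE])
  lab <- toy$labels[toy$matrix$samples]
  ed <- data.frame(a = toy$ppi$protein_a, b = toy$ppi$protein_b,
                   w = confidence_to_penalty(toy$ppi$confidence))
  expect_equal(unname(got),
               c(2,
                 oracle_separation(X, lab),
                 mean(c(oracle_shortest(ed, "PA", "PT"),
                        oracle_shortest(ed, "PG", "PT")))),
               tolerance = 1e-3)
})
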