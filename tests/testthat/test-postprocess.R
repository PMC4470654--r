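fake_front <- function(seps, k = 5) {
  n <- length(seps)
  set.seed(100 + n)
  bits <- matrix(sample(0:1, n * k, TRUE), n, k)
  bits[rowSums(bits) == 0, 1] <- 1L
  list(bits = bits,
       objectives = cbind(rowSums(bits), seps, runif(n, 0, 2)))
}

test_that("front filtering removes separations at or above the cutoff", {
  fr <- fake_front(c(-0.7, -0.6, -0.65, -0.3))
  out <- filter_front(fr, -0.6)
  expect_equal(out$objectives[, 2], c(-0.7, -0.65))
  all_in <- filter_front(fake_front(c(-0.2, -0.05)), 0)
  expect_equal(nrow(all_in$bits), 2)
  expect_error(filter_front(fake_front(c(-0.1, -0.2)), -0.6), "relax")
})

test_that("a constructed 77-solution front keeps 53 after the cutoff", {
  seps <- c(seq(-1, -0.61, length.out = 53), seq(-0.6, -0.1, length.out = 24))
  out <- filter_front(fake_front(seps), -0.6)
  expect_equal(nrow(out$bits), 53)
})

test_that("Ward clustering recovers planted groups and degenerate cuts", {
  g1 <- matrix(rep(c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L), 5), 5, byrow = TRUE)
  g2 <- matrix(rep(c(0L, 0L, 0L, 0L, 0L, 1L, 1L, 1L), 5), 5, byrow = TRUE)
  g1[cbind(1:5, 4)] <- c(1L, 0L, 1L, 0L, 1L)  # light within-group jitter
  g2[cbind(1:5, 5)] <- c(0L, 1L, 0L, 1L, 0L)
  bits <- rbind(g1, g2)
  cl <- cluster_solutions(bits, 2)
  expect_equal(length(unique(cl[1:5])), 1)
  expect_equal(length(unique(cl[6:10])), 1)
  expect_false(cl[1] == cl[6])

  expect_equal(cluster_solutions(bits, nrow(bits)), 1:10)
  expect_error(cluster_solutions(bits, 11), "clusters")

  # duplicates co-cluster at any k
  dup <- rbind(g1[1, ], g1[1, ], g2[1, ], g2[2, ])
  cl <- cluster_solutions(dup, 2)
  expect_equal(cl[1], cl[2])
})

test_that("representatives minimize centroid distance with separation tie-break", {
  bits <- rbind(c(1L, 1L, 0L, 0L, 0L),
                c(1L, 1L, 0L, 0L, 0L),
                c(1L, 0L, 1L, 0L, 0L))
  obj <- cbind(2, c(-0.65, -0.7, -0.6), 1)
  rep1 <- select_representatives(bits, obj, rep(1L, 3))
  # centroid (1, 2/3, 1/3, 0, 0): the duplicated 11000 pattern is closest;
  # the exact tie between rows 1 and 2 goes to the better separation (-0.7)
  expect_equal(unname(rep1), 2L)

  # singleton cluster: its only member
  reps <- select_representatives(bits, obj, c(1L, 1L, 2L))
  expect_equal(unname(reps[2]), 3L)
})

test_that("final predictors separate clean training data and calibrate at 0.5", {
  toy <- make_toy_fixture()
  pr <- train_final_predictor(c("PA_S1", "PA_S2"), toy$matrix, toy$labels)
  X <- t(toy$matrix$values[match(pr$site_ids, toy$matrix$sites$site_id), ])
  p <- predict(pr, X)
  lab <- toy$labels[toy$matrix$samples]
  expect_true(all(p[lab == 1] < 0.5) && all(p[lab == -1] > 0.5))
  # a point on the hyperplane gets probability exactly one half
  expect_equal(predict(pr$sigmoid, 0), 0.5)
  expect_error(train_final_predictor("NOT_A_SITE", toy$matrix, toy$labels),
               "absent")
})

test_that("training is invariant to sample order up to solver tolerance", {
  toy <- make_toy_fixture()
  perm <- c(4, 1, 6, 2, 5, 3)
  shuffled <- phospho_matrix(toy$matrix$values[, perm],
                             toy$matrix$sites,
                             toy$matrix$samples[perm])
  a <- train_final_predictor(c("PA_S1", "PG_S7"), toy$matrix, toy$labels)
  b <- train_final_predictor(c("PA_S1", "PG_S7"), shuffled, toy$labels)
  grid <- cbind(seq(-1, 1, 0.25), seq(1, -1, -0.25))
  expect_equal(predict(a, grid), predict(b, grid), tolerance = 1e-6)
})

test_that("validation imputation uses the mean of training class means", {
  train <- phospho_matrix(
    rbind(c(0.4, 0.4, 0.8, 0.8), c(0.3, 0.3, 0.3, 0.3)),
    data.frame(site_id = c("A_1", "B_2"), protein_id = c("A", "B")),
    c("t1", "t2", "t3", "t4")
  )
  lab <- c(t1 = 1L, t2 = 1L, t3 = -1L, t4 = -1L)
  validation <- phospho_matrix(
    rbind(c(NA, 0.9), c(0.1, NA)),
    data.frame(site_id = c("A_1", "B_2"), protein_id = c("A", "B")),
    c("v1", "v2")
  )
  X <- impute_validation(validation, train, lab, c("A_1", "B_2"))
  expect_equal(X["v1", "A_1"], 0.6)   # (0.4 + 0.8) / 2
  expect_equal(X["v2", "A_1"], 0.9)   # present value untouched
  expect_equal(X["v2", "B_2"], 0.3)   # equal class means stay put
  # a site entirely absent from validation is imputed with a warning
  expect_warning(
    X2 <- impute_validation(
      phospho_matrix(matrix(0.1, 1, 2),
                     data.frame(site_id = "A_1", protein_id = "A"),
                     c("v1", "v2")),
      train, lab, c("A_1", "B_2")),
    "absent")
  expect_equal(unname(X2[, "B_2"]), c(0.3, 0.3))
})

test_that("prediction scoring applies the strict 0.5 rule and distance formula", {
  stub <- structure(
    list(model = list(coefs = matrix(1), SV = matrix(1, 1, 1), rho = 0),
         sigmoid = structure(list(A = 1, B = 0), class = "sigmoid_model"),
         site_ids = "s"),
    class = "signature_predictor"
  )
  # decision values equal the single feature; A = 1 gives p = 1/(1+exp(x))
  X <- matrix(c(log(4), -log(9)), ncol = 1,
              dimnames = list(c("v1", "v2"), "s"))
  out <- predict_and_score(stub, X, c(v1 = 1L, v2 = -1L))
  expect_equal(out$per_sample$p_resistant, c(0.2, 0.9))
  expect_equal(out$accuracy, 1)
  expect_equal(out$avg_prob_distance, 0.35)

  X0 <- matrix(c(0, 0), ncol = 1, dimnames = list(c("v1", "v2"), "s"))
  out0 <- predict_and_score(stub, X0, c(v1 = 1L, v2 = -1L))
  expect_equal(out0$accuracy, 0)  # exactly 0.5 counts as incorrect
  expect_equal(out0$avg_prob_distance, 0)

  Xmax <- matrix(c(50, -50), ncol = 1, dimnames = list(c("v1", "v2"), "s"))
  outm <- predict_and_score(stub, Xmax, c(v1 = 1L, v2 = -1L))
  expect_equal(outm$avg_prob_distance, 0.5, tolerance = 1e-10)
})

test_that("the pipeline is deterministic and validation-optional", {
  ds <- generate_dataset(synthetic_config(seed = 21))
  cfg <- default_config()
  cfg$population_size <- 40
  cfg$stagnation_generations <- 10
  cfg$max_generations <- 80
  cfg$seed <- 21
  # mechanics under test are determinism and the optional validation block,
  # so retain the whole front regardless of separation quality
  cfg$separation_cutoff <- -0.3
  with_val <- run_pipeline(ds$train, ds$train_labels, ds$ppi, ds$target,
                           validation = ds$validation,
                           validation_labels = ds$validation_labels,
                           config = cfg)
  without <- run_pipeline(ds$train, ds$train_labels, ds$ppi, ds$target,
                          config = cfg)
  expect_null(without$validation)
  expect_identical(with_val$solutions, without$solutions)
  again <- run_pipeline(ds$train, ds$train_labels, ds$ppi, ds$target,
                        validation = ds$validation,
                        validation_labels = ds$validation_labels,
                        config = cfg)
  expect_identical(with_val$solutions, again$solutions)
  expect_identical(with_val$validation$summary, again$validation$summary)
  # representatives are members of the filtered front
  expect_true(all(with_val$solutions$separation < cfg$separation_cutoff))
  expect_true(all(with_val$representatives %in%
                    seq_len(nrow(with_val$solutions))))
})
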