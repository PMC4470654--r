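# From the final Pareto front to representative signatures, final
# predictors, and independent-set validation.

#' Remove poorly separating front solutions
#'
#' Keeps solutions whose separation score is strictly below the cutoff;
#' a solution at or above it is removed. Small, network-relevant but
#' non-discriminative signatures are an inherent by-product of the
#' multi-objective search, and dropping them is the standard post hoc
#' weighting step.
#'
#' @param front List with `bits` (solutions x K 0/1 matrix) and
#'   `objectives` (solutions x 3 matrix, columns size/separation/relevance).
#' @param separation_cutoff Removal threshold (default -0.6).
#' @return Front list of the same shape, filtered.
#' @export
filter_front <- function(front, separation_cutoff = -0.6) {
  sep <- front$objectives[, 2]
  keep <- sep < separation_cutoff
  if (!any(keep)) {
    stop("no front solution has separation below ", separation_cutoff,
         "; relax the cutoff")
  }
  list(bits = front$bits[keep, , drop = FALSE],
       objectives = front$objectives[keep, , drop = FALSE])
}

#' Cluster front solutions in feature space
#'
#' Agglomerative hierarchical clustering with Ward's method on Euclidean
#' distances between the binary solution vectors; the dendrogram is cut
#' into `n_clusters` groups. Cluster labels are renumbered by dendrogram
#' leaf order so they are stable across reruns.
#'
#' @param bits Solutions x K 0/1 matrix.
#' @param n_clusters Number of clusters (default 4).
#' @return Integer cluster assignment per solution.
#' @export
cluster_solutions <- function(bits, n_clusters = 4) {
  n <- nrow(bits)
  if (n < n_clusters) {
    stop("cannot cut ", n, " solutions into ", n_clusters, " clusters")
  }
  if (n_clusters == n) return(seq_len(n))
  hc <- stats::hclust(stats::dist(bits, method = "euclidean"),
                      method = "ward.D2")
  raw <- stats::cutree(hc, k = n_clusters)
  # relabel clusters in order of first appearance along the dendrogram
  match(raw, unique(raw[hc$order]))
}

#' Pick one representative solution per cluster
#'
#' The representative is the member closest (Euclidean) to the cluster
#' centroid, i.e. the componentwise mean of the member bit vectors. Exact
#' distance ties go to the solution with the better (smaller) separation
#' score, remaining ties to the lowest solution index.
#'
#' @param bits Solutions x K 0/1 matrix.
#' @param objectives Aligned objective matrix (column 2 = separation).
#' @param assignment Integer cluster labels from [cluster_solutions()].
#' @return Integer vector of representative row indices, one per cluster,
#'   named by cluster.
#' @export
select_representatives <- function(bits, objectives, assignment) {
  vapply(sort(unique(assignment)), function(cl) {
    idx <- which(assignment == cl)
    centroid <- colMeans(bits[idx, , drop = FALSE])
    d2 <- colSums((t(bits[idx, , drop = FALSE]) - centroid)^2)
    best <- d2 <= min(d2) + 1e-12
    cand <- idx[best]
    cand[order(objectives[cand, 2], cand)][1]
  }, integer(1), USE.NAMES = TRUE)
}

#' Train the final predictor of a signature
#'
#' Linear SVM (cost `cost`) on the full training set restricted to the
#' signature sites, missing training values imputed by the mean of the
#' class means, plus a sigmoid posterior model fitted on the training
#' decision values with the offset fixed at 0.
#'
#' @param site_ids Signature site identifiers.
#' @param train A [phospho_matrix()].
#' @param labels Named `+1`/`-1` labels.
#' @param cost SVM cost parameter (default 1).
#' @return Object of class `signature_predictor`.
#' @export
train_final_predictor <- function(site_ids, train, labels, cost = 1) {
  stopifnot(length(site_ids) >= 1)
  labels <- labels[train$samples]
  check_labels(labels)
  idx <- match(site_ids, train$sites$site_id)
  if (anyNA(idx)) stop("signature site(s) absent from training matrix: ",
                       paste(site_ids[is.na(idx)], collapse = ", "))
  X <- t(train$values[idx, , drop = FALSE])
  fill <- class_mean_fill(X, labels)
  X <- apply_fill(X, fill)
  model <- fit_linear_svm(X, labels, cost)
  ftr <- svm_decision_values(model, X)
  sigmoid <- fit_sigmoid(ftr, labels)
  structure(
    list(site_ids = site_ids, model = model, sigmoid = sigmoid,
         fill = fill, cost = cost),
    class = "signature_predictor"
  )
}

#' Posterior resistant probabilities for new samples
#' @param object A [train_final_predictor()] object.
#' @param X Samples-by-signature-sites matrix (already imputed).
#' @param ... Unused.
#' @return Numeric vector of resistant-class probabilities.
#' @export
predict.signature_predictor <- function(object, X, ...) {
  predict(object$sigmoid, svm_decision_values(object$model, as.matrix(X)))
}

#' Impute a validation slice from training class means
#'
#' Each missing validation value of a signature site is replaced by the
#' mean of the two training class means of that site. Signature sites
#' entirely absent from the validation matrix are treated as all-missing
#' (with a warning) and imputed the same way.
#'
#' @param validation A [phospho_matrix()] of the independent samples.
#' @param train Training [phospho_matrix()].
#' @param labels Named training labels.
#' @param site_ids Signature site identifiers (must exist in `train`).
#' @return Samples-by-sites numeric matrix with no missing values.
#' @export
impute_validation <- function(validation, train, labels, site_ids) {
  labels <- labels[train$samples]
  check_labels(labels)
  tr_idx <- match(site_ids, train$sites$site_id)
  if (anyNA(tr_idx)) stop("signature site(s) absent from training matrix")
  fill <- class_mean_fill(t(train$values[tr_idx, , drop = FALSE]), labels)
  va_idx <- match(site_ids, validation$sites$site_id)
  if (anyNA(va_idx)) {
    warning("signature site(s) absent from validation matrix, imputed from training: ",
            paste(site_ids[is.na(va_idx)], collapse = ", "))
  }
  X <- matrix(NA_real_, nrow = length(validation$samples),
              ncol = length(site_ids),
              dimnames = list(validation$samples, site_ids))
  ok <- !is.na(va_idx)
  X[, ok] <- t(validation$values[va_idx[ok], , drop = FALSE])
  apply_fill(X, fill)
}

#' Predict an independent sample set and score the predictions
#'
#' A sensitive sample (`c = +1`) is predicted correctly iff its resistant
#' probability is below 0.5, a resistant one iff above 0.5; exactly 0.5
#' counts as incorrect. Also reports the average probability distance
#' `mean((0.5 - p_i) c_i)`, a signed confidence score in \[-0.5, 0.5\]
#' where larger is better.
#'
#' @param predictor A [train_final_predictor()] object.
#' @param X Imputed samples-by-sites matrix from [impute_validation()].
#' @param labels Named `+1`/`-1` labels of the rows of `X`.
#' @return List of class `prediction_result`: `per_sample` data frame and
#'   scalars `accuracy`, `avg_prob_distance`.
#' @export
predict_and_score <- function(predictor, X, labels) {
  labels <- labels[rownames(X)]
  p <- predict(predictor, X)
  predicted <- ifelse(p > 0.5, -1L, ifelse(p < 0.5, 1L, 0L))
  correct <- (labels == 1 & p < 0.5) | (labels == -1 & p > 0.5)
  structure(
    list(
      per_sample = data.frame(
        sample = rownames(X), p_resistant = p,
        predicted = predicted, truth = as.integer(labels),
        correct = correct, stringsAsFactors = FALSE, row.names = NULL
      ),
      accuracy = mean(correct),
      avg_prob_distance = mean((0.5 - p) * labels)
    ),
    class = "prediction_result"
  )
}

solution_table <- function(front, candidates, assignment, reps) {
  n <- nrow(front$bits)
  data.frame(
    solution = seq_len(n),
    sites = apply(front$bits, 1, function(b) {
      paste(candidates$site_id[b != 0], collapse = ";")
    }),
    size = unname(front$objectives[, 1]),
    separation = unname(front$objectives[, 2]),
    relevance = unname(front$objectives[, 3]),
    cluster = assignment,
    representative = seq_len(n) %in% reps,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Run the full signature-discovery pipeline
#'
#' Prefilter to at most `top_k` candidate sites, search signatures with
#' NSGA-II over the three objectives, filter the first front by
#' separation, cluster the surviving solutions with Ward's method, pick
#' the representative of each cluster, train one final linear SVM per
#' representative, and (when a validation matrix is supplied) predict and
#' score the independent samples.
#'
#' @param train Training [phospho_matrix()].
#' @param labels Named `+1`/`-1` training labels.
#' @param ppi A `ppi_edges` data frame.
#' @param target Drug-target protein identifier.
#' @param validation Optional validation [phospho_matrix()].
#' @param validation_labels Labels for `validation`.
#' @param config A [default_config()] list.
#' @return Object of class `pareto_result` with the candidate set, GA
#'   result, solution table, representative signatures, final predictors,
#'   and validation scores (if run).
#' @export
run_pipeline <- function(train, labels, ppi, target,
                         validation = NULL, validation_labels = NULL,
                         config = default_config()) {
  config <- validate_config(config)
  candidates <- select_candidates(
    train, labels, k = config$top_k,
    min_fraction = config$min_presence, min_fold = config$min_fold,
    stats_panel = config$rank_stats
  )
  network <- build_ppi_network(
    ppi, target, confidence_threshold = config$confidence_threshold,
    penalty_form = config$penalty_form,
    fallback_distance = config$fallback_distance
  )
  missing_proteins <- join_failure_report(train, ppi)
  ctx <- objective_context(candidates, train, labels, network, config)
  ga <- evolve(
    nrow(candidates), function(bits) evaluate_objectives(bits, ctx),
    ga_config(
      population_size = config$population_size,
      tournament_size = config$tournament_size,
      crossover_prob = config$crossover_prob,
      mutation_prob = config$mutation_prob,
      init_set_fraction = config$init_set_fraction,
      stagnation_generations = config$stagnation_generations,
      max_generations = config$max_generations,
      seed = config$seed
    )
  )
  front <- filter_front(
    list(bits = ga$front_bits, objectives = ga$front_objectives),
    config$separation_cutoff
  )
  n_clusters <- min(config$n_clusters, nrow(front$bits))
  assignment <- cluster_solutions(front$bits, n_clusters)
  reps <- select_representatives(front$bits, front$objectives, assignment)
  solutions <- solution_table(front, candidates, assignment, reps)

  predictors <- lapply(reps, function(i) {
    train_final_predictor(candidates$site_id[front$bits[i, ] != 0],
                          train, labels, cost = config$svm_cost)
  })
  names(predictors) <- paste0("Pareto", seq_along(reps))

  result <- list(
    candidates = candidates, network = network,
    join_failures = missing_proteins, ga = ga,
    front = front, solutions = solutions,
    representatives = reps, predictors = predictors,
    config = config, validation = NULL
  )
  if (!is.null(validation)) {
    if (is.null(validation_labels)) stop("validation matrix supplied without labels")
    scored <- lapply(names(predictors), function(nm) {
      pr <- predictors[[nm]]
      X <- impute_validation(validation, train, labels, pr$site_ids)
      predict_and_score(pr, X, validation_labels)
    })
    names(scored) <- names(predictors)
    per_sample <- do.call(rbind, lapply(names(scored), function(nm) {
      cbind(signature = nm, scored[[nm]]$per_sample)
    }))
    summary <- data.frame(
      signature = names(scored),
      size = vapply(predictors, function(p) length(p$site_ids), integer(1)),
      accuracy = vapply(scored, `[[`, numeric(1), "accuracy"),
      avg_prob_distance = vapply(scored, `[[`, numeric(1),
                                 "avg_prob_distance"),
      row.names = NULL, stringsAsFactors = FALSE
    )
    result$validation <- list(per_signature = scored,
                              per_sample = per_sample, summary = summary)
  }
  class(result) <- "pareto_result"
  result
}

#' @export
print.pareto_result <- function(x, ...) {
  cat(sprintf(
    "pareto_result: %d candidates, %d generations, %d filtered front solutions, %d representatives\n",
    nrow(x$candidates), x$ga$generations, nrow(x$solutions),
    length(x$representatives)
  ))
  if (!is.null(x$validation)) {
    cat("validation summary:\n")
    print(x$validation$summary, row.names = FALSE)
  }
  invisible(x)
}
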