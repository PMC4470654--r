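# The three minimized objectives: signature size, SVM-LOOCV separation,
# and PPI-network relevance (mean penalty-weighted shortest-path distance
# of signature proteins to the drug target).

#' Transform an interaction confidence into an edge penalty
#'
#' High-confidence interactions receive small penalties so that paths
#' through well-supported edges are short. The transform is
#' `rho = 1 / (-log10(1 - s))`, which maps the retained confidence range
#' \[0.9, 0.999\] onto penalties \[1, 1/3\] and is strictly decreasing in
#' `s`. A literal variant `rho = 1 - log10(1 - s)` is kept behind
#' `form = "literal"` for comparison; it is increasing on the same range
#' and is not used by default.
#'
#' @param s Numeric vector of interaction confidences, `threshold <= s < 1`.
#' @param form `"reciprocal"` (default) or `"literal"`.
#' @param threshold Lowest admissible confidence (default 0.9).
#' @return Numeric vector of positive edge penalties.
#' @export
confidence_to_penalty <- function(s, form = c("reciprocal", "literal"),
                                  threshold = 0.9) {
  form <- match.arg(form)
  if (any(s >= 1)) stop("confidence must be < 1")
  if (any(s < threshold)) stop("confidence below threshold ", threshold)
  switch(form,
    reciprocal = 1 / (-log10(1 - s)),
    literal = 1 - log10(1 - s)
  )
}

#' Build a confidence-filtered PPI network around a drug target
#'
#' Keeps edges with confidence strictly greater than `confidence_threshold`,
#' converts confidences to penalties with [confidence_to_penalty()], and
#' precomputes minimum-penalty (Dijkstra) distances from every node to the
#' target. Proteins absent from the network, or with no path to the target,
#' are later assigned `fallback_distance` (default: the largest finite
#' node-to-target distance plus one).
#'
#' @param edges A `ppi_edges` data frame.
#' @param target Drug-target protein identifier.
#' @param confidence_threshold Retain edges with confidence strictly above
#'   this value (default 0.9).
#' @param penalty_form Passed to [confidence_to_penalty()].
#' @param fallback_distance Distance for disconnected or absent proteins;
#'   `NULL` means max finite distance + 1.
#' @return Object of class `ppi_network` with the graph, the target, the
#'   per-node distance table and the fallback distance.
#' @export
build_ppi_network <- function(edges, target, confidence_threshold = 0.9,
                              penalty_form = "reciprocal",
                              fallback_distance = NULL) {
  keep <- edges$confidence > confidence_threshold
  ed <- edges[keep, , drop = FALSE]
  if (nrow(ed) == 0) {
    g <- igraph::make_empty_graph(directed = FALSE)
    g <- igraph::add_vertices(g, 1, name = target)
  } else {
    ed$weight <- confidence_to_penalty(ed$confidence, form = penalty_form,
                                       threshold = confidence_threshold)
    g <- igraph::graph_from_data_frame(
      ed[, c("protein_a", "protein_b", "weight")],
      directed = FALSE
    )
    if (!target %in% igraph::V(g)$name) {
      warning("target '", target, "' has no retained interaction")
      g <- igraph::add_vertices(g, 1, name = target)
    }
  }
  d <- igraph::distances(g, v = igraph::V(g), to = target,
                         weights = igraph::E(g)$weight,
                         algorithm = "dijkstra")[, 1]
  finite <- d[is.finite(d)]
  if (is.null(fallback_distance)) {
    fallback_distance <- if (length(finite)) max(finite) + 1 else 1
  }
  structure(
    list(graph = g, target = target, dist_to_target = d,
         fallback_distance = fallback_distance,
         confidence_threshold = confidence_threshold),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf(
    "ppi_network: %d proteins, %d edges (confidence > %s), target %s, fallback distance %.3f\n",
    igraph::vcount(x$graph), igraph::ecount(x$graph),
    format(x$confidence_threshold), x$target, x$fallback_distance
  ))
  invisible(x)
}

#' Minimum-penalty distance from a protein to the drug target
#'
#' Sum of edge penalties along the cheapest path. The target itself is at
#' distance 0; proteins absent from the network or disconnected from the
#' target get the network's fallback distance.
#'
#' @param network A [build_ppi_network()] object.
#' @param protein Character vector of protein identifiers.
#' @return Numeric vector of distances.
#' @export
shortest_distance <- function(network, protein) {
  d <- network$dist_to_target[protein]
  d[is.na(d) | is.infinite(d)] <- network$fallback_distance
  d[protein == network$target] <- 0
  unname(d)
}

#' Fit a one-parameter sigmoid posterior model to SVM decision values
#'
#' Maps a decision value `f` to the posterior probability of the resistant
#' class via `p = 1 / (1 + exp(A * f))` with the offset fixed at 0, so a
#' point on the separating hyperplane always gets `p = 0.5`. The slope `A`
#' minimizes the regularized negative log-likelihood with smoothed targets
#' `(N1 + 1)/(N1 + 2)` for resistant and `1/(N0 + 2)` for sensitive
#' samples; the one-dimensional problem is convex and solved by a damped
#' Newton iteration, so the fit is deterministic.
#'
#' @param f Numeric decision values.
#' @param c Class labels, `+1` sensitive / `-1` resistant.
#' @return Object of class `sigmoid_model` with elements `A` and `B` (= 0).
#' @export
fit_sigmoid <- function(f, c) {
  stopifnot(length(f) == length(c), all(c %in% c(-1, 1)))
  if (length(unique(c)) < 2) stop("both classes must be present")
  resistant <- c == -1
  n1 <- sum(resistant); n0 <- sum(!resistant)
  t <- ifelse(resistant, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  nll <- function(A) {
    p <- 1 / (1 + exp(A * f))
    p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
    -sum(t * log(p) + (1 - t) * log(1 - p))
  }
  if (stats::sd(f) == 0) {
    warning("all decision values identical; sigmoid slope is arbitrary")
  }
  # damped Newton on the convex 1-D problem: the smoothed targets keep the
  # optimum finite even for perfectly separated decision values
  A <- 0
  for (iter in 1:200) {
    p <- 1 / (1 + exp(A * f))
    grad <- sum(f * (t - p))
    hess <- sum(f^2 * p * (1 - p))
    if (abs(grad) < 1e-12 || hess < 1e-300) break
    step <- -grad / hess
    val <- nll(A)
    while (abs(step) > 1e-14 && nll(A + step) > val + 1e-12) step <- step / 2
    if (abs(step) <= 1e-14) break
    A <- A + step
  }
  structure(list(A = A, B = 0), class = "sigmoid_model")
}

#' Posterior resistant-class probability from a fitted sigmoid
#' @param object A `sigmoid_model`.
#' @param f Numeric decision values.
#' @param ... Unused.
#' @return Probabilities in (0, 1).
#' @export
predict.sigmoid_model <- function(object, f, ...) {
  1 / (1 + exp(object$A * f + object$B))
}

# Per-site imputation value: mean of the two class means of the present
# training values (falls back to the available class, then to 0). Used
# identically inside LOO folds and for final/validation prediction.
class_mean_fill <- function(X, labels) {
  fill_one <- function(col) {
    m1 <- mean(col[labels == 1], na.rm = TRUE)
    m2 <- mean(col[labels == -1], na.rm = TRUE)
    if (is.nan(m1) && is.nan(m2)) return(0)
    if (is.nan(m1)) return(m2)
    if (is.nan(m2)) return(m1)
    (m1 + m2) / 2
  }
  apply(X, 2, fill_one)
}

apply_fill <- function(X, fill) {
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- fill[j]
  }
  X
}

# Linear decision values without the predict() overhead:
# f(x) = x . w - rho in e1071's internal orientation.
svm_decision_values <- function(model, X) {
  w <- crossprod(model$coefs, model$SV)
  drop(X %*% t(w)) - model$rho
}

fit_linear_svm <- function(X, y, cost) {
  e1071::svm(X, factor(y, levels = c(-1, 1)), kernel = "linear",
             cost = cost, scale = FALSE)
}

#' Leave-one-out separation objective of a signature
#'
#' For each sample, a linear soft-margin SVM (cost `cost`) is trained on
#' the remaining samples restricted to the signature sites, with missing
#' values imputed per fold by the mean of the fold's class means. A
#' sigmoid posterior model is fitted on that fold's training decision
#' values and applied to the held-out sample, giving a posterior resistant
#' probability `p_i`. The objective is the negative worst per-sample
#' probability margin, `-min_i(c_i (1/2 - p_i) + 1/2)`, always in
#' \[-1, 0\]; lower means better, more confidently correct, separation.
#'
#' @param X Samples-by-sites numeric matrix (signature sites only; `NA`
#'   for missing values).
#' @param labels Vector of `+1`/`-1` class labels, one per row of `X`.
#' @param cost SVM cost parameter (default 1).
#' @return The separation score, a scalar in \[-1, 0\].
#' @export
separation_loocv <- function(X, labels, cost = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(labels) == n)
  margins <- numeric(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    ytr <- labels[tr]
    if (length(unique(ytr)) < 2) {
      margins[i] <- 0  # degenerate fold: a class vanished
      next
    }
    Xtr <- X[tr, , drop = FALSE]
    fill <- class_mean_fill(Xtr, ytr)
    Xtr <- apply_fill(Xtr, fill)
    xte <- apply_fill(X[i, , drop = FALSE], fill)
    model <- fit_linear_svm(Xtr, ytr, cost)
    ftr <- svm_decision_values(model, Xtr)
    sig <- fit_sigmoid(ftr, ytr)
    p <- predict(sig, svm_decision_values(model, xte))
    margins[i] <- labels[i] * (0.5 - p) + 0.5
  }
  -min(margins)
}

#' Bundle everything the objective evaluation needs
#'
#' Precomputes the candidate data slice (samples x sites), the distance of
#' each candidate protein to the drug target, and a memoization cache so a
#' chromosome bit pattern is evaluated at most once per run.
#'
#' @param candidates Candidate set from [select_candidates()].
#' @param train A [phospho_matrix()] holding the training samples.
#' @param labels Named `+1`/`-1` labels covering the training samples.
#' @param network A [build_ppi_network()] object.
#' @param config A [default_config()] list (uses `svm_cost`).
#' @return Object of class `objective_context`.
#' @export
objective_context <- function(candidates, train, labels, network,
                              config = default_config()) {
  labels <- labels[train$samples]
  check_labels(labels)
  idx <- match(candidates$site_id, train$sites$site_id)
  if (anyNA(idx)) stop("candidate site(s) missing from training matrix")
  X <- t(train$values[idx, , drop = FALSE])  # samples x K
  prot <- candidates$protein_id
  structure(
    list(X = X, labels = labels, proteins = prot,
         protein_dist = shortest_distance(network, prot),
         cost = config$svm_cost,
         fallback = network$fallback_distance,
         cache = new.env(parent = emptyenv())),
    class = "objective_context"
  )
}

#' Relevance objective of a chromosome
#'
#' Arithmetic mean of the target distances of the *distinct* proteins
#' carrying the selected sites; duplicated proteins count once.
#'
#' @param bits 0/1 chromosome over the candidate set.
#' @param ctx An [objective_context()].
#' @return Mean distance (the network fallback for an empty chromosome).
#' @export
relevance_objective <- function(bits, ctx) {
  sel <- which(bits != 0)
  if (!length(sel)) return(ctx$fallback)
  first <- sel[!duplicated(ctx$proteins[sel])]
  mean(ctx$protein_dist[first])
}

#' Evaluate the full objective vector of a chromosome
#'
#' Returns `(size, separation, relevance)`, all minimized. Results are
#' memoized by bit pattern. The all-zero chromosome is never sent to the
#' SVM: it gets size 0, the worst separation (0) and the fallback
#' relevance.
#'
#' @param bits 0/1 chromosome.
#' @param ctx An [objective_context()].
#' @return Named numeric vector `c(size, separation, relevance)`.
#' @export
evaluate_objectives <- function(bits, ctx) {
  key <- paste(bits, collapse = "")
  hit <- ctx$cache[[key]]
  if (!is.null(hit)) return(hit)
  sel <- which(bits != 0)
  if (!length(sel)) {
    out <- c(size = 0, separation = 0, relevance = ctx$fallback)
  } else {
    out <- c(
      size = length(sel),
      separation = separation_loocv(ctx$X[, sel, drop = FALSE], ctx$labels,
                                    cost = ctx$cost),
      relevance = relevance_objective(bits, ctx)
    )
  }
  ctx$cache[[key]] <- out
  out
}
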