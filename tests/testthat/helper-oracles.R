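# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: dominance partitions by pairwise comparison,
# shortest paths by exhaustive enumeration of simple paths, and the LOOCV
# separation score assembled step by step with e1071 directly.

oracle_dominates <- function(a, b) all(a <= b) && any(a < b)

# O(n^2) dominance partition into fronts by repeated peeling
oracle_front_ranks <- function(M) {
  n <- nrow(M)
  rank <- rep(NA_integer_, n)
  r <- 1L
  left <- seq_len(n)
  while (length(left)) {
    nd <- vapply(left, function(i) {
      !any(vapply(left, function(j) oracle_dominates(M[j, ], M[i, ]),
                  logical(1)))
    }, logical(1))
    rank[left[nd]] <- r
    left <- left[!nd]
    r <- r + 1L
  }
  rank
}

# exhaustive simple-path enumeration on a small weighted graph given as a
# data frame (a, b, w); returns the minimum total weight a -> t, Inf if
# unreachable
oracle_shortest <- function(edges, from, to) {
  if (from == to) return(0)
  best <- Inf
  recurse <- function(node, visited, acc) {
    if (acc >= best) return()
    hit <- edges$a == node | edges$b == node
    for (k in which(hit)) {
      nxt <- if (edges$a[k] == node) edges$b[k] else edges$a[k]
      if (nxt %in% visited) next
      w <- acc + edges$w[k]
      if (nxt == to) {
        if (w < best) best <<- w
      } else {
        recurse(nxt, c(visited, nxt), w)
      }
    }
  }
  recurse(from, from, 0)
  best
}

# independent reassembly of the LOOCV separation score on a complete
# (no-missing) samples x sites matrix
oracle_separation <- function(X, labels, cost = 1) {
  n <- nrow(X)
  margins <- numeric(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    ytr <- labels[tr]
    fit <- e1071::svm(X[tr, , drop = FALSE],
                      factor(ytr, levels = c(-1, 1)),
                      kernel = "linear", cost = cost, scale = FALSE)
    ftr <- as.numeric(fit$decision.values)
    # Platt slope by fine grid search, offset fixed at 0
    res <- ytr == -1
    n1 <- sum(res); n0 <- sum(!res)
    t <- ifelse(res, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
    nll <- function(A) {
      p <- pmin(pmax(1 / (1 + exp(A * ftr)), 1e-15), 1 - 1e-15)
      -sum(t * log(p) + (1 - t) * log(1 - p))
    }
    grid <- seq(-50, 50, by = 1e-3)
    A <- grid[which.min(vapply(grid, nll, numeric(1)))]
    fte <- attr(predict(fit, X[i, , drop = FALSE], decision.values = TRUE),
                "decision.values")
    p <- 1 / (1 + exp(A * as.numeric(fte)))
    margins[i] <- labels[i] * (0.5 - p) + 0.5
  }
  -min(margins)
}

# deterministic cheap objective triple over 10 bits used by the
# exhaustive-front recovery tests
toy10_weights <- c(0.30, 0.25, 0.20, 0.15, 0.10, 0.05, 0.04, 0.03, 0.02, 0.01)
toy10_dist <- c(0.33, 0.5, 1, 1, 2, 2, 3, 3, 4, 5)
toy10_objective <- function(bits) {
  sel <- bits != 0
  c(size = sum(sel),
    separation = -min(1, sum(toy10_weights[sel])),
    relevance = if (any(sel)) mean(toy10_dist[sel]) else 6)
}

# enumeration of the true Pareto-optimal bit patterns of toy10_objective
toy10_true_front <- function() {
  bits <- as.matrix(expand.grid(rep(list(0:1), 10)))[-1, , drop = FALSE]
  M <- t(apply(bits, 1, toy10_objective))
  nd <- vapply(seq_len(nrow(M)), function(i) {
    !any(vapply(seq_len(nrow(M)), function(j) {
      oracle_dominates(M[j, ], M[i, ])
    }, logical(1)))
  }, logical(1))
  keys <- apply(bits[nd, , drop = FALSE], 1, paste, collapse = "")
  sort(unique(keys))
}
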