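# Elitist NSGA-II over binary chromosomes. Populations are stored as 0/1
# integer matrices (one chromosome per row) and objective vectors as an
# aligned n x 3 matrix; all objectives are minimized.

#' Number of sites selected by a chromosome
#' @param bits 0/1 vector.
#' @return Integer popcount.
#' @export
size_objective <- function(bits) sum(bits != 0)

# an all-zero chromosome encodes no signature; set one random bit
repair_zero <- function(bits) {
  if (!any(bits != 0)) bits[sample.int(length(bits), 1)] <- 1L
  bits
}

#' GA settings with the workflow defaults
#'
#' Defaults: population 200, 5-way tournament, single-point crossover with
#' probability 0.8, per-bit flip probability 0.02, 10% of bits set at
#' initialization, termination once the first front is unchanged in
#' feature space for 200 consecutive generations (hard cap 5000).
#'
#' @param population_size Even number of chromosomes per generation.
#' @param tournament_size Individuals per selection tournament.
#' @param crossover_prob Probability of applying single-point crossover.
#' @param mutation_prob Per-bit flip probability.
#' @param init_set_fraction Expected fraction of set bits at initialization.
#' @param stagnation_generations Consecutive generations with an unchanged
#'   first front required to stop.
#' @param max_generations Safety cap on the number of generations.
#' @param seed Integer RNG seed.
#' @return List of class `ga_config`.
#' @export
ga_config <- function(population_size = 200, tournament_size = 5,
                      crossover_prob = 0.8, mutation_prob = 0.02,
                      init_set_fraction = 0.10,
                      stagnation_generations = 200,
                      max_generations = 5000, seed = 1) {
  stopifnot(population_size >= 2, population_size %% 2 == 0,
            tournament_size >= 1,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            init_set_fraction >= 0, init_set_fraction <= 1,
            stagnation_generations >= 1, max_generations >= 1)
  structure(as.list(environment()), class = "ga_config")
}

#' Random initial population
#'
#' Each bit is set independently with probability `init_set_fraction`;
#' all-zero chromosomes are repaired by setting one random bit.
#'
#' @param k Chromosome length (number of candidate sites).
#' @param config A [ga_config()].
#' @return `population_size` x `k` 0/1 integer matrix.
#' @export
initialize_population <- function(k, config = ga_config()) {
  stopifnot(k >= 2)
  pop <- matrix(
    as.integer(stats::runif(config$population_size * k) < config$init_set_fraction),
    nrow = config$population_size, ncol = k
  )
  for (i in seq_len(nrow(pop))) pop[i, ] <- repair_zero(pop[i, ])
  pop
}

#' Pareto dominance between two objective vectors (minimization)
#'
#' @param a,b Numeric vectors of equal length.
#' @return `TRUE` iff `a` is no worse in every objective and strictly
#'   better in at least one.
#' @export
dominates <- function(a, b) all(a <= b) && any(a < b)

#' Fast non-dominated sorting
#'
#' Partitions objective vectors into Pareto fronts: front 1 is the
#' non-dominated set, front r the non-dominated set once fronts < r are
#' removed.
#'
#' @param objectives n x m numeric matrix, one objective vector per row.
#' @return Integer vector of front ranks (1 = first front).
#' @export
fast_nondominated_sort <- function(objectives) {
  M <- as.matrix(objectives)
  n <- nrow(M); m <- ncol(M)
  if (n == 0) return(integer(0))
  tM <- t(M)
  dominates_list <- vector("list", n)
  n_dominators <- integer(n)
  for (i in seq_len(n)) {
    le <- colSums(tM >= M[i, ]) == m   # i no worse than j everywhere
    lt <- colSums(tM > M[i, ]) > 0     # i strictly better somewhere
    dom <- which(le & lt)
    dominates_list[[i]] <- dom
    n_dominators[dom] <- n_dominators[dom] + 1L
  }
  rank <- integer(n)
  current <- which(n_dominators == 0L)
  r <- 1L
  while (length(current)) {
    rank[current] <- r
    nxt <- integer(0)
    for (i in current) {
      dom <- dominates_list[[i]]
      n_dominators[dom] <- n_dominators[dom] - 1L
      nxt <- c(nxt, dom[n_dominators[dom] == 0L])
    }
    current <- unique(nxt)
    r <- r + 1L
  }
  rank
}

#' Crowding distance within one front
#'
#' Boundary individuals of each objective get infinite crowding; interior
#' ones accumulate the normalized gap between their neighbours. Objectives
#' with zero range contribute nothing.
#'
#' @param objectives n x m matrix of the front members' objective vectors.
#' @return Numeric vector of crowding distances.
#' @export
crowding_distance <- function(objectives) {
  M <- as.matrix(objectives)
  n <- nrow(M)
  if (n <= 2) return(rep(Inf, n))
  crowd <- numeric(n)
  for (j in seq_len(ncol(M))) {
    ord <- order(M[, j])
    rng <- M[ord[n], j] - M[ord[1], j]
    crowd[ord[c(1, n)]] <- Inf
    if (rng > 0) {
      inner <- ord[2:(n - 1)]
      crowd[inner] <- crowd[inner] +
        (M[ord[3:n], j] - M[ord[1:(n - 2)], j]) / rng
    }
  }
  crowd
}

# crowding over a full population given front ranks
population_crowding <- function(objectives, rank) {
  crowd <- numeric(nrow(objectives))
  for (r in unique(rank)) {
    idx <- which(rank == r)
    crowd[idx] <- crowding_distance(objectives[idx, , drop = FALSE])
  }
  crowd
}

#' Tournament selection by crowded comparison
#'
#' Samples `tournament_size` individuals with replacement; the winner has
#' the lowest front rank, ties broken by larger crowding distance, then at
#' random.
#'
#' @param rank Integer front ranks of the population.
#' @param crowd Crowding distances of the population.
#' @param config A [ga_config()].
#' @return Index of the selected individual.
#' @export
tournament_select <- function(rank, crowd, config = ga_config()) {
  cand <- sample.int(length(rank), config$tournament_size, replace = TRUE)
  cand[order(rank[cand], -crowd[cand], stats::runif(length(cand)))][1]
}

#' Single-point crossover
#'
#' With probability `crossover_prob` a cut point is chosen uniformly in
#' `1..K-1` and the suffixes are swapped; otherwise the parents are copied.
#' All-zero children are repaired.
#'
#' @param a,b Parent chromosomes (equal length 0/1 vectors).
#' @param config A [ga_config()].
#' @return List of two child chromosomes.
#' @export
single_point_crossover <- function(a, b, config = ga_config()) {
  stopifnot(length(a) == length(b))
  if (stats::runif(1) < config$crossover_prob) {
    cut <- sample.int(length(a) - 1L, 1)
    ca <- c(a[1:cut], b[(cut + 1):length(b)])
    cb <- c(b[1:cut], a[(cut + 1):length(a)])
  } else {
    ca <- a; cb <- b
  }
  list(repair_zero(ca), repair_zero(cb))
}

#' Independent bit-flip mutation
#'
#' Each bit flips with probability `mutation_prob`; an all-zero result is
#' repaired by setting one random bit.
#'
#' @param bits 0/1 chromosome.
#' @param config A [ga_config()].
#' @return Mutated chromosome.
#' @export
bitflip_mutate <- function(bits, config = ga_config()) {
  flip <- stats::runif(length(bits)) < config$mutation_prob
  bits[flip] <- 1L - bits[flip]
  repair_zero(bits)
}

evaluate_population <- function(pop, evaluate) {
  t(apply(pop, 1, evaluate))
}

front_signature <- function(pop, rank) {
  paste(sort(unique(apply(pop[rank == 1L, , drop = FALSE], 1,
                          paste, collapse = ""))), collapse = "|")
}

#' Run the elitist NSGA-II loop
#'
#' Standard generational scheme: `N/2` tournament-selected parent pairs
#' produce `N` offspring via single-point crossover and bit-flip mutation;
#' parents and offspring are merged, sorted by front rank then crowding
#' distance, and the top `N` survive (elitism). The run stops when the set
#' of first-front bit patterns is unchanged for `stagnation_generations`
#' consecutive generations, or at `max_generations`.
#'
#' @param k Chromosome length.
#' @param evaluate Function mapping a 0/1 chromosome to a numeric
#'   objective vector (all objectives minimized), e.g. a closure over
#'   [evaluate_objectives()].
#' @param config A [ga_config()]; its `seed` drives all randomness.
#' @return List of class `ga_result`: final `population` and `objectives`,
#'   deduplicated first-front `front_bits`/`front_objectives`,
#'   per-generation `log`, `generations` run and `converged` flag.
#' @export
evolve <- function(k, evaluate, config = ga_config()) {
  set.seed(config$seed)
  N <- config$population_size
  pop <- initialize_population(k, config)
  obj <- evaluate_population(pop, evaluate)
  rank <- fast_nondominated_sort(obj)
  crowd <- population_crowding(obj, rank)

  log_rows <- list()
  prev_sig <- front_signature(pop, rank)
  stagnant <- 0L
  gen <- 0L
  converged <- FALSE

  while (gen < config$max_generations) {
    gen <- gen + 1L
    children <- matrix(0L, nrow = N, ncol = k)
    for (p in seq_len(N / 2)) {
      i <- tournament_select(rank, crowd, config)
      j <- tournament_select(rank, crowd, config)
      kids <- single_point_crossover(pop[i, ], pop[j, ], config)
      children[2 * p - 1L, ] <- bitflip_mutate(kids[[1]], config)
      children[2 * p, ] <- bitflip_mutate(kids[[2]], config)
    }
    child_obj <- evaluate_population(children, evaluate)
    all_pop <- rbind(pop, children)
    all_obj <- rbind(obj, child_obj)
    all_rank <- fast_nondominated_sort(all_obj)
    all_crowd <- population_crowding(all_obj, all_rank)
    keep <- order(all_rank, -all_crowd, seq_along(all_rank))[seq_len(N)]
    pop <- all_pop[keep, , drop = FALSE]
    obj <- all_obj[keep, , drop = FALSE]
    rank <- all_rank[keep]
    crowd <- all_crowd[keep]
    # survivor ranks must be recomputed: dominators may not have survived
    rank <- fast_nondominated_sort(obj)
    crowd <- population_crowding(obj, rank)

    f1 <- which(rank == 1L)
    log_rows[[gen]] <- data.frame(
      generation = gen, front_size = length(f1),
      mean_size = mean(obj[f1, 1]),
      mean_separation = mean(obj[f1, 2]),
      mean_relevance = mean(obj[f1, ncol(obj)])
    )
    sig <- front_signature(pop, rank)
    if (identical(sig, prev_sig)) {
      stagnant <- stagnant + 1L
      if (stagnant >= config$stagnation_generations) {
        converged <- TRUE
        break
      }
    } else {
      stagnant <- 0L
      prev_sig <- sig
    }
  }

  f1 <- which(rank == 1L)
  keys <- apply(pop[f1, , drop = FALSE], 1, paste, collapse = "")
  uniq <- f1[!duplicated(keys)]
  uniq <- uniq[order(keys[!duplicated(keys)])]
  structure(
    list(population = pop, objectives = obj, rank = rank,
         front_bits = pop[uniq, , drop = FALSE],
         front_objectives = obj[uniq, , drop = FALSE],
         log = do.call(rbind, log_rows),
         generations = gen, converged = converged),
    class = "ga_result"
  )
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf(
    "ga_result: %d generations (%s), %d unique first-front solutions\n",
    x$generations, if (x$converged) "converged" else "generation cap",
    nrow(x$front_bits)
  ))
  invisible(x)
}
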