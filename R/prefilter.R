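# Reduction of the full site matrix to the candidate feature set handed to
# the optimizer: presence filter, fold-change filter, rank combination,
# one site per protein, top k.

class_split <- function(mat, labels) {
  labels <- labels[mat$samples]
  check_labels(labels)
  list(pos = which(labels == 1), neg = which(labels == -1), labels = labels)
}

#' Presence filter
#'
#' Keeps sites quantified in at least `min_fraction` of the samples of
#' *each* class.
#'
#' @param mat A [phospho_matrix()].
#' @param labels Named `+1`/`-1` labels.
#' @param min_fraction Minimum per-class presence fraction (default 2/3).
#' @return Character vector of retained site ids.
#' @export
presence_filter <- function(mat, labels, min_fraction = 2 / 3) {
  cs <- class_split(mat, labels)
  pm <- presence_mask(mat)
  frac_pos <- rowSums(pm[, cs$pos, drop = FALSE]) / length(cs$pos)
  frac_neg <- rowSums(pm[, cs$neg, drop = FALSE]) / length(cs$neg)
  mat$sites$site_id[frac_pos >= min_fraction & frac_neg >= min_fraction]
}

#' Fold-change filter
#'
#' Values are log10 ratios, so a `min_fold`-fold mean difference between
#' classes is `log10(min_fold)` on the stored scale. Class means use the
#' present values only.
#'
#' @param mat A [phospho_matrix()].
#' @param labels Named `+1`/`-1` labels.
#' @param min_fold Minimum fold change on the ratio scale (default 4).
#' @param sites Optional subset of site ids to consider.
#' @return Character vector of retained site ids.
#' @export
fold_change_filter <- function(mat, labels, min_fold = 4, sites = NULL) {
  cs <- class_split(mat, labels)
  V <- mat$values
  if (!is.null(sites)) V <- V[mat$sites$site_id %in% sites, , drop = FALSE]
  diff <- abs(rowMeans(V[, cs$pos, drop = FALSE], na.rm = TRUE) -
              rowMeans(V[, cs$neg, drop = FALSE], na.rm = TRUE))
  rownames(V)[!is.na(diff) & diff >= log10(min_fold)]
}

rank_statistics <- list(
  # absolute difference of class means (present values only)
  meandiff = function(x, pos, neg) {
    abs(mean(x[pos], na.rm = TRUE) - mean(x[neg], na.rm = TRUE))
  },
  # magnitude of the Welch two-sample t statistic
  welch = function(x, pos, neg) {
    a <- x[pos][!is.na(x[pos])]; b <- x[neg][!is.na(x[neg])]
    se2 <- stats::var(a) / length(a) + stats::var(b) / length(b)
    d <- abs(mean(a) - mean(b))
    if (!is.finite(se2) || se2 == 0) return(if (d > 0) Inf else 0)
    d / sqrt(se2)
  },
  # distance of the Wilcoxon rank-sum statistic from its null expectation
  wilcoxon = function(x, pos, neg) {
    a <- x[pos][!is.na(x[pos])]; b <- x[neg][!is.na(x[neg])]
    w <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)$statistic
    abs(unname(w) - length(a) * length(b) / 2)
  }
)

#' Rank sites by combined discriminative statistics
#'
#' Each site is ranked separately by a panel of two-sample statistics
#' (default: absolute class-mean difference, Welch t magnitude, Wilcoxon
#' rank-sum distance from its null mean); the final score is the mean of
#' the per-statistic ranks, lower being more discriminative. Ties are
#' broken lexicographically by site id. Sites with fewer than two present
#' values in a class are excluded with a warning.
#'
#' @param mat A [phospho_matrix()].
#' @param labels Named `+1`/`-1` labels.
#' @param sites Optional subset of site ids to rank.
#' @param stats_panel Character subset of
#'   `c("meandiff", "welch", "wilcoxon")`.
#' @return Data frame (`site_id`, `protein_id`, `mean_rank`, `rank`)
#'   ordered best first.
#' @export
rank_sites <- function(mat, labels, sites = NULL,
                       stats_panel = c("meandiff", "welch", "wilcoxon")) {
  stats_panel <- match.arg(stats_panel, several.ok = TRUE)
  cs <- class_split(mat, labels)
  keep <- if (is.null(sites)) mat$sites$site_id else sites
  idx <- match(keep, mat$sites$site_id)
  V <- mat$values[idx, , drop = FALSE]
  pm <- !is.na(V)
  enough <- rowSums(pm[, cs$pos, drop = FALSE]) >= 2 &
            rowSums(pm[, cs$neg, drop = FALSE]) >= 2
  if (any(!enough)) {
    warning(sum(!enough), " site(s) with <2 present values in a class excluded from ranking")
    V <- V[enough, , drop = FALSE]
    keep <- keep[enough]
    idx <- idx[enough]
  }
  score <- sapply(stats_panel, function(nm) {
    apply(V, 1, rank_statistics[[nm]], pos = cs$pos, neg = cs$neg)
  })
  score <- matrix(score, nrow = length(keep))
  # larger statistic = more discriminative = better (smaller) rank
  per_stat_rank <- apply(-score, 2, rank, ties.method = "average")
  per_stat_rank <- matrix(per_stat_rank, nrow = length(keep))
  mean_rank <- rowMeans(per_stat_rank)
  ord <- order(mean_rank, keep)
  data.frame(
    site_id = keep[ord],
    protein_id = mat$sites$protein_id[idx][ord],
    mean_rank = mean_rank[ord],
    rank = seq_along(ord),
    stringsAsFactors = FALSE
  )
}

#' Build the candidate set for the optimizer
#'
#' Runs the fixed pipeline presence filter, fold-change filter, rank
#' combination, then walks the ranking keeping at most one site per
#' protein until `k` sites are collected. The resulting order defines the
#' chromosome positions of the genetic algorithm.
#'
#' @param mat A [phospho_matrix()].
#' @param labels Named `+1`/`-1` labels.
#' @param k Maximum number of candidate sites (default 100).
#' @param min_fraction Presence threshold per class (default 2/3).
#' @param min_fold Minimum fold change (default 4).
#' @param stats_panel Passed to [rank_sites()].
#' @return Data frame of class `candidate_set` (`site_id`, `protein_id`,
#'   `mean_rank`, `rank`), one chromosome position per row.
#' @export
select_candidates <- function(mat, labels, k = 100, min_fraction = 2 / 3,
                              min_fold = 4,
                              stats_panel = c("meandiff", "welch", "wilcoxon")) {
  present <- presence_filter(mat, labels, min_fraction)
  folded <- fold_change_filter(mat, labels, min_fold, sites = present)
  if (length(folded) < 2) {
    stop("fewer than 2 sites survive the presence and fold-change filters")
  }
  ranked <- rank_sites(mat, labels, sites = folded, stats_panel = stats_panel)
  keep <- !duplicated(ranked$protein_id)
  if (sum(keep) < 2) stop("fewer than 2 candidate sites after per-protein deduplication")
  out <- ranked[keep, , drop = FALSE][seq_len(min(k, sum(keep))), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_set", "data.frame")
  out
}
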