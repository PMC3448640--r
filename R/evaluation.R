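# Cross-validation protocol: balanced negative-instance construction,
# ROC AUC, sensitivity at the top of the ranking, seed-connectivity
# statistics and method comparison.

#' Split a seed set into k balanced folds
#'
#' Random partition into `k` disjoint groups whose sizes differ by at most
#' one, reproducible from `rng_seed`.
#'
#' @param seeds character vector of seed identifiers
#' @param k number of folds (default 5)
#' @param rng_seed integer seed (optional)
#' @return list of `k` character vectors partitioning `seeds`
#' @export
kfold_seed_split <- function(seeds, k = 5, rng_seed = NULL) {
  if (length(seeds) < k) {
    stop(sprintf("need at least %d seeds for %d-fold cross-validation, got %d",
                 k, k, length(seeds)))
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  shuffled <- sample(seeds)
  fold_of <- rep_len(seq_len(k), length(seeds))
  unname(split(shuffled, fold_of))
}

#' Balanced negative-instance scores
#'
#' True negatives are unobtainable for gene-phenotype association, so all
#' non-seeds are treated as potential negatives: they are shuffled,
#' partitioned into exactly `n_positives` disjoint groups (sizes
#' `floor(|nonseeds| / n_positives)`, remainder spread one per group), and
#' each group's mean score becomes one negative-instance score. Every
#' non-seed is used exactly once, the evaluation set is balanced, and the
#' chance-level AUC is 0.5.
#'
#' @param scores named numeric score vector
#' @param nonseeds character vector of non-seed node identifiers
#' @param n_positives number of positives in the evaluation set
#' @param rng_seed integer seed (optional; when NULL the current RNG
#'   stream is used)
#' @return numeric vector of `n_positives` negative-instance scores
#' @export
negative_instance_scores <- function(scores, nonseeds, n_positives,
                                     rng_seed = NULL) {
  if (length(nonseeds) == 0L) stop("empty non-seed set")
  stopifnot(n_positives >= 1, length(nonseeds) >= n_positives)
  if (!all(nonseeds %in% names(scores))) stop("non-seeds missing from scores")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  shuffled <- sample(nonseeds)
  grp <- rep_len(seq_len(n_positives), length(nonseeds))
  as.numeric(tapply(scores[shuffled], grp, mean))
}

#' ROC AUC of positive versus negative scores
#'
#' Mann-Whitney form: the probability that a randomly chosen positive
#' outranks a randomly chosen negative, ties counting one half.
#'
#' @param pos_scores,neg_scores numeric vectors of scores
#' @return AUC in \[0, 1\]
#' @export
roc_auc <- function(pos_scores, neg_scores) {
  np <- length(pos_scores); nn <- length(neg_scores)
  if (np == 0L || nn == 0L) stop("both score lists must be non-empty")
  r <- rank(c(pos_scores, neg_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Sensitivity among the top fraction of the ranking
#'
#' Ranks all nodes except the training seeds (which are known a priori) by
#' descending score, breaking ties by node identifier, takes the top
#' `ceiling(fraction * length)` nodes and returns the fraction of held-out
#' test seeds recovered among them.
#'
#' @param scores named numeric score vector
#' @param test_seeds held-out seeds to recover
#' @param train_seeds seeds used for scoring; excluded from the ranking
#'   (may be empty)
#' @param fraction top fraction of the ranked list (default 0.01)
#' @return sensitivity in \[0, 1\]
#' @export
sensitivity_at_top <- function(scores, test_seeds, train_seeds = character(),
                               fraction = 0.01) {
  if (length(test_seeds) == 0L) stop("empty test seed set")
  if (length(intersect(test_seeds, train_seeds))) {
    stop("test and training seeds overlap")
  }
  ranked <- scores[!(names(scores) %in% train_seeds)]
  ord <- order(-ranked, names(ranked))
  m <- ceiling(fraction * length(ranked))
  top <- names(ranked)[ord][seq_len(m)]
  length(intersect(test_seeds, top)) / length(test_seeds)
}

#' Cross-validated evaluation of a prioritization method
#'
#' Splits the seeds into `k` folds; for each fold, scores the network using
#' the other folds as seeds, then computes the ROC AUC of the held-out
#' seeds' scores against balanced negative-instance scores, and the
#' sensitivity among the top `fraction` of the ranking (training seeds
#' excluded). Non-seeds are the nodes outside the full seed set.
#'
#' @param net connected network
#' @param seeds seed identifiers (>= k)
#' @param method a method name accepted by [guild_score()], or a function
#'   `function(net, seeds, ...)` returning a named score vector
#' @param k number of folds (default 5)
#' @param rng_seed integer seed controlling the fold split and the negative
#'   grouping
#' @param fraction top fraction for sensitivity (default 0.01)
#' @param ... passed on to the scoring method
#' @return object of class `guild_eval`: list with `per_fold_auc`,
#'   `per_fold_sensitivity`, `auc_mean`, `auc_sd`, `sensitivity_mean`,
#'   `sensitivity_sd`, `k`
#' @export
cross_validate <- function(net, seeds, method, k = 5, rng_seed = NULL,
                           fraction = 0.01, ...) {
  scorer <- if (is.function(method)) method else {
    function(net, seeds, ...) guild_score(net, seeds, method = method, ...)
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  folds <- kfold_seed_split(seeds, k = k)
  nonseeds <- setdiff(network_nodes(net), seeds)
  auc <- sens <- numeric(k)
  for (i in seq_len(k)) {
    test <- folds[[i]]
    train <- unlist(folds[-i], use.names = FALSE)
    sc <- scorer(net, train, ...)
    neg <- negative_instance_scores(sc, nonseeds, n_positives = length(test))
    auc[i] <- roc_auc(sc[test], neg)
    sens[i] <- sensitivity_at_top(sc, test, train, fraction = fraction)
  }
  structure(list(per_fold_auc = auc, per_fold_sensitivity = sens,
                 auc_mean = mean(auc), auc_sd = stats::sd(auc),
                 sensitivity_mean = mean(sens),
                 sensitivity_sd = stats::sd(sens), k = k),
            class = "guild_eval")
}

#' @export
print.guild_eval <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation\n", x$k))
  cat(sprintf("  AUC:         %.4f +/- %.4f\n", x$auc_mean, x$auc_sd))
  cat(sprintf("  sensitivity: %.4f +/- %.4f (top of ranking)\n",
              x$sensitivity_mean, x$sensitivity_sd))
  invisible(x)
}

#' Seed connectivity statistics
#'
#' `ns` is the mean, over seeds, of the number of seed neighbors; `ss` is
#' the mean unweighted shortest-path hop count over all unordered seed
#' pairs. Tight disease modules have high `ns` and low `ss`.
#'
#' @param net network
#' @param seeds seed identifiers (>= 2 for `ss`)
#' @return list with `n_seeds`, `ns`, `ss`
#' @export
seed_connectivity <- function(net, seeds) {
  nodes <- network_nodes(net)
  if (!all(seeds %in% nodes)) stop("seeds not in network")
  nbr_counts <- vapply(seeds, function(s) {
    nb <- igraph::neighbors(net, s)$name
    length(intersect(nb, seeds))
  }, integer(1))
  ns <- mean(nbr_counts)
  ss <- NA_real_
  if (length(seeds) >= 2) {
    d <- igraph::distances(net, v = seeds, to = seeds, weights = NA)
    up <- d[upper.tri(d)]
    if (any(!is.finite(up))) {
      stop("seed pair in different components; restrict to the largest connected component")
    }
    ss <- mean(up)
  }
  list(n_seeds = length(seeds), ns = ns, ss = ss)
}

#' One-sided Wilcoxon comparison of two AUC samples
#'
#' Tests whether sample `a` is stochastically greater than sample `b`
#' (alternative "a > b"), paired (signed-rank) or unpaired (rank-sum),
#' with the exact null distribution for n <= 25 and the normal
#' approximation otherwise.
#'
#' @param auc_a,auc_b numeric vectors (equal length when paired)
#' @param paired logical, default TRUE (AUCs paired over phenotypes)
#' @return one-sided p-value
#' @export
compare_methods <- function(auc_a, auc_b, paired = TRUE) {
  if (paired && length(auc_a) != length(auc_b)) {
    stop("paired comparison requires equal lengths")
  }
  if (paired && all(auc_a == auc_b)) {
    warning("all paired differences are zero; returning p = 1")
    return(1)
  }
  n <- if (paired) sum(auc_a != auc_b) else length(auc_a)
  exact <- n <= 25
  suppressWarnings(
    stats::wilcox.test(auc_a, auc_b, paired = paired,
                       alternative = "greater", exact = exact,
                       correct = !exact)$p.value
  )
}

#' Correlation between performance and a covariate
#'
#' Pearson correlation (default) with its two-sided p-value; Spearman
#' available for rank-based association.
#'
#' @param x,y numeric vectors of equal length >= 3
#' @param method `"pearson"` or `"spearman"`
#' @return list with `r` and `p`
#' @export
correlate_performance <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in input")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(r = unname(ct$estimate), p = ct$p.value)
}
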