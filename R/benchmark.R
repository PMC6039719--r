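# Score-assessment statistics: top-10 precision and FPR with tie
# bootstrapping, ROC/AUC by threshold sweep, crosslink recovery sampling,
# term-weight scanning and paired significance tests.

# rank-10 tie analysis: returns the certainly-top models and the tied block
# when the block of models sharing the score at rank 10 straddles the
# boundary; otherwise the plain top 10.
.top10_split <- function(score) {
  n <- length(score)
  if (n < 10) stop("at least 10 models are required")
  ord <- order(score, decreasing = TRUE)
  v10 <- score[ord[10]]
  above <- which(score > v10)
  tied <- which(score == v10)
  if (length(above) + length(tied) > 10) {
    list(fixed = above, tied = tied, n_from_tied = 10L - length(above))
  } else {
    list(fixed = ord[1:10], tied = integer(0), n_from_tied = 0L)
  }
}

.bootstrap_top10 <- function(score, positive, stat, reps = 1000,
                             seed = NULL) {
  sp <- .top10_split(score)
  if (!length(sp$tied)) return(stat(positive[sp$fixed]))
  if (!is.null(seed)) set.seed(seed)
  mean(vapply(seq_len(reps), function(i) {
    pick <- sample(sp$tied, sp$n_from_tied)
    stat(positive[c(sp$fixed, pick)])
  }, numeric(1)))
}

#' Top-10 precision of a scoring function
#'
#' Models are ranked by score (descending); precision is TP/(TP+FP) over
#' the 10 top-ranked models, TP being top-10 models that satisfy the
#' positive criterion. When a block of equal scores straddles the rank-10
#' boundary, 10 models are repeatedly sampled from the certain set plus the
#' tied block and the mean precision over `reps` draws is returned.
#'
#' @param score numeric model scores (higher is better), length >= 10.
#' @param positive logical, positive (acceptable) model per [model_quality].
#' @param seed optional RNG seed for the tie bootstrap.
#' @param reps bootstrap repetitions.
#' @return precision in `[0, 1]`.
#' @export
precision_top10 <- function(score, positive, seed = NULL, reps = 1000) {
  stopifnot(length(score) == length(positive))
  .bootstrap_top10(score, positive, mean, reps, seed)
}

#' Top-10 false-positive rate of a scoring function
#'
#' FP/(FP+TN): negatives ranked in the top 10 over all negatives. Ties at
#' the rank-10 boundary are bootstrapped as in [precision_top10()].
#'
#' @inheritParams precision_top10
#' @return FPR in `[0, 1]`; errors when there are no negative models.
#' @export
fpr_top10 <- function(score, positive, seed = NULL, reps = 1000) {
  stopifnot(length(score) == length(positive))
  n_neg <- sum(!positive)
  if (n_neg == 0)
    stop("no negative models: false-positive rate undefined")
  .bootstrap_top10(score, positive,
                   function(top) sum(!top) / n_neg, reps, seed)
}

#' ROC curve and AUC by threshold sweep
#'
#' The scoring threshold is lowered through the distinct score values;
#' at each threshold the models at or above it are predicted positive. AUC
#' is the trapezoidal area under the resulting (FPR, TPR) curve and equals
#' the rank-statistic (Mann-Whitney) formulation.
#'
#' @param score numeric model scores (higher is better).
#' @param positive logical labels; both classes must be present.
#' @return list with `points` (data.frame `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(score, positive) {
  stopifnot(length(score) == length(positive))
  P <- sum(positive); N <- sum(!positive)
  if (P == 0 || N == 0)
    stop("ROC requires both positive and negative models")
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; y <- positive[ord]
  # group ties: one ROC point per distinct score
  last <- cumsum(rle(s)$lengths)
  tpr <- cumsum(y)[last] / P
  fpr <- cumsum(!y)[last] / N
  pts <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  list(points = pts, auc = auc)
}

#' Sample an observed crosslink set at a given recovery rate
#'
#' Draws `round(rate * N)` crosslinks uniformly without replacement
#' (round half up), redrawing until the sample holds at least `min_inter`
#' inter-subunit crosslinks, emulating the crosslink yield of a real
#' experiment.
#'
#' @param xl theoretical crosslink table.
#' @param rate recovery rate in `(0, 1]`.
#' @param min_inter minimum number of inter-subunit crosslinks.
#' @param seed optional RNG seed.
#' @param max_tries redraw budget.
#' @return subset of `xl`.
#' @export
sample_recovery <- function(xl, rate, min_inter = 2, seed = NULL,
                            max_tries = 10000) {
  if (rate <= 0 || rate > 1) stop("rate must be in (0, 1]")
  n <- nrow(xl)
  n_inter <- sum(xl$classification == "inter")
  if (n_inter < min_inter)
    stop("theoretical set has only ", n_inter,
         " inter-subunit crosslinks; ", min_inter, " required")
  m <- floor(rate * n + 0.5)
  if (m >= n) return(xl)
  if (m < min_inter)
    stop("sample size ", m, " cannot contain ", min_inter,
         " inter-subunit crosslinks")
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(max_tries)) {
    pick <- sample(n, m)
    if (sum(xl$classification[pick] == "inter") >= min_inter)
      return(xl[sort(pick), , drop = FALSE])
  }
  stop("could not draw a sample with ", min_inter,
       " inter-subunit crosslinks in ", max_tries, " tries")
}

#' Exhaustive grid scan of term weights
#'
#' Scores each model as a weighted sum of per-term values for every weight
#' combination on a grid from 0 to 1, and returns the combination with the
#' highest mean top-10 precision across benchmark cases. Ties are broken
#' toward the lexicographically smallest weight vector. Combinations whose
#' scores are constant across all models are degenerate and excluded.
#'
#' @param cases list of benchmark cases; each a list with `terms` (matrix,
#'   models x terms) and `positive` (logical per model).
#' @param grid_step weight grid step (default 0.1).
#' @param seed RNG seed for tie bootstraps inside precision.
#' @return list with `weights` (best vector), `precision` (its mean
#'   precision) and `table` (mean precision per combination, `NA` for
#'   degenerate combinations).
#' @export
scan_weights <- function(cases, grid_step = 0.1, seed = NULL) {
  k <- ncol(cases[[1]]$terms)
  vals <- seq(0, 1, by = grid_step)
  combos <- as.matrix(expand.grid(rep(list(vals), k)))
  colnames(combos) <- colnames(cases[[1]]$terms)
  prec <- rep(NA_real_, nrow(combos))
  for (i in seq_len(nrow(combos))) {
    w <- combos[i, ]
    p <- vapply(cases, function(cs) {
      s <- as.numeric(cs$terms %*% w)
      if (length(unique(s)) == 1) return(NA_real_)  # degenerate
      precision_top10(s, cs$positive, seed = seed)
    }, numeric(1))
    if (!anyNA(p)) prec[i] <- mean(p)
  }
  if (all(is.na(prec)))
    stop("all weight combinations are degenerate (constant scores)")
  best_p <- max(prec, na.rm = TRUE)
  cand <- which(!is.na(prec) & prec == best_p)
  # lexicographic tie-break toward the smallest weight vector
  ord <- do.call(order, as.data.frame(combos[cand, , drop = FALSE]))
  best <- cand[ord[1]]
  list(weights = combos[best, ], precision = best_p,
       table = cbind(as.data.frame(combos), precision = prec))
}

#' One-sided paired t-test that mean(a) > mean(b)
#'
#' Pairs are matched benchmark cases. With zero variance of the paired
#' differences the p-value degenerates to 0 (a uniformly larger), 1
#' (uniformly smaller) or 0.5 (identical), with a warning.
#'
#' @param a,b paired numeric vectors of equal length >= 2.
#' @return p-value.
#' @export
paired_t_onesided <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 2) stop("at least 2 pairs are required")
  d <- a - b
  if (sd(d) <= sqrt(.Machine$double.eps) * (abs(mean(d)) + 1)) {
    warning("zero variance of paired differences; degenerate p-value")
    return(if (mean(d) > 0) 0 else if (mean(d) < 0) 1 else 0.5)
  }
  t.test(a, b, paired = TRUE, alternative = "greater")$p.value
}
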