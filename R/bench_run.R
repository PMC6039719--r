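# End-to-end evaluation of a scoring function on a synthetic benchmark:
# per-model scores joined to quality labels, top-10 precision/FPR, ROC/AUC
# and the recovery-rate curve.

#' Precompute distance tables for a crosslink set over many models
#'
#' Runs the SASD engine once per model for the given crosslink rows. The
#' resulting tables can be fed to [cmnxl()] (argument `distances`) or
#' [recovery_curve()] so that rescoring crosslink subsets needs no further
#' path searches.
#'
#' @param models list of `xl_complex` models.
#' @param xl crosslink table.
#' @param params a [cmnxl_params()] (grid and cap settings are used).
#' @return list of data.frames, one per model.
#' @export
benchmark_distances <- function(models, xl, params = cmnxl_params()) {
  lapply(models, function(m) {
    grid <- build_grid(m, spacing = params$spacing,
                       margin = params$margin, probe = params$probe)
    compute_sasd(m, xl, grid = grid, cap = params$cap)
  })
}

#' Evaluate cMNXL (or a term subset) on a synthetic benchmark
#'
#' Scores every decoy of the benchmark against the sampled crosslink set
#' and reports per-model scores with quality labels, top-10 precision and
#' FPR (tie-bootstrapped), and the ROC/AUC.
#'
#' @param bench an `xl_benchmark` from [make_benchmark()].
#' @param params a [cmnxl_params()].
#' @param seed RNG seed for tie bootstraps.
#' @param xl crosslink set to score against (default the benchmark's
#'   sampled set).
#' @param distances optional precomputed [benchmark_distances()] for `xl`.
#' @return object of class `xl_benchresult`: `per_model` (data.frame),
#'   `precision`, `fpr`, `auc`, `roc_points`, `top_rank_of_best`.
#' @export
run_benchmark <- function(bench, params = cmnxl_params(), seed = NULL,
                          xl = bench$sampled, distances = NULL) {
  stopifnot(inherits(bench, "xl_benchmark"))
  if (is.null(distances))
    distances <- benchmark_distances(bench$decoys, xl, params)
  score <- vapply(seq_along(bench$decoys), function(i)
    cmnxl(bench$decoys[[i]], xl, params,
          distances = distances[[i]])$total, numeric(1))
  per <- cbind(bench$quality, score = score)
  positive <- per$positive
  prec <- precision_top10(score, positive, seed = seed)
  fpr <- if (any(!positive))
    fpr_top10(score, positive, seed = seed) else NA_real_
  roc <- if (any(positive) && any(!positive))
    roc_auc(score, positive) else list(points = NULL, auc = NA_real_)
  best <- which.min(per$mean_rmsd)
  top_rank_of_best <- rank(-score, ties.method = "min")[best]
  structure(list(per_model = per, precision = prec, fpr = fpr,
                 auc = roc$auc, roc_points = roc$points,
                 top_rank_of_best = top_rank_of_best, seed = seed),
            class = "xl_benchresult")
}

#' @export
print.xl_benchresult <- function(x, ...) {
  cat(sprintf(
    "Benchmark result over %d models: precision %.3f, FPR %s, AUC %s\n",
    nrow(x$per_model), x$precision,
    ifelse(is.na(x$fpr), "NA", sprintf("%.3f", x$fpr)),
    ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  cat("  best model (lowest mean RMSD) ranked ", x$top_rank_of_best,
      " by score\n", sep = "")
  invisible(x)
}

#' Precision and AUC as a function of crosslink recovery rate
#'
#' For each rate, repeatedly samples an observed crosslink set from the
#' benchmark's theoretical set, rescores every decoy and computes top-10
#' precision and AUC; reports the means over `reps` repetitions. Distance
#' tables for the full theoretical set are computed once per decoy, so
#' each repetition only re-sums per-crosslink contributions.
#'
#' @param bench an `xl_benchmark`.
#' @param rates recovery rates in `(0, 1]`.
#' @param reps repetitions per rate (>= 1).
#' @param seed RNG seed.
#' @param params a [cmnxl_params()].
#' @param min_inter minimum inter-subunit crosslinks per sample.
#' @param distances optional precomputed [benchmark_distances()] for the
#'   theoretical set.
#' @return data.frame with columns `rate`, `precision`, `auc`.
#' @export
recovery_curve <- function(bench, rates, reps = 100, seed = 1,
                           params = cmnxl_params(), min_inter = 2,
                           distances = NULL) {
  stopifnot(inherits(bench, "xl_benchmark"))
  if (reps < 1) stop("reps must be at least 1")
  theo <- bench$theoretical
  if (is.null(distances))
    distances <- benchmark_distances(bench$decoys, theo, params)
  cls <- theo$classification
  contrib <- vapply(distances, function(dd)
    .xl_contrib(dd, cls, params)$contrib, numeric(nrow(theo)))
  positive <- bench$quality$positive
  set.seed(seed)
  out <- lapply(rates, function(rate) {
    pr <- numeric(reps); au <- numeric(reps)
    for (r in seq_len(reps)) {
      sub <- sample_recovery(theo, rate, min_inter = min_inter)
      idx <- as.integer(rownames(sub))
      score <- colSums(contrib[idx, , drop = FALSE])
      pr[r] <- precision_top10(score, positive)
      au[r] <- if (any(positive) && any(!positive))
        roc_auc(score, positive)$auc else NA_real_
    }
    data.frame(rate = rate, precision = mean(pr), auc = mean(au))
  })
  do.call(rbind, out)
}
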