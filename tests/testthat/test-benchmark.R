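# Evaluation statistics: top-10 precision/FPR with tie bootstrapping,
# ROC/AUC, recovery sampling, weight scanning and the paired t-test.

test_that("top-10 precision without ties is a plain cut", {
  score <- 100:1
  positive <- rep(FALSE, 100)
  positive[1:10] <- TRUE
  expect_equal(precision_top10(score, positive), 1)
  positive2 <- rep(FALSE, 100)
  positive2[c(1:7, 50:52)] <- TRUE
  expect_equal(precision_top10(score, positive2), 0.7)
  expect_error(precision_top10(1:5, rep(TRUE, 5)), "at least 10")
})

test_that("tie bootstrap matches the hypergeometric expectation", {
  # 20 models share the top score, 10 of them positive: expectation 0.5
  score <- c(rep(100, 20), 80:1)
  positive <- c(rep(c(TRUE, FALSE), 10), rep(FALSE, 80))
  p <- precision_top10(score, positive, seed = 1)
  expect_equal(p, 0.5, tolerance = 0.02)
  # convergence: doubling the repetitions moves the estimate < 0.01
  p2 <- precision_top10(score, positive, seed = 2, reps = 2000)
  expect_lt(abs(p2 - p), 0.01)
})

test_that("ties fully inside the top 10 do not trigger the bootstrap", {
  score <- c(rep(100, 10), 80:1)
  positive <- c(rep(TRUE, 5), rep(FALSE, 85))
  # deterministic despite no seed: no straddling tie block
  expect_equal(precision_top10(score, positive),
               precision_top10(score, positive))
  expect_equal(precision_top10(score, positive), 0.5)
})

test_that("top-10 FPR counts top-ranked negatives over all negatives", {
  score <- 100:1
  positive <- rep(FALSE, 100)
  positive[1:10] <- TRUE
  expect_equal(fpr_top10(score, positive), 0)
  # all-negative top 10 with 90 negatives total
  positive3 <- rep(FALSE, 100)
  positive3[11:20] <- TRUE
  expect_equal(fpr_top10(score, positive3), 10 / 90)
  expect_error(fpr_top10(score, rep(TRUE, 100)), "negative")
})

test_that("ROC/AUC: separation extremes and the random-score baseline", {
  score <- 1:100
  positive <- score > 50
  expect_equal(roc_auc(score, positive)$auc, 1)
  expect_equal(roc_auc(score, !positive)$auc, 0)
  set.seed(7)
  s <- rnorm(10000)
  y <- sample(c(TRUE, FALSE), 10000, replace = TRUE)
  expect_equal(roc_auc(s, y)$auc, 0.5, tolerance = 0.02)
  expect_error(roc_auc(score, rep(TRUE, 100)), "both")
})

test_that("threshold-sweep AUC equals the rank formulation and pROC", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (i in 1:10) {
    n <- sample(20:60, 1)
    s <- round(rnorm(n), 1)  # coarse scores force ties
    y <- runif(n) < 0.4
    if (!any(y) || all(y)) next
    a <- roc_auc(s, y)$auc
    expect_equal(a, rank_auc(s, y), tolerance = 1e-12)
    expect_equal(a, as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                   direction = "<"))),
                 tolerance = 1e-12)
  }
  # ROC points are monotone in both coordinates
  set.seed(12)
  s <- round(rnorm(50), 1); y <- runif(50) < 0.5
  pts <- roc_auc(s, y)$points
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
})

test_that("recovery sampling honours rate, minimum inter links and seed", {
  bench <- cached_benchmark()
  theo <- bench$theoretical
  expect_identical(sample_recovery(theo, 1), theo)
  s1 <- sample_recovery(theo, 0.15, seed = 3)
  s2 <- sample_recovery(theo, 0.15, seed = 3)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), floor(0.15 * nrow(theo) + 0.5))
  expect_gte(sum(s1$classification == "inter"), 2)
  only_intra <- theo[theo$classification == "intra", ]
  expect_error(sample_recovery(only_intra, 0.5), "inter")
})

test_that("weight scanning concentrates on the informative term", {
  set.seed(21)
  cases <- lapply(1:4, function(i) {
    n <- 60
    positive <- rep(FALSE, n); positive[sample(n, 12)] <- TRUE
    informative <- ifelse(positive, 1, 0) + rnorm(n, 0, 0.05)
    noise1 <- rnorm(n); noise2 <- rnorm(n)
    list(terms = cbind(good = informative, bad1 = noise1,
                       bad2 = noise2),
         positive = positive)
  })
  sw <- scan_weights(cases, grid_step = 0.5, seed = 1)
  expect_gt(sw$weights["good"], 0)
  expect_equal(unname(sw$weights[c("bad1", "bad2")]), c(0, 0))
  # grid_step 1 scans only the hypercube corners
  sw1 <- scan_weights(cases, grid_step = 1, seed = 1)
  expect_equal(nrow(sw1$table), 2^3)
  # constant scores are degenerate
  flat <- lapply(cases, function(cs) {
    cs$terms <- matrix(1, nrow(cs$terms), 3); cs
  })
  expect_error(scan_weights(flat, grid_step = 1), "degenerate")
})

test_that("paired one-sided t-test matches the closed-form statistic", {
  set.seed(31)
  b <- rnorm(5)
  a <- b + 1 + rnorm(5, 0, 0.1)
  p <- paired_t_onesided(a, b)
  d <- a - b
  tstat <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(p, pt(tstat, df = 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(p, 0.05)
  expect_warning(p_eq <- paired_t_onesided(b, b), "zero variance")
  expect_equal(p_eq, 0.5)
  expect_warning(p_up <- paired_t_onesided(b + 2, b), "zero variance")
  expect_equal(p_up, 0)
  expect_error(paired_t_onesided(1:3, 1:4), "equal length")
})

test_that("recovery curve: full recovery equals full-data precision", {
  bench <- cached_benchmark()
  dist_full <- benchmark_distances(bench$decoys, bench$theoretical)
  rc <- recovery_curve(bench, rates = 1, reps = 1, seed = 5,
                       distances = dist_full)
  full <- run_benchmark(bench, seed = 5, xl = bench$theoretical,
                        distances = dist_full)
  expect_equal(rc$precision, full$precision, tolerance = 1e-9)
  expect_error(recovery_curve(bench, rates = 0.5, reps = 0), "reps")
})
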