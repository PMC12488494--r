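test_that("AUROC handles separation, ties and errors", {
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)  # all ties
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUROC equals exhaustive pair counting on random sets", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(10:200, 1)
    s <- round(runif(n), sample(1:3, 1))  # rounding forces ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    expect_equal(auroc(s, y), auroc_pairs(s, y), tolerance = 1e-12)
  }
})

test_that("AUROC respects complement and monotone-transform invariances", {
  set.seed(12)
  for (i in 1:20) {
    s <- runif(60); y <- rbinom(60, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    expect_equal(auroc(1 - s, y), 1 - auroc(s, y), tolerance = 1e-12)
    expect_equal(auroc(qlogis(s), y), auroc(s, y), tolerance = 1e-12)
  }
})

test_that("AUROC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(13)
  s <- runif(300); y <- rbinom(300, 1, 0.5)
  expect_equal(auroc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("reverse-percentile interval matches the formula on fixed resamples", {
  set.seed(20)
  s <- runif(80); y <- rbinom(80, 1, plogis(3 * s - 1.5))
  y[1:2] <- c(0, 1)
  res <- bootstrap_ci(auroc, s, y, n_boot = 50, seed = 9)
  # oracle: replay the same resampling stream by hand
  point <- auroc(s, y)
  set.seed(doepred:::substream_seed(9, "bootstrap"))
  boot <- replicate(50, {
    repeat {
      i <- sample.int(80, 80, replace = TRUE)
      v <- tryCatch(auroc(s[i], y[i]), error = function(e) NA_real_)
      if (!is.na(v)) break
    }
    v
  })
  q <- quantile(boot, c(0.975, 0.025), names = FALSE)
  expect_equal(res$point, point)
  expect_equal(res$lower, 2 * point - q[1])
  expect_equal(res$upper, 2 * point - q[2])
})

test_that("bootstrap is deterministic given the seed and constant for constant metrics", {
  s <- runif(40); y <- rep(c(0, 1), 20)
  a <- bootstrap_ci(auroc, s, y, n_boot = 30, seed = 4)
  b <- bootstrap_ci(auroc, s, y, n_boot = 30, seed = 4)
  expect_identical(a, b)
  const <- function(scores, labels) 0.42
  cc <- bootstrap_ci(const, s, y, n_boot = 30, seed = 4)
  expect_equal(cc$lower, 0.42)
  expect_equal(cc$upper, 0.42)
})

test_that("macro and micro averaging coincide in the degenerate cases", {
  s <- runif(50); y <- rbinom(50, 1, 0.5); y[1:2] <- c(0, 1)
  one <- macro_micro(list(a = s), list(a = y))
  expect_equal(one$macro, one$micro)
  # identical multisets per class
  two <- macro_micro(list(a = s, b = s), list(a = y, b = y))
  expect_equal(two$macro, two$micro)
})

test_that("micro averaging equals pooled computation on a 3-class set", {
  set.seed(14)
  ss <- lapply(1:3, function(i) runif(40))
  yy <- lapply(1:3, function(i) { y <- rbinom(40, 1, 0.5); y[1:2] <- 0:1; y })
  names(ss) <- names(yy) <- c("a", "b", "c")
  mm <- macro_micro(ss, yy)
  expect_equal(mm$micro, auroc_pairs(unlist(ss), unlist(yy)), tolerance = 1e-12)
  expect_equal(mm$macro, mean(mapply(auroc_pairs, ss, yy)), tolerance = 1e-12)
})

test_that("calibration recovers slope 1, intercept 0 on conditional rates", {
  # predictions exactly equal to the conditional positive rate per group
  p_levels <- c(0.1, 0.25, 0.5, 0.75, 0.9)
  n_per <- 20
  preds <- rep(p_levels, each = n_per)
  labels <- unlist(lapply(p_levels, function(pk)
    rep(c(1, 0), c(round(pk * n_per), n_per - round(pk * n_per)))))
  cal <- calibration(preds, labels, n_bins = 10)
  expect_equal(cal$slope, 1, tolerance = 1e-9)
  expect_equal(cal$intercept, 0, tolerance = 1e-9)
  # single point: all predictions 0.5 at prevalence 0.5
  single <- calibration(rep(0.5, 40), rep(c(0, 1), 20))
  expect_equal(single$curve$mean_pred, 0.5)
  expect_equal(single$curve$obs_rate, 0.5)
})

test_that("calibration bin counts sum to n and degenerate input is flagged", {
  p <- runif(200); y <- rbinom(200, 1, p)
  cal <- calibration(p, y)
  expect_equal(sum(cal$curve$count), 200)
  single <- calibration(rep(0.5, 50), rbinom(50, 1, 0.5))
  expect_true(single$degenerate)
  expect_equal(nrow(single$curve), 1)
})

test_that("the F-beta cutoff reproduces the worked example and limits", {
  res <- optimal_cutoff(c(0.1, 0.4, 0.6, 0.9), c(0, 0, 1, 1), beta = 1)
  expect_equal(res$threshold, 0.6)
  expect_equal(res$f_beta, 1)
  # beta -> 0 favors precision: picks a pure-precision threshold when one exists
  res0 <- optimal_cutoff(c(0.1, 0.5, 0.6, 0.9), c(1, 0, 1, 1), beta = 0.01)
  expect_equal(res0$precision, 1)
  expect_error(optimal_cutoff(c(0.1, 0.2), c(0, 0)), "positive")
})

test_that("the distinct-value scan matches a dense-grid oracle", {
  set.seed(16)
  grid <- seq(0, 1, length.out = 1e4)
  for (i in 1:1000) {
    n <- sample(8:40, 1)
    # predictions on a lattice coarser than the grid, so the grid resolves
    # every distinct value (and ties are exercised)
    p <- sample(seq(0.05, 0.95, by = 0.01), n, replace = TRUE)
    y <- rbinom(n, 1, 0.5)
    if (sum(y) == 0) y[1] <- 1
    beta <- sample(c(0.2, 0.5, 1, 2), 1)
    expect_equal(optimal_cutoff(p, y, beta)$f_beta,
                 grid_cutoff_oracle(p, y, beta, grid))
  }
})

test_that("no distinct-value threshold beats the reported optimum", {
  set.seed(17)
  for (i in 1:20) {
    p <- round(runif(60), 2); y <- rbinom(60, 1, 0.5)
    if (sum(y) == 0) y[1] <- 1
    res <- optimal_cutoff(p, y, beta = 1)
    for (t in unique(p)) {
      tp <- sum(p >= t & y == 1); pp <- sum(p >= t)
      prec <- ifelse(pp == 0, 0, tp / pp); rec <- tp / sum(y)
      f <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
      expect_lte(f, res$f_beta + 1e-12)
    }
  }
})

test_that("ties in F-beta resolve to the smallest threshold", {
  # thresholds 0.2 and 0.8 both give F = 1 is impossible; craft equal-F ties
  p <- c(0.1, 0.1, 0.9, 0.9)
  y <- c(0, 0, 1, 1)
  res <- optimal_cutoff(p, y, beta = 1)
  expect_equal(res$threshold, 0.9)
  p2 <- c(0.2, 0.8); y2 <- c(1, 1)
  res2 <- optimal_cutoff(p2, y2, beta = 1)  # both thresholds give F = 1
  expect_equal(res2$threshold, 0.2)
})

test_that("evaluation reports carry coherent per-class and averaged metrics", {
  set.seed(18)
  s <- list(a = runif(120), b = runif(120))
  y <- lapply(s, function(x) rbinom(120, 1, x))
  rep <- evaluation_report(s, y, beta = 1, n_boot = 40, seed = 2)
  expect_s3_class(rep, "doe_evaluation")
  expect_equal(rep$macro_auroc, mean(c(rep$per_class$a$auroc,
                                       rep$per_class$b$auroc)))
  for (pc in rep$per_class) {
    expect_true(pc$auroc >= 0 && pc$auroc <= 1)
    expect_true(pc$cutoff$precision >= 0 && pc$cutoff$precision <= 1)
  }
})
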