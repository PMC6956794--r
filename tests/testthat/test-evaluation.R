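test_that("pair splitting partitions at the pair level deterministically", {
  pairs <- sprintf("protein:A%02d|protein:B%02d", 1:10, 1:10)
  sp <- split_pairs(pairs, 0.2, seed = 3)
  expect_identical(length(sp$test), 2L)
  expect_identical(length(sp$train), 8L)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), pairs)
  expect_identical(split_pairs(pairs, 0.2, seed = 3), sp)
  expect_false(identical(split_pairs(pairs, 0.2, seed = 4)$test, sp$test))
  expect_error(split_pairs(pairs, 0), "test_fraction")
  expect_error(split_pairs(pairs, 1.2), "test_fraction")
})

test_that("training downsampling caps each pair at the maximum", {
  withr::with_seed(5, {
    sizes <- c(5L, 250L, 100L, 101L)
    com <- do.call(rbind, lapply(seq_along(sizes), function(k) {
      make_comentions(sizes[k], doc = sprintf("d%d_%04d", k,
                                              seq_len(sizes[k])),
                      id1 = rep(sprintf("D%d", k), sizes[k]),
                      id2 = rep(sprintf("G%d", k), sizes[k]))
    }))
  })
  out <- downsample_train(com, max_per_pair = 100, seed = 2)
  kept <- table(comention_pair_keys(out))
  expect_identical(unname(sort(as.integer(kept))),
                   sort(pmin(sizes, 100L)))
  # pairs under the cap are untouched, determinism per seed
  expect_identical(downsample_train(com, 100, seed = 2), out)
  expect_error(downsample_train(com, 0), "at least 1")
})

test_that("pr_curve reproduces the hand-enumerated four-pair example", {
  scores <- c(0.9, 0.8, 0.7, 0.1)
  labels <- c(TRUE, FALSE, TRUE, FALSE)
  curve <- pr_curve(scores, labels, a = 0.5)
  expect_equal(curve$precision, c(1, 1 / 2, 2 / 3, 1 / 2))
  expect_equal(curve$recall, c(1 / 2, 1 / 2, 1, 1))
  expect_equal(curve$tp + curve$fn, rep(2L, 4))  # TP + FN = P throughout
  # a = b = 0.5 here, so adjusted precision equals precision
  expect_equal(curve$adjusted_precision, curve$precision)
  expect_equal(auprc(curve, adjusted = FALSE), 5 / 6)
  # tied scores collapse to a single threshold point
  one <- pr_curve(c(0.4, 0.4, 0.4, 0.4), labels, a = 0.1)
  expect_identical(nrow(one), 1L)
  expect_equal(one$precision, 0.5)
  expect_error(pr_curve(scores, c(TRUE, TRUE, TRUE, TRUE)), "positive")
})

test_that("adjusted precision follows its closed form", {
  expect_equal(adjusted_precision(3, 1, 0.4, 0.4), 3 / 4)
  expect_equal(adjusted_precision(7, 0, 0.1, 0.6), 1)
  expect_equal(adjusted_precision(5, 5, 0.1, 0.5), 0.1)
  expect_error(adjusted_precision(1, 1, 0, 0.5), "strictly")
  expect_error(adjusted_precision(1, 1, 0.1, 1), "strictly")
})

test_that("perfect rankings reach area 1; uninformative rankings reach b", {
  labels <- rep(c(TRUE, FALSE), c(10, 90))
  scores <- c(runif(10, 0.6, 1), runif(90, 0, 0.4))
  curve <- pr_curve(scores, labels, a = 0.1)
  expect_equal(auprc(curve, adjusted = FALSE), 1)
  expect_equal(auprc(curve, adjusted = TRUE), 1)
  flat <- pr_curve(rep(0.5, 100), labels, a = 0.1)
  expect_equal(auprc(flat, adjusted = FALSE), 0.1)
})

test_that("pr_curve and auprc agree with the brute-force oracle", {
  for (seed in 1:6) {
    withr::with_seed(seed, {
      n <- sample(20:200, 1)
      labels <- runif(n) < 0.3
      if (!any(labels)) labels[1] <- TRUE
      if (all(labels)) labels[1] <- FALSE
      # duplicate scores on purpose to exercise tie grouping
      scores <- sample(round(runif(n), 2), n, replace = TRUE)
    })
    curve <- pr_curve(scores, labels, a = 0.1)
    pts <- oracle_pr_points(scores, labels)
    expect_equal(curve$threshold, pts$threshold)
    expect_identical(as.integer(curve$tp), pts$tp)
    expect_identical(as.integer(curve$fp), pts$fp)
    expect_equal(auprc(curve, adjusted = FALSE),
                 oracle_auprc(scores, labels), tolerance = 1e-12)
    expect_equal(auprc(curve, adjusted = TRUE),
                 oracle_auprc(scores, labels, a = 0.1), tolerance = 1e-12)
  }
})

test_that("auroc matches exhaustive pair counting and pROC", {
  expect_equal(auroc(c(3, 2, 1), c(TRUE, FALSE, FALSE)), 1)
  expect_equal(auroc(rep(1, 4), c(TRUE, TRUE, FALSE, FALSE)), 0.5)
  # two positives / two negatives with one inversion (0.4 < 0.6)
  expect_equal(auroc(c(0.9, 0.6, 0.4, 0.2),
                     c(TRUE, FALSE, TRUE, FALSE)), 0.75)
  for (seed in 1:4) {
    withr::with_seed(seed, {
      n <- 60
      labels <- runif(n) < 0.4
      if (!any(labels)) labels[1] <- TRUE
      if (all(labels)) labels[1] <- FALSE
      scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
    })
    expect_equal(auroc(scores, labels), oracle_auroc(scores, labels),
                 tolerance = 1e-12)
    if (requireNamespace("pROC", quietly = TRUE)) {
      expect_equal(auroc(scores, labels),
                   as.numeric(pROC::auc(pROC::roc(
                     labels, scores, quiet = TRUE, direction = "<"))),
                   tolerance = 1e-12)
    }
  }
})

test_that("metrics are invariant under monotone score transforms", {
  withr::with_seed(9, {
    labels <- runif(80) < 0.3
    labels[1:2] <- c(TRUE, FALSE)
    scores <- runif(80)
  })
  base_ap <- auprc(pr_curve(scores, labels, a = 0.1))
  base_roc <- auroc(scores, labels)
  for (f in list(function(x) 2 * x + 3, function(x) x^3,
                 function(x) exp(x), function(x) rank(x))) {
    expect_equal(auprc(pr_curve(f(scores), labels, a = 0.1)), base_ap)
    expect_equal(auroc(f(scores), labels), base_roc)
  }
})

test_that("cross-validation over alpha folds pairs disjointly", {
  sw <- small_world(seed = 4)
  lab <- label_comentions(sw$corpus, sw$world$gold)$comentions
  # grid of one value is returned as is
  cv1 <- cv_alpha(lab, sw$world$gold, folds = 3, alpha_grid = 0.4,
                  seed = 1, hp = test_hp(), model = "baseline")
  expect_identical(cv1$best_alpha, 0.4)
  cv <- cv_alpha(lab, sw$world$gold, folds = 3,
                 alpha_grid = seq(0, 1, by = 0.25), seed = 1,
                 hp = test_hp(), model = "context")
  expect_true(cv$best_alpha %in% seq(0, 1, by = 0.25))
  expect_identical(dim(cv$fold_matrix), c(3L, 5L))
  expect_false(any(is.na(cv$results$mean_adjusted_auprc)))
  expect_error(cv_alpha(lab[1:2, ], sw$world$gold, folds = 3,
                        alpha_grid = 0.5), "too few pairs")
})

test_that("context model prefers at least as large an alpha as baseline", {
  # directional: sentence scores make counts more reliable, so the
  # context model should not down-weight counts more than the baseline
  wins <- 0L
  n_seeds <- 5L
  grid <- seq(0, 1, by = 0.1)
  for (seed in seq_len(n_seeds)) {
    sw <- small_world(seed = 400 + seed)
    lab <- label_comentions(sw$corpus, sw$world$gold)$comentions
    a_ctx <- cv_alpha(lab, sw$world$gold, folds = 3, alpha_grid = grid,
                      seed = seed, hp = test_hp(), model = "context")
    a_base <- cv_alpha(lab, sw$world$gold, folds = 3, alpha_grid = grid,
                       seed = seed, model = "baseline")
    wins <- wins + (a_ctx$best_alpha >= a_base$best_alpha)
  }
  expect_gte(wins, 4L)
})

test_that("bootstrap comparison is seeded and honest about identical models", {
  withr::with_seed(13, {
    labels <- runif(120) < 0.3
    labels[1:2] <- c(TRUE, FALSE)
    good <- labels + rnorm(120, sd = 0.6)
    other <- runif(120)
  })
  same <- bootstrap_compare(good, good, labels, n_boot = 200, seed = 7)
  expect_equal(same$mean_diff, 0)
  expect_equal(same$p_value, 1)
  cmp <- bootstrap_compare(good, other, labels, n_boot = 200, seed = 7)
  expect_gte(cmp$sd_a, 0)
  expect_gte(cmp$sd_b, 0)
  expect_identical(bootstrap_compare(good, other, labels, n_boot = 200,
                                     seed = 7)$mean_diff, cmp$mean_diff)
  expect_gt(cmp$mean_diff, 0)
  expect_lt(cmp$p_value, 0.01)
})
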