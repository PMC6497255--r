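# Feature selection, WND and SVM classifiers, grouped twofold CV.

make_gaussian_classes <- function(n_per, p, gap, seed, informative = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per * p), 2 * n_per, p)
  y <- rep(c("A", "B"), each = n_per)
  x[y == "B", seq_len(informative)] <-
    x[y == "B", seq_len(informative)] + gap
  list(x = x, y = y)
}

test_that("Fisher scores match the two-class closed form", {
  # identical feature -> 0
  x <- cbind(flat = rep(1, 20), rnorm(20))
  y <- rep(c("A", "B"), 10)
  expect_equal(fisher_scores(x, y)[1], 0)

  # mean gap 10, unit within-variance -> between 25, within 1 -> score 25
  set.seed(42)
  n <- 4000
  f <- c(rnorm(n, 0, 1), rnorm(n, 10, 1))
  yy <- rep(c("A", "B"), each = n)
  expect_equal(fisher_scores(cbind(f), yy)[1], 25, tolerance = 0.05)

  # zero within-variance with separated means hits the finite cap
  x0 <- cbind(c(rep(0, 10), rep(1, 10)))
  y_blocks <- rep(c("A", "B"), each = 10)
  expect_equal(fisher_scores(x0, y_blocks)[1], 1e6)
  expect_error(fisher_scores(x0, rep("A", 20)), "2 classes")
})

test_that("a planted feature outscores label-shuffled null scores", {
  set.seed(31)
  d <- make_gaussian_classes(40, 20, gap = 2, seed = 31)
  true_score <- fisher_scores(d$x, d$y)[1]
  null_scores <- vapply(1:100, function(i) {
    fisher_scores(d$x, sample(d$y))[1]
  }, numeric(1))
  expect_gt(true_score, quantile(null_scores, 0.95))
})

test_that("all three criteria find a planted informative feature first", {
  d <- make_gaussian_classes(250, 50, gap = 2, seed = 7)
  for (m in c("fisher", "mrmr", "cmim")) {
    expect_equal(select_features(d$x, d$y, k = 5, method = m)[1], 1,
                 info = m)
  }
})

test_that("mRMR penalizes redundant duplicates, Fisher does not", {
  d <- make_gaussian_classes(250, 30, gap = 2, seed = 13)
  x <- cbind(d$x[, 1], d$x[, 1] + rnorm(500, 0, 0.01), d$x[, -1])
  fisher_top2 <- select_features(x, d$y, k = 2, method = "fisher")
  expect_setequal(fisher_top2, c(1, 2))
  mrmr_top2 <- select_features(x, d$y, k = 2, method = "mrmr")
  expect_equal(sum(mrmr_top2 %in% c(1, 2)), 1)
})

test_that("selection clamps k and is the identity at full k", {
  d <- make_gaussian_classes(20, 5, gap = 1, seed = 3)
  expect_setequal(select_features(d$x, d$y, k = 5, method = "fisher"), 1:5)
  expect_warning(sel <- select_features(d$x, d$y, k = 10, method = "fisher"),
                 "clamp")
  expect_length(sel, 5)
})

test_that("WND predicts exact duplicates and separated Gaussians", {
  d <- make_gaussian_classes(50, 10, gap = 6, seed = 5)
  w <- fisher_scores(d$x, d$y)
  # a test row equal to a training row takes that row's class
  pred_dup <- wnd_classify(d$x, d$y, d$x[c(1, 51), , drop = FALSE], w)
  expect_equal(as.character(pred_dup), c("A", "B"))

  te <- make_gaussian_classes(50, 10, gap = 6, seed = 6)
  pred <- wnd_classify(d$x, d$y, te$x, w)
  expect_gt(mean(pred == te$y), 0.95)

  # zero-weight features cannot change predictions
  x_noise <- cbind(d$x, rnorm(100, 0, 100))
  w2 <- c(w, 0)
  pred2 <- wnd_classify(x_noise, d$y, cbind(te$x, rnorm(100, 0, 100)), w2)
  expect_equal(as.character(pred2), as.character(pred))

  expect_error(wnd_classify(d$x[d$y == "A", ], factor(rep("A", 50),
                                                      levels = c("A", "B")),
                            te$x, w),
               "empty class")
})

test_that("grouped splits keep participants whole, balanced and seeded", {
  set.seed(100)
  cohort <- data.frame(
    participant_id = rep(sprintf("P%03d", 1:80), each = 2),
    image_id = sprintf("I%03d", 1:160),
    age = rep(c(runif(40, 20, 37), runif(40, 65, 89)), each = 2)
  )
  plan <- grouped_twofold_cv(cohort, "20-37,65-89", n_splits = 10, seed = 1)
  expect_length(plan$splits, 10)
  for (sp in plan$splits) {
    tr_p <- unique(plan$participant[sp$train_ids])
    te_p <- unique(plan$participant[sp$test_ids])
    expect_length(intersect(tr_p, te_p), 0) # no leakage
    tr_lab <- table(plan$labels[sp$train_ids])
    expect_equal(unname(diff(range(tr_lab))), 0) # balanced training
  }
  plan2 <- grouped_twofold_cv(cohort, "20-37,65-89", n_splits = 10, seed = 1)
  expect_identical(plan$splits, plan2$splits)

  # unbalanced class sizes are downsampled to the smaller class
  cohort$age[1:60] <- 30 # 30 young participants vs 40+10 old
  plan3 <- grouped_twofold_cv(cohort, "20-37,65-89", n_splits = 2, seed = 2)
  tr_lab <- table(plan3$labels[plan3$splits[[1]]$train_ids])
  expect_equal(unname(diff(range(tr_lab))), 0)

  tiny <- cohort[1:2, ]
  expect_error(grouped_twofold_cv(tiny, "20-37,65-89", seed = 1),
               "fewer than 2 participants")
  expect_error(parse_class_ranges("20-37,old"), "malformed")
})

test_that("the ensemble is calibrated on label-null features and detects
           planted effects", {
  set.seed(50)
  n_part <- 80
  cohort <- data.frame(
    participant_id = sprintf("P%03d", 1:n_part),
    image_id = sprintf("I%03d", 1:n_part),
    age = runif(n_part, 20, 88)
  )
  p <- 20
  feat_null <- matrix(rnorm(n_part * p), n_part, p,
                      dimnames = list(cohort$image_id,
                                      paste0("f", seq_len(p))))
  res_null <- run_age_classification(feat_null, cohort, "20-50,51-89",
                                     n_splits = 10, seed = 9)
  acc <- tapply(res_null$cells$accuracy,
                res_null$cells$split, mean)
  se <- sd(acc) / sqrt(length(acc))
  expect_lte(abs(res_null$aggregate - 0.5), 3 * max(se, 0.02))

  # planted signal: feature 1 tracks age strongly
  feat_sig <- feat_null
  feat_sig[, 1] <- -cohort$age / 10 + rnorm(n_part, 0, 0.8)
  res_sig <- run_age_classification(feat_sig, cohort, "20-50,51-89",
                                    n_splits = 10, seed = 9)
  expect_gt(res_sig$aggregate, 0.65)
  expect_gt(res_sig$aggregate, res_null$aggregate)
})

test_that("accuracy rises monotonically with programmed effect size", {
  set.seed(60)
  n_part <- 60
  cohort <- data.frame(
    participant_id = sprintf("P%03d", 1:n_part),
    image_id = sprintf("I%03d", 1:n_part),
    age = runif(n_part, 20, 88)
  )
  agg_at <- function(slope) {
    mean(vapply(1:10, function(s) {
      set.seed(500 + s)
      feat <- matrix(rnorm(n_part * 10), n_part, 10,
                     dimnames = list(cohort$image_id, paste0("f", 1:10)))
      feat[, 1] <- slope * cohort$age + rnorm(n_part)
      run_age_classification(feat, cohort, "20-50,51-89",
                             n_splits = 4, seed = s)$aggregate
    }, numeric(1)))
  }
  a0 <- agg_at(0)
  a1 <- agg_at(0.05)
  a2 <- agg_at(0.2)
  expect_lte(a0, a1 + 0.05)
  expect_lte(a1, a2 + 0.05)
  expect_gt(a2, a0)
})

test_that("trait tables pivot to a 75-column per-image feature matrix", {
  g <- grow_vessel_tree(growth_config(seed = 2, p_bif = 0.005))
  tr <- extract_traits(g$map)$traits
  fm <- trait_feature_matrix(tr)
  expect_equal(ncol(fm), 75)
  expect_equal(nrow(fm), 1)
  expect_true(all(c("t1_Thick", "f3_Total", "j2_Thin") %in% colnames(fm)))
})
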