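# FDR adjustment, the age-association scan, subgroup summaries and the
# covariate-adjusted regression.

test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_fdr(rep(0.05, 10)), rep(0.05, 10))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(-0.1, 0.2)), "\\[0, 1\\]")
})

test_that("BH adjustment equals the brute-force step-up on random vectors", {
  set.seed(123)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), oracle_bh(p))
  }
})

test_that("the age scan recovers exact and null relationships", {
  set.seed(1)
  n <- 120
  d <- data.frame(age = runif(n, 20, 88))
  d$exact <- -d$age
  d$noise <- rnorm(n)
  res <- pearson_age_scan(d, traits = c("exact", "noise"))
  expect_equal(res$r[res$trait == "exact"], -1)
  expect_lt(res$p_adj[res$trait == "exact"], 1e-10)

  d$flat <- 5
  expect_warning(
    res2 <- pearson_age_scan(d, traits = c("exact", "flat")),
    "constant"
  )
  expect_true(is.na(res2$r[res2$trait == "flat"]))
})

test_that("null traits are rarely flagged across Monte-Carlo replicates", {
  set.seed(99)
  hits_r <- 0
  hits_p <- 0
  for (i in 1:100) {
    d <- data.frame(age = runif(500, 20, 88), x = rnorm(500))
    res <- pearson_age_scan(d, traits = "x")
    if (abs(res$r) < 0.1) hits_r <- hits_r + 1
    if (res$p_adj > 0.05) hits_p <- hits_p + 1
  }
  expect_gte(hits_r, 90)
  expect_gte(hits_p, 90)
})

test_that("a mixed panel flags only the affected traits", {
  # four age-coupled traits and two controls, mirroring the published
  # six-trait panel structure
  set.seed(77)
  successes <- 0
  for (rep in 1:20) {
    n <- 300
    age <- runif(n, 20, 88)
    d <- data.frame(
      age = age,
      a1 = -0.5 * age + rnorm(n, 0, 10),
      a2 = -0.3 * age + rnorm(n, 0, 8),
      a3 = 0.2 * age + rnorm(n, 0, 6),
      a4 = -0.1 * age + rnorm(n, 0, 3),
      c1 = rnorm(n), c2 = rnorm(n)
    )
    res <- pearson_age_scan(d, traits = c("a1", "a2", "a3", "a4",
                                          "c1", "c2"))
    flagged <- res$trait[res$p_adj < 0.05]
    if (setequal(flagged, c("a1", "a2", "a3", "a4"))) {
      successes <- successes + 1
    }
  }
  expect_gte(successes, 18)
})

test_that("j3 is excluded from scans unless asked for", {
  set.seed(5)
  d <- data.frame(age = runif(50, 20, 88), j2 = rnorm(50), j3 = rnorm(50))
  expect_false("j3" %in% pearson_age_scan(d)$trait)
  expect_true("j3" %in% pearson_age_scan(d, include_j3 = TRUE)$trait)
})

test_that("young/old summaries split at the median with shared bins", {
  set.seed(8)
  d <- data.frame(age = runif(100, 20, 88))
  d$tr <- 100 - d$age + rnorm(100, 0, 5) # declining trait
  s <- young_old_summary(d, "tr")
  expect_lte(abs(s$tr$n_young - s$tr$n_old), 1)
  expect_gt(s$tr$mean_young, s$tr$mean_old)
  expect_equal(sum(s$tr$counts_young), s$tr$n_young)
  expect_error(young_old_summary(d, "tr", cut = 10), "empty subgroup")
})

test_that("age-independent traits give balanced subgroup means", {
  set.seed(21)
  gaps <- vapply(1:50, function(i) {
    d <- data.frame(age = runif(200, 20, 88), tr = rnorm(200))
    s <- young_old_summary(d, "tr")
    se <- sqrt(1 / s$tr$n_young + 1 / s$tr$n_old)
    abs(s$tr$mean_young - s$tr$mean_old) / se
  }, numeric(1))
  expect_gte(mean(gaps < 2), 0.9)
})

test_that("the regression model recovers a pure age effect", {
  set.seed(2)
  n <- 400
  d <- data.frame(
    age = runif(n, 20, 88), sex = rbinom(n, 1, 0.5),
    sbp = rnorm(n, 120, 10), dbp = rnorm(n, 75, 8),
    waist = rnorm(n, 90, 8), hip = rnorm(n, 100, 7),
    weight = rnorm(n, 70, 9), height = rnorm(n, 168, 8),
    bmi = rnorm(n, 25, 3), imt = rnorm(n, 0.7, 0.1)
  )
  d$y <- 2 * d$age + rnorm(n, 0, 1e-6)
  res <- regress_trait(d, "y")
  expect_equal(res$beta[res$term == "A"], 2, tolerance = 1e-4)
  others <- res$beta[!res$term %in% c("A", "(Intercept)")]
  expect_true(all(abs(others) < 1e-4))

  # permutation of rows leaves estimates unchanged
  perm <- d[sample(n), ]
  expect_equal(regress_trait(perm, "y")$beta, res$beta, tolerance = 1e-10)
})

test_that("inert covariates stay non-significant across replicates", {
  set.seed(14)
  cov_names <- c("sbp", "dbp", "waist", "hip", "weight", "height", "bmi",
                 "imt")
  ok <- 0
  runs <- 0
  for (i in 1:20) {
    n <- 500
    age <- runif(n, 20, 88)
    d <- data.frame(age = age, sex = rbinom(n, 1, 0.5))
    # covariates correlated with age but causally inert given age
    for (v in cov_names) d[[v]] <- 0.3 * age + rnorm(n, 0, 10)
    d$y <- -0.5 * age + rnorm(n, 0, 5)
    res <- regress_trait(d, "y")
    pv <- res$p[res$term %in% cov_names]
    runs <- runs + length(pv)
    ok <- ok + sum(pv > 0.05)
    # the age effect survives covariate adjustment
    expect_lt(res$p[res$term == "A"], 0.05)
  }
  expect_gte(ok / runs, 0.9)
})

test_that("rank-deficient designs fail naming the collinear columns", {
  set.seed(4)
  n <- 60
  d <- data.frame(
    age = runif(n, 20, 88), sex = rbinom(n, 1, 0.5),
    sbp = rnorm(n), dbp = rnorm(n)
  )
  d$waist <- d$sbp # exact duplicate
  d$y <- rnorm(n)
  expect_error(regress_trait(d, "y", covariates = c("sbp", "dbp", "waist")),
               "waist")
})

test_that("participant tables keep one (first) image per participant", {
  traits <- data.frame(
    image_id = c("P1_I1", "P1_I2", "P2_I1"),
    class = "Thick", j2 = c(10, 20, 30)
  )
  cohort <- data.frame(
    participant_id = c("P1", "P1", "P2"),
    image_id = c("P1_I1", "P1_I2", "P2_I1"),
    age = c(40, 40, 60), sex = c(0, 0, 1)
  )
  d <- participant_table(traits, cohort, class = "Thick")
  expect_equal(nrow(d), 2)
  expect_equal(d$j2, c(10, 30)) # first image wins
})
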