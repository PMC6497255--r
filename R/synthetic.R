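# Synthetic vascular trees and aging cohorts. The growth model is a
# discrete branching random walk: unit steps, Gaussian heading noise (tau,
# rad/step) controlling tortuosity, per-step bifurcation probability p_bif,
# and a Murray-type cubed-sum width rule at forks. Rendered maps come with
# ground-truth topology so pipeline measurements can be checked against
# known truth.

#' Growth configuration for a synthetic vascular tree
#'
#' Defaults reflect a plausible retinal vessel map at the pipeline's working
#' resolution: a handful of major vessels entering at the image border with
#' root caliber around 7 px, gentle heading noise, and symmetric Murray
#' branching (parent and child widths related by `w_p^3 = w_c1^3 + w_c2^3`).
#'
#' @param width,height Image size in px (default 565 x 584).
#' @param p_bif Per-step bifurcation probability, in \[0, 0.05\].
#' @param tau Heading-noise standard deviation (rad/step); larger values
#'   give more tortuous vessels.
#' @param w0 Root caliber in px (>= 2).
#' @param width_decay Murray exponent m in `w_child = w_parent * 2^(-1/m)`;
#'   3 is the classic cubed-sum rule, any monotone decay is acceptable.
#' @param max_steps Maximum steps from root (tree depth).
#' @param n_roots Number of border roots.
#' @param seed Mandatory integer seed.
#' @return A `growth_config` list.
#' @export
growth_config <- function(width = 565, height = 584, p_bif = 0.012,
                          tau = 0.035, w0 = 7, width_decay = 3,
                          max_steps = 420, n_roots = 5, seed) {
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is mandatory for reproducible growth")
  }
  stopifnot(p_bif >= 0, p_bif <= 0.05, tau >= 0, w0 >= 2,
            width >= 1, height >= 1)
  if (width * height == 0) stop("degenerate config: zero-area image")
  structure(
    list(
      width = as.integer(width), height = as.integer(height),
      p_bif = p_bif, tau = tau, w0 = w0, width_decay = width_decay,
      max_steps = as.integer(max_steps), n_roots = as.integer(n_roots),
      seed = as.integer(seed)
    ),
    class = "growth_config"
  )
}

#' Grow one synthetic vessel tree
#'
#' @param config A [growth_config()].
#' @param image_id Identifier for the rendered map.
#' @return List with `map` (a [vessel_map()]) and `ground_truth`: true
#'   bifurcation count, true endpoint count (terminated tips plus root
#'   origins), and a per-branch table of true width, arc and chord length.
#' @export
grow_vessel_tree <- function(config, image_id = "synthetic") {
  stopifnot(inherits(config, "growth_config"))
  set.seed(config$seed)
  res <- .cpp_grow_tree(
    config$height, config$width, config$n_roots, config$w0, config$p_bif,
    config$tau, config$max_steps, 1.0,
    20 * pi / 180, 40 * pi / 180, config$width_decay, 1024L
  )
  gt <- list(
    n_bifurcations = res$n_bifurcations,
    n_endpoints = res$n_endpoints + config$n_roots,
    branches = data.frame(
      width = res$branch_width, arc = res$branch_arc,
      chord = res$branch_chord, depth = res$branch_depth
    )
  )
  gt$branches$arc_chord <- with(gt$branches,
                                ifelse(chord > 0, arc / chord, NA_real_))
  list(map = vessel_map(res$mask, image_id = image_id), ground_truth = gt)
}

#' Cohort configuration for the aging simulator
#'
#' Participant age is uniform on `age_range`; the generative bifurcation
#' probability declines linearly with age so that the measured bifurcation
#' count (j2, Total microvasculature) averages about 74 at age 20 and about
#' 31 at age 88, matching the observed decline in the source cohort's age
#' range. Heading noise tau carries no age effect by default, so
#' curvature-per-length tortuosity traits are programmed-null. Participants
#' carry a random effect on the generative parameters so that multi-image
#' participants have correlated traits.
#'
#' @param n Number of participants (>= 4).
#' @param age_range Age range in years, default 20.3--88.4.
#' @param sex_ratio Probability of sex = 1.
#' @param p_bif_age Intercept and slope (per year) of the bifurcation
#'   probability; the defaults are calibrated to the j2 = 74 -> 31 decline.
#' @param tau_age Intercept and slope of heading noise; zero slope by
#'   default.
#' @param p_bif_sd Participant-level standard deviation of p_bif.
#' @param tau_sd Participant-level standard deviation of tau.
#' @param images_per_participant Images per participant (default 1).
#' @param seed Mandatory integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n = 200, age_range = c(20.3, 88.4),
                          sex_ratio = 0.5,
                          p_bif_age = c(intercept = 0.007675,
                                        slope = -4.375e-05),
                          tau_age = c(intercept = 0.035, slope = 0),
                          p_bif_sd = 0.0008, tau_sd = 0.002,
                          images_per_participant = 1, seed) {
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is mandatory for reproducible cohorts")
  }
  if (n < 4) stop("need at least 4 participants for downstream statistics")
  structure(
    list(
      n = as.integer(n), age_range = age_range, sex_ratio = sex_ratio,
      p_bif_age = p_bif_age, tau_age = tau_age,
      p_bif_sd = p_bif_sd, tau_sd = tau_sd,
      images_per_participant = as.integer(images_per_participant),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# Age-correlated cardiovascular/anthropometric covariates with plausible
# population means; used to exercise the regression model, not to model
# physiology.
.simulate_covariates <- function(age, sex) {
  n <- length(age)
  height <- 168 - 0.10 * (age - 50) - 10 * (sex == 0) + rnorm(n, 0, 6)
  weight <- 72 + 0.05 * (age - 50) - 8 * (sex == 0) + rnorm(n, 0, 10)
  bmi <- weight / (height / 100)^2
  data.frame(
    sbp = 110 + 0.55 * (age - 20) + rnorm(n, 0, 12),
    dbp = 70 + 0.12 * (age - 20) + rnorm(n, 0, 8),
    waist = 0.55 * weight + 55 + rnorm(n, 0, 6),
    hip = 0.45 * weight + 68 + rnorm(n, 0, 5),
    weight = weight, height = height, bmi = bmi,
    imt = 0.50 + 0.0085 * (age - 20) + rnorm(n, 0, 0.08)
  )
}

#' Simulate an aging cohort of synthetic vessel maps
#'
#' Per participant: age ~ Uniform(range), sex ~ Bernoulli, generative
#' parameters linear in age plus participant noise, one or more vessel maps
#' grown per image, age-correlated covariates, and ground truth retained.
#' Trait measurement runs the package's own extraction pipeline.
#'
#' @param config A [cohort_config()].
#' @param measure One of "total" (measure traits on the Total
#'   microvasculature only; fast), "full" (all three caliber classes with a
#'   cohort-pooled uber-mean) or "none".
#' @param smoothed Compute smoothed tortuosity variants (default TRUE for
#'   "full", FALSE for "total").
#' @param keep_images Return the grown [vessel_map()] objects (memory-heavy
#'   for large cohorts).
#' @param write_dir Optional directory: write each mask as PNG plus a
#'   ground-truth JSON.
#' @param families Trait families to measure; omitted families stay `NA`.
#' @return List with `cohort` (one row per image: participant_id, image_id,
#'   age, sex, covariates, ground-truth counts, and measured traits with a
#'   `class` column), `ground_truth`, `um`, and optionally `images`.
#' @export
simulate_cohort <- function(config, measure = c("total", "full", "none"),
                            smoothed = NULL, keep_images = FALSE,
                            write_dir = NULL,
                            families = c("tortuosity", "fractal",
                                         "junction")) {
  stopifnot(inherits(config, "cohort_config"))
  measure <- match.arg(measure)
  if (is.null(smoothed)) smoothed <- (measure == "full")
  set.seed(config$seed)
  n <- config$n
  age <- runif(n, config$age_range[1], config$age_range[2])
  sex <- rbinom(n, 1, config$sex_ratio)
  p_bif <- config$p_bif_age[[1]] + config$p_bif_age[[2]] * age +
    rnorm(n, 0, config$p_bif_sd)
  p_bif <- pmin(pmax(p_bif, 0.0005), 0.05)
  tau <- config$tau_age[[1]] + config$tau_age[[2]] * age +
    rnorm(n, 0, config$tau_sd)
  tau <- pmax(tau, 0)
  cov <- .simulate_covariates(age, sex)
  # per-image seeds drawn once so each image is independently reproducible
  nimg <- config$images_per_participant
  img_seed <- matrix(sample.int(.Machine$integer.max, n * nimg), n, nimg)

  rows <- list()
  gts <- list()
  images <- list()
  trait_rows <- list()
  for (i in seq_len(n)) {
    for (k in seq_len(nimg)) {
      iid <- sprintf("P%04d_I%d", i, k)
      gc <- growth_config(
        p_bif = p_bif[i], tau = tau[i], seed = img_seed[i, k]
      )
      tree <- grow_vessel_tree(gc, image_id = iid)
      gts[[iid]] <- tree$ground_truth
      if (keep_images || measure == "full") images[[iid]] <- tree$map
      if (measure == "total") {
        trait_rows[[iid]] <- extract_traits(tree$map, classes = "Total",
                                            smoothed = smoothed,
                                            families = families)$traits
      }
      if (!is.null(write_dir)) {
        dir.create(write_dir, showWarnings = FALSE, recursive = TRUE)
        write_vessel_map(tree$map, file.path(write_dir,
                                             paste0(iid, ".png")))
        jsonlite::write_json(
          list(
            n_bifurcations = tree$ground_truth$n_bifurcations,
            n_endpoints = tree$ground_truth$n_endpoints
          ),
          file.path(write_dir, paste0(iid, ".json")),
          auto_unbox = TRUE
        )
      }
      rows[[iid]] <- data.frame(
        participant_id = sprintf("P%04d", i), image_id = iid,
        age = age[i], sex = sex[i], cov[i, , drop = FALSE],
        true_bifurcations = tree$ground_truth$n_bifurcations,
        true_endpoints = tree$ground_truth$n_endpoints,
        stringsAsFactors = FALSE, row.names = NULL
      )
    }
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL

  um <- NA_real_
  traits <- NULL
  if (measure == "total") {
    traits <- do.call(rbind, trait_rows)
    rownames(traits) <- NULL
  } else if (measure == "full") {
    # two passes: pool branch calibers for the run-level uber-mean, then
    # split and measure each image against it
    pooled <- unlist(lapply(images, function(m) {
      sk <- skeletonize(m)
      cal <- estimate_caliber(m, sk)
      branch_calibers(cal, extract_branches(sk))
    }))
    um <- compute_uber_mean(pooled)
    traits <- do.call(rbind, lapply(images, function(m) {
      extract_traits(m, um = um, smoothed = smoothed,
                     families = families)$traits
    }))
    rownames(traits) <- NULL
  }
  if (!is.null(traits)) {
    cohort <- merge(cohort, traits, by = "image_id", sort = FALSE)
  }
  out <- list(cohort = cohort, ground_truth = gts, um = um,
              config = config)
  if (keep_images) out$images <- images
  out
}
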