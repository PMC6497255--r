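# Age-association scan, Benjamini-Hochberg FDR, young/old subgroup
# summaries, and the covariate-adjusted regression model
# y = A + A^2 + A*S + S + x1 + ... + x8.

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Step-up procedure: sort ascending, `q_i = min_{j >= i} p_j * n / j`,
#' capped at 1, restored to the original order. The FDR family is whatever
#' vector is passed in one call.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\] (`NA` allowed and
#'   passed through).
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) stop("p-values must be numeric")
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' One analysis row per participant
#'
#' Joins a trait table (one row per image and class) to a cohort table and
#' keeps a single image per participant -- the first by image id -- for the
#' given caliber class, since association and regression analyses use one
#' image per participant.
#'
#' @param traits Trait table with `image_id`, `class` and trait columns.
#' @param cohort Cohort table with `participant_id`, `image_id`, `age`,
#'   `sex` and covariates.
#' @param class Caliber class to analyze (default "Thick").
#' @return Data frame, one row per participant.
#' @export
participant_table <- function(traits, cohort, class = "Thick") {
  tr <- traits[traits$class == class, , drop = FALSE]
  meta_cols <- setdiff(names(cohort), names(tr))
  d <- merge(cohort[, c("image_id", meta_cols), drop = FALSE], tr,
             by = "image_id", sort = FALSE)
  d <- d[order(d$participant_id, d$image_id), , drop = FALSE]
  d <- d[!duplicated(d$participant_id), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Pearson age-association scan with FDR adjustment
#'
#' Pearson correlation of each trait with age (pairwise complete
#' observations), two-sided p-values, and Benjamini-Hochberg adjustment
#' across the scanned trait set. Trait j3 is excluded by default: apparent
#' vessel crossings are projections of distinct vessels, not true
#' junctions, and carry no age information.
#'
#' @param data Data frame with an age column and trait columns.
#' @param traits Character vector of trait columns to scan; defaults to all
#'   canonical trait names present in `data`.
#' @param age_col Name of the age column.
#' @param include_j3 Scan j3 as well (default FALSE).
#' @return Data frame: trait, n, r, p, p_adj. Constant traits give `NA`
#'   with a warning.
#' @export
pearson_age_scan <- function(data, traits = NULL, age_col = "age",
                             include_j3 = FALSE) {
  if (is.null(traits)) traits <- intersect(trait_names(), names(data))
  if (!include_j3) traits <- setdiff(traits, "j3")
  if (!length(traits)) stop("no trait columns to scan")
  age <- data[[age_col]]
  res <- lapply(traits, function(tr) {
    v <- data[[tr]]
    ok <- is.finite(v) & is.finite(age)
    if (sum(ok) < 4) {
      warning("trait ", tr, ": fewer than 4 complete observations")
      return(data.frame(trait = tr, n = sum(ok), r = NA_real_,
                        p = NA_real_))
    }
    if (sd(v[ok]) == 0) {
      warning("trait ", tr, " is constant; correlation undefined")
      return(data.frame(trait = tr, n = sum(ok), r = NA_real_,
                        p = NA_real_))
    }
    ct <- cor.test(v[ok], age[ok], method = "pearson")
    data.frame(trait = tr, n = sum(ok), r = unname(ct$estimate),
               p = ct$p.value)
  })
  out <- do.call(rbind, res)
  out$p_adj <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}

#' Young/old subgroup summaries
#'
#' Splits the cohort at a cutoff age (default: the cohort median, the
#' convention used for subgroup histograms) and summarizes each trait in
#' both subgroups with shared histogram bin edges.
#'
#' @param data Data frame with age and trait columns.
#' @param traits Trait columns to summarize.
#' @param cut Cutoff age; `NULL` means the cohort median.
#' @param bins Number of histogram bins.
#' @param age_col Name of the age column.
#' @return List per trait: `n_young`, `n_old`, `mean_young`, `mean_old`,
#'   `breaks`, `counts_young`, `counts_old`; plus attribute `cut`.
#' @export
young_old_summary <- function(data, traits = NULL, cut = NULL, bins = 20,
                              age_col = "age") {
  if (is.null(traits)) traits <- intersect(trait_names(), names(data))
  age <- data[[age_col]]
  if (is.null(cut)) cut <- median(age, na.rm = TRUE)
  young <- age < cut
  old <- age >= cut
  if (!any(young) || !any(old)) {
    stop("empty subgroup at cutoff age ", cut)
  }
  out <- lapply(traits, function(tr) {
    v <- data[[tr]]
    vy <- v[young & is.finite(v)]
    vo <- v[old & is.finite(v)]
    rng <- range(c(vy, vo), finite = TRUE)
    if (!all(is.finite(rng))) rng <- c(0, 1)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = bins + 1)
    list(
      n_young = length(vy), n_old = length(vo),
      mean_young = mean(vy), mean_old = mean(vo),
      breaks = breaks,
      counts_young = hist(vy, breaks = breaks, plot = FALSE)$counts,
      counts_old = hist(vo, breaks = breaks, plot = FALSE)$counts
    )
  })
  names(out) <- traits
  attr(out, "cut") <- cut
  out
}

#' Covariate-adjusted regression for one trait
#'
#' Ordinary least squares of a microvascular trait on
#' `A + A^2 + A:S + S + x1 + ... + x8` (intercept included), where A is
#' age, S is sex coded 0/1 and the x's are cardiovascular/anthropometric
#' covariates. This tests trait-covariate association while adjusting for
#' the change in microvasculature due to age, and the age effect while
#' adjusting for the covariates.
#'
#' @param data Data frame with the trait, age, sex and covariate columns.
#' @param trait Trait column name.
#' @param covariates Covariate column names (default the eight standard
#'   ones).
#' @param age_col,sex_col Column names for age and sex.
#' @return Data frame: term, beta, se, p. Errors on rank-deficient designs,
#'   naming the collinear columns.
#' @export
regress_trait <- function(data, trait,
                          covariates = c("sbp", "dbp", "waist", "hip",
                                         "weight", "height", "bmi", "imt"),
                          age_col = "age", sex_col = "sex") {
  covariates <- intersect(covariates, names(data))
  cols <- c(trait, age_col, sex_col, covariates)
  d <- data[, cols, drop = FALSE]
  d <- d[complete.cases(d) & is.finite(d[[trait]]), , drop = FALSE]
  k <- 4 + length(covariates)
  if (nrow(d) < k + 2) {
    stop("too few complete cases (", nrow(d), ") for ", k + 1,
         " model terms")
  }
  A <- d[[age_col]]
  S <- d[[sex_col]]
  X <- cbind(A = A, A2 = A^2, S = S, `A:S` = A * S)
  if (length(covariates)) {
    X <- cbind(X, as.matrix(d[, covariates, drop = FALSE]))
  }
  mm <- cbind(`(Intercept)` = 1, X)
  qx <- qr(mm)
  if (qx$rank < ncol(mm)) {
    bad <- colnames(mm)[qx$pivot[(qx$rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  df <- data.frame(y = d[[trait]], X, check.names = FALSE)
  fit <- lm(y ~ ., data = df)
  sm <- summary(fit)$coefficients
  data.frame(
    term = rownames(sm), beta = sm[, 1], se = sm[, 2], p = sm[, 4],
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Regression scan across traits with per-term FDR
#'
#' Runs [regress_trait()] for each trait and adjusts p-values across traits
#' separately for each model term (the family is the trait panel, per
#' term).
#'
#' @inheritParams regress_trait
#' @param traits Trait columns to scan.
#' @return Data frame: trait, term, beta, se, p, p_adj.
#' @export
regress_scan <- function(data, traits, ...) {
  res <- do.call(rbind, lapply(traits, function(tr) {
    out <- regress_trait(data, tr, ...)
    out$trait <- tr
    out
  }))
  res$p_adj <- NA_real_
  for (term in unique(res$term)) {
    sel <- res$term == term
    res$p_adj[sel] <- bh_fdr(res$p[sel])
  }
  res[, c("trait", "term", "beta", "se", "p", "p_adj")]
}
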