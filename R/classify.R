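# Age-cohort classification: Fisher / mRMR / CMIM feature selection, the
# weighted-neighbor-distance (WND) classifier, a linear SVM, and
# participant-grouped twofold cross-validation with 10 randomized splits.

#' Fisher discriminant scores
#'
#' Per feature: variance of the class means around their grand mean,
#' divided by the mean within-class variance. Features with zero
#' within-class variance but separated means get a large finite cap.
#'
#' @param x Numeric matrix, samples in rows (z-normalize on training data
#'   before scoring).
#' @param y Class labels (>= 2 classes, each with >= 2 samples).
#' @param cap Score assigned when the within-class variance is zero but the
#'   class means differ.
#' @return Numeric vector of scores, one per feature.
#' @export
fisher_scores <- function(x, y, cap = 1e6) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2) stop("Fisher scores need at least 2 classes")
  if (any(table(y) < 2)) stop("every class needs at least 2 samples")
  mu <- apply(x, 2, function(v) tapply(v, y, mean))
  s2 <- apply(x, 2, function(v) tapply(v, y, var))
  between <- colMeans(sweep(mu, 2, colMeans(mu))^2)
  within <- colMeans(s2)
  score <- ifelse(within > 0, between / within,
                  ifelse(between > 0, cap, 0))
  pmin(unname(score), cap)
}

# ---- mutual-information machinery (10 equal-frequency bins) ---------------

.discretize <- function(v, breaks = NULL, nbins = 10) {
  if (is.null(breaks)) {
    breaks <- unique(quantile(v, probs = seq(0, 1, length.out = nbins + 1),
                              na.rm = TRUE, names = FALSE))
  }
  if (length(breaks) < 2) return(list(code = rep(1L, length(v)),
                                      breaks = breaks))
  code <- findInterval(v, breaks[-c(1, length(breaks))]) + 1L
  list(code = as.integer(code), breaks = breaks)
}

.mi <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  if (n == 0) return(0)
  p <- tab / n
  pa <- rowSums(p)
  pb <- colSums(p)
  sel <- p > 0
  sum(p[sel] * log(p[sel] / outer(pa, pb)[sel]))
}

.cmi <- function(a, b, z) {
  tot <- 0
  n <- length(z)
  for (lev in unique(z)) {
    sel <- z == lev
    tot <- tot + sum(sel) / n * .mi(a[sel], b[sel])
  }
  tot
}

#' Select features by Fisher score, mRMR or CMIM
#'
#' Fisher: top-k by score. mRMR: greedy maximization of relevance minus
#' mean redundancy, with mutual information estimated on 10
#' equal-frequency bins. CMIM: greedy maximization of the minimum
#' conditional mutual information with the label given each already
#' selected feature.
#'
#' @param x Numeric matrix (training samples x features).
#' @param y Class labels.
#' @param k Number of features to select; clamped with a warning if larger
#'   than the feature count.
#' @param method One of "fisher", "mrmr", "cmim".
#' @return Integer vector of selected column indices, in selection order.
#' @export
select_features <- function(x, y, k, method = c("fisher", "mrmr", "cmim")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  p <- ncol(x)
  if (k > p) {
    warning("k = ", k, " exceeds the ", p, " available features; clamping")
    k <- p
  }
  if (method == "fisher") {
    return(order(fisher_scores(x, y), decreasing = TRUE)[seq_len(k)])
  }
  yd <- as.integer(factor(y))
  xd <- lapply(seq_len(p), function(j) .discretize(x[, j])$code)
  rel <- vapply(xd, function(a) .mi(a, yd), numeric(1))
  sel <- integer(0)
  if (method == "mrmr") {
    red_cache <- matrix(NA_real_, p, p)
    red_sum <- numeric(p)
    for (step in seq_len(k)) {
      if (step == 1) {
        score <- rel
      } else {
        j_new <- sel[length(sel)]
        for (j in seq_len(p)) {
          if (j %in% sel) next
          if (is.na(red_cache[j, j_new])) {
            red_cache[j, j_new] <- .mi(xd[[j]], xd[[j_new]])
          }
          red_sum[j] <- red_sum[j] + red_cache[j, j_new]
        }
        score <- rel - red_sum / length(sel)
      }
      score[sel] <- -Inf
      sel <- c(sel, which.max(score))
    }
  } else { # cmim
    part_min <- rel
    for (step in seq_len(k)) {
      score <- part_min
      score[sel] <- -Inf
      j_star <- which.max(score)
      sel <- c(sel, j_star)
      if (step < k) {
        for (j in seq_len(p)) {
          if (j %in% sel) next
          part_min[j] <- min(part_min[j],
                             .cmi(xd[[j]], yd, xd[[j_star]]))
        }
      }
    }
  }
  sel
}

#' Weighted-neighbor-distance (WND) classification
#'
#' Distance from a test sample to a training sample is the Fisher-weighted
#' squared Euclidean distance; the similarity of a test sample to a class
#' is the mean of `d^-5` over that class's training samples, and the
#' predicted class is the most similar one. A test sample identical to a
#' training sample takes that sample's class.
#'
#' @param train_x,train_y Training matrix (z-normalized) and labels.
#' @param test_x Test matrix, normalized with the training statistics.
#' @param weights Per-feature weights; typically training Fisher scores.
#' @param power Distance exponent (default 5, the usual WND setting).
#' @return Factor of predicted classes.
#' @export
wnd_classify <- function(train_x, train_y, test_x, weights, power = 5) {
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  y <- if (is.factor(train_y)) train_y else factor(train_y)
  if (any(table(y) == 0)) stop("empty class in training data")
  w <- as.numeric(weights)
  # weighted squared distances via the expansion of (x - t)^2
  tx2 <- as.numeric(train_x^2 %*% w)
  sx2 <- as.numeric(test_x^2 %*% w)
  cross <- tcrossprod(sweep(test_x, 2, sqrt(w), `*`),
                      sweep(train_x, 2, sqrt(w), `*`))
  D <- outer(sx2, tx2, `+`) - 2 * cross
  D[D < 0] <- 0
  lev <- levels(y)
  pred <- character(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    di <- D[i, ]
    if (any(di == 0)) {
      pred[i] <- as.character(y[which(di == 0)[1]])
      next
    }
    rel <- (di / min(di))^(-power) # row-scaled to avoid overflow
    sim <- tapply(rel, y, mean)
    pred[i] <- lev[which.max(sim)]
  }
  factor(pred, levels = lev)
}

#' Participant-grouped twofold cross-validation plan
#'
#' Randomizes participants (never single images) of each age class into
#' train and test halves, so that all images of one participant land on the
#' same side of every split; per-class training image counts are balanced
#' by downsampling the larger class. Ten independent randomized splits by
#' default.
#'
#' @param cohort Data frame with `participant_id`, `image_id`, `age`.
#' @param class_ranges List of `c(lo, hi)` age ranges (inclusive), or a
#'   spec string like `"20-37,65-89"`.
#' @param n_splits Number of randomized splits (default 10).
#' @param seed Integer seed.
#' @return List of class `split_plan`: `splits` (each with `train_ids`,
#'   `test_ids` image-id vectors), `labels` (named class per image),
#'   `class_ranges`.
#' @export
grouped_twofold_cv <- function(cohort, class_ranges, n_splits = 10, seed) {
  if (missing(seed)) stop("`seed` is required for a reproducible plan")
  ranges <- parse_class_ranges(class_ranges)
  lab <- rep(NA_character_, nrow(cohort))
  for (k in seq_along(ranges)) {
    sel <- cohort$age >= ranges[[k]][1] & cohort$age <= ranges[[k]][2]
    lab[sel] <- names(ranges)[k]
  }
  keep <- !is.na(lab)
  co <- cohort[keep, , drop = FALSE]
  lab <- lab[keep]
  labels <- setNames(lab, co$image_id)
  cls_of_part <- tapply(lab, co$participant_id, function(v) v[1])
  for (k in names(ranges)) {
    if (sum(cls_of_part == k) < 2) {
      stop("age class ", k, " has fewer than 2 participants")
    }
  }
  set.seed(seed)
  splits <- lapply(seq_len(n_splits), function(s) {
    train_ids <- character(0)
    test_ids <- character(0)
    for (k in names(ranges)) {
      parts <- names(cls_of_part)[cls_of_part == k]
      parts <- sample(parts)
      ntr <- floor(length(parts) / 2)
      tr_part <- parts[seq_len(ntr)]
      te_part <- parts[-seq_len(ntr)]
      train_ids <- c(train_ids,
                     co$image_id[co$participant_id %in% tr_part])
      test_ids <- c(test_ids,
                    co$image_id[co$participant_id %in% te_part])
    }
    # balance per-class training image counts by downsampling
    tr_lab <- labels[train_ids]
    n_min <- min(table(factor(tr_lab, levels = names(ranges))))
    bal <- unlist(lapply(names(ranges), function(k) {
      ids <- train_ids[tr_lab == k]
      if (length(ids) > n_min) sample(ids, n_min) else ids
    }), use.names = FALSE)
    list(train_ids = bal, test_ids = test_ids)
  })
  structure(
    list(splits = splits, labels = labels, class_ranges = ranges,
         participant = setNames(co$participant_id, co$image_id)),
    class = "split_plan"
  )
}

#' Parse an age-class range specification
#'
#' @param spec Either a list of `c(lo, hi)` pairs or a string such as
#'   `"20-37,65-89"`.
#' @return Named list of numeric `c(lo, hi)` ranges.
#' @export
parse_class_ranges <- function(spec) {
  if (is.character(spec) && length(spec) == 1) {
    toks <- strsplit(spec, ",", fixed = TRUE)[[1]]
    spec <- lapply(toks, function(tok) {
      m <- regmatches(tok, regexec("^\\s*([0-9.]+)\\s*-\\s*([0-9.]+)\\s*$",
                                   tok))[[1]]
      if (length(m) != 3) stop("malformed age-range token: '", tok, "'")
      as.numeric(m[2:3])
    })
  }
  stopifnot(is.list(spec), length(spec) >= 2)
  for (r in spec) {
    if (length(r) != 2 || !is.numeric(r) || r[1] > r[2]) {
      stop("each age class must be a numeric c(lo, hi) range")
    }
  }
  setNames(spec, vapply(spec, function(r) paste0(r[1], "-", r[2]), ""))
}

# z-normalization by training statistics; constant features are dropped.
.znorm <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, sd)
  keep <- which(sdv > 0)
  list(
    train = sweep(sweep(train[, keep, drop = FALSE], 2, mu[keep]), 2,
                  sdv[keep], `/`),
    test = sweep(sweep(test[, keep, drop = FALSE], 2, mu[keep]), 2,
                 sdv[keep], `/`),
    keep = keep
  )
}

# per-class accuracy cells for one prediction vector
.accuracy_cells <- function(pred, truth, classifier, split) {
  do.call(rbind, lapply(levels(factor(truth)), function(k) {
    sel <- truth == k
    data.frame(
      classifier = classifier, split = split, class = k,
      n_test = sum(sel),
      accuracy = mean(pred[sel] == k),
      stringsAsFactors = FALSE
    )
  }))
}

#' Run the three-classifier age-cohort classification
#'
#' For each of the grouped twofold splits: select features on the training
#' half only, fit WND (Fisher top-75), SVM on the mRMR top-30 and SVM on
#' the CMIM top-30 (linear kernel, C = 1, on z-normalized features), and
#' score the held-out half. The aggregate accuracy is the arithmetic mean
#' of the per-(classifier, split, class) accuracy cells. Train/test
#' participant disjointness is asserted on every split.
#'
#' @param traits Trait table (`image_id`, `class`, trait columns) or a
#'   ready feature matrix with image ids as row names.
#' @param cohort Cohort table (`participant_id`, `image_id`, `age`).
#' @param class_ranges Age classes (see [parse_class_ranges()]).
#' @param n_splits Number of randomized splits (default 10).
#' @param seed Integer seed.
#' @param k_wnd,k_svm Feature-count caps for WND (75) and the SVMs (30).
#' @return Object of class `age_classification`: `cells` (per classifier,
#'   split and class accuracies), `aggregate`, `plan`, `features_used`.
#' @export
run_age_classification <- function(traits, cohort, class_ranges,
                                   n_splits = 10, seed, k_wnd = 75,
                                   k_svm = 30) {
  if (missing(seed)) stop("`seed` is required")
  feat <- if (is.matrix(traits)) traits else trait_feature_matrix(traits)
  cohort <- cohort[!duplicated(cohort$image_id), , drop = FALSE]
  plan <- grouped_twofold_cv(cohort, class_ranges, n_splits, seed)
  ids <- intersect(names(plan$labels), rownames(feat))
  feat <- feat[ids, , drop = FALSE]
  # complete features only: a column with any missing value is unusable
  feat <- feat[, colSums(!is.finite(feat)) == 0, drop = FALSE]
  if (ncol(feat) < 2) stop("fewer than 2 complete features available")
  cells <- list()
  for (s in seq_along(plan$splits)) {
    sp <- plan$splits[[s]]
    tr_ids <- intersect(sp$train_ids, ids)
    te_ids <- intersect(sp$test_ids, ids)
    # leakage guard: no participant on both sides
    stopifnot(length(intersect(plan$participant[tr_ids],
                               plan$participant[te_ids])) == 0)
    ytr <- factor(plan$labels[tr_ids])
    yte <- factor(plan$labels[te_ids], levels = levels(ytr))
    z <- .znorm(feat[tr_ids, , drop = FALSE], feat[te_ids, , drop = FALSE])
    # WND on the Fisher top-k
    fs <- fisher_scores(z$train, ytr)
    top <- order(fs, decreasing = TRUE)[seq_len(min(k_wnd, ncol(z$train)))]
    pred_wnd <- wnd_classify(z$train[, top, drop = FALSE], ytr,
                             z$test[, top, drop = FALSE], fs[top])
    cells[[length(cells) + 1]] <-
      .accuracy_cells(pred_wnd, yte, "WND", s)
    for (m in c("mrmr", "cmim")) {
      selk <- select_features(z$train, ytr, min(k_svm, ncol(z$train)), m)
      fit <- e1071::svm(z$train[, selk, drop = FALSE], ytr,
                        kernel = "linear", cost = 1, scale = FALSE)
      pred <- predict(fit, z$test[, selk, drop = FALSE])
      cells[[length(cells) + 1]] <-
        .accuracy_cells(pred, yte, paste0("SVM-", toupper(m)), s)
    }
  }
  cells <- do.call(rbind, cells)
  structure(
    list(
      cells = cells, aggregate = mean(cells$accuracy), plan = plan,
      features_used = colnames(feat)
    ),
    class = "age_classification"
  )
}

#' @export
print.age_classification <- function(x, ...) {
  cat("<age_classification>\n")
  cat("  classes:", paste(names(x$plan$class_ranges), collapse = " vs "),
      "\n")
  cat("  splits:", length(x$plan$splits), " features:",
      length(x$features_used), "\n")
  agg <- tapply(x$cells$accuracy, x$cells$classifier, mean)
  for (k in names(agg)) cat(sprintf("  %-10s %.3f\n", k, agg[k]))
  cat(sprintf("  aggregate  %.3f\n", x$aggregate))
  invisible(x)
}

#' Wide per-image feature matrix from a trait table
#'
#' Pivots the long trait table (one row per image and caliber class) into
#' an image x feature matrix with columns like `t1_Thick`, giving the 75
#' microvascular features per image when all three classes are present.
#'
#' @param traits Trait table with `image_id`, `class` and trait columns.
#' @return Numeric matrix with image ids as row names.
#' @export
trait_feature_matrix <- function(traits) {
  tn <- intersect(trait_names(), names(traits))
  ids <- unique(traits$image_id)
  cls <- unique(traits$class)
  out <- matrix(NA_real_, length(ids), length(tn) * length(cls),
                dimnames = list(ids, paste(rep(tn, length(cls)),
                                           rep(cls, each = length(tn)),
                                           sep = "_")))
  for (k in cls) {
    sub <- traits[traits$class == k, , drop = FALSE]
    out[sub$image_id, paste(tn, k, sep = "_")] <-
      as.matrix(sub[, tn, drop = FALSE])
  }
  out
}
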