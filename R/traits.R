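# The 25 microvascular traits: tortuosity t1..t15 (seven arc/chord and
# integral-curvature measures, each on the sampled and on a smoothed contour,
# plus the smoothed/sampled arc-length ratio), box-counting fractal ratios
# f2..f8, and junction counts j1..j3.

#' Tortuosity basis quantities for one branch
#'
#' Computes arc length, chord length and signed curvature along an ordered
#' point sequence. Curvature uses central finite differences of the
#' arc-length-parametrized coordinates,
#' `kappa = (x'y'' - y'x'') / (x'^2 + y'^2)^(3/2)`,
#' at interior samples; the integration weights partition the full arc
#' length so integral measures cover the whole curve.
#'
#' @param points n x 2 matrix of ordered (row, col) coordinates, n >= 5.
#' @param closed Logical; closed curves have no usable chord, so chord-based
#'   measures are returned as `NA`.
#' @return List: `arc`, `chord`, `kappa` (interior samples), `w`
#'   (integration weights, same length as `kappa`), `n`.
#' @export
tortuosity_basis <- function(points, closed = FALSE) {
  n <- nrow(points)
  if (is.null(n) || n < 5) {
    return(list(arc = NA_real_, chord = NA_real_, kappa = NULL, w = NULL,
                n = if (is.null(n)) 0L else n))
  }
  y <- points[, 1]
  x <- points[, 2]
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  if (any(seg == 0)) { # drop exact duplicates
    keep <- c(TRUE, seg > 0)
    x <- x[keep]
    y <- y[keep]
    n <- length(x)
    if (n < 5) {
      return(list(arc = NA_real_, chord = NA_real_, kappa = NULL, w = NULL,
                  n = n))
    }
    seg <- sqrt(diff(x)^2 + diff(y)^2)
  }
  s <- c(0, cumsum(seg))
  arc <- s[n]
  chord <- sqrt((x[n] - x[1])^2 + (y[n] - y[1])^2)
  if (closed || chord < 1e-9) chord <- NA_real_
  i <- 2:(n - 1)
  h1 <- s[i] - s[i - 1]
  h2 <- s[i + 1] - s[i]
  xp <- (x[i + 1] - x[i - 1]) / (h1 + h2)
  yp <- (y[i + 1] - y[i - 1]) / (h1 + h2)
  xpp <- 2 * ((x[i + 1] - x[i]) / h2 - (x[i] - x[i - 1]) / h1) / (h1 + h2)
  ypp <- 2 * ((y[i + 1] - y[i]) / h2 - (y[i] - y[i - 1]) / h1) / (h1 + h2)
  denom <- (xp^2 + yp^2)^1.5
  kappa <- ifelse(denom > 0, (xp * ypp - yp * xpp) / denom, 0)
  # weights: interior midpoint spans, end cells absorbed into first/last
  w <- (s[i + 1] - s[i - 1]) / 2
  w[1] <- (s[3] + s[2]) / 2 - s[1]
  w[length(w)] <- s[n] - (s[n - 1] + s[n - 2]) / 2
  list(arc = arc, chord = chord, kappa = kappa, w = w, n = n)
}

# The seven tortuosity measures from a basis: T1 arc/chord, T2 total
# curvature, T3 total squared curvature, T4/T5 per arc length, T6/T7 per
# chord length.
.tortuosity_T <- function(b) {
  if (is.null(b$kappa)) return(rep(NA_real_, 7))
  T2 <- sum(abs(b$kappa) * b$w)
  T3 <- sum(b$kappa^2 * b$w)
  c(
    T1 = b$arc / b$chord, T2 = T2, T3 = T3,
    T4 = T2 / b$arc, T5 = T3 / b$arc,
    T6 = T2 / b$chord, T7 = T3 / b$chord
  )
}

#' Smooth a branch contour
#'
#' Least-squares cubic spline of the coordinates against arc length, with
#' knots every 10 samples, re-sampled at unit arc steps. This suppresses the
#' pixel-lattice jitter of digitized centerlines while preserving genuine
#' curvature.
#'
#' @param points n x 2 matrix of ordered (row, col) coordinates.
#' @return Matrix of re-sampled smoothed coordinates (possibly fewer rows).
#' @export
smooth_branch <- function(points) {
  n <- nrow(points)
  if (n < 5) return(points)
  y <- points[, 1]
  x <- points[, 2]
  s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  if (s[n] <= 0) return(points)
  ik <- if (n > 14) s[seq(10, n - 5, by = 10)] else numeric(0)
  B <- splines::bs(s, knots = ik, degree = 3, intercept = TRUE,
                   Boundary.knots = range(s))
  cx <- stats::lm.fit(B, x)$coefficients
  cy <- stats::lm.fit(B, y)$coefficients
  cx[is.na(cx)] <- 0
  cy[is.na(cy)] <- 0
  sf <- seq(0, s[n], length.out = max(4L * ceiling(s[n]), 20L))
  Bf <- splines::bs(sf, knots = ik, degree = 3, intercept = TRUE,
                    Boundary.knots = range(s))
  xf <- as.numeric(Bf %*% cx)
  yf <- as.numeric(Bf %*% cy)
  cl <- c(0, cumsum(sqrt(diff(xf)^2 + diff(yf)^2)))
  L <- cl[length(cl)]
  stations <- unique(c(seq(0, L, by = 1), L))
  if (length(stations) < 5) stations <- seq(0, L, length.out = 5)
  cbind(
    stats::approx(cl, yf, xout = stations, ties = "ordered")$y,
    stats::approx(cl, xf, xout = stations, ties = "ordered")$y
  )
}

# Anchor points at a fixed arc spacing along a pixel chain. Curvature from
# per-pixel samples measures the lattice, not the vessel: on identical
# geometry, per-pixel mean squared curvature varies several-fold with the
# rendered width. Anchors spaced beyond the lattice correlation length
# (~ the half-width of the thickest vessels) suppress that digitization
# noise while leaving analytic accuracy intact (bending radii are tens of
# px).
.anchor_points <- function(points, spacing) {
  n <- nrow(points)
  if (spacing <= 1 || n < 3) return(points)
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-n, , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  keep <- !duplicated(floor(s / spacing))
  keep[n] <- TRUE
  points[keep, , drop = FALSE]
}

#' The 15 tortuosity traits of one branch
#'
#' The branch centerline is reduced to anchor points at a fixed arc spacing
#' (default 4 px), and the seven measures T1..T7 are mapped to trait pairs:
#' `t(2k-1)` is Tk on the sampled anchor contour and `t(2k)` Tk on the
#' smoothed contour, for k = 1..7; t15 is the smoothed/sampled arc-length
#' ratio. Branches with fewer than `min_len` anchors, and chord-based
#' measures of closed branches, are `NA`.
#'
#' @param points n x 2 matrix of ordered coordinates (a branch centerline).
#' @param closed Logical, closed-curve flag.
#' @param min_len Minimum number of anchor points (default 5);
#'   finite-difference curvature is undefined or dominated by noise below
#'   that.
#' @param anchor_spacing Arc distance between anchor points, in px.
#' @return Named numeric vector t1..t15.
#' @export
tortuosity_traits <- function(points, closed = FALSE, min_len = 5,
                              anchor_spacing = 4) {
  out <- setNames(rep(NA_real_, 15), paste0("t", 1:15))
  n <- nrow(points)
  if (is.null(n) || n < min_len) return(out)
  points <- .anchor_points(points, anchor_spacing)
  if (nrow(points) < min_len) return(out)
  bs <- tortuosity_basis(points, closed = closed)
  if (is.null(bs$kappa)) return(out)
  sm <- smooth_branch(points)
  bm <- tortuosity_basis(sm, closed = closed)
  Ts <- .tortuosity_T(bs)
  Tm <- .tortuosity_T(bm)
  out[seq(1, 13, by = 2)] <- Ts
  out[seq(2, 14, by = 2)] <- Tm
  out["t15"] <- if (is.finite(bm$arc) && is.finite(bs$arc) && bs$arc > 0) {
    bm$arc / bs$arc
  } else {
    NA_real_
  }
  out
}

#' Aggregate branch tortuosity to one per-image value per trait
#'
#' Unweighted arithmetic mean over eligible branches, per trait (missing
#' branch values are excluded per trait). With no eligible branch all 15
#' values are `NA`.
#'
#' @param branch_traits Matrix or data frame, one row per branch, columns
#'   t1..t15.
#' @return Named numeric vector t1..t15.
#' @export
aggregate_tortuosity <- function(branch_traits) {
  nm <- paste0("t", 1:15)
  if (is.null(branch_traits) || NROW(branch_traits) == 0) {
    return(setNames(rep(NA_real_, 15), nm))
  }
  m <- as.matrix(branch_traits[, nm, drop = FALSE])
  res <- colMeans(m, na.rm = TRUE)
  res[!is.finite(res)] <- NA_real_
  setNames(res, nm)
}

#' Box-counting fractal ratios f2..f8
#'
#' For scale index s in 2..8 the mask is tiled with grid-aligned boxes of
#' side `2^s` px anchored at the origin; `N_s` is the number of boxes
#' containing foreground and `r_s = ceiling(max(H, W) / 2^s)` the number of
#' boxes along the longest side. The trait is `f_s = log(N_s) / log(r_s)`,
#' the per-scale box count on a log scale over resolution on a log scale;
#' scales with `r_s = 1` are undefined. The definition has the analytic
#' limits 1 for a line and 2 for a filled plane.
#'
#' @param mask Binary matrix.
#' @return Named numeric vector f2..f8 (`NA` for empty masks or degenerate
#'   scales).
#' @export
fractal_traits <- function(mask) {
  px <- if (inherits(mask, "vessel_map")) mask$pixels else mask
  nm <- paste0("f", 2:8)
  out <- setNames(rep(NA_real_, 7), nm)
  if (!any(px != 0)) return(out)
  H <- nrow(px)
  W <- ncol(px)
  pxn <- matrix(as.numeric(px != 0), H, W)
  for (s in 2:8) {
    b <- 2^s
    r <- ceiling(max(H, W) / b)
    if (r <= 1) next
    ri <- (seq_len(H) - 1L) %/% b
    ci <- (seq_len(W) - 1L) %/% b
    m <- rowsum(pxn, ri)
    m <- t(rowsum(t(m), ci))
    N <- sum(m > 0)
    out[paste0("f", s)] <- log(N) / log(r)
  }
  out
}

# Compute the 25-trait vector for one binary class mask.
.class_traits <- function(mask, min_branch_len = 5, smoothed = TRUE,
                          families = c("tortuosity", "fractal",
                                       "junction")) {
  nm <- trait_names()
  out <- setNames(rep(NA_real_, 25), nm)
  if (!any(mask != 0)) return(out)
  sk <- skeletonize(mask)
  an <- .skeleton_analysis(sk)
  if ("junction" %in% families) {
    out["j1"] <- an$junctions$j1
    out["j2"] <- an$junctions$j2
    out["j3"] <- an$junctions$j3
  }
  # crossing-attached branches carry overlap (projection) geometry and are
  # excluded from tortuosity, like the crossing count itself
  elig <- if ("tortuosity" %in% families) {
    Filter(function(b) {
      nrow(b$points) >= min_branch_len && !isTRUE(b$near_crossing)
    }, an$branches)
  } else {
    list()
  }
  if (length(elig)) {
    if (smoothed) {
      bt <- t(vapply(
        elig,
        function(b) tortuosity_traits(b$points, b$closed, min_branch_len),
        numeric(15)
      ))
    } else {
      # sampled-only fast path: smoothed entries stay NA
      bt <- t(vapply(elig, function(b) {
        v <- setNames(rep(NA_real_, 15), paste0("t", 1:15))
        ap <- .anchor_points(b$points, 4)
        if (nrow(ap) >= min_branch_len) {
          bsx <- tortuosity_basis(ap, closed = b$closed)
          if (!is.null(bsx$kappa)) {
            v[seq(1, 13, by = 2)] <- .tortuosity_T(bsx)
          }
        }
        v
      }, numeric(15)))
    }
    colnames(bt) <- paste0("t", 1:15)
    out[paste0("t", 1:15)] <- aggregate_tortuosity(bt)
  }
  if ("fractal" %in% families) {
    out[paste0("f", 2:8)] <- fractal_traits(mask)
  }
  out
}

#' Assemble the per-image trait table
#'
#' Computes the 25 named traits independently on each caliber-class mask
#' (skeleton, branches, junctions and fractal ratios per class), yielding
#' 75 values per image in the fixed order t1..t15, f2..f8, j1..j3. Empty
#' classes produce 25 missing values, never zeros.
#'
#' @param split Result of [split_by_caliber()].
#' @param image_id Image identifier.
#' @param min_branch_len Minimum branch length (in skeleton pixels) entering
#'   tortuosity.
#' @param smoothed Compute the smoothed-contour variants (default TRUE).
#' @param classes Which classes to compute (default all three).
#' @param families Trait families to compute; omitted families stay `NA`.
#' @return Data frame, one row per class, columns `image_id`, `class` and
#'   the 25 traits.
#' @export
assemble_trait_vector <- function(split, image_id = "image",
                                  min_branch_len = 5, smoothed = TRUE,
                                  classes = c("Thin", "Thick", "Total"),
                                  families = c("tortuosity", "fractal",
                                               "junction")) {
  classes <- match.arg(classes, c("Thin", "Thick", "Total"),
                       several.ok = TRUE)
  rows <- lapply(classes, function(k) {
    tv <- .class_traits(split$masks[[k]], min_branch_len, smoothed,
                        families)
    cbind(
      data.frame(image_id = image_id, class = k, stringsAsFactors = FALSE),
      as.data.frame(as.list(tv))
    )
  })
  do.call(rbind, rows)
}

#' Extract all microvascular traits from one vessel map
#'
#' The full per-image pipeline: skeletonize, estimate caliber, split into
#' caliber classes around `F * Um`, and compute the 25 traits per class.
#' When `um` is `NULL` the uber-mean is taken over this image's branches
#' alone; for a dataset-level Um, pool [branch_calibers()] across images
#' with [compute_uber_mean()] and pass the result.
#'
#' @param map A [vessel_map()] object.
#' @param F Caliber threshold factor (default 0.5).
#' @param um Optional pre-computed uber-mean caliber.
#' @param classes Caliber classes to compute. `"Total"` alone skips the
#'   caliber split entirely.
#' @param smoothed Compute smoothed-contour tortuosity variants.
#' @param min_branch_len Minimum branch length for tortuosity.
#' @param families Trait families to compute; omitted families stay `NA`.
#' @return List with `traits` (data frame, one row per class), `summary`
#'   (caliber summary row, when the split was computed) and `um`.
#' @export
extract_traits <- function(map, F = 0.5, um = NULL,
                           classes = c("Thin", "Thick", "Total"),
                           smoothed = TRUE, min_branch_len = 5,
                           families = c("tortuosity", "fractal",
                                        "junction")) {
  stopifnot(inherits(map, "vessel_map"))
  classes <- match.arg(classes, c("Thin", "Thick", "Total"),
                       several.ok = TRUE)
  if (map$empty) {
    split <- list(masks = list(
      Thin = map$pixels, Thick = map$pixels, Total = map$pixels
    ))
    return(list(
      traits = assemble_trait_vector(split, map$image_id, min_branch_len,
                                     smoothed, classes, families),
      summary = NULL, um = NA_real_
    ))
  }
  if (identical(classes, "Total")) {
    split <- list(masks = list(Total = map$pixels))
    return(list(
      traits = assemble_trait_vector(split, map$image_id, min_branch_len,
                                     smoothed, "Total", families),
      summary = NULL, um = NA_real_
    ))
  }
  sk <- skeletonize(map)
  cal <- estimate_caliber(map, sk)
  br <- extract_branches(sk)
  bc <- branch_calibers(cal, br)
  if (is.null(um)) um <- compute_uber_mean(bc)
  split <- split_by_caliber(map, sk, br, cal, um = um, F = F)
  list(
    traits = assemble_trait_vector(split, map$image_id, min_branch_len,
                                   smoothed, classes, families),
    summary = caliber_summary(map, split, bc),
    um = um
  )
}
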