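# Vessel-map handling: loading binary masks, caliber estimation via the
# Euclidean distance transform, the dataset-wide mean caliber (uber-mean Um)
# and the Thin/Thick/Total caliber split.

#' Construct a vessel map object
#'
#' A vessel map is a binary raster in which foreground pixels mark segmented
#' vasculature. Pixels are stored as an integer H x W matrix (row = y).
#'
#' @param pixels Binary matrix (any nonzero value is foreground).
#' @param image_id Identifier carried through all per-image outputs.
#' @return An object of class `vessel_map` with fields `pixels`, `image_id`,
#'   `height`, `width` and `empty` (TRUE when no foreground pixel exists).
#' @export
vessel_map <- function(pixels, image_id = "image") {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  px <- matrix(as.integer(pixels != 0), nrow(pixels), ncol(pixels))
  if (nrow(px) < 64 || ncol(px) < 64) {
    stop("vessel maps must be at least 64 x 64 pixels")
  }
  structure(
    list(
      image_id = as.character(image_id), pixels = px,
      height = nrow(px), width = ncol(px), empty = !any(px > 0)
    ),
    class = "vessel_map"
  )
}

#' @export
print.vessel_map <- function(x, ...) {
  cat(sprintf(
    "<vessel_map '%s'> %d x %d px, %d foreground (%s)\n",
    x$image_id, x$height, x$width, sum(x$pixels),
    if (x$empty) "empty" else "non-empty"
  ))
  invisible(x)
}

#' Load a binary vessel map from a PNG or TIFF file
#'
#' Multi-channel rasters are collapsed by taking the per-pixel maximum over
#' channels; any value strictly greater than zero becomes foreground, so
#' masks coded 0/1 and 0/255 load identically.
#'
#' @param path Path to a PNG or TIFF image.
#' @param image_id Identifier; defaults to the file name without extension.
#' @return A [vessel_map()] object. An all-background image is returned
#'   flagged empty, not treated as an error.
#' @export
load_vessel_map <- function(path, image_id = NULL) {
  if (!file.exists(path)) stop("cannot read vessel map: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)")
  )
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), max)
  if (is.null(image_id)) {
    image_id <- tools::file_path_sans_ext(basename(path))
  }
  vessel_map(img > 0, image_id = image_id)
}

#' Write a vessel map to a PNG file
#'
#' @param map A [vessel_map()] object or binary matrix.
#' @param path Output PNG path.
#' @return The path, invisibly.
#' @export
write_vessel_map <- function(map, path) {
  px <- if (inherits(map, "vessel_map")) map$pixels else map
  png::writePNG(matrix(as.numeric(px != 0), nrow(px), ncol(px)), path)
  invisible(path)
}

#' Downscale a raster by area-weighted averaging
#'
#' Reduces a raster to the working resolution of the pipeline (by default
#' 565 x 584, width x height) by exact area-weighted averaging through an
#' integral image, then binarizes at 0.5 when the input is binary. Area
#' averaging preserves thin structures better than nearest-neighbour
#' sampling. The reported linear factor is `sqrt(source_area / target_area)`.
#'
#' @param pixels Numeric or binary matrix (H x W).
#' @param target Target size as `c(width, height)`; default `c(565, 584)`.
#' @param binarize Threshold the area averages at 0.5 (default TRUE).
#' @return List with `pixels` (target-sized matrix) and `factor` (linear
#'   downscale factor).
#' @export
downscale_image <- function(pixels, target = c(565, 584), binarize = TRUE) {
  if (inherits(pixels, "vessel_map")) pixels <- pixels$pixels
  stopifnot(is.matrix(pixels), length(target) == 2)
  Wt <- as.integer(target[1])
  Ht <- as.integer(target[2])
  H <- nrow(pixels)
  W <- ncol(pixels)
  if (H < Ht || W < Wt) {
    stop("source (", W, "x", H, ") smaller than target (", Wt, "x", Ht,
         "): upscaling is not supported")
  }
  factor <- sqrt((H * W) / (Ht * Wt))
  if (H == Ht && W == Wt) {
    out <- if (binarize) matrix(as.integer(pixels >= 0.5), H, W) else pixels
    return(list(pixels = out, factor = 1.0))
  }
  # integral image; S[i+1, j+1] = sum of pixels[1..i, 1..j]
  S <- matrix(0, H + 1, W + 1)
  S[-1, -1] <- t(apply(apply(pixels, 2, cumsum), 1, cumsum))
  interp_rows <- function(M, pos) {
    lo <- pmin(floor(pos), nrow(M) - 1)
    fr <- pos - lo
    M[lo + 1, , drop = FALSE] * (1 - fr) + M[lo + 2, , drop = FALSE] * fr
  }
  re <- (0:Ht) * (H / Ht) # fractional row edges in source units
  ce <- (0:Wt) * (W / Wt)
  Sr <- interp_rows(S, pmin(re, H - 1e-12))
  Sc <- t(interp_rows(t(Sr), pmin(ce, W - 1e-12)))
  block <- Sc[-1, -1] - Sc[-1, -(Wt + 1)] - Sc[-(Ht + 1), -1] +
    Sc[-(Ht + 1), -(Wt + 1)]
  avg <- block / ((H / Ht) * (W / Wt))
  out <- if (binarize) matrix(as.integer(avg >= 0.5), Ht, Wt) else avg
  list(pixels = out, factor = factor)
}

#' Per-pixel caliber field from the Euclidean distance transform
#'
#' Caliber at a skeleton pixel is defined as twice the Euclidean distance
#' from that pixel to the nearest background pixel (a standard morphometric
#' estimate of local vessel width from a segmented map).
#'
#' @param map A [vessel_map()] object or binary matrix.
#' @param skeleton Binary skeleton matrix derived from the same map
#'   (see [skeletonize()]).
#' @return Numeric matrix of calibers; `NA` outside the skeleton.
#' @export
estimate_caliber <- function(map, skeleton) {
  px <- if (inherits(map, "vessel_map")) map$pixels else map
  stopifnot(is.matrix(skeleton), all(dim(px) == dim(skeleton)))
  if (any(skeleton != 0 & px == 0)) {
    stop("internal consistency error: skeleton pixel outside map foreground")
  }
  bg <- matrix(as.integer(px == 0), nrow(px), ncol(px))
  d <- .cpp_edt(bg)$dist
  cal <- 2 * d
  cal[skeleton == 0] <- NA_real_
  cal
}

#' Mean caliber per branch
#'
#' Arithmetic mean of the per-pixel calibers along each branch's skeleton
#' pixels.
#'
#' @param caliber Caliber matrix from [estimate_caliber()].
#' @param branches Branch list from [extract_branches()].
#' @return Numeric vector, one mean caliber per branch.
#' @export
branch_calibers <- function(caliber, branches) {
  vapply(branches$branches, function(b) {
    mean(caliber[b$points], na.rm = TRUE)
  }, numeric(1))
}

#' Dataset-wide mean caliber (uber-mean, Um)
#'
#' The unweighted arithmetic mean of per-branch calibers pooled across all
#' images of a run; pooling is image-agnostic.
#'
#' @param branch_calibers Numeric vector of per-branch mean calibers, pooled
#'   over the dataset.
#' @return Scalar Um.
#' @export
compute_uber_mean <- function(branch_calibers) {
  v <- branch_calibers[is.finite(branch_calibers)]
  if (length(v) == 0) stop("cannot compute the uber-mean of an empty dataset")
  mean(v)
}

#' Branch-level caliber classification
#'
#' Applies the caliber rule to a vector of per-branch mean calibers:
#' Thick when caliber is at least `F * Um`, Thin otherwise. Ties go to
#' Thick, consistent with most vessels scoring Thick at the default F.
#'
#' @param branch_calibers Numeric vector of per-branch mean calibers.
#' @param um Uber-mean caliber.
#' @param F Threshold factor in (0, 1].
#' @return Character vector of "Thin"/"Thick", one per branch.
#' @export
split_branches <- function(branch_calibers, um, F = 0.5) {
  stopifnot(um > 0, F > 0, F <= 1)
  ifelse(branch_calibers >= F * um, "Thick", "Thin")
}

#' Split a vessel map into Thin/Thick/Total caliber classes
#'
#' Each branch is assigned whole to one class: Thick when its mean caliber is
#' at least `F * Um`, Thin otherwise (ties go to Thick, consistent with most
#' vessels scoring Thick at the default F). Class pixel masks are built by
#' assigning every foreground pixel to its nearest skeleton pixel's branch;
#' junction-cluster pixels follow the widest adjacent branch, so class masks
#' stay connected through forks. Total is always the full foreground.
#'
#' @param map A [vessel_map()] object or binary matrix.
#' @param skeleton Skeleton of the map.
#' @param branches Branch list from [extract_branches()].
#' @param caliber Caliber matrix from [estimate_caliber()].
#' @param um Uber-mean caliber (pooled over the run, or per-image for
#'   self-contained use).
#' @param F Caliber threshold factor in (0, 1]; default 0.5.
#' @return List with `masks` (list of binary matrices `Thin`, `Thick`,
#'   `Total`), `branch_class` (factor per branch), `um`, `F` and `threshold`.
#' @export
split_by_caliber <- function(map, skeleton, branches, caliber, um, F = 0.5) {
  px <- if (inherits(map, "vessel_map")) map$pixels else map
  stopifnot(um > 0, F > 0, F <= 1)
  thr <- F * um
  bc <- branch_calibers(caliber, branches)
  cls <- split_branches(bc, um, F)
  # label every skeleton pixel with its branch id; junction pixels take the
  # widest adjacent branch so classes remain connected through forks
  bid <- branches$branch_id
  jpix <- which(skeleton != 0 & bid == 0)
  if (length(jpix)) {
    H <- nrow(px)
    rc <- arrayInd(jpix, dim(px))
    for (i in seq_len(nrow(rc))) {
      r <- rc[i, 1]
      c <- rc[i, 2]
      nb <- bid[
        cbind(
          pmax(1, pmin(H, r + c(-1, -1, -1, 0, 0, 1, 1, 1))),
          pmax(1, pmin(ncol(px), c + c(-1, 0, 1, -1, 1, -1, 0, 1)))
        )
      ]
      nb <- nb[nb > 0]
      if (length(nb)) {
        bid[r, c] <- nb[which.max(bc[nb])]
      } else {
        bid[r, c] <- 0L
      }
    }
  }
  masks <- list(Thin = NULL, Thick = NULL, Total = px)
  if (any(skeleton != 0)) {
    seeds <- matrix(0L, nrow(px), ncol(px))
    sk <- which(skeleton != 0 & bid > 0)
    seeds[sk] <- bid[sk]
    if (length(sk)) {
      near <- .cpp_edt(seeds)$label
      pix_cls <- matrix("", nrow(px), ncol(px))
      fg <- px != 0
      pix_cls[fg] <- cls[near[fg]]
      for (k in c("Thin", "Thick")) {
        masks[[k]] <- matrix(as.integer(fg & pix_cls == k), nrow(px), ncol(px))
      }
    }
  }
  if (is.null(masks$Thin)) masks$Thin <- matrix(0L, nrow(px), ncol(px))
  if (is.null(masks$Thick)) masks$Thick <- matrix(0L, nrow(px), ncol(px))
  list(
    masks = masks, branch_class = factor(cls, levels = c("Thin", "Thick")),
    um = um, F = F, threshold = thr
  )
}

#' Per-image caliber summary
#'
#' @param map A [vessel_map()] object.
#' @param split Result of [split_by_caliber()].
#' @param branch_cal Per-branch mean calibers.
#' @return One-row data frame: image_id, n_branches, mean_caliber, um, F,
#'   n_thick, n_thin.
#' @export
caliber_summary <- function(map, split, branch_cal) {
  data.frame(
    image_id = map$image_id,
    n_branches = length(branch_cal),
    mean_caliber = mean(branch_cal, na.rm = TRUE),
    um = split$um, F = split$F,
    n_thick = sum(split$branch_class == "Thick"),
    n_thin = sum(split$branch_class == "Thin"),
    stringsAsFactors = FALSE
  )
}
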