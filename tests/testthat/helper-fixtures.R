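# Fixtures and independent oracles used across the suite. Everything is
# generated in code; oracles are deliberately naive (brute force) and
# independent of the package's implementation paths.

# horizontal stripe of given width centered in an HxW canvas
make_stripe <- function(width, H = 100, W = 100, margin = 10) {
  m <- matrix(0L, H, W)
  r0 <- (H - width) %/% 2
  m[(r0 + 1):(r0 + width), (margin + 1):(W - margin)] <- 1L
  m
}

# wedge tapering linearly from w_from to w_to px across the canvas
make_wedge <- function(w_from = 3, w_to = 9, H = 100, W = 200, margin = 10) {
  m <- matrix(0L, H, W)
  cols <- (margin + 1):(W - margin)
  widths <- round(seq(w_from, w_to, length.out = length(cols)))
  for (i in seq_along(cols)) {
    half <- widths[i] / 2
    r0 <- round(H / 2 - half)
    m[(r0 + 1):(r0 + widths[i]), cols[i]] <- 1L
  }
  m
}

# ideal 1-px Y skeleton: one vertical stem, two diagonal arms
make_y_skeleton <- function(H = 100, W = 100) {
  m <- matrix(0L, H, W)
  m[30:50, 50] <- 1L
  for (i in 1:20) {
    m[50 + i, 50 - i] <- 1L
    m[50 + i, 50 + i] <- 1L
  }
  m
}

# ideal 1-px + skeleton: four axis-aligned arms
make_plus_skeleton <- function(H = 100, W = 100) {
  m <- matrix(0L, H, W)
  m[30:70, 50] <- 1L
  m[50, 30:70] <- 1L
  m
}

# ideal comb tree: vertical trunk with k diagonal side arms, all simple
# forks, no crossings
make_comb_skeleton <- function(k, H = 400, W = 400) {
  m <- matrix(0L, H, W)
  m[20:(40 + 30 * k), 50] <- 1L
  for (j in seq_len(k)) {
    m[20 + 30 * j, 51:65] <- 1L # horizontal side arm, clean fork
  }
  m
}

# digitized ring (circle outline) skeleton
make_ring_skeleton <- function(R = 20, H = 100, W = 100) {
  m <- matrix(0L, H, W)
  th <- seq(0, 2 * pi, length.out = 720)
  r <- pmin(pmax(round(H / 2 + R * sin(th)), 1), H)
  c <- pmin(pmax(round(W / 2 + R * cos(th)), 1), W)
  m[cbind(r, c)] <- 1L
  skeletonize(m) # re-thin to guarantee 1-px
}

# analytic open curve sampled at unit arc steps
make_arc_points <- function(R, theta, scale = 1) {
  n <- max(ceiling(R * theta), 8) + 1
  th <- seq(0, theta, length.out = n)
  cbind(R * scale * sin(th), R * scale * cos(th))
}

# brute-force crossing number by transition counting (independent oracle)
oracle_crossing_number <- function(window) {
  ord <- rbind(
    c(1, 2), c(1, 3), c(2, 3), c(3, 3), c(3, 2), c(3, 1), c(2, 1), c(1, 1)
  )
  p <- as.integer(window[ord] != 0)
  tot <- 0L
  for (k in 1:8) tot <- tot + abs(p[k] - p[if (k == 8) 1 else k + 1])
  tot %/% 2L
}

# brute-force grid-aligned box scan (independent oracle for box counting)
oracle_box_count <- function(mask, b) {
  H <- nrow(mask)
  W <- ncol(mask)
  count <- 0
  for (r0 in seq(1, H, by = b)) {
    for (c0 in seq(1, W, by = b)) {
      blk <- mask[r0:min(r0 + b - 1, H), c0:min(c0 + b - 1, W)]
      if (any(blk != 0)) count <- count + 1
    }
  }
  count
}

# brute-force Benjamini-Hochberg step-up (independent oracle)
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[i] <- min(p[ord][i:n] * n / (i:n)[seq_len(n - i + 1)], 1)
  }
  out <- numeric(n)
  out[ord] <- q
  out
}

# dense numerical quadrature oracle for tortuosity integrals of y = f(x)
# curves, at 10x the pixel sampling
oracle_curve_integrals <- function(fx, dfx, ddfx, from, to, n = 10000) {
  x <- seq(from, to, length.out = n)
  kap <- ddfx(x) / (1 + dfx(x)^2)^1.5
  ds <- sqrt(1 + dfx(x)^2)
  h <- diff(x)[1]
  arc <- sum(ds) * h
  chord <- sqrt((to - from)^2 + (fx(to) - fx(from))^2)
  list(
    T1 = arc / chord,
    T2 = sum(abs(kap) * ds) * h,
    T3 = sum(kap^2 * ds) * h,
    arc = arc, chord = chord
  )
}
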