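# Tortuosity, fractal and trait-vector assembly.

test_that("a straight line has unit arc/chord ratio and zero curvature", {
  for (pts in list(
    cbind(rep(50, 100), 1:100), # horizontal
    cbind(1:100, 1:100) # diagonal
  )) {
    tt <- tortuosity_traits(pts)
    expect_equal(unname(tt["t1"]), 1, tolerance = 1e-9)
    expect_equal(unname(tt["t2"]), 1, tolerance = 1e-6)
    expect_true(all(abs(tt[paste0("t", 3:14)]) < 1e-6))
    expect_equal(unname(tt["t15"]), 1, tolerance = 1e-3)
  }
})

test_that("analytic semicircle recovers arc/chord and curvature integrals", {
  pts <- make_arc_points(R = 50, theta = pi)
  b <- tortuosity_basis(pts)
  expect_equal(b$arc / b$chord, pi / 2, tolerance = 0.02)
  tt <- tortuosity_traits(pts)
  expect_equal(unname(tt["t3"]), pi, tolerance = 0.02) # total curvature
  expect_equal(unname(tt["t5"]), pi / 50, tolerance = 0.03) # total squared
})

test_that("curvature traits follow their scaling laws on a circular arc", {
  base <- make_arc_points(R = 40, theta = pi / 2)
  Tb <- retmorph:::.tortuosity_T(tortuosity_basis(base))
  for (m in c(2, 3)) {
    Tm <- retmorph:::.tortuosity_T(tortuosity_basis(
      make_arc_points(R = 40, theta = pi / 2, scale = m)
    ))
    expect_equal(Tm[["T1"]], Tb[["T1"]], tolerance = 0.01) # invariant
    expect_equal(Tm[["T2"]], Tb[["T2"]], tolerance = 0.01) # total angle
    expect_equal(Tm[["T3"]], Tb[["T3"]] / m, tolerance = 0.01)
    expect_equal(Tm[["T4"]], Tb[["T4"]] / m, tolerance = 0.01)
    expect_equal(Tm[["T5"]], Tb[["T5"]] / m^2, tolerance = 0.01)
    expect_equal(Tm[["T6"]], Tb[["T6"]] / m, tolerance = 0.01)
    expect_equal(Tm[["T7"]], Tb[["T7"]] / m^2, tolerance = 0.01)
  }
})

test_that("sampled curvature integrals match a dense quadrature oracle", {
  # sine curve y = 10 sin(x / 20) on x in [0, 200], sampled at ~unit steps
  fx <- function(x) 10 * sin(x / 20)
  dfx <- function(x) 0.5 * cos(x / 20)
  ddfx <- function(x) -(10 / 400) * sin(x / 20)
  x <- seq(0, 200, by = 0.8)
  pts <- cbind(fx(x), x)
  orc <- oracle_curve_integrals(fx, dfx, ddfx, 0, 200)
  Tv <- retmorph:::.tortuosity_T(tortuosity_basis(pts))
  expect_equal(Tv[["T1"]], orc$T1, tolerance = 0.03)
  expect_equal(Tv[["T2"]], orc$T2, tolerance = 0.03)
  expect_equal(Tv[["T3"]], orc$T3, tolerance = 0.03)
})

test_that("t1 is at least 1 for open branches, 1 only when collinear", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(6:60, 1)
    pts <- cbind(cumsum(runif(n, 0.5, 1)), cumsum(runif(n, -1, 1)))
    b <- tortuosity_basis(pts)
    expect_gte(b$arc / b$chord, 1 - 1e-9)
  }
})

test_that("smoothing contracts the arc length of noisy digitized lines", {
  set.seed(11)
  for (i in 1:10) {
    x <- 1:80
    y <- 50 + sample(c(0L, 1L), 80, replace = TRUE) # pixel jitter
    tt <- tortuosity_traits(cbind(y, x))
    expect_lte(unname(tt["t15"]), 1 + 1e-9)
  }
})

test_that("branch aggregation is an unweighted mean, order-invariant", {
  bt <- rbind(
    setNames(c(1.0, rep(0, 14)), paste0("t", 1:15)),
    setNames(c(1.2, rep(0, 14)), paste0("t", 1:15))
  )
  agg <- aggregate_tortuosity(bt)
  expect_equal(unname(agg["t1"]), 1.1)
  expect_equal(aggregate_tortuosity(bt[2:1, ]), agg)
  expect_true(all(is.na(aggregate_tortuosity(bt[0, ]))))
  one <- aggregate_tortuosity(bt[1, , drop = FALSE])
  expect_equal(unname(one["t1"]), 1.0)
})

test_that("short and closed branches propagate missing values", {
  expect_true(all(is.na(tortuosity_traits(cbind(1:3, 1:3)))))
  ring <- make_ring_skeleton()
  b <- extract_branches(ring)$branches[[1]]
  tt <- tortuosity_traits(b$points, closed = b$closed)
  expect_true(is.na(tt["t1"])) # chord-based traits undefined
  expect_false(is.na(tt["t3"])) # curvature integrals still defined
})

test_that("fractal ratios hit the analytic line and plane limits", {
  filled <- matrix(1L, 512, 512)
  ff <- fractal_traits(filled)
  expect_equal(unname(ff), rep(2, 7)) # exact at dyadic sizes

  line <- matrix(0L, 512, 512)
  line[256, ] <- 1L
  fl <- fractal_traits(line)
  expect_true(all(abs(fl - 1) <= 0.05))

  # the coarsest scale degenerates to a single box on small images
  expect_true(is.na(fractal_traits(make_stripe(3, 200, 200))["f8"]))
  expect_true(all(is.na(fractal_traits(matrix(0L, 64, 64)))))
})

test_that("box counts equal the brute-force box scanner at every scale", {
  set.seed(3)
  m <- matrix(rbinom(300 * 280, 1, 0.2), 300, 280)
  ff <- fractal_traits(m)
  for (s in 2:8) {
    b <- 2^s
    r <- ceiling(max(dim(m)) / b)
    expected <- if (r <= 1) NA_real_ else log(oracle_box_count(m, b)) / log(r)
    expect_equal(unname(ff[paste0("f", s)]), expected)
  }
})

test_that("fractal ratios stay within (0, 2] for random masks", {
  set.seed(9)
  for (dens in c(0.05, 0.3, 0.8)) {
    m <- matrix(rbinom(300 * 300, 1, dens), 300, 300)
    ff <- fractal_traits(m)
    ok <- !is.na(ff)
    expect_true(all(ff[ok] > 0 & ff[ok] <= 2 + 1e-9))
  }
})

test_that("trait vectors have 75 named values in fixed order per image", {
  g <- grow_vessel_tree(growth_config(seed = 9, p_bif = 0.004))
  res <- extract_traits(g$map)
  expect_equal(nrow(res$traits), 3)
  expect_setequal(res$traits$class, c("Thin", "Thick", "Total"))
  expect_equal(names(res$traits)[-(1:2)], trait_names())
  expect_equal(sum(!names(res$traits) %in% c("image_id", "class")), 25)

  # Total-class junctions equal a direct junction count on the full map
  jc <- count_junctions(skeletonize(g$map$pixels))
  tot <- res$traits[res$traits$class == "Total", ]
  expect_equal(tot$j1, jc$j1)
  expect_equal(tot$j2, jc$j2)
  expect_equal(tot$j3, jc$j3)
})

test_that("an empty caliber class yields 25 missing values, not zeros", {
  # one thick stripe only: Thin class is empty
  m <- matrix(0L, 120, 120)
  m[50:60, 11:110] <- 1L
  res <- extract_traits(vessel_map(m, "thick_only"))
  thin <- res$traits[res$traits$class == "Thin", trait_names()]
  expect_true(all(is.na(thin)))
  thick <- res$traits[res$traits$class == "Thick", trait_names()]
  expect_false(all(is.na(thick)))
})
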