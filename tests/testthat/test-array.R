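# small helper: paint a uniform disc spot onto a constant background
spot_image <- function(n = 31, center = c(16, 16), r = 1.8, fg = 100, bg = 0) {
  m <- matrix(bg, n, n)
  d2 <- outer(seq_len(n) - center[1], seq_len(n) - center[2],
              function(a, b) a^2 + b^2)
  m[d2 <= r^2] <- fg
  m
}

test_that("spot integration subtracts the annulus background and floors at 0", {
  # disc of radius 1.8 px covers 9 pixels
  img <- spot_image(fg = 100, bg = 0)
  expect_equal(integrate_spot(img, c(16, 16), radius = 1.8,
                              annulus_inner = 3, annulus_outer = 6), 900)
  img2 <- spot_image(fg = 100, bg = 50)
  expect_equal(integrate_spot(img2, c(16, 16), radius = 1.8,
                              annulus_inner = 3, annulus_outer = 6),
               9 * (100 - 50))
  dim_spot <- spot_image(fg = 10, bg = 50)
  expect_equal(integrate_spot(dim_spot, c(16, 16), radius = 1.8,
                              annulus_inner = 3, annulus_outer = 6), 0)
  expect_error(integrate_spot(img, c(2, 2), radius = 1.8,
                              annulus_inner = 3, annulus_outer = 6),
               class = "oir_out_of_bounds")
})

test_that("membrane quantification is duplicate-symmetric and exposure invariant", {
  mb <- generate_array_membrane(membrane_spec(seed = 21))
  q1 <- quantify_membrane(mb$image, mb$grid)
  # swap the duplicate spots of every target: raw densities unchanged
  g <- mb$grid
  swapped <- spot_grid(g$target, g$row_px, g$col_px,
                       ifelse(g$is_reference, g$spot_index, 3L - g$spot_index),
                       g$is_reference,
                       radius = attr(g, "radius"),
                       annulus_inner = attr(g, "annulus_inner"),
                       annulus_outer = attr(g, "annulus_outer"))
  q2 <- quantify_membrane(mb$image, swapped)
  expect_equal(q1$raw, q2$raw)

  # doubling every pixel emulates a longer exposure
  px <- as.matrix(mb$image)
  q3 <- quantify_membrane(oir_image(px * 2, 16L), mb$grid)
  expect_equal(q1$normalized, q3$normalized, tolerance = 1e-9)

  blank <- oir_image(matrix(5, 400, 400), 16L)
  expect_error(quantify_membrane(blank, mb$grid),
               class = "oir_normalization_error")
})

test_that("noiseless membranes are recovered within 1 percent", {
  mb <- generate_array_membrane(membrane_spec(seed = 22, noise_sd = 0))
  q <- quantify_membrane(mb$image, mb$grid)
  expect_equal(q$raw, mb$truth$true_density, tolerance = 0.01)
  expect_equal(q$normalized, mb$truth$true_density / mb$ref_density,
               tolerance = 0.01)
})

test_that("fold changes are ratios with zero-control flagging", {
  tr <- c(a = 8, b = 2, c = 5)
  ct <- c(a = 2, b = 2, c = 0)
  fc <- fold_changes(tr, ct)
  expect_equal(fc$fold[fc$target == "a"], 4)
  expect_equal(fc$fold[fc$target == "b"], 1)
  expect_true(is.na(fc$fold[fc$target == "c"]))
  expect_false(fc$defined[fc$target == "c"])
  expect_error(fold_changes(tr, ct[1:2]), class = "oir_target_mismatch")
})

test_that("BH adjustment matches the literal step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_adjust(c(0.005, 0.5)), c(0.01, 0.5))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.1, 1.2)), class = "oir_invalid_argument")
  set.seed(19)
  for (i in 1:60) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_brute(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
  }
})

test_that("per-target F-test behaves at its limits", {
  # identical group means with nonzero within-group spread: F ~ 0, p ~ 1
  v <- matrix(c(1, 2, 1, 2), nrow = 1)
  p <- per_target_test(v, c("a", "a", "b", "b"))
  expect_gt(p, 0.99)
  expect_error(per_target_test(v, c("a", "b", "b", "b")),
               class = "oir_insufficient_replicates")
  expect_error(per_target_test(matrix(1:2, 1), c("a", "b")),
               class = "oir_insufficient_replicates")
})

test_that("arcsine transform maps percentages to radians monotonically", {
  expect_equal(arcsine_transform(0), 0)
  expect_equal(arcsine_transform(100), pi / 2)
  expect_equal(arcsine_transform(25), pi / 6)
  x <- arcsine_transform(seq(0, 100, by = 0.5))
  expect_true(all(diff(x) > 0))
  expect_error(arcsine_transform(101), class = "oir_invalid_argument")
  expect_error(arcsine_transform(-1), class = "oir_invalid_argument")
})

test_that("spiked targets dominate fold ranking and pass FDR control", {
  base <- stats::setNames(seq(500, 2600, length.out = 43), sprintf("K%02d", 1:43))
  spiked <- sprintf("K%02d", c(3, 9, 17, 28, 40))
  mems <- list(); grp <- character(0)
  set.seed(31)
  for (g in 1:2) for (r in 1:4) {
    amps <- base * exp(rnorm(43, 0, 0.08)); names(amps) <- names(base)
    if (g == 2) amps[spiked] <- amps[spiked] * 4
    mb <- generate_array_membrane(
      membrane_spec(seed = 3100 + g * 10 + r,
                    exposure = exp(rnorm(1, 0, 0.15))),
      amplitudes = amps)
    mems <- c(mems, list(mb$image)); grp <- c(grp, c("ctrl", "vegf")[g])
  }
  res <- analyze_arrays(mems, factor(grp, levels = c("ctrl", "vegf")), mb$grid)
  top5 <- res$target[order(-res$fold_vegf)][1:5]
  expect_setequal(top5, spiked)
  expect_true(all(res$p_adj[res$target %in% spiked] <= 0.05))
})
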