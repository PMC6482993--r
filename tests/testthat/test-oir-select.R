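# helpers: a tiny bright-disc image and the default pipeline config

make_disc_image <- function(n = 64, r = 24, bg = 10, fg = 120) {
  d <- sqrt(outer(seq_len(n) - (n + 1) / 2, seq_len(n) - (n + 1) / 2,
                  function(a, b) a^2 + b^2))
  m <- matrix(bg, n, n)
  m[d <= r] <- fg
  list(img = m, disc = d <= r, d = d)
}

test_that("area report reproduces the canonical 40/20/40 control split", {
  ret <- matrix(FALSE, 100, 101); ret[1:100, 1:100] <- TRUE  # 10000 px
  av <- matrix(FALSE, 100, 101); av[1:40, 1:100] <- TRUE     # 4000 px
  nv <- matrix(FALSE, 100, 101); nv[41:60, 1:100] <- TRUE    # 2000 px
  vasc <- ret & !av
  rep <- compute_area_report(oir_mask_set(ret, vasc, nv, av))
  expect_equal(rep$avascular_pct, 40)
  expect_equal(rep$neovascular_pct, 20)
  expect_equal(rep$normal_vascular_pct, 40)
  expect_identical(sum(rep$counts[c("avascular", "neovascular", "normal")]),
                   rep$counts[["retina"]])

  rep0 <- compute_area_report(list(retina = ret, vascular = ret,
                                   neovascular = ret & FALSE,
                                   avascular = ret & FALSE))
  expect_equal(c(rep0$neovascular_pct, rep0$avascular_pct,
                 rep0$normal_vascular_pct), c(0, 0, 100))

  # avascular + neovascular exceeding the retina is a hierarchy violation
  big_av <- matrix(FALSE, 100, 101); big_av[, 1:101] <- TRUE
  expect_error(compute_area_report(list(retina = ret, vascular = ret,
                                        neovascular = nv, avascular = big_av)),
               class = "oir_mask_hierarchy")
  empty <- matrix(FALSE, 2, 2)
  expect_error(compute_area_report(list(retina = empty, vascular = empty,
                                        neovascular = empty, avascular = empty)),
               class = "oir_empty_retina")
})

test_that("avascular derivation is the complement of closed vasculature", {
  ret <- make_disc_image()$disc
  expect_equal(sum(derive_avascular(ret, ret, oir_config())), 0)
  none <- ret & FALSE
  expect_identical(derive_avascular(ret, none, oir_config()), ret)
  outside <- !ret
  expect_error(derive_avascular(ret, outside, oir_config()),
               class = "oir_mask_hierarchy")
})

test_that("retina segmentation fills holes and rejects empty images", {
  di <- make_disc_image()
  holey <- di$img
  holey[30:34, 30:34] <- 10  # dark interior hole
  mask <- segment_retina(oir_image(holey))
  expect_true(all(mask[30:34, 30:34]))
  expect_error(segment_retina(oir_image(matrix(0, 16, 16))),
               class = "oir_empty_retina")
})

test_that("vasculature is thresholded within the retina only", {
  di <- make_disc_image(n = 96, r = 40, bg = 5, fg = 80)
  img <- di$img
  inside <- di$d <= 20
  img[inside] <- 200                       # bright vessels inside
  img[5:8, 5:8] <- 250                     # bright blob outside the retina
  vasc <- segment_vasculature(oir_image(img), di$disc, oir_config(min_object_px = 0))
  expect_true(all(vasc[inside]))
  expect_false(any(vasc & !di$disc))       # intersection contract
  # uniform retina intensity cannot be split
  expect_error(segment_vasculature(oir_image(di$img), di$disc, oir_config()),
               class = "oir_degenerate_histogram")
})

test_that("pipeline recovers generator truth masks", {
  fm <- generate_flatmount(flatmount_spec(seed = 101))
  res <- run_oir_select(fm$image)
  expect_gte(iou_coef(res$masks$retina, fm$truth$retina), 0.95)
  vasc <- segment_vasculature(fm$image, res$masks$retina, oir_config())
  expect_gte(dice_coef(vasc, fm$truth$vessels), 0.80)
  nv <- segment_neovascular(fm$image, vasc, oir_config())
  expect_gte(dice_coef(nv, fm$truth$neovascular), 0.70)
  expect_false(any(nv & !vasc))            # subset by construction
})

test_that("tuft-free retinas yield an empty neovascular mask", {
  fm <- generate_flatmount(flatmount_spec(seed = 102, f_nv = 0))
  res <- run_oir_select(fm$image)
  expect_equal(res$report$neovascular_pct, 0)
  expect_equal(sum(res$masks$neovascular), 0)
})

test_that("pipeline output satisfies the exact partition and nesting", {
  for (seed in c(103, 104)) {
    fm <- generate_flatmount(flatmount_spec(seed = seed))
    res <- run_oir_select(fm$image)
    m <- res$masks; r <- res$report
    expect_true(all(m$neovascular <= m$vascular))
    expect_true(all(m$vascular <= m$retina))
    expect_true(all(m$avascular <= m$retina))
    expect_false(any(m$avascular & m$vascular))
    expect_true(all(m$retina == (m$avascular | m$vascular)))
    expect_identical(sum(r$counts[c("avascular", "neovascular", "normal")]),
                     r$counts[["retina"]])
    expect_equal(r$avascular_pct + r$neovascular_pct + r$normal_vascular_pct,
                 100, tolerance = 1e-12)
  }
})

test_that("reruns with the recorded thresholds reproduce masks exactly", {
  fm <- generate_flatmount(flatmount_spec(seed = 105))
  res <- run_oir_select(fm$image)
  th <- attr(res$report, "thresholds")
  cfg <- oir_config(t_retina = th$t_retina, t_vascular = th$t_vascular,
                    t_neovascular = th$t_neovascular,
                    closing_radius = th$closing_radius)
  res2 <- run_oir_select(fm$image, cfg)
  expect_identical(res$masks, res2$masks)
})

test_that("calibration scales areas quadratically and leaves percentages alone", {
  fm <- generate_flatmount(flatmount_spec(seed = 106))
  r1 <- run_oir_select(fm$image, oir_config(calibration = 2))$report
  r2 <- run_oir_select(fm$image, oir_config(calibration = 4))$report
  expect_equal(r2$retina_um2, 4 * r1$retina_um2)
  expect_equal(r1$avascular_pct, r2$avascular_pct)
  expect_equal(r1$neovascular_pct, r2$neovascular_pct)
})
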