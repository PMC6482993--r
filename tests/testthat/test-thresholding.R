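test_that("histograms count pixels, honor masks and rescale 16-bit input", {
  img <- oir_image(matrix(c(0, 255, 0, 255), 2, 2))
  h <- build_histogram(img)
  expect_equal(h$counts[1], 2)
  expect_equal(h$counts[256], 2)
  expect_equal(sum(h$counts), 4)

  mask <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)  # first row only
  hm <- build_histogram(img, mask)
  expect_equal(sum(hm$counts), 2)
  expect_equal(hm$counts[1], 2)

  img16 <- oir_image(matrix(c(0, 65535, 0, 65535), 2, 2), bit_depth = 16L)
  h16 <- build_histogram(img16)
  expect_equal(h16$counts[1], 2)
  expect_equal(h16$counts[256], 2)
  # bin map inverts back to the original gray range
  expect_equal(h16$bin_map$offset + 255 * h16$bin_map$scale, 65535)

  expect_error(build_histogram(img, matrix(FALSE, 2, 2)),
               class = "oir_empty_selection")
  expect_error(build_histogram(img, matrix(TRUE, 3, 3)),
               class = "oir_shape_mismatch")
})

test_that("Otsu returns the smallest maximizer of between-class variance", {
  counts <- integer(256); counts[c(51, 201)] <- 100  # bins 50 and 200
  r <- otsu_threshold(as_hist(counts))
  expect_equal(r$t, 50)
  b <- otsu_brute(counts)
  expect_equal(r$t, b$t)
  expect_equal(r$objective, b$objective)

  counts2 <- integer(256); counts2[c(1, 256)] <- 7  # bins 0 and 255
  expect_equal(otsu_threshold(as_hist(counts2))$t, 0)

  counts1 <- integer(256); counts1[100] <- 50
  expect_error(otsu_threshold(as_hist(counts1)),
               class = "oir_degenerate_histogram")
})

test_that("Huang returns the smallest minimizer of the fuzzy entropy", {
  counts <- integer(256); counts[c(51, 201)] <- 100
  r <- huang_threshold(as_hist(counts))
  b <- huang_brute(counts)
  expect_equal(r$t, b$t)
  expect_equal(r$objective, b$objective)

  counts1 <- integer(256); counts1[100] <- 50
  expect_error(huang_threshold(as_hist(counts1)),
               class = "oir_degenerate_histogram")
})

test_that("Huang objective is mirror-symmetric about the histogram center", {
  for (seed in 1:10) {
    counts <- random_histogram(seed)
    mir <- rev(counts)
    r <- huang_threshold(as_hist(counts))
    rm_ <- huang_threshold(as_hist(mir))
    # threshold t in the original maps to 254 - t in the mirrored histogram
    expect_equal(r$objective, rm_$objective, tolerance = 1e-9)
  }
})

test_that("both thresholds agree with exhaustive-search oracles", {
  for (seed in 1:40) {
    counts <- random_histogram(seed)
    h <- as_hist(counts)
    ro <- otsu_threshold(h); bo <- otsu_brute(counts)
    expect_identical(ro$t, as.integer(bo$t))
    rh <- huang_threshold(h); bh <- huang_brute(counts)
    expect_identical(rh$t, as.integer(bh$t))
  }
})

test_that("thresholds are count-scale invariant and shift equivariant", {
  for (seed in 11:25) {
    counts <- random_histogram(seed)
    h <- as_hist(counts)
    t_otsu <- otsu_threshold(h)$t
    t_huang <- huang_threshold(h)$t
    # integer count scaling
    hs <- as_hist(counts * 7L)
    expect_identical(otsu_threshold(hs)$t, t_otsu)
    expect_identical(huang_threshold(hs)$t, t_huang)
    # shift all occupied bins by +c without clipping
    occ <- which(counts > 0) - 1
    c_shift <- min(10, 255 - max(occ))
    if (c_shift > 0) {
      shifted <- integer(256)
      shifted[occ + c_shift + 1] <- counts[occ + 1]
      expect_identical(otsu_threshold(as_hist(shifted))$t,
                       t_otsu + as.integer(c_shift))
      expect_identical(huang_threshold(as_hist(shifted))$t,
                       t_huang + as.integer(c_shift))
    }
  }
})

test_that("apply_threshold splits the image into complementary masks", {
  img <- oir_image(matrix(c(0, 0, 255, 255), 1, 4))
  above <- apply_threshold(img, 0, "above")
  expect_equal(as.vector(above), c(FALSE, FALSE, TRUE, TRUE))
  below <- apply_threshold(img, 0, "below")
  expect_true(all(xor(above, below)))  # exact partition

  set.seed(7)
  m <- matrix(sample(0:255, 100, TRUE), 10)
  a <- apply_threshold(oir_image(m), 128, "above")
  b <- apply_threshold(oir_image(m), 128, "below")
  expect_true(all(a | b))
  expect_false(any(a & b))
})
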