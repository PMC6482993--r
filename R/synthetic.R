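# Seeded generators for flatmount images, CNV z-stacks and array membranes
# with exact ground truth. All randomness flows through set.seed(spec$seed),
# so a given spec is bit-reproducible.

#' Specification for a synthetic OIR flatmount
#'
#' Defaults emulate a P17 OIR control retina: a bright tissue disc with
#' petal cuts on a dark background, a central capillary-free (avascular)
#' zone occupying 40% of the retina, hyper-intense neovascular tufts at the
#' ischemic border occupying 20%, a stochastically branched vessel network
#' in the remaining territory, Gaussian noise and a smooth illumination
#' gradient. Intensity levels are ordered background < tissue < vessels <
#' tufts.
#'
#' @param seed Integer seed.
#' @param size Image side in pixels (square image).
#' @param retina_radius Retina disc radius in pixels.
#' @param petal_count,petal_angle Number and angular width (degrees) of the
#'   dissection wedges cut from the rim.
#' @param f_av,f_nv Requested avascular and neovascular area fractions of
#'   the retina (`f_av + f_nv < 1`).
#' @param n_walkers Vessel walkers seeded on the avascular border.
#' @param branch_prob Per-step branching probability of a walker.
#' @param vessel_width Vessel stroke radius in pixels.
#' @param vessel_coverage Fraction of the vascularized territory painted by
#'   vessel strokes; growth stops once reached.
#' @param tuft_intensity Tuft intensity as a multiple of the vessel level.
#' @param bg_level,tissue_level,vessel_level 8-bit intensity levels.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param illum_amp Relative amplitude of the left-right illumination ramp.
#' @return A `flatmount_spec` list.
#' @export
flatmount_spec <- function(seed = 1L, size = 320L, retina_radius = 140L,
                           petal_count = 4L, petal_angle = 22,
                           f_av = 0.40, f_nv = 0.20,
                           n_walkers = 110L, branch_prob = 0.10,
                           vessel_width = 2L, vessel_coverage = 0.28,
                           tuft_intensity = 1.8,
                           bg_level = 12, tissue_level = 80,
                           vessel_level = 170, noise_sd = 8,
                           illum_amp = 0.10) {
  if (f_av < 0 || f_nv < 0 || f_av + f_nv >= 1)
    abort_oir("need f_av >= 0, f_nv >= 0 and f_av + f_nv < 1",
              "oir_infeasible_fractions")
  if (!(bg_level < tissue_level && tissue_level < vessel_level &&
        vessel_level < vessel_level * tuft_intensity))
    abort_oir("intensity levels must be ordered background < tissue < vessel < tuft",
              "oir_invalid_argument")
  structure(as.list(environment()), class = "flatmount_spec")
}

.disc_offsets <- function(radius) {
  r <- ceiling(radius)
  dr <- rep(-r:r, times = 2L * r + 1L)
  dc <- rep(-r:r, each = 2L * r + 1L)
  keep <- dr^2 + dc^2 <= radius^2
  cbind(dr[keep], dc[keep])
}

#' Generate a synthetic OIR flatmount with ground truth
#'
#' @param spec A [flatmount_spec()].
#' @return A list with `image` (an [oir_image]) and `truth`, which holds
#'   the masks `retina`, `vascular` (vascularized territory,
#'   `retina - avascular`), `vessels` (painted vessel strokes),
#'   `neovascular`, `avascular`, and `fractions` (realized area fractions).
#'   The truth masks satisfy the OIR mask-set hierarchy exactly.
#' @export
generate_flatmount <- function(spec = flatmount_spec()) {
  set.seed(spec$seed)
  n <- spec$size
  ctr <- (n + 1) / 2
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  dx <- cols - ctr; dy <- rows - ctr
  dist <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx)

  R <- spec$retina_radius
  wedge <- matrix(FALSE, n, n)
  if (spec$petal_count > 0L) {
    half <- spec$petal_angle / 2 * pi / 180
    th <- 2 * pi * (seq_len(spec$petal_count) - 1) / spec$petal_count + pi / 4
    for (t0 in th) {
      d <- abs(((ang - t0 + pi) %% (2 * pi)) - pi)
      wedge <- wedge | (d < half & dist > 0.45 * R)
    }
  }
  retina <- dist <= R & !wedge
  n_ret <- sum(retina)

  # central avascular zone sized by the radial quantile of retina pixels
  if (spec$f_av > 0) {
    r_av <- stats::quantile(dist[retina], probs = spec$f_av, names = FALSE)
    av_zone <- retina & dist <= r_av
  } else {
    r_av <- 0
    av_zone <- matrix(FALSE, n, n)
  }
  territory <- retina & !av_zone    # where vessels may grow

  # stochastically branching random-walk vessel tree, grown outward from
  # the avascular border (or the center when there is no avascular zone)
  stroke <- .disc_offsets(spec$vessel_width)
  r_seed <- r_av + spec$vessel_width + 1   # roots just outside the border
  step_len <- 2
  vessels <- matrix(FALSE, n, n)
  vessel_px <- 0L
  target_vessel_px <- round(spec$vessel_coverage * sum(territory))

  paint_step <- function(r, c) {
    rr <- round(r) + stroke[, 1]; cc <- round(c) + stroke[, 2]
    ok <- rr >= 1L & rr <= n & cc >= 1L & cc <= n
    idx <- cbind(rr[ok], cc[ok])
    idx <- idx[territory[idx] & !vessels[idx], , drop = FALSE]
    if (nrow(idx) > 0L) {
      vessels[idx] <<- TRUE
      vessel_px <<- vessel_px + nrow(idx)
    }
  }
  walk <- function(r, c, dir, max_steps, radial_bias) {
    stack <- list(list(r = r, c = c, dir = dir))
    while (length(stack) > 0L) {
      w <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (s in seq_len(max_steps)) {
        w$dir <- w$dir + stats::rnorm(1, 0, 0.18)
        if (radial_bias > 0) {
          # pull the heading back toward the local outward radial direction
          out_ang <- atan2(w$r - ctr, w$c - ctr)
          w$dir <- w$dir + radial_bias * sin(out_ang - w$dir)
        }
        w$r <- w$r + step_len * sin(w$dir)
        w$c <- w$c + step_len * cos(w$dir)
        d <- sqrt((w$r - ctr)^2 + (w$c - ctr)^2)
        if (d > R + 2 || d < r_av - 1 ||
            w$r < 1 || w$r > n || w$c < 1 || w$c > n) break
        paint_step(w$r, w$c)
        if (stats::runif(1) < spec$branch_prob && length(stack) < 400L) {
          stack[[length(stack) + 1L]] <-
            list(r = w$r, c = w$c,
                 dir = w$dir + sample(c(-1, 1), 1) * stats::runif(1, 0.4, 0.9))
        }
      }
    }
  }

  # phase 1: radially biased mains from the avascular border to the rim
  if (sum(territory) > 0L) {
    seeds_ang <- seq(0, 2 * pi, length.out = spec$n_walkers + 1L)[-1L] +
      stats::runif(spec$n_walkers, -0.02, 0.02)
    for (a in seeds_ang)
      walk(ctr + r_seed * sin(a), ctr + r_seed * cos(a), a,
           max_steps = 200L, radial_bias = 0.25)
    # phase 2: capillary mesh grown from open territory until the
    # requested coverage is reached
    cohorts <- 0L
    while (vessel_px < target_vessel_px) {
      cohorts <- cohorts + 1L
      if (cohorts > 200L)
        abort_oir("vessel coverage target unreachable for this geometry",
                  "oir_infeasible_fractions")
      open <- which(territory & !vessels)
      if (length(open) == 0L) break
      pick <- open[sample.int(length(open), min(spec$n_walkers, length(open)))]
      for (i in pick) {
        r0 <- ((i - 1L) %% n) + 1L
        c0 <- ((i - 1L) %/% n) + 1L
        walk(r0, c0, stats::runif(1, 0, 2 * pi),
             max_steps = 40L, radial_bias = 0)
        if (vessel_px >= target_vessel_px) break
      }
    }
  }

  # neovascular tufts: bright blobs hugging the avascular border
  tufts <- matrix(FALSE, n, n)
  if (spec$f_nv > 0) {
    target_px <- round(spec$f_nv * n_ret)
    tries <- 0L
    while (sum(tufts) < target_px) {
      tries <- tries + 1L
      if (tries > 20000L)
        abort_oir("could not place the requested tuft area; fractions infeasible for this geometry",
                  "oir_infeasible_fractions")
      rt <- stats::runif(1, 3.5, 6.5)
      a <- stats::runif(1, 0, 2 * pi)
      rad <- r_av + rt + stats::runif(1, 0, 16)
      cy <- ctr + rad * sin(a); cx <- ctr + rad * cos(a)
      if (cy < 1 || cy > n || cx < 1 || cx > n) next
      if (!territory[round(cy), round(cx)]) next
      off <- .disc_offsets(rt)
      rr <- round(cy) + off[, 1]; cc <- round(cx) + off[, 2]
      ok <- rr >= 1L & rr <= n & cc >= 1L & cc <= n
      idx <- cbind(rr[ok], cc[ok])
      idx <- idx[territory[idx], , drop = FALSE]
      tufts[idx] <- TRUE
    }
  }

  vascular_strokes <- vessels | tufts
  neovascular <- tufts
  avascular <- av_zone
  vascular_territory <- territory

  img <- matrix(spec$bg_level, n, n)
  img[retina] <- spec$tissue_level
  img[vessels] <- spec$vessel_level
  img[tufts] <- spec$vessel_level * spec$tuft_intensity
  illum <- 1 + spec$illum_amp * ((cols / n) - 0.5)
  img <- img * illum + stats::rnorm(n * n, 0, spec$noise_sd)
  img <- round(pmin(pmax(img, 0), 255))

  fr <- c(avascular = sum(avascular) / n_ret,
          neovascular = sum(neovascular) / n_ret,
          normal_vascular = (n_ret - sum(avascular) - sum(neovascular)) / n_ret)

  list(image = oir_image(img, bit_depth = 8L),
       truth = list(retina = retina, vascular = vascular_territory,
                    vessels = vascular_strokes, neovascular = neovascular,
                    avascular = avascular, fractions = fr))
}

#' Specification for a synthetic CNV lesion z-stack
#'
#' A bright ellipsoidal lesion nested inside a burn region (cylindrical
#' through the full depth, or a concentric sphere), with a faint burn
#' autofluorescence level and Gaussian noise. Voxel dimensions default to
#' confocal serial sectioning at 1.5 um z-steps.
#'
#' @param seed Integer seed.
#' @param dims `c(rows, cols, slices)`.
#' @param dx,dy,dz Voxel dimensions in micrometers.
#' @param burn_shape `"cylinder"` or `"sphere"`.
#' @param burn_radius Burn radius in voxels (in-plane).
#' @param lesion_radii Ellipsoid semi-axes `c(rx, ry, rz)` in voxels; must
#'   fit inside the burn.
#' @param bg_level,burn_level,lesion_level 8-bit intensity levels.
#' @param noise_sd Gaussian voxel noise standard deviation.
#' @return A `cnv_spec` list.
#' @export
cnv_spec <- function(seed = 1L, dims = c(64L, 64L, 40L),
                     dx = 0.5, dy = 0.5, dz = 1.5,
                     burn_shape = c("cylinder", "sphere"),
                     burn_radius = 24, lesion_radii = c(12, 12, 10),
                     bg_level = 10, burn_level = 30, lesion_level = 200,
                     noise_sd = 5) {
  burn_shape <- match.arg(burn_shape)
  if (length(lesion_radii) == 1L) lesion_radii <- rep(lesion_radii, 3L)
  if (any(lesion_radii[1:2] > burn_radius) ||
      (burn_shape == "sphere" && any(lesion_radii > burn_radius)))
    abort_oir("lesion radii must fit inside the burn", "oir_lesion_exceeds_burn")
  structure(as.list(environment()), class = "cnv_spec")
}

#' Generate a synthetic CNV stack with ground truth
#'
#' @param spec A [cnv_spec()].
#' @return A list with `stack` (an [oir_stack]) and `truth` holding the
#'   `lesion` and `burn` masks and their true volumes in um^3.
#' @export
generate_cnv_stack <- function(spec = cnv_spec()) {
  set.seed(spec$seed)
  d <- spec$dims
  ctr <- (d + 1) / 2
  rows <- array(rep(seq_len(d[1]), times = d[2] * d[3]), dim = d)
  cols <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), dim = d)
  zs <- array(rep(seq_len(d[3]), each = d[1] * d[2]), dim = d)
  dr <- rows - ctr[1]; dc <- cols - ctr[2]; dzv <- zs - ctr[3]
  lr <- spec$lesion_radii
  lesion <- if (all(lr > 0))
    (dr / lr[1])^2 + (dc / lr[2])^2 + (dzv / lr[3])^2 <= 1
  else array(FALSE, dim = d)
  burn <- if (spec$burn_shape == "cylinder")
    dr^2 + dc^2 <= spec$burn_radius^2
  else dr^2 + dc^2 + dzv^2 <= spec$burn_radius^2
  if (any(lesion & !burn))
    abort_oir("lesion extends outside the burn", "oir_lesion_exceeds_burn")
  img <- array(spec$bg_level, dim = d)
  img[burn] <- spec$burn_level
  img[lesion] <- spec$lesion_level
  img <- round(pmin(pmax(img + stats::rnorm(prod(d), 0, spec$noise_sd), 0), 255))
  stack <- oir_stack(img, dx = spec$dx, dy = spec$dy, dz = spec$dz)
  vox <- spec$dx * spec$dy * spec$dz
  list(stack = stack,
       truth = list(lesion = lesion, burn = burn,
                    lesion_volume = sum(lesion) * vox,
                    burn_volume = sum(burn) * vox))
}

#' Specification for a synthetic array membrane
#'
#' Emulates a duplicate-spot phospho-kinase membrane: 43 targets spotted in
#' duplicate on a 9 x 10 grid with positive-control reference spots in the
#' four corners. Spots have Gaussian profiles; duplicates are jittered by
#' at most 1 pixel; a background offset and Gaussian noise are added. The
#' image is rendered 16-bit so bright spots do not saturate.
#'
#' @param seed Integer seed.
#' @param n_targets Number of duplicate-spot targets (default 43).
#' @param spacing Grid pitch in pixels.
#' @param spot_sigma Gaussian spot sigma in pixels.
#' @param radius,annulus_inner,annulus_outer Integration geometry recorded
#'   in the grid.
#' @param ref_amplitude Peak amplitude of the reference spots.
#' @param base_amplitude_range Range of per-target peak amplitudes drawn
#'   uniformly at spec creation (seeded).
#' @param bg_level Constant background offset.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param exposure Multiplicative exposure factor for the whole membrane.
#' @param rep_cv Per-target multiplicative (lognormal) replicate
#'   variability applied to the amplitudes at generation time.
#' @return A `membrane_spec` list (includes the spot layout).
#' @export
membrane_spec <- function(seed = 1L, n_targets = 43L, spacing = 16L,
                          spot_sigma = 2, radius = 5, annulus_inner = 6,
                          annulus_outer = 9, ref_amplitude = 2000,
                          base_amplitude_range = c(300, 3000),
                          bg_level = 100, noise_sd = 10,
                          exposure = 1, rep_cv = 0) {
  if (n_targets < 1L || n_targets > 43L)
    abort_oir("n_targets must lie in [1, 43] for the 9 x 10 layout",
              "oir_invalid_argument")
  structure(as.list(environment()), class = "membrane_spec")
}

# 9 x 10 layout: corners are reference spots; targets fill the remaining
# positions as horizontally adjacent duplicate pairs.
.membrane_layout <- function(spec) {
  nrow_g <- 9L; ncol_g <- 10L
  margin <- spec$spacing
  pos_r <- function(r) margin + (r - 1L) * spec$spacing
  pos_c <- function(c) margin + (c - 1L) * spec$spacing
  corners <- cbind(c(1L, 1L, nrow_g, nrow_g), c(1L, ncol_g, 1L, ncol_g))
  tgt_rows <- integer(0); tgt_cols <- integer(0)
  for (r in seq_len(nrow_g)) {
    cc <- if (r %in% c(1L, nrow_g)) 2:(ncol_g - 1L) else seq_len(ncol_g)
    tgt_rows <- c(tgt_rows, rep(r, length(cc)))
    tgt_cols <- c(tgt_cols, cc)
  }
  npairs <- length(tgt_rows) %/% 2L
  if (spec$n_targets > npairs)
    abort_oir("too many targets for the grid", "oir_invalid_grid")
  k <- spec$n_targets
  idx <- seq_len(2L * k)
  target <- sprintf("K%02d", rep(seq_len(k), each = 2L))
  spot_index <- rep(1:2, times = k)
  grid <- data.frame(
    target = c(target, rep("REF", 4L)),
    row_px = c(pos_r(tgt_rows[idx]), pos_r(corners[, 1])),
    col_px = c(pos_c(tgt_cols[idx]), pos_c(corners[, 2])),
    spot_index = c(spot_index, 1:4),
    is_reference = c(rep(FALSE, 2L * k), rep(TRUE, 4L)),
    stringsAsFactors = FALSE)
  list(grid = grid,
       img_dim = c(pos_r(nrow_g) + margin, pos_c(ncol_g) + margin))
}

#' Generate a synthetic array membrane with ground truth
#'
#' @param spec A [membrane_spec()].
#' @param amplitudes Optional named numeric vector of per-target peak
#'   amplitudes (names `K01`..); when omitted, amplitudes are drawn
#'   uniformly from `spec$base_amplitude_range` under the spec seed.
#' @return A list with `image` (16-bit [oir_image]), `grid` (a
#'   [spot_grid()] of nominal positions), `truth` (data.frame `target`,
#'   `amplitude`, `true_density`: integration of the noiseless rendered
#'   membrane, jitter included, over the nominal grid) and `ref_density`
#'   (true reference-spot mean).
#' @export
generate_array_membrane <- function(spec = membrane_spec(), amplitudes = NULL) {
  set.seed(spec$seed)
  lay <- .membrane_layout(spec)
  g <- lay$grid
  dimg <- lay$img_dim
  k <- spec$n_targets
  tnames <- sprintf("K%02d", seq_len(k))
  if (is.null(amplitudes)) {
    amplitudes <- stats::setNames(
      stats::runif(k, spec$base_amplitude_range[1], spec$base_amplitude_range[2]),
      tnames)
  } else {
    if (!all(tnames %in% names(amplitudes)))
      abort_oir("amplitudes must be named for every target", "oir_invalid_argument")
    amplitudes <- amplitudes[tnames]
  }
  amp_real <- amplitudes
  if (spec$rep_cv > 0)
    amp_real <- amp_real * exp(stats::rnorm(k, 0, spec$rep_cv))
  spot_amp <- ifelse(g$is_reference, spec$ref_amplitude,
                     amp_real[match(g$target, tnames)])
  jit_r <- sample(-1:1, nrow(g), replace = TRUE)
  jit_c <- sample(-1:1, nrow(g), replace = TRUE)

  img <- matrix(0, dimg[1], dimg[2])
  half <- ceiling(4 * spec$spot_sigma)
  off <- -half:half
  kernel_d2 <- outer(off^2, off^2, `+`)
  for (i in seq_len(nrow(g))) {
    r0 <- g$row_px[i] + jit_r[i]
    c0 <- g$col_px[i] + jit_c[i]
    patch <- spot_amp[i] * exp(-kernel_d2 / (2 * spec$spot_sigma^2))
    img[r0 + off, c0 + off] <- img[r0 + off, c0 + off] + patch
  }
  clean <- (img + spec$bg_level) * spec$exposure
  noisy <- clean + stats::rnorm(prod(dimg), 0, spec$noise_sd)
  noisy <- round(pmin(pmax(noisy, 0), 65535))

  grid <- spot_grid(g$target, g$row_px, g$col_px, g$spot_index,
                    g$is_reference, radius = spec$radius,
                    annulus_inner = spec$annulus_inner,
                    annulus_outer = spec$annulus_outer)
  clean_img <- oir_image(clean, bit_depth = 16L)
  true_d <- vapply(seq_len(nrow(g)), function(i)
    integrate_spot(clean_img, c(g$row_px[i], g$col_px[i]),
                   spec$radius, spec$annulus_inner, spec$annulus_outer),
    numeric(1))
  tgt <- !g$is_reference
  truth <- data.frame(
    target = tnames,
    amplitude = unname(amp_real),
    true_density = vapply(tnames, function(t)
      mean(true_d[tgt & g$target == t]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(image = oir_image(noisy, bit_depth = 16L), grid = grid,
       truth = truth, ref_density = mean(true_d[!tgt]))
}
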