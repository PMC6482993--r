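# Skeleton-based vascular-network metrics: total vessel length, branching
# index (junctions per mm^2) and gliding-box lacunarity.

# 8-neighbour shift list in circular order N, NE, E, SE, S, SW, W, NW.
.NB_ORDER <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                  c(1, 0), c(1, -1), c(0, -1), c(-1, -1))

.shift_mat <- function(m, dr, dc) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(0L, n, p)
  rs <- max(1, 1 - dr):min(n, n - dr)
  cs <- max(1, 1 - dc):min(p, p - dc)
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

.neighbor_stack <- function(m) lapply(.NB_ORDER, function(s) .shift_mat(m, s[1], s[2]))

#' Skeletonize a binary mask
#'
#' Topology-preserving thinning (Zhang-Suen, two-subiteration form) to
#' 8-connected unit-width centerlines. Connectivity and loop structure of
#' the source mask are preserved.
#'
#' @param mask Logical matrix.
#' @return Logical matrix of centerlines (a subset of `mask`).
#' @export
skeletonize <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      nb <- .neighbor_stack(m)
      B <- Reduce(`+`, nb)
      # A = number of 0 -> 1 transitions around the circular neighbour list
      A <- matrix(0L, nrow(m), ncol(m))
      for (k in 1:8) {
        nxt <- if (k == 8L) 1L else k + 1L
        A <- A + (nb[[k]] == 0L & nb[[nxt]] == 1L)
      }
      P2 <- nb[[1]]; P4 <- nb[[3]]; P6 <- nb[[5]]; P8 <- nb[[7]]
      if (sub == 1L) {
        cond <- P2 * P4 * P6 == 0L & P4 * P6 * P8 == 0L
      } else {
        cond <- P2 * P4 * P8 == 0L & P2 * P6 * P8 == 0L
      }
      del <- m == 1L & B >= 2L & B <= 6L & A == 1L & cond
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

#' Total centerline length
#'
#' Chain-code accounting over unique skeleton adjacencies: each axial
#' (horizontal/vertical) neighbour pair contributes 1 pixel of length, each
#' diagonal pair contributes sqrt(2), multiplied by the calibration. Note
#' that chain-code length is exact for axis-aligned and 45-degree segments
#' and overestimates intermediate angles by up to ~8%.
#'
#' @param skel Logical skeleton matrix.
#' @param calibration Micrometers per pixel (default 1 = pixel units).
#' @return Length in micrometers.
#' @export
vessel_length <- function(skel, calibration = 1) {
  if (!any(skel)) return(0)
  s <- skel
  n_ax <- sum(s[, -ncol(s)] & s[, -1]) + sum(s[-nrow(s), ] & s[-1, ])
  n_di <- sum(s[-nrow(s), -ncol(s)] & s[-1, -1]) +
          sum(s[-1, -ncol(s)] & s[-nrow(s), -1])
  (n_ax + sqrt(2) * n_di) * calibration
}

#' Junction (branch-point) count and density
#'
#' Junction pixels are skeleton pixels with at least three skeleton
#' neighbours; 8-connected clusters of junction pixels are merged and
#' counted once (thinning leaves small clumps at crossings which would
#' otherwise be over-counted).
#'
#' @param skel Logical skeleton matrix.
#' @param area_mm2 Analyzed area in mm^2 (must be positive).
#' @return A list with `junctions` (count) and `density` (per mm^2).
#' @export
junction_density <- function(skel, area_mm2) {
  if (!is.numeric(area_mm2) || area_mm2 <= 0)
    abort_oir("area_mm2 must be positive", "oir_invalid_argument")
  m <- matrix(as.integer(skel), nrow(skel), ncol(skel))
  B <- Reduce(`+`, .neighbor_stack(m))
  jpx <- skel & B >= 3L
  count <- max(label_components(jpx, 8L))
  list(junctions = count, density = count / area_mm2)
}

#' Gliding-box lacunarity
#'
#' For each box size `r`, every `r x r` window fully inside the image
#' (stride 1) contributes its foreground count `M_r`;
#' `Lambda(r) = var(M_r) / mean(M_r)^2` (population variance). The returned
#' lacunarity is the mean of `Lambda(r)` over `box_sizes`, the usual
#' single-figure summary per retina. Defaults to a dyadic ladder of box
#' sizes: powers of 2 from 2 up to a quarter of the smaller image dimension.
#'
#' @param mask Logical matrix (non-empty).
#' @param box_sizes Integer vector of box edge lengths; each must not
#'   exceed the smaller image dimension.
#' @return A single dimensionless value >= 0; attribute `"per_box"` carries
#'   `Lambda(r)` for each size.
#' @export
lacunarity <- function(mask, box_sizes = NULL) {
  if (!any(mask))
    abort_oir("lacunarity is undefined for an empty mask",
              "oir_undefined_lacunarity")
  mind <- min(dim(mask))
  if (is.null(box_sizes)) {
    rmax <- mind %/% 4L
    if (rmax < 2L)
      abort_oir("image too small for the default box-size ladder",
                "oir_invalid_argument")
    box_sizes <- 2^(1:floor(log2(rmax)))
  }
  if (any(box_sizes < 1L) || any(box_sizes > mind))
    abort_oir("box sizes must lie in [1, min image dimension]",
              "oir_invalid_argument")
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  # summed-area table with a zero border
  S <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
  S[-1, -1] <- t(apply(apply(m, 2, cumsum), 1, cumsum))
  lam <- vapply(box_sizes, function(r) {
    nr <- nrow(m) - r + 1L; nc <- ncol(m) - r + 1L
    i <- seq_len(nr); j <- seq_len(nc)
    M <- S[i + r, j + r, drop = FALSE] - S[i, j + r, drop = FALSE] -
         S[i + r, j, drop = FALSE] + S[i, j, drop = FALSE]
    mu <- mean(M)
    v <- mean((M - mu)^2)
    v / mu^2
  }, numeric(1))
  out <- mean(lam)
  attr(out, "per_box") <- stats::setNames(lam, box_sizes)
  out
}

#' Vessel-network metrics for a binary vessel mask
#'
#' Skeletonizes the mask and reports total vessel length (um), branching
#' index (junctions per mm^2 of analyzed area) and lacunarity. The analyzed
#' area defaults to `area_mask` (e.g. the retina mask) when given, else the
#' full image, so densities stay comparable across crops.
#'
#' @param mask Logical vessel mask.
#' @param um_per_px Micrometers per pixel.
#' @param area_mask Optional logical mask defining the analyzed area.
#' @param box_sizes Passed to [lacunarity()].
#' @return A `vessel_metrics` list: `total_length_um`, `junctions`,
#'   `branching_index`, `lacunarity`, `area_mm2`.
#' @export
analyze_vessels <- function(mask, um_per_px = 1, area_mask = NULL,
                            box_sizes = NULL) {
  skel <- skeletonize(mask)
  area_px <- if (is.null(area_mask)) length(mask) else sum(area_mask)
  area_mm2 <- area_px * (um_per_px / 1000)^2
  jd <- junction_density(skel, area_mm2)
  structure(list(
    total_length_um = vessel_length(skel, um_per_px),
    junctions = jd$junctions,
    branching_index = jd$density,
    lacunarity = as.numeric(lacunarity(mask, box_sizes)),
    area_mm2 = area_mm2), class = "vessel_metrics")
}

#' @export
print.vessel_metrics <- function(x, ...) {
  cat("Vessel network metrics\n")
  cat(sprintf("  total vessel length: %.1f um\n", x$total_length_um))
  cat(sprintf("  junctions: %d (%.2f per mm^2 over %.4f mm^2)\n",
              x$junctions, x$branching_index, x$area_mm2))
  cat(sprintf("  lacunarity: %.4f\n", x$lacunarity))
  invisible(x)
}
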