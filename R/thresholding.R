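#' Build a 256-bin gray-level histogram
#'
#' 8-bit images are binned identically (bin = gray value); 16-bit images are
#' min-max rescaled into 256 bins and the affine bin-to-gray mapping
#' recorded, mirroring how auto-thresholds are conventionally computed on
#' 256-bin histograms regardless of bit depth.
#'
#' @param image An [oir_image] (or numeric matrix, assumed 8-bit).
#' @param mask Optional logical matrix restricting which pixels are counted.
#' @return An `oir_histogram`: `counts` (256 integers, bins 0..255),
#'   `bin_map` (`offset`, `scale`, so gray = offset + bin * scale) and `n`.
#' @export
build_histogram <- function(image, mask = NULL) {
  image <- as_oir_image(image)
  px <- image$pixels
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(px)))
      abort_oir("mask shape must match image shape", "oir_shape_mismatch")
    if (!any(mask))
      abort_oir("mask selects no pixels", "oir_empty_selection")
    px <- px[mask]
  }
  bins_and_map <- .to_bins(px, image$bit_depth)
  counts <- tabulate(bins_and_map$bins + 1L, nbins = 256L)
  structure(
    list(counts = counts, bin_map = bins_and_map$map, n = length(px)),
    class = "oir_histogram")
}

# Map raw gray values to bin indices 0..255 plus the inverse-affine record.
.to_bins <- function(values, bit_depth) {
  if (bit_depth == 8L) {
    return(list(bins = as.integer(round(values)),
                map = list(offset = 0, scale = 1)))
  }
  vmin <- min(values); vmax <- max(values)
  if (vmax == vmin) {
    # constant image: everything in bin 0; degenerate for thresholding
    return(list(bins = integer(length(values)) ,
                map = list(offset = vmin, scale = 1)))
  }
  scale <- (vmax - vmin) / 255
  bins <- as.integer(round((values - vmin) / scale))
  list(bins = bins, map = list(offset = vmin, scale = scale))
}

#' @export
print.oir_histogram <- function(x, ...) {
  occ <- which(x$counts > 0L) - 1L
  cat(sprintf("<oir_histogram> n = %d, occupied bins = %d [%d..%d]\n",
              x$n, length(occ), min(occ), max(occ)))
  invisible(x)
}

.check_histogram <- function(hist) {
  if (!inherits(hist, "oir_histogram"))
    abort_oir("expected an oir_histogram", "oir_invalid_histogram")
  if (sum(hist$counts > 0L) < 2L)
    abort_oir("histogram has fewer than 2 occupied bins; cannot threshold",
              "oir_degenerate_histogram")
}

threshold_result <- function(method, t, objective = NULL) {
  structure(list(method = method, t = as.integer(t), objective = objective),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  obj <- if (is.null(x$objective)) "" else sprintf(", objective = %.6g", x$objective)
  cat(sprintf("<threshold_result> method = %s, t = %d%s\n", x$method, x$t, obj))
  invisible(x)
}

#' Otsu threshold (between-class variance)
#'
#' Selects the histogram split `t` maximizing the between-class variance
#' \deqn{\sigma_B^2(t) = \omega_0(t)\,\omega_1(t)\,[\mu_0(t)-\mu_1(t)]^2}
#' where \eqn{\omega} are the class probabilities and \eqn{\mu} the class
#' mean gray levels of bins \eqn{\le t} (background) versus \eqn{> t}
#' (foreground). Ties are broken toward the smallest `t`; both classes are
#' required to be non-empty.
#'
#' @param hist An `oir_histogram` from [build_histogram()].
#' @return A `threshold_result` with `method = "otsu"`, the bin index `t`
#'   in `[0, 254]` and the attained between-class variance.
#' @export
otsu_threshold <- function(hist) {
  .check_histogram(hist)
  counts <- as.numeric(hist$counts)
  n <- sum(counts)
  g <- 0:255
  p <- counts / n
  w0 <- cumsum(p)                  # P(bin <= t), index t+1
  s0 <- cumsum(p * g)              # partial first moment
  mu_tot <- s0[256L]
  w0t <- w0[1:255]; s0t <- s0[1:255]
  w1t <- 1 - w0t
  valid <- w0t > 0 & w1t > 0
  sigma2 <- rep(-Inf, 255L)
  mu0 <- s0t[valid] / w0t[valid]
  mu1 <- (mu_tot - s0t[valid]) / w1t[valid]
  sigma2[valid] <- w0t[valid] * w1t[valid] * (mu0 - mu1)^2
  t <- which.max(sigma2) - 1L      # first maximum => smallest t
  threshold_result("otsu", t, sigma2[t + 1L])
}

#' Huang threshold (minimum fuzzy entropy)
#'
#' Selects the split `t` minimizing the fuzzy Shannon entropy
#' \deqn{E(t) = \sum_g h(g)\, S(\mu_t(g)),\qquad
#'       \mu_t(g) = \frac{1}{1 + |g - m(t,g)|/C}}
#' where `m(t, g)` is the mean gray level of the class that bin `g` falls in
#' at threshold `t`, `C` is the occupied gray-level range
#' (`g_max - g_min`), and `S(u) = -u log u - (1-u) log(1-u)` with the
#' convention `S(0) = S(1) = 0`. Ties are broken toward the smallest `t`.
#'
#' @inheritParams otsu_threshold
#' @return A `threshold_result` with `method = "huang"` and the attained
#'   fuzzy entropy.
#' @export
huang_threshold <- function(hist) {
  .check_histogram(hist)
  counts <- as.numeric(hist$counts)
  g <- 0:255
  occ <- which(counts > 0L)
  gmin <- occ[1L] - 1L
  gmax <- occ[length(occ)] - 1L
  C <- gmax - gmin
  w0 <- cumsum(counts)
  s0 <- cumsum(counts * g)
  n <- w0[256L]; s_tot <- s0[256L]
  shannon <- function(u) {
    s <- numeric(length(u))
    inner <- u > 0 & u < 1
    ui <- u[inner]
    s[inner] <- -ui * log(ui) - (1 - ui) * log(1 - ui)
    s
  }
  best_t <- NA_integer_; best_e <- Inf
  for (t in gmin:(gmax - 1L)) {
    c0 <- w0[t + 1L]; c1 <- n - c0
    if (c0 <= 0 || c1 <= 0) next
    m0 <- s0[t + 1L] / c0
    m1 <- (s_tot - s0[t + 1L]) / c1
    m <- ifelse(g <= t, m0, m1)
    u <- 1 / (1 + abs(g - m) / C)
    e <- sum(counts * shannon(u))
    if (e < best_e) { best_e <- e; best_t <- t }
  }
  threshold_result("huang", best_t, best_e)
}

#' Apply a threshold to an image
#'
#' @param image An [oir_image] or matrix.
#' @param threshold A `threshold_result` or an integer bin index.
#' @param polarity `"above"` marks pixels whose bin exceeds `t`
#'   (foreground); `"below"` marks the complement (bin `<= t`).
#' @param bin_map Affine bin mapping from the histogram used to choose `t`;
#'   required for 16-bit images thresholded on a rescaled histogram. For
#'   8-bit images the identity map is assumed.
#' @return A logical matrix the same shape as the image.
#' @export
apply_threshold <- function(image, threshold, polarity = c("above", "below"),
                            bin_map = NULL) {
  polarity <- match.arg(polarity)
  image <- as_oir_image(image)
  t <- if (inherits(threshold, "threshold_result")) threshold$t
       else as.integer(threshold)
  if (t < 0L || t > 254L)
    abort_oir("threshold bin index must lie in [0, 254]", "oir_invalid_threshold")
  px <- image$pixels
  if (is.null(bin_map)) {
    if (image$bit_depth != 8L)
      abort_oir("bin_map is required to threshold a 16-bit image",
                "oir_invalid_threshold")
    bins <- px
  } else {
    # same rounding as histogram construction, so mask and counts agree
    bins <- round((px - bin_map$offset) / bin_map$scale)
  }
  m <- bins > t
  if (polarity == "below") m <- !m
  m
}
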