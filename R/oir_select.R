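#' Configuration for the OIR flatmount pipeline
#'
#' The pipeline is driven by four user-adjustable values, each
#' auto-initialized and overridable: the whole-retina threshold (Huang), the
#' vascular and neovascular thresholds (Otsu, computed on progressively
#' restricted histograms), and a closing radius that absorbs inter-capillary
#' gaps before the avascular complement is taken.
#'
#' @param t_retina,t_vascular,t_neovascular `"auto"` or a manual bin index
#'   in `[0, 254]`.
#' @param closing_radius Disc radius (pixels) for the vessel-closing step.
#' @param min_object_px Vascular specks smaller than this are removed.
#' @param nv_min_contrast Minimum within-vessel class-mean separation (in
#'   histogram bins) required before the bright class is accepted as
#'   neovascular tufts; below it the neovascular mask is empty. Guards
#'   against splitting pure noise on tuft-free retinas.
#' @param calibration Optional micrometers per pixel.
#' @return An `oir_config` list.
#' @export
oir_config <- function(t_retina = "auto", t_vascular = "auto",
                       t_neovascular = "auto", closing_radius = 6L,
                       min_object_px = 20L, nv_min_contrast = 40,
                       calibration = NULL) {
  chk_t <- function(t, name) {
    if (identical(t, "auto")) return(t)
    t <- as.integer(t)
    if (is.na(t) || t < 0L || t > 254L)
      abort_oir(sprintf("%s must be 'auto' or an integer in [0, 254]", name),
                "oir_invalid_argument")
    t
  }
  if (closing_radius < 0L || min_object_px < 0L)
    abort_oir("closing_radius and min_object_px must be >= 0",
              "oir_invalid_argument")
  structure(list(
    t_retina = chk_t(t_retina, "t_retina"),
    t_vascular = chk_t(t_vascular, "t_vascular"),
    t_neovascular = chk_t(t_neovascular, "t_neovascular"),
    closing_radius = as.integer(closing_radius),
    min_object_px = as.integer(min_object_px),
    nv_min_contrast = nv_min_contrast,
    calibration = calibration), class = "oir_config")
}

# threshold helper: auto (huang/otsu) or manual; returns threshold_result
.resolve_threshold <- function(hist, setting, auto_method) {
  if (identical(setting, "auto")) {
    if (auto_method == "huang") huang_threshold(hist) else otsu_threshold(hist)
  } else {
    threshold_result("manual", setting)
  }
}

#' Segment the whole retina from a flatmount image
#'
#' Huang-thresholds the full image (the dissected retina is the large bright
#' region on a dark background), fills interior holes and keeps the largest
#' 8-connected component, discarding petal-cut wedges and debris.
#'
#' @param image An [oir_image].
#' @param cfg An [oir_config()].
#' @return Logical retina mask with the threshold used attached as
#'   attribute `"threshold"`.
#' @export
segment_retina <- function(image, cfg = oir_config()) {
  image <- as_oir_image(image)
  hist <- build_histogram(image)
  tr <- tryCatch(.resolve_threshold(hist, cfg$t_retina, "huang"),
                 oir_degenerate_histogram = function(e)
                   abort_oir("image is single-valued; no retina to segment",
                             "oir_empty_retina"))
  mask <- apply_threshold(image, tr, "above", bin_map = hist$bin_map)
  if (!any(mask))
    abort_oir("retina threshold produced an empty mask", "oir_empty_retina")
  mask <- fill_holes(mask)
  mask <- largest_component(mask, 8L)
  attr(mask, "threshold") <- tr$t
  mask
}

#' Segment the vasculature within the retina
#'
#' Otsu threshold computed on the histogram restricted to retina pixels;
#' the resulting mask is intersected with the retina and components smaller
#' than `min_object_px` removed.
#'
#' @inheritParams segment_retina
#' @param retina Logical retina mask.
#' @return Logical vascular mask with attribute `"threshold"`.
#' @export
segment_vasculature <- function(image, retina, cfg = oir_config()) {
  image <- as_oir_image(image)
  if (!any(retina))
    abort_oir("retina mask is empty", "oir_empty_retina")
  hist <- build_histogram(image, mask = retina)
  tv <- .resolve_threshold(hist, cfg$t_vascular, "otsu")
  mask <- apply_threshold(image, tv, "above", bin_map = hist$bin_map) & retina
  mask <- remove_small_objects(mask, cfg$min_object_px, 8L)
  attr(mask, "threshold") <- tv$t
  mask
}

#' Segment neovascular tufts within the vasculature
#'
#' Second-stage Otsu on intensities restricted to vascular pixels; tufts are
#' the bright class. If the within-vessel class separation falls below
#' `nv_min_contrast` bins (no genuinely hyper-intense structures), the
#' empty mask is returned rather than splitting noise.
#'
#' @inheritParams segment_vasculature
#' @param vascular Logical vascular mask.
#' @return Logical tuft mask (possibly empty) with attributes
#'   `"threshold"` (NA when the guard fires) and `"contrast"`.
#' @export
segment_neovascular <- function(image, vascular, cfg = oir_config()) {
  image <- as_oir_image(image)
  if (!any(vascular))
    abort_oir("vascular mask is empty", "oir_empty_selection")
  empty <- array(FALSE, dim(image))
  hist <- tryCatch(build_histogram(image, mask = vascular),
                   oir_error = function(e) NULL)
  if (is.null(hist) || sum(hist$counts > 0L) < 2L) {
    attr(empty, "threshold") <- NA_integer_; attr(empty, "contrast") <- 0
    return(empty)
  }
  tn <- .resolve_threshold(hist, cfg$t_neovascular, "otsu")
  # class-mean separation in bin units at the chosen split
  g <- 0:255; cnt <- hist$counts
  lo <- g <= tn$t
  c0 <- sum(cnt[lo]); c1 <- sum(cnt[!lo])
  if (c0 == 0 || c1 == 0) {
    attr(empty, "threshold") <- NA_integer_; attr(empty, "contrast") <- 0
    return(empty)
  }
  contrast <- sum(cnt[!lo] * g[!lo]) / c1 - sum(cnt[lo] * g[lo]) / c0
  if (identical(cfg$t_neovascular, "auto") && contrast < cfg$nv_min_contrast) {
    attr(empty, "threshold") <- NA_integer_; attr(empty, "contrast") <- contrast
    return(empty)
  }
  mask <- apply_threshold(image, tn, "above", bin_map = hist$bin_map) & vascular
  attr(mask, "threshold") <- tn$t
  attr(mask, "contrast") <- contrast
  mask
}

#' Derive the avascular zone
#'
#' The avascular area is the part of the retina not reached by the closed
#' vasculature: `retina AND NOT close(vascular, radius)`. Closing with a
#' disc of `closing_radius` pixels absorbs normal inter-capillary spacing so
#' only genuinely capillary-free territory counts as avascular. The
#' effective vascular area is then `retina - avascular`, which makes the
#' avascular/vascular partition of the retina exact.
#'
#' @param retina,vascular Logical masks with `vascular` a subset of `retina`.
#' @param cfg An [oir_config()].
#' @return Logical avascular mask.
#' @export
derive_avascular <- function(retina, vascular, cfg = oir_config()) {
  if (any(vascular & !retina))
    abort_oir("vascular mask must be a subset of the retina mask",
              "oir_mask_hierarchy")
  closed <- close_mask(vascular, cfg$closing_radius)
  retina & !closed
}

#' Bundle the four OIR masks
#'
#' Validates the mask hierarchy: neovascular within vascular within retina,
#' avascular within retina and disjoint from vascular, and avascular plus
#' vascular covering the retina exactly.
#'
#' @param retina,vascular,neovascular,avascular Logical masks, same shape.
#' @return An `oir_masks` list.
#' @export
oir_mask_set <- function(retina, vascular, neovascular, avascular) {
  shp <- dim(retina)
  for (m in list(vascular, neovascular, avascular))
    if (!identical(dim(m), shp))
      abort_oir("all masks must share one shape", "oir_shape_mismatch")
  if (any(vascular & !retina) || any(neovascular & !vascular) ||
      any(avascular & !retina))
    abort_oir("mask hierarchy violated (need neovascular within vascular within retina, avascular within retina)",
              "oir_mask_hierarchy")
  if (any(avascular & vascular))
    abort_oir("avascular and vascular masks overlap", "oir_mask_hierarchy")
  if (any(retina & !(avascular | vascular)))
    abort_oir("avascular and vascular masks must cover the retina",
              "oir_mask_hierarchy")
  structure(list(retina = retina, vascular = vascular,
                 neovascular = neovascular, avascular = avascular),
            class = "oir_masks")
}

#' Percent-of-retina area accounting
#'
#' Computes the neovascular, avascular and normal vascular areas as
#' percentages of the total retinal area. The normal vascular area is the
#' total vascular area minus the neovascular area; pixel counts are integers
#' so the three percentages partition 100 exactly.
#'
#' @param masks An [oir_mask_set()] (or plain list with the four masks).
#' @param cfg An [oir_config()]; its `calibration` converts areas to um^2.
#' @return An `oir_area_report` with pixel/um^2 retina area and the three
#'   percentages.
#' @export
compute_area_report <- function(masks, cfg = oir_config()) {
  n_ret <- sum(masks$retina)
  n_av <- sum(masks$avascular)
  n_nv <- sum(masks$neovascular)
  if (n_ret == 0L) abort_oir("retina mask is empty", "oir_empty_retina")
  if (n_av + n_nv > n_ret)
    abort_oir("avascular + neovascular pixel counts exceed the retina",
              "oir_mask_hierarchy")
  n_norm <- n_ret - n_av - n_nv
  cal <- cfg$calibration
  structure(list(
    retina_px = n_ret,
    retina_um2 = if (is.null(cal)) NA_real_ else n_ret * cal^2,
    neovascular_pct = 100 * n_nv / n_ret,
    avascular_pct = 100 * n_av / n_ret,
    normal_vascular_pct = 100 * n_norm / n_ret,
    counts = c(retina = n_ret, avascular = n_av, neovascular = n_nv,
               normal = n_norm)), class = "oir_area_report")
}

#' @export
print.oir_area_report <- function(x, ...) {
  cat("OIR flatmount area report\n")
  cat(sprintf("  retina area: %d px%s\n", x$retina_px,
              if (is.na(x$retina_um2)) "" else sprintf(" (%.1f um^2)", x$retina_um2)))
  cat(sprintf("  neovascular:     %6.2f %%\n", x$neovascular_pct))
  cat(sprintf("  avascular:       %6.2f %%\n", x$avascular_pct))
  cat(sprintf("  normal vascular: %6.2f %%\n", x$normal_vascular_pct))
  th <- attr(x, "thresholds")
  if (!is.null(th))
    cat(sprintf("  thresholds: retina=%s vascular=%s neovascular=%s closing=%s\n",
                th$t_retina, th$t_vascular,
                ifelse(is.na(th$t_neovascular), "guarded", th$t_neovascular),
                th$closing_radius))
  invisible(x)
}

#' Run the full four-threshold OIR flatmount pipeline
#'
#' Composes retina, vascular and neovascular segmentation with the
#' avascular complement, reconciles the vascular mask to the exact retina
#' partition, and reports the three areas as percentages of the retina. The
#' thresholds actually used are recorded so a run can be reproduced exactly
#' with manual values.
#'
#' @inheritParams segment_retina
#' @return A list with `masks` (an `oir_masks`) and `report`
#'   (an `oir_area_report` carrying a `"thresholds"` attribute).
#' @export
run_oir_select <- function(image, cfg = oir_config()) {
  image <- as_oir_image(image)
  retina <- segment_retina(image, cfg)
  vascular_raw <- segment_vasculature(image, retina, cfg)
  neovascular <- segment_neovascular(image, vascular_raw, cfg)
  avascular <- derive_avascular(retina, vascular_raw, cfg)
  vascular <- retina & !avascular      # exact partition of the retina
  masks <- oir_mask_set(strip_attrs(retina), strip_attrs(vascular),
                        strip_attrs(neovascular), strip_attrs(avascular))
  report <- compute_area_report(masks, cfg)
  attr(report, "thresholds") <- list(
    t_retina = attr(retina, "threshold"),
    t_vascular = attr(vascular_raw, "threshold"),
    t_neovascular = attr(neovascular, "threshold"),
    closing_radius = cfg$closing_radius)
  list(masks = masks, report = report)
}

strip_attrs <- function(m) {
  attributes(m) <- list(dim = dim(m))
  m
}
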