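#' Spot-grid layout for a membrane array
#'
#' Describes where each capture-antibody spot sits on the membrane image:
#' every target appears as a duplicate spot pair, plus a set of
#' positive-control (reference) spots used for per-membrane normalization.
#'
#' @param target Character vector, one entry per spot.
#' @param row_px,col_px Spot centers in pixels (1-based).
#' @param spot_index 1 or 2 within each target's duplicate pair (ignored
#'   for reference spots).
#' @param is_reference Logical; reference spots are positive controls.
#' @param radius Spot integration disc radius in pixels.
#' @param annulus_inner,annulus_outer Background annulus radii; the annulus
#'   must not overlap the spot disc (`annulus_inner > radius`).
#' @return A `spot_grid` (a validated data.frame with the geometry as
#'   attributes).
#' @export
spot_grid <- function(target, row_px, col_px, spot_index, is_reference,
                      radius = 5, annulus_inner = 6, annulus_outer = 9) {
  df <- data.frame(target = as.character(target), row_px = row_px,
                   col_px = col_px, spot_index = as.integer(spot_index),
                   is_reference = as.logical(is_reference),
                   stringsAsFactors = FALSE)
  if (annulus_inner <= radius || annulus_outer <= annulus_inner)
    abort_oir("need radius < annulus_inner < annulus_outer",
              "oir_invalid_argument")
  if (!any(df$is_reference))
    abort_oir("grid must contain at least one reference spot",
              "oir_invalid_grid")
  tgt <- df[!df$is_reference, ]
  dup <- table(tgt$target)
  if (any(dup != 2L))
    abort_oir(sprintf("every target needs exactly 2 spots; offending: %s",
                      paste(names(dup)[dup != 2L], collapse = ", ")),
              "oir_invalid_grid")
  structure(df, class = c("spot_grid", "data.frame"),
            radius = radius, annulus_inner = annulus_inner,
            annulus_outer = annulus_outer)
}

#' Background-subtracted integrated spot density
#'
#' Sums intensities over the spot disc and subtracts `disc_area x
#' median(annulus)`, the robust local background estimate; negative results
#' are floored at 0.
#'
#' @param image An [oir_image] or matrix.
#' @param center `c(row, col)` spot center in pixels.
#' @param radius Disc radius.
#' @param annulus_inner,annulus_outer Background annulus radii.
#' @return Integrated density (non-negative scalar).
#' @export
integrate_spot <- function(image, center, radius = 5,
                           annulus_inner = 6, annulus_outer = 9) {
  px <- as.matrix(as_oir_image(image))
  r0 <- center[1]; c0 <- center[2]
  if (r0 - annulus_outer < 1 || r0 + annulus_outer > nrow(px) ||
      c0 - annulus_outer < 1 || c0 + annulus_outer > ncol(px))
    abort_oir("spot disc/annulus extends outside the image",
              "oir_out_of_bounds")
  win_r <- (r0 - annulus_outer):(r0 + annulus_outer)
  win_c <- (c0 - annulus_outer):(c0 + annulus_outer)
  sub <- px[win_r, win_c]
  dr <- matrix(win_r - r0, length(win_r), length(win_c))
  dc <- matrix(win_c - c0, length(win_r), length(win_c), byrow = TRUE)
  d2 <- dr^2 + dc^2
  disc <- d2 <= radius^2
  annulus <- d2 > annulus_inner^2 & d2 <= annulus_outer^2
  bg <- stats::median(sub[annulus])
  max(0, sum(sub[disc]) - sum(disc) * bg)
}

#' Quantify a membrane: per-target normalized densities
#'
#' Integrates every spot, averages each target's duplicate pair, and
#' normalizes to the membrane's positive-control reference spots so that
#' densities are comparable across membranes and exposures:
#' `normalized = raw * reference_constant / mean(reference densities)`.
#' With the default `reference_constant = 1`, densities are expressed as a
#' fraction of the membrane's own positive-control signal, which makes them
#' invariant to overall exposure. Passing the control membrane's reference
#' mean as the constant (the convention used by [analyze_arrays()]) puts
#' every membrane back on the control's density scale.
#'
#' @param image An [oir_image] or matrix.
#' @param grid A [spot_grid()].
#' @param reference_constant Optional scalar; see Details.
#' @return A data.frame `target`, `raw`, `normalized` (one row per target,
#'   in first-appearance order) with the membrane reference mean as
#'   attribute `"reference_mean"`.
#' @export
quantify_membrane <- function(image, grid, reference_constant = NULL) {
  radius <- attr(grid, "radius")
  ai <- attr(grid, "annulus_inner"); ao <- attr(grid, "annulus_outer")
  dens <- vapply(seq_len(nrow(grid)), function(i) {
    integrate_spot(image, c(grid$row_px[i], grid$col_px[i]), radius, ai, ao)
  }, numeric(1))
  ref_mean <- mean(dens[grid$is_reference])
  if (!is.finite(ref_mean) || ref_mean <= 0)
    abort_oir("reference spots have zero density; cannot normalize",
              "oir_normalization_error")
  k <- (reference_constant %||% 1) / ref_mean
  tgt <- grid[!grid$is_reference, ]
  tdens <- dens[!grid$is_reference]
  targets <- unique(tgt$target)
  raw <- vapply(targets, function(t) mean(tdens[tgt$target == t]), numeric(1))
  out <- data.frame(target = targets, raw = unname(raw),
                    normalized = unname(raw) * k, stringsAsFactors = FALSE)
  attr(out, "reference_mean") <- ref_mean
  out
}

#' Per-target fold change versus the untreated control
#'
#' @param treated,control Named numeric vectors of normalized densities, or
#'   data.frames with `target` and `normalized` columns (as returned by
#'   [quantify_membrane()]).
#' @return A data.frame `target`, `fold`, `defined`; targets whose control
#'   density is 0 are flagged `defined = FALSE` (fold `NA`) and should be
#'   excluded downstream.
#' @export
fold_changes <- function(treated, control) {
  as_named <- function(x) {
    if (is.data.frame(x)) stats::setNames(x$normalized, x$target)
    else if (!is.null(names(x))) x
    else abort_oir("densities must be named or carry a 'target' column",
                   "oir_invalid_argument")
  }
  tr <- as_named(treated); ct <- as_named(control)
  if (!setequal(names(tr), names(ct)))
    abort_oir("treated and control target sets differ", "oir_target_mismatch")
  ct <- ct[names(tr)]
  defined <- ct != 0
  fold <- ifelse(defined, tr / ct, NA_real_)
  data.frame(target = names(tr), fold = unname(fold),
             defined = unname(defined), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted values are `q(i) = min_{j >= i} min(1, p(j) * m / j)` on the
#' sorted p-values, returned in input order; declaring targets with
#' `q <= alpha` controls the false discovery rate at `alpha`.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    abort_oir("p-values must lie in [0, 1]", "oir_invalid_argument")
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-target one-way ANOVA F-test
#'
#' Classic fixed-effects one-way ANOVA (equal-variance F-test) applied to
#' each target independently; the resulting p-values are intended to be fed
#' to [bh_adjust()].
#'
#' @param values Numeric matrix, one row per target and one column per
#'   sample (e.g. normalized densities across replicate membranes).
#' @param group Factor (or coercible) of length `ncol(values)` assigning
#'   samples to treatment groups; at least 2 groups with at least 2
#'   replicates each.
#' @return Named numeric vector of p-values (one per target, row order).
#' @export
per_target_test <- function(values, group) {
  if (!is.matrix(values))
    abort_oir("'values' must be a targets x samples matrix",
              "oir_invalid_argument")
  group <- as.factor(group)
  if (length(group) != ncol(values))
    abort_oir("'group' length must equal the number of samples",
              "oir_invalid_argument")
  if (nlevels(group) < 2L || any(table(group) < 2L))
    abort_oir("need >= 2 groups with >= 2 replicates each",
              "oir_insufficient_replicates")
  p <- apply(values, 1L, function(y)
    stats::oneway.test(y ~ group, var.equal = TRUE)$p.value)
  stats::setNames(as.numeric(p), rownames(values))
}

#' Arcsine-square-root transform of percentage data
#'
#' Variance-stabilizing transform conventionally applied to percentage
#' readouts before parametric testing: `asin(sqrt(pct / 100))`, in radians.
#'
#' @param pct Numeric vector of percentages in `[0, 100]`.
#' @return Transformed values in `[0, pi/2]`.
#' @export
arcsine_transform <- function(pct) {
  if (anyNA(pct) || any(pct < 0 | pct > 100))
    abort_oir("percentages must lie in [0, 100]", "oir_invalid_argument")
  asin(sqrt(pct / 100))
}

#' End-to-end array comparison
#'
#' Quantifies replicate treated and control membranes against a shared
#' grid, computes per-target fold changes of group means, per-target
#' one-way F-tests across groups, and BH-adjusted p-values.
#'
#' @param membranes List of images (matrices or [oir_image]s), one per
#'   replicate membrane.
#' @param group Factor assigning membranes to groups; the first level is
#'   the untreated control.
#' @param grid A [spot_grid()] shared by all membranes.
#' @return An `array_result` data.frame: `target`, group-mean normalized
#'   densities, `fold`, `p`, `p_adj`.
#' @export
analyze_arrays <- function(membranes, group, grid) {
  group <- as.factor(group)
  if (length(membranes) != length(group))
    abort_oir("one group label per membrane required", "oir_invalid_argument")
  # reference constant: mean positive-control signal of the control group,
  # so all membranes are expressed on the control membranes' density scale
  ctrl_idx <- which(group == levels(group)[1])
  ref_const <- mean(vapply(membranes[ctrl_idx], function(m)
    attr(quantify_membrane(m, grid), "reference_mean"), numeric(1)))
  qs <- lapply(membranes, quantify_membrane, grid = grid,
               reference_constant = ref_const)
  targets <- qs[[1]]$target
  mat <- vapply(qs, function(q) q$normalized[match(targets, q$target)],
                numeric(length(targets)))
  rownames(mat) <- targets
  ctrl <- levels(group)[1]
  ctrl_mean <- rowMeans(mat[, group == ctrl, drop = FALSE])
  p <- per_target_test(mat, group)
  res <- data.frame(target = targets, stringsAsFactors = FALSE)
  for (g in levels(group))
    res[[paste0("mean_", g)]] <- rowMeans(mat[, group == g, drop = FALSE])
  fold_ref <- stats::setNames(ctrl_mean, targets)
  for (g in setdiff(levels(group), ctrl))
    res[[paste0("fold_", g)]] <-
      ifelse(fold_ref != 0, res[[paste0("mean_", g)]] / fold_ref, NA_real_)
  res$p <- unname(p)
  res$p_adj <- bh_adjust(res$p)
  structure(res, class = c("array_result", "data.frame"))
}
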