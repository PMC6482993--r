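#' Read a grayscale image or z-stack
#'
#' Reads 8/16-bit grayscale TIFF (single- or multi-page) and 8-bit PNG.
#' Multi-page TIFFs become an [oir_stack]; single pages an [oir_image].
#' Multi-channel inputs require an explicit channel index.
#'
#' @param path File path (`.tif`, `.tiff` or `.png`).
#' @param channel Channel index (1-based) for multi-channel images; must be
#'   given when the file has more than one channel.
#' @param calibration Optional micrometers per pixel (2D images).
#' @param dx,dy,dz Voxel dimensions for stacks (um), `dz` defaulting to
#'   1.5 um.
#' @return An [oir_image] or [oir_stack].
#' @export
read_image <- function(path, channel = NULL, calibration = NULL,
                       dx = 1, dy = 1, dz = 1.5) {
  if (!file.exists(path))
    abort_oir(sprintf("input file not found: %s", path), "oir_io_error")
  ext <- tolower(tools::file_ext(path))
  pick_channel <- function(a) {
    if (length(dim(a)) == 2L) return(a)
    nch <- dim(a)[3]
    if (is.null(channel))
      abort_oir(sprintf(
        "image has %d channels; pass channel = <index> to select one", nch),
        "oir_format_error")
    if (channel < 1L || channel > nch)
      abort_oir("channel index out of range", "oir_format_error")
    a[, , channel]
  }
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    bits <- attr(pages[[1]], "bits.per.sample") %||% 8L
    if (!bits %in% c(8L, 16L))
      abort_oir(sprintf("unsupported TIFF bit depth: %d", bits),
                "oir_format_error")
    mats <- lapply(pages, function(p) {
      m <- pick_channel(p)
      attributes(m) <- list(dim = dim(m))   # drop TIFF metadata attributes
      m
    })
    if (length(mats) == 1L)
      oir_image(mats[[1]], bit_depth = bits, calibration = calibration)
    else
      oir_stack(mats, dx = dx, dy = dy, dz = dz, bit_depth = as.integer(bits))
  } else if (ext == "png") {
    a <- png::readPNG(path)
    m <- round(pick_channel(a) * 255)
    storage.mode(m) <- "integer"
    attributes(m) <- list(dim = dim(m))
    oir_image(m, bit_depth = 8L, calibration = calibration)
  } else {
    abort_oir(sprintf("unsupported format '%s' (use TIFF or PNG)", ext),
              "oir_format_error")
  }
}

#' Write masks as a multi-page binary TIFF
#'
#' Masks are serialized as 8-bit pages with foreground 255.
#'
#' @param masks A named list of logical matrices (e.g. an `oir_masks`).
#' @param path Output `.tif` path.
#' @export
write_masks <- function(masks, path) {
  pages <- lapply(unclass(masks), function(m) {
    if (is.null(dim(m)) || !(is.logical(m) || all(m %in% c(0, 1))))
      abort_oir("masks must be binary matrices", "oir_invalid_argument")
    matrix(as.numeric(m), nrow(m), ncol(m))
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write a grayscale image or stack to TIFF
#' @param x An [oir_image], [oir_stack] or matrix (8-bit values assumed).
#' @param path Output `.tif` path.
#' @export
write_image <- function(x, path) {
  if (inherits(x, "oir_stack")) {
    maxv <- 2^x$bit_depth - 1
    pages <- lapply(seq_len(dim(x$voxels)[3]),
                    function(z) x$voxels[, , z] / maxv)
    tiff::writeTIFF(pages, path, bits.per.sample = x$bit_depth)
  } else {
    x <- as_oir_image(x)
    tiff::writeTIFF(x$pixels / (2^x$bit_depth - 1), path,
                    bits.per.sample = x$bit_depth)
  }
  invisible(path)
}

#' Write an analysis report as CSV
#'
#' Deterministic column order, percentages formatted to 4 decimal places,
#' thresholds and package version recorded per row, so re-running the same
#' analysis reproduces the file byte for byte.
#'
#' @param rows A data.frame (possibly zero rows).
#' @param path Output `.csv` path.
#' @export
write_report <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  out <- rows
  pct_cols <- grep("_pct$", names(out), value = TRUE)
  for (cn in pct_cols) out[[cn]] <- sprintf("%.4f", out[[cn]])
  if (nrow(out) > 0L)
    out$oirquant_version <- as.character(utils::packageVersion("oirquant"))
  else out$oirquant_version <- character(0)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# one-row data.frame for an OIR report
.oir_report_row <- function(image_name, report) {
  th <- attr(report, "thresholds")
  data.frame(
    image = image_name,
    retina_px = report$retina_px,
    retina_um2 = report$retina_um2,
    neovascular_pct = report$neovascular_pct,
    avascular_pct = report$avascular_pct,
    normal_vascular_pct = report$normal_vascular_pct,
    t_retina = th$t_retina %||% NA_integer_,
    t_vascular = th$t_vascular %||% NA_integer_,
    t_neovascular = th$t_neovascular %||% NA_integer_,
    closing_radius = th$closing_radius %||% NA_integer_,
    stringsAsFactors = FALSE)
}
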