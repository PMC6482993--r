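# Binary-mask morphology shared by the segmentation pipelines.
#
# Connected-component labelling is built on igraph over pixel-adjacency
# edges because the pipelines require 8-connectivity in 2D and
# 26-connectivity in 3D. Closing and hole filling delegate to EBImage.

# Half-neighbourhood shift sets (each undirected adjacency counted once).
.SHIFTS_2D_8 <- rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
.SHIFTS_2D_4 <- rbind(c(0, 1), c(1, 0))

.shifts_3d_26 <- function() {
  s <- as.matrix(expand.grid(dr = -1:1, dc = -1:1, dz = -1:1))
  s <- s[!(s[, 1] == 0 & s[, 2] == 0 & s[, 3] == 0), , drop = FALSE]
  # keep lexicographically positive half
  keep <- s[, 3] > 0 | (s[, 3] == 0 & (s[, 2] > 0 | (s[, 2] == 0 & s[, 1] > 0)))
  s[keep, , drop = FALSE]
}
.SHIFTS_3D_26 <- .shifts_3d_26()

#' Label connected components of a binary mask
#'
#' @param mask Logical matrix (2D) or 3D logical array.
#' @param connectivity 8 or 4 for 2D masks; 26 or 6 for 3D masks.
#' @return Integer array of the same shape: 0 for background, components
#'   numbered from 1 in first-pixel order.
#' @export
label_components <- function(mask, connectivity = if (length(dim(mask)) == 3L) 26L else 8L) {
  d <- dim(mask)
  lab <- array(0L, d)
  fg <- which(mask)
  nfg <- length(fg)
  if (nfg == 0L) return(lab)
  id <- array(0L, d)
  id[fg] <- seq_len(nfg)
  shifts <- if (length(d) == 3L) {
    if (connectivity == 26L) .SHIFTS_3D_26
    else if (connectivity == 6L) rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
    else abort_oir("3D connectivity must be 6 or 26", "oir_invalid_argument")
  } else {
    if (connectivity == 8L) .SHIFTS_2D_8
    else if (connectivity == 4L) .SHIFTS_2D_4
    else abort_oir("2D connectivity must be 4 or 8", "oir_invalid_argument")
  }
  edges <- vector("list", nrow(shifts))
  for (k in seq_len(nrow(shifts))) {
    sh <- shifts[k, ]
    a <- .offset_slab(d, sh, lead = TRUE)
    b <- .offset_slab(d, sh, lead = FALSE)
    ma <- .index_array(mask, a); mb <- .index_array(mask, b)
    both <- ma & mb
    if (!any(both)) next
    ia <- .index_array(id, a)[both]
    ib <- .index_array(id, b)[both]
    edges[[k]] <- rbind(ia, ib)
  }
  em <- do.call(cbind, edges)
  if (is.null(em)) {
    memb <- seq_len(nfg)  # all isolated pixels
  } else {
    gr <- igraph::make_graph(as.vector(em), n = nfg, directed = FALSE)
    memb <- igraph::components(gr)$membership
  }
  # renumber in order of first appearance for determinism
  memb <- match(memb, unique(memb))
  lab[fg] <- memb
  lab
}

# Index ranges for a shifted overlap between an array and itself.
.offset_slab <- function(d, sh, lead) {
  lapply(seq_along(d), function(i) {
    s <- sh[i]
    if (lead) seq_len(d[i] - abs(s)) + max(s, 0)
    else      seq_len(d[i] - abs(s)) + max(-s, 0)
  })
}

.index_array <- function(x, idx) {
  if (length(idx) == 2L) x[idx[[1]], idx[[2]], drop = FALSE]
  else x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Keep only the largest connected component
#'
#' @inheritParams label_components
#' @return Logical array; empty input stays empty. Ties go to the
#'   first-labelled (earliest-pixel) component.
#' @export
largest_component <- function(mask, connectivity = if (length(dim(mask)) == 3L) 26L else 8L) {
  lab <- label_components(mask, connectivity)
  nlab <- max(lab)
  if (nlab == 0L) return(array(FALSE, dim(mask)))
  sizes <- tabulate(lab[lab > 0L], nbins = nlab)
  lab == which.max(sizes)
}

#' Remove connected components smaller than a pixel count
#' @inheritParams label_components
#' @param min_px Components with fewer pixels are dropped.
#' @export
remove_small_objects <- function(mask, min_px, connectivity = 8L) {
  if (min_px <= 1L || !any(mask)) return(mask)
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- which(sizes >= min_px)
  array(lab %in% keep & mask, dim(mask))
}

#' Fill interior holes of a 2D binary mask
#' @param mask Logical matrix.
#' @export
fill_holes <- function(mask) {
  filled <- EBImage::fillHull(mask * 1L)
  filled > 0
}

#' Morphological closing with a disc structuring element
#'
#' @param mask Logical matrix.
#' @param radius Disc radius in pixels; 0 returns the mask unchanged.
#' @export
close_mask <- function(mask, radius) {
  if (radius <= 0L) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  EBImage::closing(mask * 1L, brush) > 0
}
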