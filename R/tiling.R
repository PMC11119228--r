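# --- tissue detection ---------------------------------------------------

#' Detect tissue on an RGB raster
#'
#' Computes the HSV saturation channel, thresholds it with Otsu's method
#' (via EBImage) and removes connected components smaller than `min_area`
#' pixels. Rasters whose saturation never exceeds `blank_sat` (near-white
#' scans) return an empty mask rather than letting Otsu split noise.
#'
#' @param pixels numeric array H x W x 3 with values in \[0,1\], or a
#'   `synthetic_slide`.
#' @param min_area connected components smaller than this many pixels are
#'   dropped (default: one 64 px patch; pipelines pass `patch_size^2`).
#' @param blank_sat saturation below which the raster counts as blank.
#' @return logical H x W matrix of class `tissue_mask`.
#' @export
detect_tissue <- function(pixels, min_area = 64^2, blank_sat = 0.08) {
  if (inherits(pixels, "synthetic_slide")) pixels <- pixels$pixels
  assert_that(length(dim(pixels)) == 3 && dim(pixels)[3] == 3,
              "detect_tissue expects an RGB raster (H x W x 3)")
  mx <- pmax(pixels[, , 1], pixels[, , 2], pixels[, , 3])
  mn <- pmin(pixels[, , 1], pixels[, , 2], pixels[, , 3])
  sat <- (mx - mn) / pmax(mx, 1e-8)
  if (max(sat) < blank_sat) {
    mask <- matrix(FALSE, nrow(sat), ncol(sat))
    class(mask) <- c("tissue_mask", class(mask))
    return(mask)
  }
  th <- EBImage::otsu(sat, range = c(0, 1))
  mask <- sat > th
  if (min_area > 0 && any(mask)) {
    lab <- EBImage::bwlabel(mask)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_area)
    mask <- matrix(lab %in% keep & lab > 0, nrow(mask), ncol(mask))
  }
  class(mask) <- c("tissue_mask", class(mask))
  mask
}

# --- tiling -------------------------------------------------------------

#' Tile a slide into a bag of fixed-size patches
#'
#' Lays a non-overlapping grid of `patch_size` x `patch_size` cells over the
#' raster (stride = patch size; trailing partial rows/columns are dropped)
#' and keeps every cell whose tissue fraction is at least `min_tissue_frac`.
#' Patch anchors are 0-based, half-open `[x0, x0+p) x [y0, y0+p)` with x
#' along rows and y along columns, sorted row-major. The bag inherits the
#' slide's label.
#'
#' @param slide a `synthetic_slide` or an H x W x 3 array.
#' @param mask tissue mask from [detect_tissue()] (same dimensions).
#' @param patch_size patch side in pixels.
#' @param min_tissue_frac minimum within-cell tissue fraction (default 0.5).
#' @param keep_pixels store the full-resolution patch pixels in the bag.
#' @return object of class `wsi_bag`: list with `slide_id`, `patient_id`,
#'   `label`, `patch_size`, `anchors` (data.frame `x0`, `y0`),
#'   `tissue_frac`, `evidence_frac` (when the slide carries a ground-truth
#'   evidence mask), and `pixels` (p x p x 3 x N array if kept).
#' @export
tile <- function(slide, mask, patch_size = 256, min_tissue_frac = 0.5,
                 keep_pixels = TRUE) {
  px <- if (inherits(slide, "synthetic_slide")) slide$pixels else slide
  assert_that(length(dim(px)) == 3 && dim(px)[3] == 3, "slide must be H x W x 3")
  assert_that(all(dim(mask)[1:2] == dim(px)[1:2]),
              "mask and slide dimensions differ")
  assert_that(min_tissue_frac >= 0 && min_tissue_frac <= 1,
              "min_tissue_frac must lie in [0, 1]")
  p <- as.integer(patch_size)
  H <- dim(px)[1]; W <- dim(px)[2]
  gh <- H %/% p; gw <- W %/% p
  assert_that(gh >= 1 && gw >= 1, "raster smaller than one patch")
  cell_frac <- function(m) {
    mm <- m[seq_len(gh * p), seq_len(gw * p), drop = FALSE] * 1
    dim(mm) <- c(p, gh, p, gw)
    apply(mm, c(2, 4), sum) / p^2
  }
  frac <- cell_frac(mask)
  keep <- which(frac >= min_tissue_frac - 1e-12, arr.ind = TRUE)
  if (nrow(keep) == 0) {
    warning("empty tissue mask at this tiling: returning an empty bag")
  }
  # row-major over the raster: sort by x0 (rows) then y0 (cols)
  ord <- order(keep[, 1], keep[, 2])
  keep <- keep[ord, , drop = FALSE]
  anchors <- data.frame(x0 = (keep[, 1] - 1L) * p, y0 = (keep[, 2] - 1L) * p)
  n <- nrow(anchors)
  ev_frac <- NULL
  if (inherits(slide, "synthetic_slide")) {
    evf <- cell_frac(slide$evidence_mask)
    ev_frac <- evf[keep]
  }
  pixels <- NULL
  if (keep_pixels && n > 0) {
    pixels <- array(0, c(p, p, 3, n))
    for (i in seq_len(n)) {
      pixels[, , , i] <- px[anchors$x0[i] + 1:p, anchors$y0[i] + 1:p, ]
    }
  }
  structure(
    list(
      slide_id = if (inherits(slide, "synthetic_slide")) slide$slide_id else NA_character_,
      patient_id = if (inherits(slide, "synthetic_slide")) slide$patient_id else NA_character_,
      label = if (inherits(slide, "synthetic_slide")) slide$label else NA_integer_,
      patch_size = p,
      anchors = anchors,
      tissue_frac = unname(frac[keep]),
      evidence_frac = ev_frac,
      pixels = pixels,
      n = n
    ),
    class = "wsi_bag"
  )
}

#' @export
print.wsi_bag <- function(x, ...) {
  cat(sprintf("<wsi_bag %s: %d patches of %d px, label %s>\n",
              x$slide_id %||% "?", x$n, x$patch_size, x$label))
  invisible(x)
}

#' Export bag patch coordinates as CSV
#'
#' Writes (slide_id, x0, y0, patch_size) rows, 0-based half-open anchors.
#'
#' @param bag a `wsi_bag`.
#' @param path CSV path.
#' @export
write_bag_csv <- function(bag, path) {
  df <- data.frame(slide_id = bag$slide_id, x0 = bag$anchors$x0,
                   y0 = bag$anchors$y0, patch_size = bag$patch_size)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Downsample bag patches to the feature-extractor input resolution and
# flatten each patch to a feature row. Returns matrix N x (d*d*3).
bag_input_matrix <- function(bag, input_px = 32) {
  assert_that(bag$n > 0, "bag %s is empty", bag$slide_id %||% "?")
  assert_that(!is.null(bag$pixels), "bag carries no pixels")
  f <- bag$patch_size / input_px
  assert_that(f == as.integer(f), "patch_size must be a multiple of input_px")
  X <- matrix(0, bag$n, input_px * input_px * 3)
  for (i in seq_len(bag$n)) {
    X[i, ] <- as.vector(block_reduce(bag$pixels[, , , i], as.integer(f)))
  }
  X
}

# Compact a bag for model consumption: precompute the downsampled input
# matrix and drop full-resolution pixels (memory control for large runs).
prepare_bag <- function(bag, input_px = 32, drop_pixels = TRUE) {
  bag$input <- bag_input_matrix(bag, input_px)
  bag$input_px <- input_px
  if (drop_pixels) bag$pixels <- NULL
  bag
}
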