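# --- attention heatmaps and top-attention patches -----------------------

#' Min-max normalize attention scores
#'
#' `(s - min) / (max - min)`; a constant vector maps to all zeros (so a bag
#' with no informative patch renders as visually null).
#'
#' @param scores nonempty numeric vector.
#' @return normalized scores in \[0, 1\].
#' @export
minmax_normalize <- function(scores) {
  assert_that(length(scores) > 0, "cannot normalize an empty score vector")
  rng <- range(scores)
  if (rng[2] - rng[1] < .Machine$double.eps) {
    return(rep(0, length(scores)))
  }
  (scores - rng[1]) / (rng[2] - rng[1])
}

# Fixed blue -> yellow -> red colormap (byte-stable, no external palettes).
heat_colormap <- function(v) {
  r <- pmin(1, pmax(0, 2 * v))
  g <- pmin(1, pmax(0, 1.6 * (1 - abs(v - 0.5) * 2) + 0.2))
  b <- pmin(1, pmax(0, 2 * (1 - v) - 0.6))
  cbind(r, g, b)
}

#' Render an attention heatmap over a slide
#'
#' Paints each retained patch rectangle with its min-max-normalized
#' attention score; regions outside retained patches are zero (fully
#' transparent in the PNG). Rendering is pure: identical inputs yield
#' byte-identical PNGs.
#'
#' @param bag a `wsi_bag`.
#' @param result an `attention_result` (or a bare score vector) aligned
#'   1:1 with the bag's patches.
#' @param slide_dim raster dimensions c(H, W); defaults to the grid extent.
#' @param path optional PNG output path (RGBA, fixed colormap).
#' @return object of class `attention_heatmap`: list with `values`
#'   (H x W matrix of normalized scores, 0 off-tissue), `normalized`
#'   (per-patch normalized scores) and `colormap` tag.
#' @export
render_heatmap <- function(bag, result, slide_dim = NULL, path = NULL) {
  scores <- if (inherits(result, "attention_result")) result$scores else result
  assert_that(length(scores) == bag$n,
              "scores (%d) do not align with bag patches (%d)",
              length(scores), bag$n)
  p <- bag$patch_size
  H <- (slide_dim %||% c(max(bag$anchors$x0) + p, max(bag$anchors$y0) + p))[1]
  W <- (slide_dim %||% c(max(bag$anchors$x0) + p, max(bag$anchors$y0) + p))[2]
  nv <- minmax_normalize(scores)
  vals <- matrix(0, H, W)
  covered <- matrix(FALSE, H, W)
  for (i in seq_len(bag$n)) {
    vals[bag$anchors$x0[i] + 1:p, bag$anchors$y0[i] + 1:p] <- nv[i]
    covered[bag$anchors$x0[i] + 1:p, bag$anchors$y0[i] + 1:p] <- TRUE
  }
  if (!is.null(path)) {
    rgb <- heat_colormap(as.vector(vals))
    img <- array(0, c(H, W, 4))
    img[, , 1] <- rgb[, 1]
    img[, , 2] <- rgb[, 2]
    img[, , 3] <- rgb[, 3]
    img[, , 4] <- as.numeric(covered)
    png::writePNG(img, path)
  }
  structure(list(values = vals, normalized = nv, covered = covered,
                 colormap = "fixed-bgr-ramp", slide_id = bag$slide_id),
            class = "attention_heatmap")
}

#' Extract the top-k patches by attention score
#'
#' Patches are sorted by attention score descending; ties are broken by
#' row-major anchor order.
#'
#' @param bag a `wsi_bag`.
#' @param result `attention_result` or score vector aligned with the bag.
#' @param k number of patches to return (`k <= N`).
#' @param dir optional directory: each selected patch is written as
#'   `<slide_id>_x<My>_y<N>.png` (requires the bag to carry pixels).
#' @return data.frame with `rank`, `slide_id`, `x0`, `y0`, `patch_size`,
#'   `score`, `normalized_score`, and (when pixels are available) a list
#'   column `pixels` of p x p x 3 arrays.
#' @export
top_patches <- function(bag, result, k, dir = NULL) {
  scores <- if (inherits(result, "attention_result")) result$scores else result
  assert_that(length(scores) == bag$n, "scores do not align with bag patches")
  assert_that(k >= 1 && k <= bag$n, "k must be between 1 and the bag size (%d)", bag$n)
  ord <- order(-scores, bag$anchors$x0, bag$anchors$y0)[seq_len(k)]
  nv <- minmax_normalize(scores)
  out <- data.frame(
    rank = seq_len(k),
    slide_id = bag$slide_id %||% NA_character_,
    x0 = bag$anchors$x0[ord],
    y0 = bag$anchors$y0[ord],
    patch_size = bag$patch_size,
    score = scores[ord],
    normalized_score = nv[ord],
    stringsAsFactors = FALSE
  )
  if (!is.null(bag$pixels)) {
    out$pixels <- lapply(ord, function(i) bag$pixels[, , , i])
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      for (j in seq_len(k)) {
        png::writePNG(out$pixels[[j]],
                      file.path(dir, sprintf("%s_x%d_y%d.png", out$slide_id[j],
                                             out$x0[j], out$y0[j])))
      }
    }
  }
  out
}

#' Export per-patch attention scores as CSV
#'
#' Columns: slide_id, x0, y0, score, normalized_score (0-based half-open
#' anchors, the same convention as [write_bag_csv()]).
#'
#' @param bag a `wsi_bag`.
#' @param result `attention_result` or score vector.
#' @param path CSV path.
#' @export
write_attention_csv <- function(bag, result, path) {
  scores <- if (inherits(result, "attention_result")) result$scores else result
  assert_that(length(scores) == bag$n, "scores do not align with bag patches")
  utils::write.csv(
    data.frame(slide_id = bag$slide_id, x0 = bag$anchors$x0,
               y0 = bag$anchors$y0, score = scores,
               normalized_score = minmax_normalize(scores)),
    path, row.names = FALSE
  )
  invisible(path)
}
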