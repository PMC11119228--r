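# --- low-level raster helpers -------------------------------------------

# Smooth random field on an S x S raster: iid normal values on a coarse
# (cells+1)^2 grid, bilinearly interpolated. Cheap stand-in for band-limited
# noise; `cells` sets the spatial frequency.
smooth_noise <- function(S, cells) {
  g <- matrix(stats::rnorm((cells + 1)^2), cells + 1, cells + 1)
  u <- (seq_len(S) - 1) / max(S - 1, 1) * cells
  i0 <- pmin(floor(u), cells - 1)
  fr <- u - i0
  i0 <- i0 + 1
  # separable bilinear interpolation
  a <- g[i0, i0, drop = FALSE]
  b <- g[i0 + 1, i0, drop = FALSE]
  cc <- g[i0, i0 + 1, drop = FALSE]
  d <- g[i0 + 1, i0 + 1, drop = FALSE]
  fx <- matrix(fr, S, S)
  fy <- matrix(fr, S, S, byrow = TRUE)
  a * (1 - fx) * (1 - fy) + b * fx * (1 - fy) + cc * (1 - fx) * fy + d * fx * fy
}

# Mean-pool an S x S (x C) raster by an integer factor.
block_reduce <- function(x, f) {
  if (f == 1) return(x)
  if (length(dim(x)) == 2) {
    S1 <- dim(x)[1]; S2 <- dim(x)[2]
    stopifnot(S1 %% f == 0, S2 %% f == 0)
    dim(x) <- c(f, S1 / f, S2)
    x <- colMeans(x)                      # (S1/f) x S2
    dim(x) <- c(S1 / f, f, S2 / f)
    x <- aperm(x, c(2, 1, 3))
    dim(x) <- c(f, (S1 / f) * (S2 / f))
    out <- colMeans(x)
    dim(out) <- c(S1 / f, S2 / f)
    out
  } else {
    out <- vapply(seq_len(dim(x)[3]),
                  function(k) block_reduce(x[, , k], f),
                  matrix(0, dim(x)[1] / f, dim(x)[2] / f))
    out
  }
}

# Stamp filled disks of radius r at (rows, cols) into logical S x S mask.
stamp_disks <- function(S, rows, cols, r) {
  off <- expand.grid(dr = -r:r, dc = -r:r)
  off <- off[off$dr^2 + off$dc^2 <= r^2, ]
  m <- matrix(FALSE, S, S)
  for (i in seq_along(rows)) {
    rr <- rows[i] + off$dr
    cx <- cols[i] + off$dc
    keep <- rr >= 1 & rr <= S & cx >= 1 & cx <= S
    m[cbind(rr[keep], cx[keep])] <- TRUE
  }
  m
}

# --- generator parameters -----------------------------------------------

#' Default slide-generator parameters
#'
#' @param size raster side in pixels (square slides; default 2048, a
#'   "x20-equivalent" nominal scale).
#' @param patch_size patch side used downstream; a raster smaller than one
#'   patch is rejected by [render_slide()].
#' @param evidence_frac fraction of the tissue area overwritten with the
#'   high-frequency evidence texture on LNM-positive slides (default 0.05).
#' @param evidence_clusters number of planted evidence foci.
#' @param tissue_extent optional fixed tissue fraction; by default drawn
#'   uniformly from `extent_endoscopic` / `extent_surgical` per specimen,
#'   endoscopic specimens being smaller fragments of the submucosal layer.
#' @param extent_endoscopic,extent_surgical ranges for the tissue fraction.
#' @param nuclei_density nuclei per tissue pixel in the normal-gland texture.
#' @return named list of generator settings.
#' @export
slide_params <- function(size = 2048, patch_size = 256,
                         evidence_frac = 0.05, evidence_clusters = 3,
                         tissue_extent = NULL,
                         extent_endoscopic = c(0.10, 0.25),
                         extent_surgical = c(0.30, 0.60),
                         nuclei_density = 0.002) {
  list(size = size, patch_size = patch_size,
       evidence_frac = evidence_frac, evidence_clusters = evidence_clusters,
       tissue_extent = tissue_extent,
       extent_endoscopic = extent_endoscopic,
       extent_surgical = extent_surgical,
       nuclei_density = nuclei_density)
}

# --- slide rendering ----------------------------------------------------

#' Render one synthetic H&E-like slide for a patient record
#'
#' Produces a near-white background with one smooth tissue blob textured
#' like eosin-stained stroma with sparse dark nuclei. For LNM-positive
#' patients a configurable fraction of the tissue area (default 5%) is
#' overwritten with a distinct high-frequency "evidence" texture (dense,
#' hyperchromatic, budding/micropapillary-like foci) and recorded in a
#' ground-truth evidence mask. Deterministic given the seed.
#'
#' @param record one-row slice of a `patient_cohort` (or any list providing
#'   `patient_id`, `specimen_type`, `lnm_label`).
#' @param params generator settings from [slide_params()].
#' @param seed integer seed.
#' @param slide_index index of the slide within the patient (for ids).
#' @return object of class `synthetic_slide`: list with `slide_id`,
#'   `patient_id`, `label`, `specimen_type`, `pixels` (size x size x 3 array
#'   in \[0,1\]), `evidence_mask` and `tissue_truth` (logical matrices) and
#'   `tissue_extent`.
#' @export
render_slide <- function(record, params = slide_params(), seed = 1,
                         slide_index = 1) {
  S <- params$size
  assert_that(S >= params$patch_size,
              "raster size (%d) is smaller than one patch (%d)",
              S, params$patch_size)
  specimen <- as.character(record$specimen_type)
  label <- as.integer(record$lnm_label)
  with_seed(seed, {
    extent <- params$tissue_extent %||% {
      rng <- if (specimen == "endoscopic") params$extent_endoscopic else params$extent_surgical
      stats::runif(1, rng[1], rng[2])
    }
    # tissue blob: radial bowl + smooth perturbation, thresholded at the
    # quantile that yields exactly the requested extent
    cx <- stats::runif(1, 0.40, 0.60)
    cy <- stats::runif(1, 0.40, 0.60)
    ax <- stats::runif(1, 0.8, 1.6)
    ay <- stats::runif(1, 0.8, 1.6)
    u <- (seq_len(S) - 0.5) / S
    d <- sqrt(outer((u - cx)^2 * ax, (u - cy)^2 * ay, "+"))
    field <- 0.18 * smooth_noise(S, 6) - d
    tissue <- field >= stats::quantile(field, 1 - extent)
    # keep the largest connected component: the thresholded field can shed
    # small satellite specks that downstream tissue detection would drop
    lab <- EBImage::bwlabel(tissue)
    sizes <- tabulate(lab[lab > 0])
    tissue <- lab == which.max(sizes)
    n_tissue <- sum(tissue)

    # background: near-white with faint scanner noise
    base <- 0.965 + 0.01 * matrix(stats::runif(S * S), S, S)
    px <- array(0, c(S, S, 3))
    px[, , 1] <- base; px[, , 2] <- base; px[, , 3] <- base

    # normal-gland texture: pink stroma modulated by a medium-frequency field
    gl <- smooth_noise(S, 24)
    gl <- gl / max(abs(gl), 1e-8)
    tcol <- list(r = 0.90 - 0.06 * gl, g = 0.68 - 0.10 * gl, b = 0.80 - 0.06 * gl)
    for (k in 1:3) {
      ch <- px[, , k]
      ch[tissue] <- tcol[[k]][tissue]
      px[, , k] <- ch
    }
    # sparse nuclei dots
    n_nuc <- round(params$nuclei_density * n_tissue)
    if (n_nuc > 0) {
      idx <- which(tissue)
      pick <- idx[sample.int(length(idx), min(n_nuc, length(idx)))]
      rows <- (pick - 1) %% S + 1
      cols <- (pick - 1) %/% S + 1
      nuc <- stamp_disks(S, rows, cols, 2) & tissue
      for (k in 1:3) {
        ch <- px[, , k]
        ch[nuc] <- c(0.38, 0.28, 0.55)[k]
        px[, , k] <- ch
      }
    }

    # evidence foci on positive slides: the frac * tissue-area pixels
    # closest to a few seeded centers, overwritten with a dense
    # hyperchromatic high-frequency texture
    evidence <- matrix(FALSE, S, S)
    target <- round(params$evidence_frac * n_tissue)
    if (label == 1L && target > 0) {
      idx <- which(tissue)
      centers <- idx[sample.int(length(idx), params$evidence_clusters)]
      crow <- (centers - 1) %% S + 1
      ccol <- (centers - 1) %/% S + 1
      irow <- (idx - 1) %% S + 1
      icol <- (idx - 1) %/% S + 1
      dmin <- rep(Inf, length(idx))
      for (j in seq_along(centers)) {
        dj <- (irow - crow[j])^2 + (icol - ccol[j])^2
        dmin <- pmin(dmin, dj)
      }
      evidence[idx[order(dmin)[seq_len(target)]]] <- TRUE
      ne <- sum(evidence)
      speck <- matrix(stats::runif(S * S), S, S)
      for (k in 1:3) {
        ch <- px[, , k]
        # strongly saturated base so the evidence always survives the
        # saturation-based tissue detector, with per-pixel brightness
        # noise and dense dark "nuclei" speckle as the high-frequency cue
        ch[evidence] <- c(0.72, 0.32, 0.62)[k] +
          0.20 * (speck[evidence] - 0.5) * 2
        dark <- evidence & speck > 0.68
        ch[dark] <- c(0.25, 0.10, 0.32)[k]
        px[, , k] <- ch
      }
    }
    px[px < 0] <- 0; px[px > 1] <- 1
    structure(
      list(
        slide_id = sprintf("%s_S%d", record$patient_id, slide_index),
        patient_id = as.character(record$patient_id),
        label = label,
        specimen_type = specimen,
        pixels = px,
        evidence_mask = evidence,
        tissue_truth = tissue,
        tissue_extent = extent,
        size = S
      ),
      class = "synthetic_slide"
    )
  })
}

#' @export
print.synthetic_slide <- function(x, ...) {
  cat(sprintf("<synthetic_slide %s: %dx%d px, label %d, tissue %.1f%%, evidence %.2f%% of raster>\n",
              x$slide_id, x$size, x$size, x$label,
              100 * mean(x$tissue_truth), 100 * mean(x$evidence_mask)))
  invisible(x)
}

#' Render and write all slides of a cohort to disk
#'
#' Writes one PNG per slide, one 0/255 PNG per evidence mask, a cohort CSV
#' and a manifest CSV mapping `slide_id` to file paths, patient and label.
#'
#' @param cohort a `patient_cohort`.
#' @param dir output directory (created; must be empty unless `force`).
#' @param params generator settings from [slide_params()].
#' @param seed integer seed; each slide gets a derived child seed.
#' @param force overwrite a non-empty directory.
#' @return the manifest data.frame, invisibly; also written as
#'   `manifest.csv` in `dir`.
#' @export
simulate_dataset <- function(cohort, dir, params = slide_params(), seed = 1,
                             force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !force) {
    stopf("output directory %s is not empty (use force = TRUE)", dir)
  }
  dir.create(file.path(dir, "slides"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  write_cohort_csv(cohort, file.path(dir, "cohort.csv"))
  rows <- list()
  for (i in seq_len(nrow(cohort))) {
    rec <- cohort[i, ]
    for (s in seq_len(rec$n_slides)) {
      sl <- render_slide(rec, params, seed = derive_seed(seed, i * 10 + s),
                         slide_index = s)
      slide_path <- file.path(dir, "slides", paste0(sl$slide_id, ".png"))
      mask_path <- file.path(dir, "masks", paste0(sl$slide_id, "_evidence.png"))
      png::writePNG(aperm(sl$pixels, c(1, 2, 3)), slide_path)
      png::writePNG(matrix(as.numeric(sl$evidence_mask), sl$size, sl$size),
                    mask_path)
      rows[[length(rows) + 1]] <- data.frame(
        slide_id = sl$slide_id, patient_id = sl$patient_id,
        label = sl$label, specimen_type = sl$specimen_type,
        slide_path = slide_path, mask_path = mask_path,
        stringsAsFactors = FALSE
      )
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
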