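test_that("tissue detection handles blank, blocky and real synthetic input", {
  # all-near-white raster -> empty mask
  blank <- array(0.97, c(128, 128, 3))
  expect_equal(sum(detect_tissue(blank, min_area = 16)), 0)
  # one saturated 128x128 block in a white 256 raster
  img <- array(0.95, c(256, 256, 3))
  img[65:192, 65:192, 1] <- 0.9
  img[65:192, 65:192, 2] <- 0.4
  img[65:192, 65:192, 3] <- 0.6
  m <- detect_tissue(img, min_area = 64)
  expect_equal(sum(m), 128^2)
  expect_true(all(m[65:192, 65:192]))
  # idempotence
  d <- demo_slides()
  m1 <- detect_tissue(d$pos, min_area = 64^2)
  m2 <- detect_tissue(d$pos, min_area = 64^2)
  expect_identical(m1, m2)
  # non-RGB input rejected
  expect_error(detect_tissue(matrix(0.5, 10, 10)), "RGB")
  expect_error(detect_tissue(array(0.5, c(10, 10, 2))), "RGB")
})

test_that("small-object removal drops specks below one patch area", {
  img <- array(0.95, c(256, 256, 3))
  # large block (kept) + 5x5 speck (dropped at min_area 64)
  img[11:138, 11:138, 2] <- 0.4
  img[200:204, 200:204, 2] <- 0.4
  m <- detect_tissue(img, min_area = 64)
  expect_equal(sum(m), 128^2)
  m_all <- detect_tissue(img, min_area = 0)
  expect_equal(sum(m_all), 128^2 + 25)
})

test_that("tiling counts match simple grids", {
  img <- array(0.5, c(256, 256, 3))
  full <- matrix(TRUE, 256, 256)
  bag <- tile(img, full, patch_size = 64, min_tissue_frac = 0.5)
  expect_equal(bag$n, 16)
  # left half tissue -> half the grid
  half <- matrix(FALSE, 256, 256)
  half[, 1:128] <- TRUE
  expect_equal(tile(img, half, 64, 0.5)$n, 8)
  # frac = 0 retains the full grid even on a nearly-empty mask
  sparse <- matrix(FALSE, 256, 256)
  sparse[1, 1] <- TRUE
  expect_equal(tile(img, sparse, 64, 0)$n, 16)
  # empty mask -> empty bag with warning
  expect_warning(b0 <- tile(img, matrix(FALSE, 256, 256), 64, 0.5), "empty")
  expect_equal(b0$n, 0)
})

test_that("tile equals the brute-force grid count on random masks", {
  withr::with_seed(606, {
    img <- array(0.5, c(192, 192, 3))
    for (rep in 1:12) {
      p <- sample(c(32, 48, 64), 1)
      frac <- sample(c(0, 0.25, 0.5, 0.9), 1)
      # random blobby mask: coarse cells + pixel noise
      cell <- matrix(runif(36) > 0.5, 6, 6)
      ri <- ceiling(row(matrix(0, 192, 192)) / 32)
      ci <- ceiling(col(matrix(0, 192, 192)) / 32)
      mask <- matrix(cell[cbind(as.vector(ri), as.vector(ci))], 192, 192)
      mask <- xor(mask, matrix(runif(192^2) < 0.05, 192, 192))
      bag <- suppressWarnings(tile(img, mask, p, frac))
      expect_equal(bag$n, brute_tile_count(mask, p, frac))
    }
  })
})

test_that("bags carry coherent anchors, labels and evidence fractions", {
  d <- demo_slides()
  mask <- detect_tissue(d$pos, min_area = 64^2)
  bag <- tile(d$pos, mask, 64, 0.5)
  expect_s3_class(bag, "wsi_bag")
  expect_equal(bag$label, 1L)
  expect_equal(bag$slide_id, d$pos$slide_id)
  # anchors unique, inside the raster, row-major sorted
  expect_equal(anyDuplicated(bag$anchors), 0)
  expect_true(all(bag$anchors$x0 >= 0 & bag$anchors$x0 + 64 <= 256))
  expect_true(all(bag$anchors$y0 >= 0 & bag$anchors$y0 + 64 <= 256))
  ord <- order(bag$anchors$x0, bag$anchors$y0)
  expect_equal(ord, seq_len(bag$n))
  # at least one retained patch overlaps the evidence mask
  expect_gt(sum(bag$evidence_frac > 0), 0)
  # patch pixels match the raster slices
  i <- which.max(bag$evidence_frac)
  expect_equal(bag$pixels[, , , i],
               d$pos$pixels[bag$anchors$x0[i] + 1:64, bag$anchors$y0[i] + 1:64, ])
  # bag CSV round-trips coordinates
  path <- withr::local_tempfile(fileext = ".csv")
  write_bag_csv(bag, path)
  back <- utils::read.csv(path)
  expect_equal(back$x0, bag$anchors$x0)
  expect_equal(back$y0, bag$anchors$y0)
})

test_that("prepared bags expose the encoder input matrix", {
  d <- demo_slides()
  mask <- detect_tissue(d$pos, min_area = 64^2)
  bag <- prepare_bag(tile(d$pos, mask, 64, 0.5), input_px = 32)
  expect_equal(dim(bag$input), c(bag$n, 32 * 32 * 3))
  expect_null(bag$pixels)
  expect_true(all(is.finite(bag$input)))
})
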