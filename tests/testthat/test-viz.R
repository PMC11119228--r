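test_that("min-max normalization follows the declared conventions", {
  expect_equal(minmax_normalize(c(0.2, 0.5, 0.8)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(rep(0.3, 4)), rep(0, 4))
  expect_error(minmax_normalize(numeric(0)), "empty")
  withr::with_seed(31, {
    for (rep in 1:10) {
      s <- rnorm(sample(2:20, 1))
      if (diff(range(s)) < 1e-12) next
      n <- minmax_normalize(s)
      expect_equal(min(n), 0)
      expect_equal(max(n), 1)
    }
  })
})

test_that("heatmaps paint normalized scores into patch rectangles", {
  fx <- small_fixture()
  lab <- vapply(fx$bags, `[[`, 1L, "label")
  n_of <- vapply(fx$bags, `[[`, 1L, "n")
  bag <- fx$bags[[which(lab == 1 & n_of >= 3)[1]]]
  res <- mil_forward(fx$model, encode(fx$fe, bag))
  hm <- render_heatmap(bag, res, slide_dim = c(256, 256))
  expect_true(all(hm$values >= 0 & hm$values <= 1))
  # untissued regions stay zero and uncovered
  expect_true(all(hm$values[!hm$covered] == 0))
  # the argmax rectangle belongs to the top-attention patch
  i <- which.max(res$scores)
  peak <- which(hm$values == 1, arr.ind = TRUE)[1, ]
  expect_true(peak[1] > bag$anchors$x0[i] && peak[1] <= bag$anchors$x0[i] + 64)
  expect_true(peak[2] > bag$anchors$y0[i] && peak[2] <= bag$anchors$y0[i] + 64)
  # single-patch bag renders as zeros (constant-vector rule)
  one <- bag
  one$anchors <- bag$anchors[1, , drop = FALSE]
  one$n <- 1L
  one$evidence_frac <- bag$evidence_frac[1]
  hm1 <- render_heatmap(one, res$scores[1], slide_dim = c(256, 256))
  expect_true(all(hm1$values == 0))
  # mismatched score length rejected
  expect_error(render_heatmap(bag, res$scores[-1]), "align")
})

test_that("heatmap PNGs are byte-stable", {
  fx <- small_fixture()
  bag <- fx$bags[[1]]
  res <- mil_forward(fx$model, encode(fx$fe, bag))
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  render_heatmap(bag, res, slide_dim = c(256, 256), path = p1)
  render_heatmap(bag, res, slide_dim = c(256, 256), path = p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("attention localizes on the evidence of a positive slide", {
  # uses the benchmark-scale model: the tiny fixture model is too weak to
  # generalize to slides outside its own cohort
  d <- demo_slides()
  model <- get_benchmark()$model
  mask <- detect_tissue(d$pos, min_area = 64^2)
  bag <- prepare_bag(tile(d$pos, mask, 64, 0.5), input_px = 32)
  res <- mil_forward(model, encode(model$fe, bag))
  hm <- render_heatmap(bag, res, slide_dim = c(256, 256))
  ev <- d$pos$evidence_mask
  expect_gt(mean(hm$values[ev]), mean(hm$values[hm$covered & !ev]))
})

test_that("top_patches sorts by score with row-major tie-breaks", {
  fx <- small_fixture()
  bag <- fx$bags[[1]]
  res <- mil_forward(fx$model, encode(fx$fe, bag))
  all_p <- top_patches(bag, res, k = bag$n)
  expect_equal(nrow(all_p), bag$n)
  expect_true(all(diff(all_p$score) <= 1e-15))
  top1 <- top_patches(bag, res, k = 1)
  expect_equal(top1$score, max(res$scores))
  expect_error(top_patches(bag, res, k = bag$n + 1), "between 1 and")
  # deterministic tie-break on constant scores: row-major anchor order
  const <- rep(1 / bag$n, bag$n)
  t2 <- top_patches(bag, const, k = bag$n)
  expect_equal(order(t2$x0, t2$y0), seq_len(bag$n))
})

test_that("attention CSV round-trips scores and coordinates", {
  fx <- small_fixture()
  bag <- fx$bags[[2]]
  res <- mil_forward(fx$model, encode(fx$fe, bag))
  path <- withr::local_tempfile(fileext = ".csv")
  write_attention_csv(bag, res, path)
  back <- utils::read.csv(path)
  expect_equal(back$x0, bag$anchors$x0)
  expect_equal(back$score, res$scores, tolerance = 1e-12)
  expect_equal(back$normalized_score, minmax_normalize(res$scores),
               tolerance = 1e-12)
})
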