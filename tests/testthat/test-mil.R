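test_that("attention scores are a proper softmax over the bag", {
  withr::with_seed(21, {
    m <- mil_new(mil_config(feat_dim = 8, attention_hidden = 4))
    F <- matrix(rnorm(7 * 8), 7)
    at <- attend(m, F)
    expect_equal(sum(at$scores), 1, tolerance = 1e-9)
    expect_true(all(at$scores >= 0 & at$scores <= 1))
    # single patch
    at1 <- attend(m, F[1, , drop = FALSE])
    expect_equal(at1$scores, 1)
    expect_equal(at1$wsi_feature, as.vector(F[1, ]))
    # identical feature vectors share the weight
    at2 <- attend(m, F[c(3, 3), ])
    expect_equal(at2$scores, c(0.5, 0.5))
  })
})

test_that("attention logits (ln 2, 0) give scores (2/3, 1/3)", {
  # 1-d features, 1 hidden unit with identity-ish weights: u_i = tanh(f_i)
  m <- mil_new(mil_config(feat_dim = 1, attention_hidden = 1))
  m$am$V <- matrix(1); m$am$bV <- 0
  m$am$w <- matrix(1); m$am$bw <- 0
  f <- matrix(c(atanh(log(2)), 0), ncol = 1)
  at <- attend(m, f)
  expect_equal(at$scores, c(2 / 3, 1 / 3), tolerance = 1e-12)
})

test_that("wsi_feature equals the independently recomputed weighted sum", {
  withr::with_seed(22, {
    m <- mil_new(mil_config(feat_dim = 16, attention_hidden = 8))
    for (rep in 1:5) {
      F <- matrix(rnorm(sample(2:20, 1) * 16), ncol = 16)
      at <- attend(m, F)
      oracle <- rep(0, 16)
      for (i in seq_len(nrow(F))) oracle <- oracle + at$scores[i] * F[i, ]
      expect_equal(at$wsi_feature, oracle, tolerance = 1e-10)
    }
  })
})

test_that("bag predictions are permutation-invariant, scores equivariant", {
  withr::with_seed(23, {
    m <- mil_new(mil_config(feat_dim = 12, attention_hidden = 6))
    F <- matrix(rnorm(9 * 12), 9)
    res <- mil_forward(m, F)
    perm <- sample(9)
    res_p <- mil_forward(m, F[perm, ])
    expect_equal(res_p$probability, res$probability, tolerance = 1e-6)
    expect_equal(res_p$scores, res$scores[perm], tolerance = 1e-9)
    expect_equal(res_p$wsi_feature, res$wsi_feature, tolerance = 1e-9)
  })
})

test_that("the classification module is a calibrated monotone logistic", {
  m <- mil_new(mil_config(feat_dim = 4, attention_hidden = 2))
  m$cm$w <- matrix(0, 4, 1); m$cm$b <- 0
  expect_equal(predict_prob(m, rep(1, 4)), 0.5)
  m$cm$w <- matrix(c(1, 0, 0, 0), 4, 1)
  p <- vapply(c(-2, 0, 2, 5), function(v) predict_prob(m, c(v, 0, 0, 0)), 1.0)
  expect_true(all(diff(p) > 0))
  expect_error(predict_prob(m, rep(0, 3)), "length")
  expect_error(attend(m, matrix(NaN, 2, 4)), "finite")
})

test_that("encode produces ordered, pure 512-d features", {
  fx <- small_fixture()
  bag <- fx$bags[[1]]
  f <- encode(fx$fe, bag)
  expect_equal(dim(f), c(bag$n, 512))
  expect_true(all(is.finite(f)))
  # purity
  expect_identical(unclass(encode(fx$fe, bag)), unclass(f))
  # duplicating a patch duplicates its row
  X <- bag$input[c(1, 1, 2), , drop = FALSE]
  f2 <- encode(fx$fe, X)
  expect_identical(f2[1, ], f2[2, ])
  expect_false(identical(f2[1, ], f2[3, ]))
})

test_that("pretraining is deterministic, balanced and 512-dimensional", {
  fx <- small_fixture()
  sub <- fx$bags[c(which(vapply(fx$bags, `[[`, 1L, "label") == 1)[1:3],
                   which(vapply(fx$bags, `[[`, 1L, "label") == 0)[1:3])]
  a <- pretrain_fe(sub, epochs = 2, seed = 99)
  b <- pretrain_fe(sub, epochs = 2, seed = 99)
  expect_identical(fe_params(a), fe_params(b))
  expect_equal(ncol(encode(a, sub[[1]])), 512)
  # single-class input rejected
  only_neg <- fx$bags[vapply(fx$bags, `[[`, 1L, "label") == 0]
  expect_error(pretrain_fe(only_neg, epochs = 1, seed = 1), "both classes")
})

test_that("end-to-end training is deterministic and learns the fixture", {
  fx <- small_fixture()
  m2 <- train_end_to_end(fx$bags, fe = fx$fe, epochs = 15, seed = 423)
  expect_identical(mil_params(fx$model), mil_params(m2))
  # loss trend: first-quarter mean above last-quarter mean
  h <- fx$model$history$loss
  expect_gt(mean(head(h, 4)), mean(tail(h, 4)))
  # separation on the training bags (sanity, not held out)
  pred <- predict_bags(fx$model, fx$bags)
  expect_gt(mean(pred$probability[pred$label == 1]),
            mean(pred$probability[pred$label == 0]))
  # single-class labels rejected
  expect_error(train_end_to_end(fx$bags, labels = rep(1, length(fx$bags)),
                                fe = fx$fe, epochs = 1, seed = 1),
               "both classes")
})

test_that("fine-tuned encoder mode runs and remains deterministic", {
  fx <- small_fixture()
  sub <- fx$bags[c(which(vapply(fx$bags, `[[`, 1L, "label") == 1)[1:2],
                   which(vapply(fx$bags, `[[`, 1L, "label") == 0)[1:2])]
  a <- train_end_to_end(sub, fe = fx$fe, epochs = 2, freeze_fe = FALSE, seed = 7)
  b <- train_end_to_end(sub, fe = fx$fe, epochs = 2, freeze_fe = FALSE, seed = 7)
  expect_identical(mil_params(a), mil_params(b))
  expect_identical(fe_params(a$fe), fe_params(b$fe))
  # fine-tuning actually moved the encoder
  expect_false(identical(fe_params(a$fe), fe_params(fx$fe)))
})

test_that("attention scores sum to one on every fixture bag", {
  fx <- small_fixture()
  for (bag in fx$bags) {
    res <- mil_forward(fx$model, encode(fx$fe, bag))
    expect_equal(sum(res$scores), 1, tolerance = 1e-6)
    expect_true(all(res$scores >= 0 & res$scores <= 1))
    # oracle re-check of the pooled feature
    f <- unclass(encode(fx$fe, bag))
    expect_equal(res$wsi_feature, as.vector(t(f) %*% res$scores),
                 tolerance = 1e-8)
  }
})
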