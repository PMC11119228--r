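# --- attention pooling + bag classifier ---------------------------------

#' MIL head settings
#'
#' @param feat_dim patch feature dimension (512).
#' @param attention_hidden width of the tanh attention hidden layer.
#' @param gated use the gated attention variant (tanh x sigmoid gates).
#' @return named list.
#' @export
mil_config <- function(feat_dim = 512, attention_hidden = 128, gated = FALSE) {
  list(feat_dim = feat_dim, attention_hidden = attention_hidden, gated = gated)
}

# Instantiate attention module (AM) + classification module (CM) weights.
mil_new <- function(config = mil_config()) {
  d <- config$feat_dim; hdim <- config$attention_hidden
  am <- list(
    V = matrix(stats::rnorm(d * hdim, sd = sqrt(1 / d)), d, hdim),
    bV = numeric(hdim),
    w = matrix(stats::rnorm(hdim, sd = sqrt(1 / hdim)), hdim, 1),
    bw = 0
  )
  if (config$gated) {
    am$U <- matrix(stats::rnorm(d * hdim, sd = sqrt(1 / d)), d, hdim)
    am$bU <- numeric(hdim)
  }
  cm <- list(w = matrix(stats::rnorm(d, sd = sqrt(1 / d)), d, 1), b = 0)
  structure(list(am = am, cm = cm, config = config), class = "mil_model")
}

#' @export
print.mil_model <- function(x, ...) {
  cat(sprintf("<mil_model: %d-d features, %s attention (hidden %d)%s>\n",
              x$config$feat_dim, if (x$config$gated) "gated" else "tanh",
              x$config$attention_hidden,
              if (isTRUE(x$trained)) ", trained" else ""))
  invisible(x)
}

softmax <- function(u) {
  e <- exp(u - max(u))
  e / sum(e)
}

# Attention logits for a feature matrix F (N x d).
attention_logits <- function(am, F, gated = FALSE) {
  h <- tanh(sweep(F %*% am$V, 2, am$bV, "+"))
  if (gated) {
    g <- sigmoid(sweep(F %*% am$U, 2, am$bU, "+"))
    h <- h * g
  }
  list(u = (h %*% am$w)[, 1] + am$bw, h = h)
}

#' Attention pooling of a feature bag
#'
#' Computes a softmax-normalized attention score per patch (scores in
#' \[0,1\], summing to 1 over the bag) and the attention-weighted average of
#' the patch feature vectors — the 512-d slide-level deep feature.
#'
#' @param model a `mil_model`.
#' @param fbag N x 512 feature matrix (from [encode()]).
#' @return list with `scores` (length N) and `wsi_feature` (length 512).
#' @export
attend <- function(model, fbag) {
  stopifnot(inherits(model, "mil_model"))
  F <- unclass(fbag)
  assert_that(nrow(F) >= 1, "cannot attend over an empty bag")
  assert_that(all(is.finite(F)), "feature bag contains non-finite values")
  al <- attention_logits(model$am, F, model$config$gated)
  a <- softmax(al$u)
  list(scores = a, wsi_feature = as.vector(crossprod(F, a)))
}

#' Bag-level LNM probability from a slide feature
#'
#' Logistic classification module applied to the 512-d slide deep feature.
#'
#' @param model a `mil_model`.
#' @param wsi_feature numeric vector of length `feat_dim`.
#' @return probability in (0, 1).
#' @export
predict_prob <- function(model, wsi_feature) {
  stopifnot(inherits(model, "mil_model"))
  assert_that(length(wsi_feature) == model$config$feat_dim,
              "wsi_feature must have length %d", model$config$feat_dim)
  assert_that(all(is.finite(wsi_feature)), "wsi_feature must be finite")
  sigmoid(sum(wsi_feature * model$cm$w[, 1]) + model$cm$b)
}

#' Full MIL forward pass on one bag
#'
#' @param model a `mil_model`.
#' @param fbag N x 512 feature matrix.
#' @return object of class `attention_result`: list with `scores`,
#'   `wsi_feature` and `probability`.
#' @export
mil_forward <- function(model, fbag) {
  at <- attend(model, fbag)
  structure(
    list(scores = at$scores, wsi_feature = at$wsi_feature,
         probability = predict_prob(model, at$wsi_feature),
         slide_id = attr(fbag, "slide_id")),
    class = "attention_result"
  )
}

# Analytic gradients of the weighted BCE loss of one bag w.r.t. AM + CM
# parameters (and optionally the feature matrix, for end-to-end training).
mil_bag_grad <- function(model, F, y, w, need_dF = FALSE) {
  gated <- model$config$gated
  al <- attention_logits(model$am, F, gated)
  a <- softmax(al$u)
  z <- as.vector(crossprod(F, a))
  logit <- sum(z * model$cm$w[, 1]) + model$cm$b
  p <- sigmoid(logit)
  eps <- 1e-12
  loss <- -w * (y * log(p + eps) + (1 - y) * log(1 - p + eps))
  ds <- w * (p - y)
  dz <- ds * model$cm$w[, 1]
  da <- as.vector(F %*% dz)
  du <- a * (da - sum(a * da))
  h <- al$h
  if (gated) {
    hraw <- tanh(sweep(F %*% model$am$V, 2, model$am$bV, "+"))
    g <- sigmoid(sweep(F %*% model$am$U, 2, model$am$bU, "+"))
    dh_gated <- du %*% t(model$am$w)           # N x hdim (grad w.r.t. h*g)
    dpreV <- dh_gated * g * (1 - hraw^2)
    dpreU <- dh_gated * hraw * g * (1 - g)
    grads <- list(
      V = crossprod(F, dpreV), bV = colSums(dpreV),
      U = crossprod(F, dpreU), bU = colSums(dpreU),
      w = crossprod(h, du), bw = sum(du),
      cw = matrix(ds * z, ncol = 1), cb = ds
    )
    dF <- if (need_dF) {
      outer(a, dz) + dpreV %*% t(model$am$V) + dpreU %*% t(model$am$U)
    } else NULL
  } else {
    dpre <- (du %*% t(model$am$w)) * (1 - h^2)
    grads <- list(
      V = crossprod(F, dpre), bV = colSums(dpre),
      w = crossprod(h, du), bw = sum(du),
      cw = matrix(ds * z, ncol = 1), cb = ds
    )
    dF <- if (need_dF) outer(a, dz) + dpre %*% t(model$am$V) else NULL
  }
  list(loss = loss, p = p, grads = grads, dF = dF)
}

mil_params <- function(model) {
  p <- list(V = model$am$V, bV = model$am$bV, w = model$am$w, bw = model$am$bw,
            cw = model$cm$w, cb = model$cm$b)
  if (model$config$gated) {
    p$U <- model$am$U; p$bU <- model$am$bU
  }
  p
}

mil_set_params <- function(model, p) {
  model$am$V <- p$V; model$am$bV <- p$bV
  model$am$w <- p$w; model$am$bw <- p$bw
  model$cm$w <- p$cw; model$cm$b <- p$cb
  if (model$config$gated) {
    model$am$U <- p$U; model$am$bU <- p$bU
  }
  model
}

#' Train the attention-MIL model end to end on bag labels
#'
#' Optimises the attention module and classification module (and, unless
#' the encoder is frozen, the feature extractor) by class-weighted binary
#' cross-entropy on bag labels, one bag per gradient step (Adam).
#' Bags larger than `bag_cap` patches are subsampled without replacement
#' (seeded, per epoch) during training; inference always uses full bags.
#'
#' @param bags list of `wsi_bag`s.
#' @param labels bag labels (defaults to the labels carried by the bags).
#' @param fe a (pretrained) `fe_model`.
#' @param config head settings from [mil_config()].
#' @param epochs,lr optimisation settings.
#' @param freeze_fe if `TRUE` (default) patch features are computed once
#'   and the encoder stays fixed; if `FALSE` the encoder is fine-tuned
#'   through the attention pooling.
#' @param bag_cap training-time cap on patches per bag.
#' @param seed integer seed; training is deterministic given the seed.
#' @param features optional list of precomputed N x 512 feature matrices
#'   aligned with `bags` (frozen-encoder mode only); avoids re-encoding
#'   when training repeatedly on the same bags, e.g. across permutations.
#' @return trained `mil_model` with `history` (per-epoch mean loss) and the
#'   `fe` used (updated when fine-tuned).
#' @export
train_end_to_end <- function(bags, labels = NULL, fe, config = mil_config(),
                             epochs = 40, lr = 5e-4, freeze_fe = TRUE,
                             bag_cap = 500, seed = 1, features = NULL) {
  y <- if (is.null(labels)) vapply(bags, function(b) as.integer(b$label), 1L)
       else as.integer(labels)
  assert_that(length(unique(y)) == 2, "training needs bags of both classes")
  n <- length(bags)
  w_class <- n / (2 * c(`0` = sum(y == 0), `1` = sum(y == 1)))
  w <- unname(w_class[as.character(y)])
  feats <- NULL
  if (freeze_fe) {
    feats <- features %||% lapply(bags, function(b) unclass(encode(fe, b)))
    assert_that(length(feats) == length(bags), "features must align with bags")
  }
  with_seed(seed, {
    model <- mil_new(config)
    params <- mil_params(model)
    fparams <- if (!freeze_fe) fe_params(fe) else NULL
    opt <- adam_new(params, lr = lr)
    fopt <- if (!freeze_fe) adam_new(fparams, lr = lr) else NULL
    history <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (i in ord) {
        sub <- NULL
        ni <- bags[[i]]$n
        if (ni > bag_cap) sub <- sort(sample.int(ni, bag_cap))
        model <- mil_set_params(model, params)
        if (freeze_fe) {
          F <- feats[[i]]
          if (!is.null(sub)) F <- F[sub, , drop = FALSE]
          g <- mil_bag_grad(model, F, y[i], w[i], need_dF = FALSE)
        } else {
          fe <- fe_set_params(fe, fparams)
          X <- bags[[i]]$input %||% bag_input_matrix(bags[[i]], fe$config$input_px)
          if (!is.null(sub)) X <- X[sub, , drop = FALSE]
          fwd <- fe_forward(fe, X, keep_cache = TRUE)
          g <- mil_bag_grad(model, fwd$features, y[i], w[i], need_dF = TRUE)
          fgrads <- fe_backward(fe, fwd$cache, g$dF)
          fst <- adam_step(fopt, fparams, fgrads)
          fopt <- fst$opt; fparams <- fst$params
        }
        if (!is.finite(g$loss)) stopf("MIL training diverged (non-finite loss)")
        st <- adam_step(opt, params, g$grads)
        opt <- st$opt; params <- st$params
        ep_loss <- ep_loss + g$loss
      }
      history[ep] <- ep_loss / n
    }
    model <- mil_set_params(model, params)
    if (!freeze_fe) fe <- fe_set_params(fe, fparams)
    model$trained <- TRUE
    model$history <- data.frame(epoch = seq_len(epochs), loss = history)
    model$fe <- fe
    model
  })
}

#' Predict slide probabilities for a list of bags
#'
#' @param model trained `mil_model` (carrying its `fe`).
#' @param bags list of `wsi_bag`s.
#' @return data.frame with `slide_id`, `patient_id`, `label`, `probability`.
#' @export
predict_bags <- function(model, bags) {
  fe <- model$fe
  rows <- lapply(bags, function(b) {
    res <- mil_forward(model, encode(fe, b))
    data.frame(slide_id = b$slide_id, patient_id = b$patient_id,
               label = b$label, probability = res$probability,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
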