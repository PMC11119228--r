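# --- convolutional patch feature extractor ------------------------------

#' Feature-extractor architecture settings
#'
#' A desk-scale convolutional encoder: four 3x3 stride-2 convolution blocks
#' with ReLU, global average pooling, and an affine map to the
#' 512-dimensional patch feature vector.
#'
#' @param input_px patch input resolution fed to the encoder (patches are
#'   mean-pooled down to this size; default 32).
#' @param channels channel widths of the four convolution blocks.
#' @param feat_dim embedding dimension (512; the one hard architectural
#'   constraint of the pipeline).
#' @param pool global pooling over the final activation map: `"max"`
#'   (default; keeps the response of a focal texture covering only part of
#'   a patch) or `"mean"`.
#' @return named list of architecture settings.
#' @export
fe_config <- function(input_px = 32, channels = c(8, 16, 32, 64),
                      feat_dim = 512, pool = c("max", "mean")) {
  list(input_px = input_px, channels = channels, feat_dim = feat_dim,
       pool = match.arg(pool))
}

# Instantiate an untrained feature extractor (+ detachable patch head).
fe_new <- function(config = fe_config()) {
  d <- config$input_px
  cin <- 3
  conv <- list()
  h <- d
  for (i in seq_along(config$channels)) {
    conv[[i]] <- conv_layer_new(h, h, cin, config$channels[i])
    h <- conv[[i]]$gather$ho
    cin <- config$channels[i]
  }
  structure(
    list(conv = conv,
         dense = dense_layer_new(cin, config$feat_dim),
         head = dense_layer_new(config$feat_dim, 1),
         config = config,
         final_hw = h),
    class = "fe_model"
  )
}

#' @export
print.fe_model <- function(x, ...) {
  cat(sprintf("<fe_model: %dpx -> conv(%s) -> global %s pool -> %d-d feature%s>\n",
              x$config$input_px, paste(x$config$channels, collapse = ","),
              x$config$pool %||% "mean", x$config$feat_dim,
              if (isTRUE(x$trained)) ", pretrained" else ""))
  invisible(x)
}

# Forward pass. X: N x (d*d*3) flattened patch inputs.
# Returns features (N x feat_dim) and caches for backprop.
fe_forward <- function(fe, X, keep_cache = FALSE) {
  d <- fe$config$input_px
  N <- nrow(X)
  x <- array(t(X), c(d, d, 3, N))
  caches <- vector("list", length(fe$conv))
  for (i in seq_along(fe$conv)) {
    cf <- conv_forward(fe$conv[[i]], x, keep_cache = keep_cache)
    x <- cf$out
    caches[[i]] <- cf$cache
  }
  gap_in_dim <- dim(x)
  pool <- fe$config$pool %||% "mean"
  if (pool == "max") {
    gm <- gmp_forward(x)
    pooled <- gm$out
    pool_idx <- gm$idx
  } else {
    pooled <- gap_forward(x)                   # N x c_last
    pool_idx <- NULL
  }
  feats <- dense_forward(fe$dense, pooled)
  list(features = feats,
       cache = if (keep_cache) {
         list(caches = caches, gap_in_dim = gap_in_dim, pooled = pooled,
              pool_idx = pool_idx)
       } else NULL)
}

# Backprop dL/dfeatures through the encoder; returns parameter gradients.
fe_backward <- function(fe, cache, dfeat) {
  grads <- list()
  dd <- dense_backward(fe$dense, cache$pooled, dfeat)
  grads$dW <- dd$grad$W
  grads$db <- dd$grad$b
  dx <- if (!is.null(cache$pool_idx)) {
    gmp_backward(dd$dx, cache$pool_idx, cache$gap_in_dim)
  } else {
    gap_backward(dd$dx, cache$gap_in_dim)
  }
  for (i in rev(seq_along(fe$conv))) {
    cb <- conv_backward(fe$conv[[i]], cache$caches[[i]],
                        array(dx, c(prod(dim(dx)[1:2]), dim(dx)[3], dim(dx)[4])),
                        need_dx = i > 1)
    grads[[paste0("c", i, "W")]] <- cb$grad$W
    grads[[paste0("c", i, "b")]] <- cb$grad$b
    dx <- cb$dx
  }
  grads
}

#' Encode a bag of patches into 512-d feature vectors
#'
#' Applies the (pretrained) feature extractor to every patch of a bag,
#' preserving patch order.
#'
#' @param fe an `fe_model` (see [pretrain_fe()]).
#' @param bag a `wsi_bag`; its patches are mean-pooled to the encoder input
#'   resolution if not already prepared.
#' @param batch_size forward-pass batch size.
#' @return matrix N x 512 of class `feature_bag` with the bag's ids carried
#'   in attributes.
#' @export
encode <- function(fe, bag, batch_size = 256) {
  stopifnot(inherits(fe, "fe_model"))
  if (inherits(bag, "wsi_bag")) {
    assert_that(bag$n > 0, "cannot encode an empty bag")
    X <- bag$input %||% bag_input_matrix(bag, fe$config$input_px)
    ids <- list(slide_id = bag$slide_id, patient_id = bag$patient_id,
                label = bag$label)
  } else {
    X <- bag
    ids <- list()
  }
  N <- nrow(X)
  out <- matrix(0, N, fe$config$feat_dim)
  i <- 1
  while (i <= N) {
    j <- min(i + batch_size - 1, N)
    out[i:j, ] <- fe_forward(fe, X[i:j, , drop = FALSE])$features
    i <- j + 1
  }
  structure(out, class = c("feature_bag", "matrix", "array"),
            slide_id = ids$slide_id, patient_id = ids$patient_id,
            label = ids$label)
}

# weighted binary cross-entropy on logits; returns loss and dL/dlogit
wbce <- function(logit, y, w) {
  p <- sigmoid(logit)
  eps <- 1e-12
  loss <- -sum(w * (y * log(p + eps) + (1 - y) * log(1 - p + eps))) / sum(w)
  dlogit <- w * (p - y) / sum(w)
  list(loss = loss, dlogit = dlogit, p = p)
}

#' Pretrain the patch feature extractor with bag-inherited labels
#'
#' Every patch inherits its slide's LNM label; a patch-level binary
#' classifier (encoder + logistic head) is trained with class-weighted
#' cross-entropy and Adam, after which the head is discarded and the
#' encoder serves as the patch feature extractor.
#'
#' @param bags list of `wsi_bag`s (at least one per class).
#' @param config architecture from [fe_config()].
#' @param epochs,batch_size,lr optimisation settings.
#' @param max_patches cap on the number of training patches; patches are
#'   subsampled class-stratified beyond it.
#' @param seed integer seed; training is deterministic given the seed.
#' @param labels optional bag-label override (defaults to the labels the
#'   bags carry); used e.g. by permutation-null analyses.
#' @return trained `fe_model` with a `history` data.frame of per-epoch loss.
#' @export
pretrain_fe <- function(bags, config = fe_config(), epochs = 10,
                        batch_size = 128, lr = 1e-3, max_patches = 4000,
                        seed = 1, labels = NULL) {
  labels <- if (is.null(labels)) {
    vapply(bags, function(b) as.integer(b$label), 1L)
  } else as.integer(labels)
  assert_that(length(labels) == length(bags),
              "labels must align with bags")
  assert_that(length(unique(labels)) == 2,
              "pretraining needs bags from both classes")
  X <- do.call(rbind, lapply(bags, function(b) {
    b$input %||% bag_input_matrix(b, config$input_px)
  }))
  y <- rep(labels, vapply(bags, function(b) b$n, 1L))
  with_seed(seed, {
    if (length(y) > max_patches) {
      # class-stratified subsample
      keep <- unlist(lapply(split(seq_along(y), y), function(ix) {
        n_take <- max(1, round(max_patches * length(ix) / length(y)))
        sample(ix, min(n_take, length(ix)))
      }))
      X <- X[keep, , drop = FALSE]
      y <- y[keep]
    }
    n <- length(y)
    w_class <- n / (2 * c(`0` = sum(y == 0), `1` = sum(y == 1)))
    w <- unname(w_class[as.character(y)])
    fe <- fe_new(config)
    params <- c(fe_params(fe), list(hW = fe$head$W, hb = fe$head$b))
    opt <- adam_new(params, lr = lr)
    history <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; n_batches <- 0
      for (start in seq(1, n, by = batch_size)) {
        ix <- ord[start:min(start + batch_size - 1, n)]
        fe <- fe_set_params(fe, params)
        fe$head$W <- params$hW; fe$head$b <- params$hb
        fwd <- fe_forward(fe, X[ix, , drop = FALSE], keep_cache = TRUE)
        logit <- dense_forward(fe$head, fwd$features)[, 1]
        lb <- wbce(logit, y[ix], w[ix])
        if (!is.finite(lb$loss)) stopf("pretraining diverged (non-finite loss)")
        hb_ <- dense_backward(fe$head, fwd$features, matrix(lb$dlogit, ncol = 1))
        grads <- fe_backward(fe, fwd$cache, hb_$dx)
        grads$hW <- hb_$grad$W; grads$hb <- hb_$grad$b
        st <- adam_step(opt, params, grads)
        opt <- st$opt; params <- st$params
        ep_loss <- ep_loss + lb$loss; n_batches <- n_batches + 1
      }
      history[ep] <- ep_loss / n_batches
    }
    fe <- fe_set_params(fe, params)
    fe$head$W <- params$hW; fe$head$b <- params$hb
    fe$trained <- TRUE
    fe$history <- data.frame(epoch = seq_len(epochs), loss = history)
    fe
  })
}

# Held-out patch-level accuracy of the pretrained encoder + head against
# bag-inherited labels (noisy: positive bags contain mostly normal patches).
patch_accuracy <- function(fe, bags) {
  X <- do.call(rbind, lapply(bags, function(b) {
    b$input %||% bag_input_matrix(b, fe$config$input_px)
  }))
  y <- rep(vapply(bags, function(b) as.integer(b$label), 1L),
           vapply(bags, function(b) b$n, 1L))
  f <- encode(fe, X)
  p <- sigmoid(dense_forward(fe$head, unclass(f))[, 1])
  mean((p > 0.5) == (y == 1))
}

#' Evidence-vs-normal patch discrimination of the pretrained extractor
#'
#' Scores every patch of the given bags with the pretraining head and
#' measures how well evidence-bearing patches (ground-truth evidence
#' fraction above `evidence_min`) are separated from normal patches, as
#' balanced accuracy at the balanced-optimal threshold.
#'
#' @param fe pretrained `fe_model`.
#' @param bags list of `wsi_bag`s carrying `evidence_frac` (synthetic
#'   slides only).
#' @param evidence_min minimum ground-truth evidence fraction for a patch
#'   to count as an evidence patch.
#' @return balanced accuracy in \[0, 1\].
#' @export
evidence_patch_accuracy <- function(fe, bags, evidence_min = 0.25) {
  keep <- !vapply(bags, function(b) is.null(b$evidence_frac), TRUE)
  bags <- bags[keep]
  assert_that(length(bags) > 0, "no bags carry ground-truth evidence fractions")
  X <- do.call(rbind, lapply(bags, function(b) {
    b$input %||% bag_input_matrix(b, fe$config$input_px)
  }))
  ev <- unlist(lapply(bags, function(b) b$evidence_frac))
  truth <- ev >= evidence_min
  # drop ambiguous partial-overlap patches
  use <- truth | ev == 0
  assert_that(any(truth) && any(ev == 0),
              "need both evidence and normal patches to measure separation")
  f <- encode(fe, X[use, , drop = FALSE])
  p <- sigmoid(dense_forward(fe$head, unclass(f))[, 1])
  y <- truth[use]
  cut <- youden_cutoff(p, as.integer(y))
  (cut$sensitivity + cut$specificity) / 2
}
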