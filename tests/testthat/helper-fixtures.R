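# Shared fixtures, built lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small mixed cohort with slides/bags and a trained model: the workhorse
# fixture for MIL, CV, ensemble and visualization tests.
small_fixture <- function() {
  cached("small_fixture", function() {
    config <- run_config(seed = 42, n_endoscopic = 18, n_surgical = 18,
                         prev_endo = 1 / 3, prev_surg = 1 / 3,
                         slide_px = 256, patch_size = 64,
                         fe_epochs = 4, mil_epochs = 15)
    cohort <- generate_cohort(config$n_endoscopic, config$n_surgical,
                              config$prev_endo, config$prev_surg, seed = 421)
    bags <- suppressWarnings(build_bags(cohort, config))
    cohort <- cohort[cohort$patient_id %in%
                       vapply(bags, `[[`, "", "patient_id"), ]
    fe <- pretrain_fe(bags, config = fe_config(), epochs = config$fe_epochs,
                      seed = 422)
    model <- train_end_to_end(bags, fe = fe, epochs = config$mil_epochs,
                              seed = 423)
    list(config = config, cohort = cohort, bags = bags, fe = fe,
         model = model)
  })
}

# One small positive and negative synthetic slide each.
demo_slides <- function() {
  cached("demo_slides", function() {
    cohort <- generate_cohort(2, 2, prev_endo = 0.5, prev_surg = 0.5,
                              seed = 77)
    par <- slide_params(size = 256, patch_size = 64)
    pos_row <- which(cohort$lnm_label == 1)[1]
    neg_row <- which(cohort$lnm_label == 0)[1]
    list(
      pos = render_slide(cohort[pos_row, ], par, seed = 78),
      neg = render_slide(cohort[neg_row, ], par, seed = 79),
      params = par,
      cohort = cohort
    )
  })
}

# The study-conditions benchmark (used by the acceptance suite); one run
# shared by every block that reads it.
get_benchmark <- function() {
  cached("benchmark", function() synthetic_benchmark(seed = 20260922 %% 1000))
}

# Cohort with the published split-table composition (71/329 endoscopic,
# 101/780 surgical positives/negatives).
table2_cohort <- function() {
  cached("table2_cohort", function() {
    generate_cohort(400, 881, prev_endo = 71 / 400, prev_surg = 101 / 881,
                    seed = 5)
  })
}

# Brute-force oracles -----------------------------------------------------

# pairwise-concordance AUC: ties count 1/2
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# exhaustive Youden scan with the same candidate set and tie rules
brute_youden <- function(scores, labels) {
  s <- sort(unique(scores))
  cand <- c(-Inf, if (length(s) > 1) (s[-length(s)] + s[-1]) / 2, Inf)
  rows <- lapply(cand, function(t) {
    pred <- scores > t
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    data.frame(threshold = t, sensitivity = sens, specificity = spec,
               j = sens + spec - 1)
  })
  df <- do.call(rbind, rows)
  df <- df[order(-df$j, -df$sensitivity, df$threshold), ]
  df[1, ]
}

# brute-force grid tiling count
brute_tile_count <- function(mask, p, frac) {
  gh <- nrow(mask) %/% p
  gw <- ncol(mask) %/% p
  n <- 0
  for (i in seq_len(gh)) for (j in seq_len(gw)) {
    cell <- mask[((i - 1) * p + 1):(i * p), ((j - 1) * p + 1):(j * p)]
    if (mean(cell) >= frac - 1e-12) n <- n + 1
  }
  n
}
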