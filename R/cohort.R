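# Per-stratum covariate distributions. Strata are specimen type x LNM
# status; continuous variables are parameterised by published median/IQR
# (normal on the log scale for sizes/depths, identity scale for age/BMI),
# categoricals by published proportions. Proportions are renormalised so
# each variable sums to 1 within a stratum.
stratum_params <- function(specimen, lnm) {
  key <- paste(specimen, lnm, sep = "_")
  p <- switch(
    key,
    endoscopic_0 = list(
      age = c(med = 59, q1 = 52, q3 = 65), male = .587, bmi = c(med = 23.9, q1 = 22.0, q3 = 26.1),
      comorbidity = .340, family_history = .137,
      smoking = c(.650, .179, .170), alcohol = c(.584, .082, .334),
      right_side = .267, size = c(med = 10.0, q1 = 7.3, q3 = 14.0),
      sm_depth = c(med = 1800, q1 = 1075, q3 = 2300), sm_tier = NULL,
      differentiation = c(.553, .404, .043), lvi = .261, budding = .122,
      margin_positive = .286, msi = c(.250, .024, .726)
    ),
    endoscopic_1 = list(
      age = c(med = 60, q1 = 52, q3 = 68), male = .648, bmi = c(med = 24.8, q1 = 23.3, q3 = 27.4),
      comorbidity = .493, family_history = .141,
      smoking = c(.606, .141, .254), alcohol = c(.437, .127, .437),
      right_side = .296, size = c(med = 8.0, q1 = 7.0, q3 = 12.0),
      sm_depth = c(med = 1500, q1 = 1000, q3 = 2000), sm_tier = NULL,
      differentiation = c(.775, .197, .028), lvi = .310, budding = .127,
      margin_positive = .282, msi = c(.394, .028, .577)
    ),
    surgical_0 = list(
      age = c(med = 60, q1 = 52, q3 = 69), male = .599, bmi = c(med = 24.1, q1 = 22.2, q3 = 26.0),
      comorbidity = .387, family_history = .092,
      smoking = c(.754, .133, .113), alcohol = c(.671, .037, .292),
      right_side = .305, size = c(med = 20.0, q1 = 15.0, q3 = 25.0),
      sm_depth = NULL, sm_tier = c(.408, .237, .355),
      differentiation = c(.615, .367, .018), lvi = .114, budding = .145,
      margin_positive = 0, msi = c(.855, .088, .056)
    ),
    surgical_1 = list(
      age = c(med = 59, q1 = 52, q3 = 67), male = .574, bmi = c(med = 24.8, q1 = 23.0, q3 = 26.0),
      comorbidity = .356, family_history = .109,
      smoking = c(.663, .228, .109), alcohol = c(.624, .059, .317),
      right_side = .208, size = c(med = 16.5, q1 = 14.3, q3 = 25.0),
      sm_depth = NULL, sm_tier = c(.218, .327, .455),
      differentiation = c(.426, .515, .059), lvi = .535, budding = .347,
      margin_positive = 0, msi = c(.881, .069, .050)
    ),
    stopf("unknown stratum %s", key)
  )
  p
}

# Draw n values matching a median/IQR summary. `log = TRUE` samples a
# log-normal (sizes, depths are right-skewed); otherwise a normal with
# sd = IQR / 1.349.
draw_mediqr <- function(n, par, log = FALSE, lower = -Inf, digits = 1) {
  if (n == 0) return(numeric(0))
  if (log) {
    mu <- log(par[["med"]])
    sdl <- (log(par[["q3"]]) - log(par[["q1"]])) / (2 * stats::qnorm(0.75))
    x <- stats::rlnorm(n, mu, sdl)
  } else {
    sd <- (par[["q3"]] - par[["q1"]]) / (2 * stats::qnorm(0.75))
    x <- stats::rnorm(n, par[["med"]], sd)
  }
  round(pmax(x, lower), digits)
}

draw_level <- function(n, probs, levels) {
  if (n == 0) return(character(0))
  sample(levels, n, replace = TRUE, prob = probs / sum(probs))
}

sm_tier_from_depth <- function(depth_um) {
  ifelse(depth_um <= 1000, "SM1", ifelse(depth_um <= 2000, "SM2", "SM3"))
}

draw_stratum <- function(n, specimen, lnm, informative) {
  if (n == 0) {
    return(NULL)
  }
  p <- stratum_params(specimen, lnm)
  if (!informative) {
    # marginal over LNM within specimen: removes the label signal that the
    # published proportions carry (mostly via LVI/budding/differentiation)
    p0 <- stratum_params(specimen, 0)
    w <- if (specimen == "endoscopic") 0.178 else 0.066
    mix <- function(a, b) (1 - w) * b + w * a
    for (nm in c("male", "comorbidity", "family_history", "right_side",
                 "lvi", "budding", "margin_positive")) {
      p[[nm]] <- mix(stratum_params(specimen, 1)[[nm]], p0[[nm]])
    }
    for (nm in c("smoking", "alcohol", "differentiation", "msi")) {
      p[[nm]] <- mix(stratum_params(specimen, 1)[[nm]], p0[[nm]])
    }
    p$size <- p0$size
    if (!is.null(p0$sm_depth)) p$sm_depth <- p0$sm_depth
    if (!is.null(p0$sm_tier)) p$sm_tier <- p0$sm_tier
  }
  if (specimen == "endoscopic") {
    depth <- draw_mediqr(n, p$sm_depth, log = TRUE, lower = 100, digits = 0)
    tier <- sm_tier_from_depth(depth)
  } else {
    tier <- draw_level(n, p$sm_tier, c("SM1", "SM2", "SM3"))
    # representative depths for the tiers (tiers are thirds of the SM layer)
    depth <- round(ifelse(tier == "SM1", stats::runif(n, 200, 1000),
                   ifelse(tier == "SM2", stats::runif(n, 1000, 2000),
                          stats::runif(n, 2000, 3500))))
  }
  data.frame(
    specimen_type = specimen,
    lnm_label = lnm,
    age = draw_mediqr(n, p$age, lower = 20, digits = 0),
    sex = draw_level(n, c(p$male, 1 - p$male), c("male", "female")),
    bmi = draw_mediqr(n, p$bmi, lower = 14, digits = 1),
    comorbidity = stats::rbinom(n, 1, p$comorbidity),
    family_history = stats::rbinom(n, 1, p$family_history),
    smoking = draw_level(n, p$smoking, c("never", "ex", "current")),
    alcohol = draw_level(n, p$alcohol, c("never", "ex", "current")),
    tumor_location = draw_level(n, c(1 - p$right_side, p$right_side),
                                c("left", "right")),
    cancer_size_mm = draw_mediqr(n, p$size, log = TRUE, lower = 1, digits = 1),
    sm_depth_um = depth,
    sm_tier = tier,
    differentiation = draw_level(n, p$differentiation,
                                 c("well", "moderate", "poor")),
    lvi = stats::rbinom(n, 1, p$lvi),
    budding = stats::rbinom(n, 1, p$budding),
    margin_positive = stats::rbinom(n, 1, p$margin_positive),
    msi = draw_level(n, p$msi, c("stable", "unstable", "unknown")),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic T1 colorectal cancer cohort
#'
#' Draws a patient table emulating the statistical structure of the study
#' population: two specimen strata ("endoscopic" resections followed by
#' surgery, and primary "surgical" resections) with stratum-specific LNM
#' prevalence, clinicopathologic covariates drawn per specimen-by-LNM
#' stratum from the published summary distributions, and a fraction of
#' patients contributing two slides.
#'
#' @param n_endoscopic,n_surgical patient counts per specimen stratum.
#' @param prev_endo,prev_surg LNM prevalence per stratum (defaults are the
#'   study values 17.8% and 6.6%).
#' @param seed integer seed; generation is deterministic given the seed.
#' @param rounding `"deterministic"` (default) sets the number of positives
#'   to the nearest integer of n x prevalence; `"binomial"` draws it.
#' @param informative_covariates if `TRUE` (default) covariates are drawn
#'   from the LNM-stratified published proportions, so histologic risk
#'   factors (LVI, budding, differentiation) carry a weak label signal, as
#'   they do in the study table; if `FALSE`, covariates are drawn from the
#'   specimen-stratum marginals and carry no label signal.
#' @param two_slide_rate fraction of patients assigned a second slide
#'   (default 0.10), so slide totals exceed patient totals.
#' @return data.frame of class `patient_cohort`, one row per patient, with
#'   `patient_id`, `specimen_type`, `lnm_label`, covariates, `n_slides`.
#' @examples
#' cohort <- generate_cohort(40, 88, seed = 1)
#' table(cohort$specimen_type, cohort$lnm_label)
#' @export
generate_cohort <- function(n_endoscopic, n_surgical,
                            prev_endo = 0.178, prev_surg = 0.066,
                            seed = 1,
                            rounding = c("deterministic", "binomial"),
                            informative_covariates = TRUE,
                            two_slide_rate = 0.10) {
  rounding <- match.arg(rounding)
  assert_that(n_endoscopic >= 0 && n_surgical >= 0, "patient counts must be >= 0")
  assert_that(prev_endo >= 0 && prev_endo <= 1 && prev_surg >= 0 && prev_surg <= 1,
              "prevalences must lie in [0, 1]")
  with_seed(seed, {
    n_pos <- if (rounding == "deterministic") {
      c(endo = round_half_up(n_endoscopic * prev_endo, 0),
        surg = round_half_up(n_surgical * prev_surg, 0))
    } else {
      c(endo = stats::rbinom(1, n_endoscopic, prev_endo),
        surg = stats::rbinom(1, n_surgical, prev_surg))
    }
    parts <- list(
      draw_stratum(n_endoscopic - n_pos[["endo"]], "endoscopic", 0, informative_covariates),
      draw_stratum(n_pos[["endo"]], "endoscopic", 1, informative_covariates),
      draw_stratum(n_surgical - n_pos[["surg"]], "surgical", 0, informative_covariates),
      draw_stratum(n_pos[["surg"]], "surgical", 1, informative_covariates)
    )
    cohort <- do.call(rbind, parts[!vapply(parts, is.null, TRUE)])
    if (is.null(cohort)) {
      cohort <- draw_stratum(1, "endoscopic", 0, TRUE)[0, ]
    }
    n <- nrow(cohort)
    cohort$margin_positive[cohort$specimen_type == "surgical"] <- 0L
    cohort$n_slides <- if (n > 0) 1L + stats::rbinom(n, 1, two_slide_rate) else integer(0)
    cohort$patient_id <- if (n > 0) sprintf("P%04d", seq_len(n)) else character(0)
    rownames(cohort) <- NULL
    cohort <- cohort[, c("patient_id", setdiff(names(cohort), "patient_id"))]
    class(cohort) <- c("patient_cohort", "data.frame")
    cohort
  })
}

#' Summarise a cohort and its lymph-node yield
#'
#' @param cohort a `patient_cohort`.
#' @param ln_positive,ln_total positive and total lymph nodes retrieved
#'   across the cohort's surgeries (`ln_total >= ln_positive >= 0`).
#' @return list with per-stratum and overall prevalence (percent, one
#'   decimal, half-up) and the LN ratio (percent, two decimals).
#' @examples
#' # the published cohort arithmetic: (58 + 71) / 1281 -> 10.1%
#' ch <- generate_cohort(400, 881, seed = 7)
#' cohort_summary(ch, ln_positive = 273, ln_total = 22022)
#' @export
cohort_summary <- function(cohort, ln_positive = NA, ln_total = NA) {
  if (!is.na(ln_positive) || !is.na(ln_total)) {
    assert_that(ln_total >= ln_positive && ln_positive >= 0,
                "need ln_total >= ln_positive >= 0")
  }
  n <- nrow(cohort)
  strat <- function(sp) {
    sub <- cohort[cohort$specimen_type == sp, ]
    if (nrow(sub) == 0) return(c(n = 0, positives = 0, prevalence_pct = NA_real_))
    c(n = nrow(sub), positives = sum(sub$lnm_label),
      prevalence_pct = round_half_up(100 * mean(sub$lnm_label), 1))
  }
  list(
    n_patients = n,
    n_slides = if (n > 0) sum(cohort$n_slides) else 0L,
    endoscopic = strat("endoscopic"),
    surgical = strat("surgical"),
    overall_prevalence_pct = if (n > 0) round_half_up(100 * mean(cohort$lnm_label), 1) else NA_real_,
    ln_ratio_pct = if (!is.na(ln_positive) && ln_total > 0) {
      round_half_up(100 * ln_positive / ln_total, 2)
    } else NA_real_
  )
}

#' Write / read a cohort table as CSV
#'
#' @param cohort a `patient_cohort`.
#' @param path file path.
#' @return `path` invisibly (`write_cohort_csv`) or the cohort
#'   (`read_cohort_csv`).
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(cohort) <- c("patient_cohort", "data.frame")
  cohort
}

#' Encode cohort covariates for the tabular baseline
#'
#' Produces the numeric/factor feature frame used by [rf_baseline()]:
#' the clinical and pathologic covariates (age, sex, BMI, comorbidity,
#' family history, smoking, alcohol, location, cancer size, submucosal
#' invasion depth tier, LVI, differentiation, budding, MSI), excluding
#' identifiers, labels and slide counts.
#'
#' @param cohort a `patient_cohort`.
#' @return data.frame of factors and numerics, rows aligned with `cohort`.
#' @export
cohort_features <- function(cohort) {
  f <- data.frame(
    age = cohort$age,
    sex = factor(cohort$sex, levels = c("male", "female")),
    bmi = cohort$bmi,
    comorbidity = cohort$comorbidity,
    family_history = cohort$family_history,
    smoking = factor(cohort$smoking, levels = c("never", "ex", "current")),
    alcohol = factor(cohort$alcohol, levels = c("never", "ex", "current")),
    tumor_location = factor(cohort$tumor_location, levels = c("left", "right")),
    cancer_size_mm = cohort$cancer_size_mm,
    sm_tier = factor(cohort$sm_tier, levels = c("SM1", "SM2", "SM3")),
    differentiation = factor(cohort$differentiation,
                             levels = c("well", "moderate", "poor")),
    lvi = cohort$lvi,
    budding = cohort$budding,
    msi = factor(cohort$msi, levels = c("stable", "unstable", "unknown"))
  )
  rownames(f) <- cohort$patient_id
  f
}
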