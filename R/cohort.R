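# ---------------------------------------------------------------------------
# Synthetic cohort: a clinical/procedural covariate table whose binary
# outcome (residual >= moderate PVL) follows a known logistic model on
# standardized latent drivers, plus optional co-registered phantom volumes
# whose calcification volume agrees with the tabular covariate.
# ---------------------------------------------------------------------------

#' Specification of a synthetic cohort
#'
#' The outcome is drawn from `y ~ Bernoulli(plogis(a + sum(beta_j z_j)))`
#' where `z_j` are cohort-standardized drivers. The default drivers and signs
#' follow the anatomical contrasts reported for leak-prone roots: higher
#' calcification burden, larger annular perimeter and sinotubular-junction
#' diameter, older age, male sex. The intercept is calibrated so the expected
#' event rate equals `event_rate` (16.7% = 35/210 in the reference cohort).
#'
#' @param n_total cohort size (>= 10).
#' @param event_rate target event rate.
#' @param coefficients named log-odds per standardized unit of each driver;
#'   names must be `log_calc_volume`, `annular_perimeter_mm`,
#'   `stj_diameter_mm`, `age_years`, `sex_male` (any subset).
#' @param seed RNG seed.
#' @export
cohort_spec <- function(n_total = 210L, event_rate = 35 / 210,
                        coefficients = c(log_calc_volume = 1.4,
                                         annular_perimeter_mm = 0.75,
                                         stj_diameter_mm = 0.75,
                                         age_years = 0.45,
                                         sex_male = 0.75),
                        seed = 1L) {
  if (n_total < 10) stop("n_total must be at least 10")
  if (event_rate < 0 || event_rate > 1) stop("event_rate must be in [0, 1]")
  if (n_total * event_rate < 1) {
    warning("expected event count below 1; downstream cross-validation ",
            "will likely fail")
  }
  structure(list(n_total = as.integer(n_total), event_rate = event_rate,
                 coefficients = coefficients, seed = as.integer(seed)),
            class = "pvl_cohort_spec")
}

# continuous covariates: name, location, scale, generator shape
.clin_continuous <- c("age_years", "bmi_kg_m2", "sts_score_pct", "lvef_pct",
                      "lvedd_mm", "annular_perimeter_mm", "annular_area_mm2",
                      "sov_perimeter_mm", "stj_diameter_mm",
                      "lvot_perimeter_mm", "max_ascending_mm",
                      "calc_volume_mm3", "post_dilatation_balloon_mm")
.clin_binary <- c("sex_male", "hypertension", "diabetes", "copd", "cad",
                  "ckd", "af", "pvd", "prior_stroke", "new_gen_thv",
                  "thv_lt_26mm", "transfemoral", "pre_dilatation")
.binary_prev <- c(sex_male = 0.567, hypertension = 0.306, diabetes = 0.179,
                  copd = 0.154, cad = 0.236, ckd = 0.052, af = 0.087,
                  pvd = 0.184, prior_stroke = 0.107, new_gen_thv = 0.386,
                  thv_lt_26mm = 0.338, transfemoral = 0.99,
                  pre_dilatation = 0.948)

# Draw the covariate table (no outcome yet). Marginals are centred on the
# published cohort medians/IQRs; anatomy covariates are mutually correlated
# through the annular perimeter so the "globally dilated root" phenotype
# exists in the synthetic population too.
.draw_covariates <- function(n) {
  age <- round(rnorm(n, 72, 7))
  bmi <- round(rnorm(n, 22.7, 3.3), 1)
  sts <- round(exp(rnorm(n, log(2.75), 0.55)), 2)
  lvef <- round(pmin(pmax(rnorm(n, 56, 13), 15), 78))
  lvedd <- round(rnorm(n, 50, 8))
  ann_per <- rnorm(n, 78.6, 9.5)
  ecc <- runif(n, 1.02, 1.15)                 # perimeter excess over circle
  ann_area <- (ann_per / ecc)^2 / (4 * pi) + rnorm(n, 0, 20)
  sov_per <- 1.38 * ann_per + rnorm(n, 0, 5)
  stj <- 0.25 * ann_per + rnorm(n, 11.5, 2.8)
  lvot_per <- ann_per + rnorm(n, 5, 6)
  asc <- 0.28 * stj + rnorm(n, 33.8, 4)
  calc <- exp(rnorm(n, log(578), 0.75))
  balloon <- sample(c(18, 20, 22, 24), n, replace = TRUE,
                    prob = c(0.15, 0.45, 0.3, 0.1))
  cont <- data.frame(age_years = age, bmi_kg_m2 = bmi, sts_score_pct = sts,
                     lvef_pct = lvef, lvedd_mm = lvedd,
                     annular_perimeter_mm = round(ann_per, 1),
                     annular_area_mm2 = round(ann_area, 1),
                     sov_perimeter_mm = round(sov_per, 1),
                     stj_diameter_mm = round(stj, 1),
                     lvot_perimeter_mm = round(lvot_per, 1),
                     max_ascending_mm = round(asc, 1),
                     calc_volume_mm3 = round(calc, 1),
                     post_dilatation_balloon_mm = balloon)
  for (nm in .clin_binary) {
    cont[[nm]] <- rbinom(n, 1, .binary_prev[[nm]])
  }
  cont
}

.zstd <- function(x) (x - mean(x)) / stats::sd(x)

# Linear predictor (without intercept) of the outcome model.
.cohort_lp <- function(tab, coefficients) {
  drivers <- list(log_calc_volume = .zstd(log1p(tab$calc_volume_mm3)),
                  annular_perimeter_mm = .zstd(tab$annular_perimeter_mm),
                  stj_diameter_mm = .zstd(tab$stj_diameter_mm),
                  age_years = .zstd(tab$age_years),
                  sex_male = tab$sex_male - mean(tab$sex_male))
  unknown <- setdiff(names(coefficients), names(drivers))
  if (length(unknown)) stop("unknown outcome drivers: ",
                            paste(unknown, collapse = ", "))
  lp <- rep(0, nrow(tab))
  for (nm in names(coefficients)) lp <- lp + coefficients[[nm]] * drivers[[nm]]
  lp
}

#' Generate a synthetic cohort (clinical table, optionally phantom volumes)
#'
#' @param spec a [cohort_spec()].
#' @param phantom_defaults a [phantom_params()] object used as the template
#'   for every patient's phantom; per-patient target calcification volume and
#'   root radius are taken from the clinical record.
#' @param images generate phantom volumes (`TRUE`) or the table only.
#' @return list with `clinical` (data.frame incl. `pvl_ge_moderate` outcome),
#'   `samples` (list of `pvl_volume_sample` or NULL), and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            phantom_defaults = phantom_params(),
                            images = TRUE) {
  with_seed(spec$seed, {
    n <- spec$n_total
    tab <- .draw_covariates(n)
    tab$patient_id <- sprintf("P%04d", seq_len(n))
    lp0 <- .cohort_lp(tab, spec$coefficients)
    if (spec$event_rate <= 0) {
      intercept <- -Inf
    } else if (spec$event_rate >= 1) {
      intercept <- Inf
    } else {
      intercept <- stats::uniroot(function(a) {
        mean(stats::plogis(a + lp0)) - spec$event_rate
      }, c(-30, 30))$root
    }
    prob <- stats::plogis(intercept + lp0)
    tab$pvl_ge_moderate <- rbinom(n, 1, prob)
    tab <- tab[, c("patient_id", .clin_continuous, .clin_binary,
                   "pvl_ge_moderate")]
    attr(tab, "latent_prob") <- prob
    attr(tab, "intercept") <- intercept
    samples <- NULL
    if (images) {
      seeds <- sample.int(.Machine$integer.max, n)
      samples <- lapply(seq_len(n), function(i) {
        p <- phantom_defaults
        p$target_calc_volume_mm3 <- tab$calc_volume_mm3[i]
        p$root_radius_mm <- tab$annular_perimeter_mm[i] / (2 * pi) +
          p$wall_mm + 1
        p$seed <- seeds[i]
        generate_phantom(p, patient_id = tab$patient_id[i])
      })
    }
    list(clinical = tab, samples = samples, spec = spec)
  })
}

#' Write a cohort to disk (CSV table + NIfTI volume triplets)
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  for (s in cohort$samples %||% list()) {
    write_nifti(s$ct, file.path(dir, paste0(s$patient_id, "_ct.nii.gz")),
                spacing = s$spacing, datatype = "float32")
    write_nifti(s$root_mask,
                file.path(dir, paste0(s$patient_id, "_root.nii.gz")),
                spacing = s$spacing, datatype = "uint8")
    write_nifti(s$calc_mask,
                file.path(dir, paste0(s$patient_id, "_calc.nii.gz")),
                spacing = s$spacing, datatype = "uint8")
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @param images read the NIfTI volumes too.
#' @export
read_cohort <- function(dir, images = TRUE) {
  tab <- utils::read.csv(file.path(dir, "clinical.csv"))
  samples <- NULL
  if (images) {
    samples <- lapply(tab$patient_id, function(id) {
      ct <- read_nifti(file.path(dir, paste0(id, "_ct.nii.gz")))
      root <- read_nifti(file.path(dir, paste0(id, "_root.nii.gz")))
      calc <- read_nifti(file.path(dir, paste0(id, "_calc.nii.gz")))
      structure(list(patient_id = id, ct = ct$data,
                     root_mask = root$data, calc_mask = calc$data,
                     spacing = ct$spacing,
                     calc_volume_mm3 = sum(calc$data) * prod(ct$spacing)),
                class = "pvl_volume_sample")
    })
  }
  list(clinical = tab, samples = samples)
}
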