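#' Configuration of a synthetic neonatal DTI / toddler gait cohort
#'
#' Defines every parameter of the generator: cohort size and scan-age
#' distribution, the per-region diffusion-tensor eigenvalue model (baseline
#' triples in mm^2/s, linear maturation slopes per week of postmenstrual
#' age, and eigenvalue noise), the planted outcome signal (which features
#' carry real effects and how strong), the clinical outcome scale and
#' normative reference, the target impairment prevalence, and the binary
#' MRI findings model.
#'
#' Defaults emulate the study conditions the analysis is designed for:
#' 52 subjects scanned at 36.5 (SD 1.2) weeks postmenstrual age, a
#' velocity-like outcome with impairment prevalence 14/52, three planted
#' features, and a signal strength giving population R^2 of about 0.5.
#' The default feature pool is 20 (region, metric) pairs — the first five
#' atlas regions by all four metrics — which keeps exhaustive searches
#' fast; the full 99 x 4 grid is available via `n_features = 396`.
#'
#' @param seed Integer seed; the cohort is fully reproducible from it.
#'   Internally split into independent sub-streams (scan ages, tensors,
#'   outcome noise, findings), so enlarging the region pool does not
#'   perturb the outcome noise.
#' @param n_subjects Cohort size (default 52).
#' @param n_features Size of the (region, metric) feature pool
#'   (default 20); drawn region-major from `regions`.
#' @param regions Region vocabulary (default [dti_atlas()]).
#' @param pma_mean_weeks,pma_sd_weeks Scan-age distribution (weeks);
#'   defaults 36.5 and 1.2, truncated at +/- 3 SD.
#' @param eigen_baseline Function of a region index returning the baseline
#'   eigenvalue triple (mm^2/s, descending); the default spans typical
#'   neonatal white-matter values (MD ~ 1.0-1.4e-3 mm^2/s, FA ~ 0.15-0.45).
#' @param eigen_slope Per-week maturation slopes of the three eigenvalues
#'   (mm^2/s per week). The default shrinks the radial eigenvalues faster
#'   than the axial one, so FA rises while MD and RD fall with age — the
#'   maturational directionality regional DTI shows.
#' @param eigen_noise_sd Subject-level eigenvalue noise SDs (mm^2/s), one
#'   per eigenvalue. The default spreads variation unevenly across the
#'   eigenvalues so the within-region metric correlations are strong but
#'   well short of singular (worst pairs |r| ~ 0.75-0.8), the regime in
#'   which a planted signal is identifiable.
#' @param planted_features Character vector of k feature identifiers
#'   carrying real effects (default: 3 spread across the pool).
#' @param planted_weights Effect weights on the standardized planted
#'   features (default `c(1, -0.8, 0.6)`).
#' @param target_r2 Population fraction of latent outcome variance
#'   explained by the planted signal (default 0.5); sets the outcome noise
#'   SD unless `noise_sd` is given.
#' @param noise_sd Outcome noise SD on the latent scale; overrides
#'   `target_r2`. `0` gives a noiseless outcome.
#' @param outcome,direction,normative_mean,normative_sd,normative_n The
#'   outcome name, impairment direction and normative reference (defaults:
#'   a velocity-like outcome in cm/s, low scores impaired, typical mean 95,
#'   SD 16, n 42).
#' @param cohort_sd Clinical-scale SD of the generated cohort outcome
#'   (default `1.15 * normative_sd`: a preterm cohort spreads somewhat
#'   wider than the typical one).
#' @param target_prevalence Target impairment prevalence (default 14/52);
#'   the clinical-scale offset is calibrated so the expected prevalence
#'   matches it.
#' @param findings Tibble with columns `name`, `base_rate` (flag rate among
#'   unimpaired) and `odds_ratio` (association with impairment). Defaults:
#'   four findings with base rates like the published comparison arm and a
#'   mild odds ratio of 2.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(seed = 1L,
                          n_subjects = 52L,
                          n_features = 20L,
                          regions = dti_atlas(),
                          pma_mean_weeks = 36.5,
                          pma_sd_weeks = 1.2,
                          eigen_baseline = default_eigen_baseline,
                          eigen_slope = c(-2e-6, -1.6e-5, -1.6e-5),
                          eigen_noise_sd = c(4.5e-5, 5e-5, 2.5e-5),
                          planted_features = NULL,
                          planted_weights = c(1, -0.9, 0.8),
                          target_r2 = 0.5,
                          noise_sd = NULL,
                          outcome = "velocity",
                          direction = "low_is_impaired",
                          normative_mean = 95,
                          normative_sd = 16,
                          normative_n = 42L,
                          cohort_sd = NULL,
                          target_prevalence = 14 / 52,
                          findings = default_findings()) {
  pool <- head(feature_grid(regions), n_features)
  if (length(pool) < n_features) abort("Region vocabulary too small for 'n_features'.")
  if (is.null(planted_features)) {
    # up to three distinct regions, metrics preferring FA/AD/RD: MD is an
    # exact linear combination of same-region AD and RD, so planting it
    # would make the planted set unidentifiable by construction
    pool_regions <- unique(parse_feature_id(pool)$region)
    rr <- utils::head(pool_regions, 3)
    prefer <- list(c("FA", "AD", "RD"), c("AD", "RD", "FA"), c("RD", "FA", "AD"))
    planted_features <- vapply(seq_along(rr), function(i) {
      cand <- feature_id(rr[i], c(prefer[[i]], "MD"))
      cand[cand %in% pool][1]
    }, "")
    planted_weights <- planted_weights[seq_along(planted_features)]
  }
  if (!all(planted_features %in% pool)) {
    abort("All 'planted_features' must be in the feature pool.")
  }
  if (length(planted_weights) != length(planted_features)) {
    abort("'planted_weights' must match 'planted_features' in length.")
  }
  if (target_prevalence <= 0 || target_prevalence >= 1) {
    abort("'target_prevalence' must be in (0, 1).")
  }
  structure(
    list(
      seed = as.integer(seed), n_subjects = as.integer(n_subjects),
      pool = pool, regions = regions,
      pma_mean_weeks = pma_mean_weeks, pma_sd_weeks = pma_sd_weeks,
      eigen_baseline = eigen_baseline, eigen_slope = eigen_slope,
      eigen_noise_sd = eigen_noise_sd,
      planted_features = planted_features, planted_weights = planted_weights,
      target_r2 = target_r2, noise_sd = noise_sd,
      outcome = outcome, direction = direction,
      normative_mean = normative_mean, normative_sd = normative_sd,
      normative_n = normative_n,
      cohort_sd = cohort_sd %||% (1.15 * normative_sd),
      target_prevalence = target_prevalence,
      findings = findings
    ),
    class = "cohort_config"
  )
}

# Baseline eigenvalue triple (mm^2/s) for region index j: a deterministic
# spread over plausible neonatal white/deep-gray matter values, ordered
# descending. FA at baseline ranges roughly 0.15-0.45.
default_eigen_baseline <- function(j) {
  u <- (j %% 7) / 7 + 0.05 * (j %% 3)  # deterministic variety across regions
  l1 <- (1.45 + 0.35 * u) * 1e-3
  l2 <- (1.05 - 0.15 * u) * 1e-3
  l3 <- (0.95 - 0.20 * u) * 1e-3
  sort(c(l1, l2, l3), decreasing = TRUE)
}

default_findings <- function() {
  tibble::tibble(
    name = c("WMA_present", "cerebellar_signal_abnormality",
             "cerebellar_asymmetry", "IVH_grade_3_or_4"),
    base_rate = c(0.08, 0.16, 0.11, 0.05),
    odds_ratio = c(2, 2, 2, 2)
  )
}

#' Tensor scalar metrics from eigenvalues
#'
#' Computes the four scalar DTI metrics from an eigenvalue triple
#' (vectorized over subjects): axial diffusivity `AD = l1`, radial
#' diffusivity `RD = (l2 + l3) / 2`, mean diffusivity
#' `MD = (AD + 2 RD) / 3` (exactly, by construction), and fractional
#' anisotropy `FA = sqrt(3/2) * sqrt(sum((l - MD)^2)) / sqrt(sum(l^2))`,
#' which lies in \[0, 1\].
#'
#' @param l1,l2,l3 Eigenvalues with `l1 >= l2 >= l3 > 0` (mm^2/s).
#' @return A tibble with columns `FA`, `MD`, `AD`, `RD`.
#' @export
tensor_scalars <- function(l1, l2, l3) {
  ad <- l1
  rd <- (l2 + l3) / 2
  md <- (ad + 2 * rd) / 3
  num <- sqrt((l1 - md)^2 + (l2 - md)^2 + (l3 - md)^2)
  den <- sqrt(l1^2 + l2^2 + l3^2)
  fa <- ifelse(den == 0, 0, sqrt(1.5) * num / den)
  tibble::tibble(FA = pmin(fa, 1), MD = md, AD = ad, RD = rd)
}

#' Sample diffusion-tensor scalars for one region
#'
#' Draws per-subject eigenvalue triples for `region` as
#' baseline + maturation slope x (PMA - mean PMA) + Gaussian noise, re-sorts
#' them in descending order, floors them at a small positive value
#' (1e-9 mm^2/s), and derives the scalar metrics with the exact tensor
#' identities. Uses the current RNG state.
#'
#' @param config A [cohort_config()].
#' @param pma Numeric vector of scan ages (weeks), one per subject.
#' @param region Region label (its index in `config$regions` selects the
#'   baseline).
#' @return A tibble with one row per subject: `region`, `l1`, `l2`, `l3`,
#'   `FA`, `MD`, `AD`, `RD`.
#' @export
sample_tensor_scalars <- function(config, pma, region) {
  j <- match(region, config$regions)
  if (is.na(j)) abort(paste0("Unknown region: ", region))
  base <- config$eigen_baseline(j)
  n <- length(pma)
  dev <- pma - config$pma_mean_weeks
  lam <- t(vapply(seq_len(n), function(i) {
    l <- base + config$eigen_slope * dev[i] +
      rnorm(3, sd = config$eigen_noise_sd)
    pmax(sort(l, decreasing = TRUE), 1e-9)
  }, numeric(3)))
  sc <- tensor_scalars(lam[, 1], lam[, 2], lam[, 3])
  tibble::add_column(sc, region = region, l1 = lam[, 1], l2 = lam[, 2],
                     l3 = lam[, 3], .before = 1)
}

#' Generate a synthetic cohort with a planted gait signal
#'
#' Produces the full bundle the pipeline consumes: a feature table of
#' regional tensor scalars confounded by scan age, a continuous gait
#' outcome driven by the planted features, the normative reference,
#' impairment labels, binary MRI findings associated with impairment, and
#' a truth record (planted set, weights, realized prevalence and signal
#' fraction) for recovery tests.
#'
#' The latent outcome is `sum(w_j * z_j) + noise` over the standardized
#' planted features, affinely mapped to the clinical scale so the cohort
#' has SD `cohort_sd` and the expected impairment prevalence equals
#' `target_prevalence` (the normative threshold cuts the latent
#' distribution at its target quantile). `generate_null_cohort()` zeroes
#' the planted weights, making the outcome independent of every feature.
#'
#' @param config A [cohort_config()].
#' @return A `synthetic_cohort` list: `features` (validated feature
#'   table), `outcome` (tibble `subject_id`, value column named after the
#'   outcome), `reference`, `labels`, `findings`, `truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  streams <- sample.int(.Machine$integer.max - 1L, 4L)
  n <- config$n_subjects
  ids <- sprintf("S%03d", seq_len(n))

  # scan ages: truncated normal at +/- 3 SD via inverse CDF (one draw each)
  set.seed(streams[1])
  u <- runif(n, pnorm(-3), pnorm(3))
  pma <- config$pma_mean_weeks + config$pma_sd_weeks * qnorm(u)

  # tensors, region by region (appending regions never reorders draws)
  set.seed(streams[2])
  pool_ids <- parse_feature_id(config$pool)
  pool_regions <- unique(pool_ids$region)
  scalars <- lapply(pool_regions, function(r) sample_tensor_scalars(config, pma, r))
  names(scalars) <- pool_regions
  vals <- vapply(seq_along(config$pool), function(j) {
    scalars[[pool_ids$region[j]]][[pool_ids$metric[j]]]
  }, numeric(n))
  colnames(vals) <- config$pool
  features <- tibble::tibble(subject_id = ids, pma_weeks = pma)
  features <- dplyr::bind_cols(features, tibble::as_tibble(vals, .name_repair = "minimal"))
  features <- as_feature_table(features, atlas = config$regions)

  # planted signal on the scan-age-adjusted, standardized planted columns:
  # the toddler outcome depends on microstructure, not on when the scan
  # happened, so the PMA component of a feature carries no outcome signal
  qr_pma <- qr(cbind(1, pma))
  zp <- vapply(config$planted_features, function(f) {
    v <- qr.resid(qr_pma, vals[, f])
    (v - mean(v)) / pop_sd(v)
  }, numeric(n))
  signal <- drop(zp %*% config$planted_weights)
  s_sig <- pop_sd(signal)
  noise_sd <- config$noise_sd
  if (is.null(noise_sd)) {
    noise_sd <- if (s_sig == 0) 1 else s_sig * sqrt((1 - config$target_r2) / config$target_r2)
  }
  set.seed(streams[3])
  latent <- signal + rnorm(n, sd = noise_sd)
  s_tot <- pop_sd(latent)
  if (s_tot == 0) {
    abort("Latent outcome is degenerate (zero weights and zero noise); recalibrate the config.")
  }
  z <- (latent - mean(latent)) / s_tot

  ref <- normative_reference(config$outcome, config$normative_mean,
                             config$normative_sd, direction = config$direction,
                             n = config$normative_n)
  # place the cohort on the clinical scale so the impairment threshold cuts
  # the latent distribution at the target prevalence quantile
  if (config$direction == "low_is_impaired") {
    thr <- config$normative_mean - config$normative_sd
    offset <- thr - config$cohort_sd * qnorm(config$target_prevalence)
  } else {
    thr <- config$normative_mean + config$normative_sd
    offset <- thr - config$cohort_sd * qnorm(1 - config$target_prevalence)
  }
  outcome_vals <- offset + config$cohort_sd * z
  outcome <- tibble::tibble(subject_id = ids)
  outcome[[config$outcome]] <- outcome_vals
  labels <- label_impairment(outcome, ref)

  set.seed(streams[4])
  fnd <- tibble::tibble(subject_id = ids)
  for (i in seq_len(nrow(config$findings))) {
    p0 <- config$findings$base_rate[i]
    p <- plogis(qlogis(p0) + log(config$findings$odds_ratio[i]) * labels$impaired)
    fnd[[config$findings$name[i]]] <- rbinom(n, 1, p)
  }

  truth <- list(
    planted_features = config$planted_features,
    planted_weights = config$planted_weights,
    noise_sd = noise_sd,
    realized_prevalence = mean(labels$impaired),
    realized_signal_fraction = if (s_tot == 0) 0 else (s_sig / s_tot)^2,
    outcome = config$outcome,
    direction = config$direction,
    seed = config$seed
  )
  structure(
    list(features = features, outcome = outcome, reference = ref,
         labels = labels, findings = fnd, truth = truth),
    class = "synthetic_cohort"
  )
}

#' @rdname generate_cohort
#' @export
generate_null_cohort <- function(config) {
  config$planted_weights <- rep(0, length(config$planted_features))
  if (is.null(config$noise_sd)) config$noise_sd <- 1
  out <- generate_cohort(config)
  out$truth$null <- TRUE
  out
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d subjects x %d features; outcome '%s' (%s), prevalence %.2f\n",
    nrow(x$features), length(feature_cols(x$features)),
    x$truth$outcome, x$truth$direction, x$truth$realized_prevalence
  ))
  cat("Planted:", paste(x$truth$planted_features, collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic cohort to the delimited formats the readers consume
#'
#' Writes `features.csv`, `outcomes.csv`, `findings.csv`, `reference.yaml`
#' and `truth.json` under `dir`; the files round-trip through
#' [read_feature_table()], [read_gait_outcomes()], [read_mri_findings()]
#' and [read_normative_references()].
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tibble::as_tibble(cohort$features), file.path(dir, "features.csv"))
  readr::write_csv(cohort$outcome, file.path(dir, "outcomes.csv"))
  readr::write_csv(cohort$findings, file.path(dir, "findings.csv"))
  write_normative_references(cohort$reference, file.path(dir, "reference.yaml"))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_truth_record <- function(dir) {
  jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
}
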