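#' Cohort specification for phenotype simulation
#'
#' Describes a phenotype-generating model on top of a phased panel:
#' intercept (TPM or Z units), per-term genetic effect sizes keyed by
#' design-column name (haplotype-count columns `hap_<label>` or dosage
#' columns `dos_<snp>`), covariate effects, residual noise, and an
#' optional genotype-by-age-group interaction slope.
#'
#' @param n cohort size (>= 1).
#' @param intercept phenotype intercept.
#' @param effects named numeric vector of genetic effects (per allele /
#'   haplotype copy); names must match design-column names, e.g.
#'   `c("hap_Long-T" = -24.18)`.
#' @param sex_effect,age_effect additive covariate effects (sex coded
#'   0/1; age in years).
#' @param age_range ages drawn uniformly over this range (years).
#' @param noise_sd residual Gaussian noise standard deviation (> 0).
#' @param interaction named numeric of length 1 or `NULL`: a
#'   genotype-by-5-year-age-group interaction slope, keyed like
#'   `effects`.
#' @param floor_zero truncate phenotypes at 0 (off by default).
#' @param smoking_levels number of smoking categories sampled uniformly
#'   (0 disables the column).
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n, intercept = 0, effects = numeric(0),
                        sex_effect = 0, age_effect = 0,
                        age_range = c(38, 73), noise_sd = 1,
                        interaction = NULL, floor_zero = FALSE,
                        smoking_levels = 0L) {
  stopifnot(n >= 1, noise_sd > 0, length(age_range) == 2L,
            age_range[2] >= age_range[1])
  if (length(effects) && is.null(names(effects))) {
    stop("`effects` must be named by design column", call. = FALSE)
  }
  structure(list(n = as.integer(n), intercept = intercept, effects = effects,
                 sex_effect = sex_effect, age_effect = age_effect,
                 age_range = age_range, noise_sd = noise_sd,
                 interaction = interaction, floor_zero = floor_zero,
                 smoking_levels = as.integer(smoking_levels)),
            class = "cohort_spec")
}

## Shared machinery: draw individuals from the panel, build design
## columns (haplotype counts + dosages + covariates) and the phenotype.
build_cohort <- function(panel, spec, seed, hap_snp, z_scale = FALSE) {
  stopifnot(inherits(panel, "phased_panel"), inherits(spec, "cohort_spec"))
  with_seed(seed, {
    npan <- n_individuals(panel)
    idx <- if (spec$n <= npan) sample(npan, spec$n) else
      sample(npan, spec$n, replace = TRUE)
    sub <- panel_subset(panel, idx)

    hc <- code_haplotypes(sub, snp = hap_snp)
    df <- data.frame(id = sub$individuals$id, stringsAsFactors = FALSE)
    for (lab in colnames(hc)) df[[paste0("hap_", lab)]] <- hc[, lab]
    for (snp in colnames(sub$haplotypes)) {
      df[[paste0("dos_", snp)]] <- marker_dosage(sub, snp)
    }
    df$sex <- as.integer(stats::runif(spec$n) < 0.5)
    df$age <- stats::runif(spec$n, spec$age_range[1], spec$age_range[2])
    if (spec$smoking_levels > 0L) {
      df$smoking <- sample.int(spec$smoking_levels, spec$n, replace = TRUE) - 1L
    }

    missing <- setdiff(names(spec$effects), names(df))
    if (length(missing)) {
      stop(sprintf("effect terms not present in design: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    y <- rep(spec$intercept, spec$n)
    for (tm in names(spec$effects)) y <- y + spec$effects[[tm]] * df[[tm]]
    y <- y + spec$sex_effect * df$sex + spec$age_effect * df$age
    if (!is.null(spec$interaction)) {
      tm <- names(spec$interaction)
      if (!tm %in% names(df)) {
        stop(sprintf("interaction term %s not present in design", tm),
             call. = FALSE)
      }
      grp <- floor(df$age / 5)
      y <- y + spec$interaction[[tm]] * df[[tm]] * grp
    }
    y <- y + stats::rnorm(spec$n, 0, spec$noise_sd)
    if (spec$floor_zero) y <- pmax(y, 0)
    df$phenotype <- if (z_scale) as.numeric(scale(y)) else y
    df
  })
}

#' Simulate an expression cohort from a phased panel
#'
#' Tumor-expression-like cohort: phenotype (TPM scale) built as
#' `intercept + sum(effect * count) + covariates + noise`, with haplotype
#' counts of the VNTR class combined with `hap_snp` and additive dosage
#' columns for every SNP. The defaults mirror a pediatric tumor cohort
#' (ages drawn 1-15).
#'
#' @param panel a `phased_panel`.
#' @param spec a [cohort_spec()]; see [bl_cohort_spec()] for the default
#'   parameterization.
#' @param seed integer seed.
#' @param hap_snp SNP combined with the VNTR for haplotype counts.
#' @return data.frame with `id`, `phenotype`, haplotype-count columns
#'   (`hap_*`), dosage columns (`dos_*`), `sex` and `age`.
#' @export
simulate_expression_cohort <- function(panel, spec, seed,
                                       hap_snp = "rs10069690") {
  build_cohort(panel, spec, seed, hap_snp, z_scale = FALSE)
}

#' Default expression-cohort specification
#'
#' 78 individuals, intercept 59.7 TPM, haplotype effects (relative to the
#' Short-C reference) Short-T -12.2, Long-C -15.92 and Long-T -24.18
#' TPM, ages 1-15, residual noise 45 TPM.
#'
#' @param n cohort size.
#' @param noise_sd residual standard deviation (TPM).
#' @return A `cohort_spec`.
#' @export
bl_cohort_spec <- function(n = 78L, noise_sd = 45) {
  cohort_spec(n = n, intercept = 59.7,
              effects = c(`hap_Short-T` = -12.2, `hap_Long-C` = -15.92,
                          `hap_Long-T` = -24.18),
              age_range = c(1, 15), noise_sd = noise_sd)
}

#' Simulate a telomere-length cohort with an age-group interaction
#'
#' Biobank-like cohort for relative leukocyte telomere length (rLTL):
#' additive haplotype effect, age trend, optional genotype-by-5-year-age-
#' group interaction slope and a smoking covariate; the phenotype is
#' returned on its generated scale (rLTL effects are specified in Z
#' units, so the default noise of ~1 keeps the phenotype approximately
#' standardized). Ages must span at least two 5-year groups.
#'
#' @inheritParams simulate_expression_cohort
#' @return data.frame as in [simulate_expression_cohort()] plus
#'   `smoking` when configured.
#' @export
simulate_rltl_cohort <- function(panel, spec, seed, hap_snp = "rs10069690") {
  if (floor(spec$age_range[2] / 5) == floor(spec$age_range[1] / 5)) {
    stop("ages must span at least two 5-year groups", call. = FALSE)
  }
  build_cohort(panel, spec, seed, hap_snp, z_scale = FALSE)
}

#' Default telomere-length cohort specification
#'
#' 100,000 individuals, Short-C haplotype effect -0.049 Z units per copy,
#' age trend -0.0025 per year (about -0.025 per decade), smoking in three
#' categories, residual noise 0.95, ages 38-73.
#'
#' @param n cohort size.
#' @param interaction optional named interaction slope (see
#'   [cohort_spec()]).
#' @return A `cohort_spec`.
#' @export
ukb_cohort_spec <- function(n = 100000L, interaction = NULL) {
  cohort_spec(n = n, intercept = 0.35,
              effects = c(`hap_Short-C` = -0.049),
              age_effect = -0.0025, age_range = c(38, 73),
              noise_sd = 0.95, smoking_levels = 3L,
              interaction = interaction)
}
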