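#' Additive dosage coding of biallelic genotypes
#'
#' Counts copies of the effect allele per individual: `"CC"/"CT"/"TT"`
#' with effect allele `"T"` codes to 0/1/2. Missing genotypes yield
#' missing dosages (complete-case handling happens downstream).
#'
#' @param genotypes character vector of two-letter genotypes (e.g.
#'   `"CT"`), or `NA`.
#' @param effect_allele single base counted as the effect allele.
#' @return Integer dosage vector (0, 1, 2 or `NA`).
#' @export
#' @examples
#' code_additive(c("CC", "CT", "TT"), "T")
code_additive <- function(genotypes, effect_allele) {
  stopifnot(is.character(effect_allele), nchar(effect_allele) == 1L)
  out <- vapply(genotypes, function(g) {
    if (is.na(g)) return(NA_integer_)
    if (nchar(g) != 2L) stop("genotypes must be two-letter strings",
                             call. = FALSE)
    sum(strsplit(g, "", fixed = TRUE)[[1L]] == effect_allele)
  }, integer(1), USE.NAMES = FALSE)
  out
}

#' Marker dosage from a phased panel
#'
#' @param panel a `phased_panel`.
#' @param marker marker id.
#' @return Integer alt-allele dosage (0/1/2) per individual.
#' @export
marker_dosage <- function(panel, marker) {
  stopifnot(inherits(panel, "phased_panel"))
  x <- panel$haplotypes[, marker]
  x[c(TRUE, FALSE)] + x[c(FALSE, TRUE)]
}

#' Haplotype coding of phased VNTR/SNP diplotypes
#'
#' Combines each haplotype's VNTR class (Short/Long) with its allele at a
#' SNP into four haplotype labels (e.g. Short-C, Short-T, Long-C,
#' Long-T), and counts them per individual. The reference haplotype
#' (default the first in allele order, Short-ref) is retained in the
#' count matrix but omitted from regression designs.
#'
#' @param panel a `phased_panel` (phase is required).
#' @param snp SNP id combined with the VNTR class.
#' @return Integer matrix of class `haplotype_coding`, one row per
#'   individual and one column per haplotype label; rows sum to 2. The
#'   reference label is stored in the `reference` attribute.
#' @export
code_haplotypes <- function(panel, snp = "rs10069690") {
  stopifnot(inherits(panel, "phased_panel"))
  if (!isTRUE(attr(panel, "phased"))) {
    stop("haplotype coding requires phased input", call. = FALSE)
  }
  mk <- panel$markers[panel$markers$id == snp, ]
  if (nrow(mk) != 1L) stop(sprintf("unknown marker %s", snp), call. = FALSE)
  allele <- ifelse(panel$haplotypes[, snp] == 1, mk$alt, mk$ref)
  lab <- paste(vntr_hap_class(panel), allele, sep = "-")
  levels <- paste(rep(c("Short", "Long"), each = 2L),
                  c(mk$ref, mk$alt), sep = "-")
  lab <- factor(lab, levels = levels)
  idx <- rep(seq_len(n_individuals(panel)), each = 2L)
  counts <- t(vapply(split(lab, idx), function(x) tabulate(x, length(levels)),
                     integer(length(levels))))
  colnames(counts) <- levels
  rownames(counts) <- panel$individuals$id
  structure(counts, class = "haplotype_coding",
            reference = levels[1L], snp = snp)
}

## Build a model frame from a cohort data.frame with complete-case
## filtering; terms are column names.
design_frame <- function(data, response, terms) {
  stopifnot(is.data.frame(data), response %in% names(data),
            all(terms %in% names(data)))
  if (anyDuplicated(c(response, terms))) {
    stop("column labels must be unique", call. = FALSE)
  }
  df <- data[, c(response, terms), drop = FALSE]
  df[stats::complete.cases(df), , drop = FALSE]
}

fit_table <- function(coefs) {
  data.frame(term = gsub("`", "", rownames(coefs), fixed = TRUE),
             beta = coefs[, 1], se = coefs[, 2],
             stat = coefs[, 3], p = coefs[, 4],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Linear regression fit (OLS)
#'
#' Ordinary least squares via the QR decomposition (through
#' [stats::lm()]), with t statistics on `n - p` degrees of freedom.
#' Rank-deficient designs are rejected with the offending columns named.
#'
#' @param data cohort data.frame.
#' @param response response column name.
#' @param terms character vector of predictor column names.
#' @return An `assoc_fit`: data.frame with `term`, `beta`, `se`, `stat`,
#'   `p`; attributes `loglik`, `n`, `family`.
#' @export
fit_linear <- function(data, response, terms) {
  df <- design_frame(data, response, terms)
  if (nrow(df) <= length(terms) + 1L) {
    stop("need more observations than model columns", call. = FALSE)
  }
  fm <- stats::reformulate(sprintf("`%s`", terms),
                           response = sprintf("`%s`", response))
  fit <- stats::lm(fm, data = df)
  alias <- is.na(stats::coef(fit))
  if (any(alias)) {
    stop(sprintf("rank-deficient design; collinear columns: %s",
                 paste(names(stats::coef(fit))[alias], collapse = ", ")),
         call. = FALSE)
  }
  out <- fit_table(summary(fit)$coefficients)
  attr(out, "loglik") <- as.numeric(stats::logLik(fit))
  attr(out, "n") <- nrow(df)
  attr(out, "family") <- "gaussian"
  class(out) <- c("assoc_fit", class(out))
  out
}

#' Logistic regression fit
#'
#' Maximum-likelihood binomial fit (through [stats::glm()], IRLS to
#' convergence) with Wald tests. Perfect or quasi-perfect separation is
#' detected (non-convergence or fitted probabilities collapsing to 0/1)
#' and reported via the `separation` attribute and a warning.
#'
#' @inheritParams fit_linear
#' @return An `assoc_fit` (see [fit_linear()]); `family` is
#'   `"binomial"`.
#' @export
fit_logistic <- function(data, response, terms) {
  df <- design_frame(data, response, terms)
  y <- df[[response]]
  if (length(unique(y)) < 2L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  fm <- stats::reformulate(sprintf("`%s`", terms),
                           response = sprintf("`%s`", response))
  fit <- withCallingHandlers(
    stats::glm(fm, data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) invokeRestart("muffleWarning"))
  alias <- is.na(stats::coef(fit))
  if (any(alias)) {
    stop(sprintf("rank-deficient design; collinear columns: %s",
                 paste(names(stats::coef(fit))[alias], collapse = ", ")),
         call. = FALSE)
  }
  mu <- stats::fitted(fit)
  separated <- !fit$converged || any(mu < 1e-8) || any(mu > 1 - 1e-8)
  if (separated) {
    warning("possible separation: fitted probabilities at 0/1 or IRLS divergence")
  }
  out <- fit_table(summary(fit)$coefficients)
  attr(out, "loglik") <- as.numeric(stats::logLik(fit))
  attr(out, "n") <- nrow(df)
  attr(out, "family") <- "binomial"
  attr(out, "separation") <- separated
  class(out) <- c("assoc_fit", class(out))
  out
}

#' @export
print.assoc_fit <- function(x, ...) {
  cat(sprintf("%s fit, n = %d\n", attr(x, "family"), attr(x, "n")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Conditional association fit
#'
#' Refits the model with an additional marker column, reporting both
#' marker terms; used to test whether one signal is accounted for by
#' another. Perfectly collinear marker pairs are rejected.
#'
#' @inheritParams fit_linear
#' @param conditioned_on column name of the additional marker.
#' @param family `"gaussian"` or `"binomial"`.
#' @return An `assoc_fit` including both marker terms.
#' @export
conditional_fit <- function(data, response, terms, conditioned_on,
                            family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  stopifnot(conditioned_on %in% names(data))
  present <- intersect(terms, names(data))
  for (tm in present) {
    r <- stats::cor(data[[tm]], data[[conditioned_on]],
                    use = "complete.obs")
    if (!is.na(r) && r^2 > 1 - 1e-12) {
      stop(sprintf("marker %s is perfectly collinear with %s (r2 = 1)",
                   conditioned_on, tm), call. = FALSE)
    }
  }
  fitter <- if (family == "gaussian") fit_linear else fit_logistic
  fitter(data, response, c(terms, conditioned_on))
}

#' Genotype-by-age-group interaction fit
#'
#' Bins age left-closed into `group_width`-year groups (anchored at the
#' cohort's youngest age) coded as an ordinal index, and adds a
#' genotype-by-group-index product term to the linear model; `p_int` is
#' the product term's Wald p-value.
#'
#' @inheritParams fit_linear
#' @param genetic column name of the genetic term (dosage or haplotype
#'   count).
#' @param age_col age column name (years).
#' @param group_width age-group width in years.
#' @return An `assoc_fit` with attribute `p_int` and the interaction term
#'   named `<genetic>:age_group`.
#' @export
interaction_fit <- function(data, response, genetic, terms = character(0),
                            age_col = "age", group_width = 5) {
  stopifnot(genetic %in% names(data), age_col %in% names(data))
  age <- data[[age_col]]
  grp <- floor((age - min(age, na.rm = TRUE)) / group_width)
  if (length(unique(grp[!is.na(grp)])) < 2L) {
    stop("ages span a single age group; interaction not estimable",
         call. = FALSE)
  }
  d <- data
  d[["age_group"]] <- grp
  int_col <- paste0(genetic, ":age_group")
  d[[int_col]] <- d[[genetic]] * grp
  fit <- fit_linear(d, response,
                    unique(c(genetic, terms, "age_group", int_col)))
  attr(fit, "p_int") <- fit$p[fit$term == int_col]
  fit
}

## t statistic of column j (1-based, excluding intercept handling: X must
## already contain an intercept column) for response y.
ols_tstat <- function(X, y, j) {
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  dfres <- length(y) - fit$rank
  R <- fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]
  XtX_inv <- chol2inv(R)
  pj <- match(j, fit$qr$pivot)  # pivoted column position
  se <- sqrt(rss / dfres * XtX_inv[pj, pj])
  fit$coefficients[j] / se
}

#' Permutation p-value for a genetic term
#'
#' Permutes the genetic term's values across individuals while holding
#' the response and covariates fixed, refitting the linear model each
#' time; the empirical p-value uses the add-one rule
#' `(1 + #(|t_perm| >= |t_obs|)) / (n_perm + 1)`.
#'
#' @inheritParams fit_linear
#' @param term the genetic column to permute (must be among `terms`).
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @return List with `p` (empirical), `stat_obs`, `n_perm`.
#' @export
permutation_p <- function(data, response, terms, term, n_perm = 999L,
                          seed = 1) {
  stopifnot(term %in% terms, n_perm >= 1)
  df <- design_frame(data, response, terms)
  y <- df[[response]]
  X <- cbind(`(Intercept)` = 1,
             as.matrix(df[, terms, drop = FALSE]))
  j <- match(term, terms) + 1L
  t_obs <- ols_tstat(X, y, j)
  with_seed(seed, {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      Xp <- X
      Xp[, j] <- X[sample(nrow(X)), j]
      if (abs(ols_tstat(Xp, y, j)) >= abs(t_obs)) exceed <- exceed + 1L
    }
    list(p = (1 + exceed) / (n_perm + 1), stat_obs = t_obs, n_perm = n_perm)
  })
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' U statistic from midranks with tie correction. For small samples
#' (`nA + nB <= 12`) the two-sided p-value is computed by exact
#' enumeration of all group assignments; otherwise by normal
#' approximation with continuity correction.
#'
#' @param group_a,group_b numeric vectors (both non-empty).
#' @return List with `u` (U statistic of group A), `p`, `method`.
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p  # exact: 0.1
rank_sum_test <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 1L, length(group_b) >= 1L)
  na <- length(group_a); nb <- length(group_b); n <- na + nb
  r <- rank(c(group_a, group_b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (n <= 12L) {
    sets <- utils::combn(n, na)
    us <- colSums(matrix(r[sets], nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    list(u = u, p = p, method = "exact enumeration")
  } else {
    ties <- table(r)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    list(u = u, p = min(1, 2 * stats::pnorm(-z)),
         method = "normal approximation")
  }
}

#' Cell doublings from CFSE dye dilution
#'
#' `doublings = -ln(final / start) / ln 2`: each halving of mean CFSE
#' fluorescence corresponds to one division.
#'
#' @param cfse_start,cfse_final positive fluorescence intensities.
#' @return Number of doublings.
#' @export
#' @examples
#' cfse_doublings(800, 100)  # 3 divisions
cfse_doublings <- function(cfse_start, cfse_final) {
  if (any(cfse_start <= 0) || any(cfse_final <= 0)) {
    stop("CFSE intensities must be positive", call. = FALSE)
  }
  -log(cfse_final / cfse_start) / log(2)
}

#' Benjamini-Hochberg adjustment
#'
#' Convenience wrapper around [stats::p.adjust()]; raw p-values are
#' reported by default throughout the package and this is opt-in.
#'
#' @param p numeric vector of p-values.
#' @return BH-adjusted p-values.
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")
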