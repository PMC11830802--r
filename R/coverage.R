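#' Simulate a windowed read-depth profile over the VNTR region
#'
#' Emulates short-read depth over the 2290-bp reference interval that
#' contains the VNTR array (27 reference copies of the 38-bp unit). The
#' expected per-base depth is `mean_depth` outside the array and
#' `mean_depth * (sum of the genotype's copies) / (2 * ref_copies)` inside
#' it; per-base depths are drawn negative-binomially with variance
#' `mu + dispersion * mu^2` (`dispersion = 0` gives the noise-free
#' expectation) and summarized as the median within each consecutive
#' window, mirroring how depth profiles are extracted from alignments.
#'
#' @param vntr_genotype length-2 numeric: the sample's two repeat copy
#'   numbers.
#' @param mean_depth expected depth outside the array (> 0).
#' @param dispersion negative-binomial overdispersion (>= 0).
#' @param seed integer seed.
#' @param sample_id identifier stored in the profile.
#' @param region_length,window,ref_copies,unit_length,array_offset
#'   geometry of the reference interval: total length, window step, the
#'   reference allele's copy number, unit length, and the 0-based offset
#'   of the array within the region.
#' @return An object of class `coverage_profile`: list with `sample_id`,
#'   `window_start` (0-based), `depth` (per-window median depth),
#'   `expected` and the geometry fields.
#' @export
simulate_coverage_profile <- function(vntr_genotype, mean_depth = 30,
                                      dispersion = 0.1, seed = 0,
                                      sample_id = "sample",
                                      region_length = 2290L, window = 50L,
                                      ref_copies = 27, unit_length = 38L,
                                      array_offset = 630L) {
  stopifnot(length(vntr_genotype) == 2L, all(vntr_genotype >= 0),
            mean_depth > 0, dispersion >= 0)
  starts <- seq.int(0L, region_length - 1L, by = window)
  arr_len <- ref_copies * unit_length
  arr_start <- array_offset
  arr_end <- array_offset + arr_len
  dosage <- sum(vntr_genotype) / (2 * ref_copies)
  base_pos <- seq_len(region_length) - 1L
  in_array <- base_pos >= arr_start & base_pos < arr_end
  mu_base <- ifelse(in_array, mean_depth * dosage, mean_depth)
  base_depth <- if (dispersion == 0) mu_base else
    with_seed(seed, stats::rnbinom(region_length, mu = mu_base,
                                   size = 1 / dispersion))
  depth <- window_coverage(as.numeric(base_depth), region_length, window,
                           statistic = "median")
  expected <- window_coverage(mu_base, region_length, window,
                              statistic = "median")
  structure(list(sample_id = sample_id, window_start = starts,
                 depth = depth, expected = expected,
                 region_length = region_length, window = window,
                 array_start = arr_start, array_end = arr_end),
            class = "coverage_profile")
}

#' Window features from a per-base depth vector
#'
#' Summarizes per-base depth into consecutive fixed-width window
#' statistics (the final partial window is included) and divides by a
#' normalization depth.
#'
#' @param depth_per_base numeric vector, one value per base of the region.
#' @param region_length region length in bp (must equal the vector
#'   length).
#' @param window window width in bp (> 0).
#' @param statistic `"median"` (default) or `"mean"`.
#' @param normalization depth used to scale the features (e.g. mean flank
#'   or genome-wide depth); default 1 leaves raw statistics.
#' @return Numeric feature vector of length `ceiling(region_length /
#'   window)`.
#' @export
window_coverage <- function(depth_per_base, region_length = length(depth_per_base),
                            window = 50L, statistic = c("median", "mean"),
                            normalization = 1) {
  statistic <- match.arg(statistic)
  if (window <= 0) stop("`window` must be positive", call. = FALSE)
  if (length(depth_per_base) != region_length) {
    stop("depth vector length must equal region_length", call. = FALSE)
  }
  idx <- rep(seq_len(ceiling(region_length / window)),
             each = window, length.out = region_length)
  f <- if (statistic == "median") stats::median else mean
  as.numeric(tapply(depth_per_base, idx, f)) / normalization
}

#' Normalized window features from a simulated coverage profile
#'
#' Divides per-window depths by the mean depth of the windows lying fully
#' outside the repeat array (flank normalization; genome-wide depth is not
#' available for summary-level profiles).
#'
#' @param profile a `coverage_profile`.
#' @return Numeric feature vector, one value per window.
#' @export
profile_features <- function(profile) {
  stopifnot(inherits(profile, "coverage_profile"))
  starts <- profile$window_start
  ends <- pmin(starts + profile$window, profile$region_length)
  flank <- ends <= profile$array_start | starts >= profile$array_end
  norm <- mean(profile$depth[flank])
  if (!is.finite(norm) || norm <= 0) norm <- mean(profile$depth)
  profile$depth / norm
}

## Penalized logistic log-likelihood (intercept unpenalized)
logis_obj <- function(beta, X, y, l2) {
  eta <- drop(X %*% beta)
  ll <- sum(y * eta - log1p(exp(eta)))
  ll - 0.5 * l2 * sum(beta[-1L]^2)
}

## Damped Newton (iteratively reweighted) ridge logistic fit.
ridge_logistic <- function(X, y, l2, max_iter = 200L, tol = 1e-8) {
  pn <- ncol(X)
  beta <- numeric(pn)
  pen <- diag(c(0, rep(l2, pn - 1L)), pn)
  obj <- logis_obj(beta, X, y, l2)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(X, y - mu)) - c(0, l2 * beta[-1L])
    if (sqrt(sum(grad^2)) < tol) {
      return(list(beta = beta, iterations = it - 1L, converged = TRUE))
    }
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * w, X) + pen
    step <- solve(H, grad)
    ## step halving keeps the penalized objective non-decreasing
    s <- 1
    repeat {
      cand <- beta + s * step
      cand_obj <- logis_obj(cand, X, y, l2)
      if (cand_obj >= obj - 1e-12 || s < 1e-8) break
      s <- s / 2
    }
    beta <- beta + s * step
    obj <- logis_obj(beta, X, y, l2)
  }
  stop(sprintf("ridge logistic fit did not converge in %d iterations",
               max_iter), call. = FALSE)
}

#' Train the regularized logistic coverage classifier
#'
#' Fits an L2-penalized binomial logistic regression (Short/Short vs
#' Long-carrier) by damped iterative reweighting with step halving, run to
#' a gradient norm below 1e-8, and evaluates it by seeded k-fold
#' cross-validation (held-out predictions from all folds are pooled into
#' one performance report).
#'
#' @param features numeric matrix, samples in rows (e.g. normalized
#'   window medians).
#' @param labels binary vector (0 = Short/Short, 1 = Long-carrier), or
#'   logical.
#' @param l2_strength ridge penalty (> 0 recommended; the intercept is
#'   unpenalized).
#' @param folds number of cross-validation folds.
#' @param seed integer seed for the fold assignment.
#' @return An object of class `coverage_model`: `weights`, `intercept`,
#'   `l2_strength`, `cv` (a [evaluate_classifier()] report on pooled
#'   held-out predictions plus `folds` and `seed`), and `iterations`.
#' @export
train_logistic <- function(features, labels, l2_strength = 1, folds = 5L,
                           seed = 1) {
  X0 <- as.matrix(features)
  y <- as.integer(labels)
  stopifnot(length(y) == nrow(X0), all(y %in% 0:1))
  if (length(unique(y)) < 2L || min(table(y)) < 2L) {
    stop("need at least 2 samples in each class", call. = FALSE)
  }
  X <- cbind(1, X0)
  fit <- ridge_logistic(X, y, l2_strength)

  cv <- NULL
  if (folds >= 2L) {
    assign_fold <- with_seed(seed, sample(rep_len(seq_len(folds), length(y))))
    prob <- numeric(length(y))
    for (f in seq_len(folds)) {
      tr <- assign_fold != f
      fold_fit <- ridge_logistic(X[tr, , drop = FALSE], y[tr], l2_strength)
      prob[!tr] <- stats::plogis(drop(X[!tr, , drop = FALSE] %*% fold_fit$beta))
    }
    cv <- evaluate_classifier(prob, as.integer(prob >= 0.5), y)
    cv$folds <- folds
    cv$seed <- seed
  }
  structure(list(weights = fit$beta[-1L], intercept = fit$beta[1L],
                 l2_strength = l2_strength, cv = cv,
                 iterations = fit$iterations),
            class = "coverage_model")
}

#' Predict carrier status from a coverage model
#'
#' @param model a `coverage_model`.
#' @param features numeric vector (one sample) or matrix (samples in
#'   rows); length/columns must match the model's weights.
#' @param cutoff probability cutoff for the Long-carrier call.
#' @return data.frame with `probability` and `label`
#'   (`"Long/any"`/`"Short/Short"`).
#' @export
predict_class <- function(model, features, cutoff = 0.5) {
  stopifnot(inherits(model, "coverage_model"))
  X <- if (is.matrix(features)) features else matrix(features, nrow = 1L)
  if (ncol(X) != length(model$weights)) {
    stop(sprintf("feature length %d does not match model (%d)",
                 ncol(X), length(model$weights)), call. = FALSE)
  }
  p <- stats::plogis(drop(X %*% model$weights) + model$intercept)
  data.frame(probability = p,
             label = ifelse(p >= cutoff, "Long/any", "Short/Short"),
             stringsAsFactors = FALSE)
}

#' Classifier performance report
#'
#' Confusion-based rates from hard labels plus rank-statistic AUC from
#' probabilities (tied probabilities contribute half a concordant pair,
#' i.e. midranks).
#'
#' @param prob predicted probabilities for the positive class.
#' @param predicted hard 0/1 predictions.
#' @param truth true 0/1 labels.
#' @return List of class `performance_report`: `sensitivity`,
#'   `specificity`, `precision`, `f_score`, `auc` (`NA` when truth has a
#'   single class) and the confusion counts `tp`, `fp`, `fn`, `tn`.
#' @export
evaluate_classifier <- function(prob, predicted, truth) {
  stopifnot(length(prob) == length(truth), length(predicted) == length(truth))
  predicted <- as.integer(predicted); truth <- as.integer(truth)
  tp <- sum(predicted == 1 & truth == 1)
  fp <- sum(predicted == 1 & truth == 0)
  fn <- sum(predicted == 0 & truth == 1)
  tn <- sum(predicted == 0 & truth == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  auc <- if (n1 > 0 && n0 > 0) {
    r <- rank(prob)  # midranks average ties
    (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  } else NA_real_
  structure(list(sensitivity = sens, specificity = spec, precision = prec,
                 f_score = f, auc = auc, tp = tp, fp = fp, fn = fn, tn = tn),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf(
    "performance: sens %.3f  spec %.3f  F %.3f  AUC %s  (TP %d FP %d FN %d TN %d)\n",
    x$sensitivity, x$specificity, x$f_score,
    ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc)),
    x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Seeded train/test split of sample indices
#'
#' Utility mirroring a 60/40 training/testing partition.
#'
#' @param n number of samples.
#' @param train_fraction fraction assigned to training.
#' @param seed integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
train_test_split <- function(n, train_fraction = 0.6, seed = 1) {
  with_seed(seed, {
    tr <- sort(sample(n, round(train_fraction * n)))
    list(train = tr, test = setdiff(seq_len(n), tr))
  })
}
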