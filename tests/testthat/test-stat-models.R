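test_that("additive coding counts effect alleles", {
  expect_identical(code_additive(c("CC", "CT", "TT"), "T"), c(0L, 1L, 2L))
  expect_identical(code_additive(c("CC", "CC"), "T"), c(0L, 0L))
  expect_true(is.na(code_additive(NA_character_, "T")))
  ## dosage sum identity on a panel
  panel <- simulate_haplotype_panel(ceu_population(), 400, seed = 36)
  d <- marker_dosage(panel, "rs10069690")
  expect_identical(sum(d),
                   sum(panel$haplotypes[, "rs10069690"]))
})

test_that("haplotype counts sum to two and follow the diplotype", {
  nh <- 8L
  mk <- data.frame(id = "rsX", pos = 1279000L, ref = "C", alt = "T",
                   stringsAsFactors = FALSE)
  ## individuals: Short-C/Short-C, Short-C/Long-T, Long-T/Long-T, Short-T/Long-C
  haps <- cbind(rsX = c(0L, 0L, 0L, 1L, 1L, 1L, 1L, 0L))
  long <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE)
  panel <- manual_panel(mk, haps, long)
  hc <- code_haplotypes(panel, "rsX")
  expect_true(all(rowSums(hc) == 2))
  expect_identical(unname(hc[1, ]), c(2L, 0L, 0L, 0L))
  expect_identical(unname(hc[2, ]), c(1L, 0L, 0L, 1L))
  expect_identical(unname(hc[3, ]), c(0L, 0L, 0L, 2L))
  expect_identical(unname(hc[4, ]), c(0L, 1L, 1L, 0L))
  expect_identical(attr(hc, "reference"), "Short-C")
})

test_that("cohort haplotype frequencies match the generator configuration", {
  panel <- simulate_haplotype_panel(yri_population(), 4000, seed = 37)
  hc <- code_haplotypes(panel, "rs10069690")
  freq <- colSums(hc) / sum(hc)
  ## expected Long-T frequency from the conditional construction
  pL <- 0.2; pT <- 0.32; r2 <- 0.2
  d <- sqrt(r2 * pL * (1 - pL) * pT * (1 - pT))
  exp_LT <- pL * (pT + d / pL)
  nh <- 8000
  expect_lt(abs(freq[["Long-T"]] - exp_LT),
            3 * sqrt(exp_LT * (1 - exp_LT) / nh))
})

test_that("OLS reproduces exact fits and hand-solved normal equations", {
  d <- data.frame(y = 3 + 2 * (1:10), x = 1:10)
  f <- suppressWarnings(fit_linear(d, "y", "x"))  # exact fit
  expect_equal(f$beta, c(3, 2), tolerance = 1e-12)
  ## 3-point closed form
  d3 <- data.frame(y = c(1, 2, 2.5), x = c(0, 1, 3))
  f3 <- fit_linear(d3, "y", "x")
  X <- cbind(1, d3$x)
  beta_hat <- solve(t(X) %*% X, t(X) %*% d3$y)
  expect_equal(f3$beta, as.numeric(beta_hat), tolerance = 1e-10)
  ## rank deficiency is named
  d$x2 <- d$x * 2
  expect_error(fit_linear(d, "y", c("x", "x2")), "collinear")
})

test_that("logistic fit matches the 2x2 odds-ratio closed form and a grid oracle", {
  d <- data.frame(y = rep(c(1, 0, 1, 0), c(20, 10, 10, 20)),
                  x = rep(c(1, 1, 0, 0), c(20, 10, 10, 20)))
  f <- fit_logistic(d, "y", "x")
  expect_equal(f$beta[f$term == "x"], log(4), tolerance = 1e-6)
  ## two-stage grid search over the slope (intercept profiled by symmetry)
  ll <- function(b) {
    eta <- b[1] + b[2] * d$x
    sum(d$y * eta - log1p(exp(eta)))
  }
  grid <- expand.grid(b0 = seq(-2, 2, by = 0.01),
                      b1 = seq(0, 3, by = 0.01))
  best <- grid[which.max(mapply(function(a, b) ll(c(a, b)),
                                grid$b0, grid$b1)), ]
  expect_lt(abs(f$beta[f$term == "x"] - best$b1), 1e-2)
  expect_equal(ll(c(f$beta[1], f$beta[2])),
               max(ll(c(best$b0, best$b1)), ll(c(f$beta[1], f$beta[2]))),
               tolerance = 1e-4)
  ## separation detection
  ds <- data.frame(y = rep(0:1, each = 10), x = rep(0:1, each = 10))
  expect_warning(fs <- fit_logistic(ds, "y", "x"), "separation")
  expect_true(attr(fs, "separation"))
  expect_error(fit_logistic(data.frame(y = rep(1, 10), x = rnorm(10)),
                            "y", "x"), "classes")
})

test_that("null logistic effects stay within two standard errors", {
  set.seed(38)
  d <- data.frame(x = rnorm(2000))
  d$y <- rbinom(2000, 1, 0.4)
  f <- fit_logistic(d, "y", "x")
  i <- which(f$term == "x")
  expect_lt(abs(f$beta[i]), 2 * f$se[i] + 1e-9)
})

test_that("conditioning removes mediated signal but rejects collinearity", {
  set.seed(39)
  n <- 2000
  vntr <- rbinom(n, 2, 0.2)
  snp <- vapply(vntr, function(v) rbinom(1, 2, 0.15 + 0.35 * v / 2),
                integer(1))
  y <- 10 - 3 * vntr + rnorm(n, 0, 2)  # SNP effect flows through the VNTR
  d <- data.frame(y = y, snp = snp, vntr = vntr, snp_dup = snp)
  marginal <- fit_linear(d, "y", "snp")
  cond <- conditional_fit(d, "y", "snp", conditioned_on = "vntr")
  b0 <- marginal$beta[marginal$term == "snp"]
  b1 <- cond$beta[cond$term == "snp"]
  expect_lt(abs(b1), abs(b0) / 2)
  expect_error(conditional_fit(d, "y", "snp", conditioned_on = "snp_dup"),
               "collinear")
  ## conditioning on an independent null marker leaves the effect in place
  d$null_m <- rbinom(n, 2, 0.3)
  cond2 <- conditional_fit(d, "y", "vntr", conditioned_on = "null_m")
  full <- fit_linear(d, "y", "vntr")
  i <- which(full$term == "vntr")
  expect_lt(abs(cond2$beta[cond2$term == "vntr"] - full$beta[i]),
            full$se[i])
})

test_that("age-group interaction recovers the generating slope's sign", {
  panel <- simulate_haplotype_panel(ceu_population(), 30000, seed = 40)
  hits <- vapply(1:5, function(r) {
    spec <- ukb_cohort_spec(n = 30000,
                            interaction = c(`hap_Short-C` = 0.01))
    coh <- simulate_rltl_cohort(panel, spec, seed = 400 + r)
    f <- interaction_fit(coh, "phenotype", "hap_Short-C",
                         terms = c("sex", "age", "smoking"))
    f$beta[f$term == "hap_Short-C:age_group"] > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  ## single age group is an error
  d <- data.frame(y = rnorm(50), g = rbinom(50, 2, 0.3),
                  age = runif(50, 38, 42))
  expect_error(interaction_fit(d, "y", "g", age_col = "age"),
               "single age group")
})

test_that("permutation p-values follow the add-one rule and track parametric p", {
  set.seed(41)
  n <- 300
  d <- data.frame(x = rnorm(n), z = rnorm(n))
  d$y <- 0.4 * d$x + rnorm(n)
  p <- permutation_p(d, "y", c("x", "z"), "x", n_perm = 999, seed = 42)
  expect_equal(p$p, 1 / 1000)  # strong effect hits the floor
  f <- fit_linear(d, "y", c("x", "z"))
  expect_lt(p$p, 10 * f$p[f$term == "x"] + 1e-3)
  ## moderate effect: permutation and parametric p agree within 2x
  d2 <- data.frame(x = rnorm(500))
  d2$y <- 0.12 * d2$x + rnorm(500)
  p2 <- permutation_p(d2, "y", "x", "x", n_perm = 999, seed = 43)
  f2 <- fit_linear(d2, "y", "x")
  pp <- f2$p[f2$term == "x"]
  expect_true(p2$p <= 2 * pp + 2e-3 && p2$p >= pp / 2 - 2e-3)
})

test_that("null permutation p-values are approximately uniform", {
  set.seed(44)
  ps <- vapply(1:100, function(r) {
    d <- data.frame(x = rnorm(60), y = rnorm(60))
    permutation_p(d, "y", "x", "x", n_perm = 99, seed = r)$p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("rank-sum test enumerates exactly for small samples", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_identical(r$method, "exact enumeration")
  expect_equal(r$p, 0.1)  # 2 of 20 arrangements are as extreme
  expect_equal(rank_sum_test(c(1, 2), c(1, 2))$p, 1)
  ## U_A + U_B identity
  set.seed(45)
  a <- rnorm(8); b <- rnorm(9)
  ua <- rank_sum_test(a, b)$u
  ub <- rank_sum_test(b, a)$u
  expect_equal(ua + ub, 8 * 9)
})

test_that("rank-sum approximation agrees with the exact path and wilcox.test", {
  set.seed(46)
  for (r in 1:10) {
    a <- rnorm(6); b <- rnorm(6, 0.5)
    exact <- rank_sum_test(a, b)$p
    big <- rank_sum_test(c(a, a[1] + 1e-7), c(b, b[1] + 1e-7))  # n = 13
    expect_identical(big$method, "normal approximation")
    ref <- suppressWarnings(stats::wilcox.test(a, b))$p.value
    expect_lt(abs(exact - ref), 0.02)
  }
  ## large-sample cross-check against the reference implementation
  a <- rnorm(40); b <- rnorm(35, 0.3)
  mine <- rank_sum_test(a, b)
  ref <- stats::wilcox.test(a, b, correct = TRUE, exact = FALSE)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-6)
  expect_equal(mine$u, unname(ref$statistic))
})

test_that("CFSE doublings follow the dye-dilution closed form", {
  expect_equal(cfse_doublings(100, 100), 0)
  expect_equal(cfse_doublings(800, 100), 3)
  for (k in 0:10) expect_equal(cfse_doublings(1024, 1024 / 2^k), k)
  expect_error(cfse_doublings(0, 10), "positive")
})

test_that("BH adjustment wraps the standard correction", {
  p <- c(0.001, 0.01, 0.04, 0.2)
  expect_equal(adjust_bh(p), stats::p.adjust(p, "BH"))
})
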