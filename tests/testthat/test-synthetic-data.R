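test_that("degenerate allele frequency puts every haplotype at that copy number", {
  cfg <- population_config(
    data.frame(id = "s1", pos = 1275000L, ref = "C", alt = "T",
               stringsAsFactors = FALSE),
    populations = list(P = list(vntr_freq = c(`27` = 1),
                                snp_freq = c(s1 = 0.3))))
  panel <- simulate_haplotype_panel(cfg, 50, seed = 1)
  expect_true(all(panel$vntr_copies == 27))
})

test_that("empirical allele frequencies match configuration within 3 binomial SD", {
  cfg <- toy_config(target_r2 = numeric(0))
  panel <- simulate_haplotype_panel(cfg, 5000, seed = 42)
  nh <- 10000
  p_hat <- mean(panel$haplotypes[, "snpA"])
  expect_lt(abs(p_hat - 0.2), 3 * sqrt(0.2 * 0.8 / nh))
  long_hat <- mean(vntr_hap_class(panel) == "Long")
  expect_lt(abs(long_hat - 0.2), 3 * sqrt(0.2 * 0.8 / nh))
})

test_that("configured LD targets are reproduced and identical seeds give identical panels", {
  cfg <- ceu_population()
  panel <- simulate_haplotype_panel(cfg, 2500, seed = 7)
  expect_lt(abs(ld_r2(panel, "VNTR", "rs2242652") - 0.62), 0.05)
  expect_lt(abs(ld_r2(panel, "VNTR", "rs10069690") - 0.48), 0.05)
  expect_identical(panel, simulate_haplotype_panel(cfg, 2500, seed = 7))
})

test_that("infeasible LD targets are rejected with the feasible bound", {
  ## pL = 0.2, pB = 0.5: r2max = 0.1^2 / (0.2*0.8*0.25) = 0.25
  expect_error(toy_config(target_r2 = c(snpB = 0.5)),
               "maximum attainable r2", fixed = FALSE)
  expect_silent(toy_config(target_r2 = c(snpB = 0.25)))
  ## bound itself: pL = 0.2, pB = 0.2 makes r2 = 1 attainable
  expect_silent(population_config(
    data.frame(id = "s1", pos = 1L, ref = "C", alt = "T",
               stringsAsFactors = FALSE),
    populations = list(P = list(vntr_freq = c(`27` = 0.8, `40.5` = 0.2),
                                snp_freq = c(s1 = 0.2))),
    target_r2 = c(s1 = 1)))
})

test_that("trio simulation transmits parental haplotypes verbatim", {
  cfg <- toy_config(target_r2 = numeric(0))
  panel <- simulate_haplotype_panel(cfg, 60, seed = 3)
  ts <- simulate_trios(panel, 20, seed = 4)
  g <- vntr_genotypes(ts$panel)
  for (i in seq_len(20)) {
    tr <- ts$trios[i, ]
    expect_equal(g[tr$child, 1], g[tr$father, tr$pat_hap])
    expect_equal(g[tr$child, 2], g[tr$mother, tr$mat_hap])
  }
  expect_error(simulate_trios(panel, 31, seed = 1), "individuals")
})

test_that("transmission from heterozygous parents is unbiased", {
  cfg <- toy_config(target_r2 = numeric(0))
  panel <- simulate_haplotype_panel(cfg, 2200, seed = 5)
  ts <- simulate_trios(panel, 1000, seed = 6)
  g <- vntr_genotypes(ts$panel)
  het <- g[ts$trios$father, 1] != g[ts$trios$father, 2]
  share <- mean(ts$trios$pat_hap[het] == 1)
  n <- sum(het)
  expect_lt(abs(share - 0.5), 3 * sqrt(0.25 / n))
})

test_that("synthesized allele lengths follow the copy arithmetic", {
  unit <- vntr_consensus_unit()
  expect_identical(nchar(synthesize_vntr_allele(0, flank_length = 100)), 200L)
  s27 <- synthesize_vntr_allele(27, flank_length = 100)
  expect_identical(nchar(s27), 27L * 38L + 200L)
  ## central segment is 27 exact concatenations
  expect_identical(substr(s27, 101, 100 + 27 * 38), strrep(unit, 27))
  expect_identical(nchar(synthesize_vntr_allele(40.5, flank_length = 0)),
                   40L * 38L + 19L)
  expect_error(synthesize_vntr_allele(-1), "non-negative")
  expect_error(synthesize_vntr_allele(2.3), "multiple of 0.5")
})

test_that("coverage profiles follow the dosage model and are seed-deterministic", {
  flat <- simulate_coverage_profile(c(27, 27), mean_depth = 30, dispersion = 0)
  expect_true(all(flat$depth == 30))
  expect_length(flat$depth, 46L)

  p <- simulate_coverage_profile(c(27, 66.5), mean_depth = 30, dispersion = 0)
  inside <- p$window_start >= p$array_start &
    p$window_start + p$window <= p$array_end
  expect_equal(unique(p$depth[inside]), 30 * 93.5 / 54)

  a <- simulate_coverage_profile(c(27, 40.5), 30, 0.1, seed = 99)
  b <- simulate_coverage_profile(c(27, 40.5), 30, 0.1, seed = 99)
  expect_identical(a, b)
})

test_that("splice-read generator mixtures are recovered by the classifier", {
  mix <- splice_mixture()
  ## point mass
  pm <- splice_mixture(rbind(XX = c(canonical = 1, INS1 = 0, INS1b = 0,
                                    unspliced = 0)), sub_threshold = 0)
  rs <- simulate_splice_reads(pm, "XX", 100, seed = 1)
  ec <- count_events(rs$reads)
  expect_identical(ec$canonical, 100L)
  expect_identical(ec$total, 100L)
  ## sub-threshold reads excluded from the total
  rs2 <- simulate_splice_reads(mix, "CC", 5000, seed = 2)
  ec2 <- count_events(rs2$reads)
  expect_identical(ec2$excluded,
                   sum(unname(rs2$truth) == "sub_threshold"))
  expect_identical(ec2$total + ec2$excluded, 5000L)
  expect_error(simulate_splice_reads(mix, "ZZ", 10, seed = 1),
               "unknown genotype")
})

test_that("expression cohort phenotype follows the configured linear model", {
  cfg <- toy_config(target_r2 = numeric(0))
  panel <- simulate_haplotype_panel(cfg, 200, seed = 8)
  spec0 <- cohort_spec(n = 50, intercept = 59.7, noise_sd = 1e-12)
  coh <- simulate_expression_cohort(panel, spec0, seed = 9, hap_snp = "snpA")
  expect_equal(coh$phenotype, rep(59.7, 50), tolerance = 1e-9)

  ## OLS recovers covariate effects: 95% CI covers truth ~95% of the time
  spec1 <- cohort_spec(n = 400, intercept = 10, sex_effect = 2,
                       age_effect = -0.5, age_range = c(20, 70),
                       noise_sd = 3)
  hit <- vapply(1:200, function(r) {
    coh <- simulate_expression_cohort(panel, spec1, seed = 7919 * r + 5,
                                      hap_snp = "snpA")
    f <- fit_linear(coh, "phenotype", c("sex", "age"))
    i <- which(f$term == "age")
    abs(f$beta[i] + 0.5) <= stats::qt(0.975, attr(f, "n") - 3) * f$se[i]
  }, logical(1))
  expect_gt(mean(hit), 0.90)
  expect_lt(mean(hit), 0.995)
})

test_that("rLTL cohort recovers the age trend and requires two age groups", {
  cfg <- toy_config(target_r2 = numeric(0))
  panel <- simulate_haplotype_panel(cfg, 20000, seed = 10)
  spec <- cohort_spec(n = 20000, age_effect = -0.002, age_range = c(38, 73),
                      noise_sd = 0.5)
  coh <- simulate_rltl_cohort(panel, spec, seed = 11, hap_snp = "snpA")
  f <- fit_linear(coh, "phenotype", c("age"))
  i <- which(f$term == "age")
  expect_lt(abs(f$beta[i] + 0.002), 2 * f$se[i] + 1e-4)

  bad <- cohort_spec(n = 100, age_range = c(40, 42))
  expect_error(simulate_rltl_cohort(panel, bad, seed = 1, hap_snp = "snpA"),
               "5-year")
})
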