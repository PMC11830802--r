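test_that("MAF filtering is strict and matches direct counting", {
  mk <- data.frame(id = c("m1", "m2", "m3"), pos = c(1L, 2L, 3L),
                   ref = "A", alt = "G", stringsAsFactors = FALSE)
  nh <- 40L
  haps <- cbind(m1 = rep(0L, nh),                      # monomorphic
                m2 = rep(c(1L, 0L), c(2L, 38L)),       # MAF 0.05 exactly
                m3 = rep(c(1L, 0L), c(10L, 30L)))      # MAF 0.25
  panel <- manual_panel(mk, haps, long = rep(c(TRUE, FALSE), c(8, 32)))
  expect_identical(filter_by_maf(panel, 0.05), "m3")
  expect_identical(filter_by_maf(panel, 0.2), "m3")
  expect_identical(filter_by_maf(panel, 0.25), character(0))
  ## counting oracle on a random panel
  panel2 <- simulate_haplotype_panel(ceu_population(), 300, seed = 17)
  p <- colMeans(panel2$haplotypes)
  expect_identical(filter_by_maf(panel2, 0.05),
                   names(p)[pmin(p, 1 - p) > 0.05])
})

test_that("chi-square scan matches the textbook 2x2 formula", {
  mk <- two_marker_map()
  ## marker mA: table (a,b;c,d) = (30,20;10,40) vs Long class
  long <- rep(c(TRUE, FALSE), c(40, 60))
  xa <- c(rep(1L, 30), rep(0L, 10), rep(1L, 20), rep(0L, 40))
  xb <- rep(c(1L, 0L), 50)  # independent of class
  panel <- manual_panel(mk, cbind(mA = xa, mB = xb), long)
  scan <- chi2_scan(panel)
  a <- 30; b <- 20; cc <- 10; d <- 40; n <- 100
  expect_equal(scan$chi2[scan$id == "mA"],
               n * (a * d - b * cc)^2 / ((a + b) * (cc + d) * (a + cc) * (b + d)))
  ## balanced 25/25/25/25 table gives statistic 0
  long2 <- rep(c(TRUE, FALSE), 50)
  x2 <- rep(c(1L, 1L, 0L, 0L), 25)
  panel2 <- manual_panel(mk, cbind(mA = x2, mB = x2), long2)
  expect_equal(chi2_scan(panel2)$chi2[1], 0)
  ## perfect association gives statistic n
  panel3 <- manual_panel(mk, cbind(mA = as.integer(long), mB = xb), long)
  expect_equal(chi2_scan(panel3)$chi2[1], 100)
})

test_that("chi-square equals n times r-squared on 2x2 haplotype tables", {
  for (s in 1:20) {
    panel <- simulate_haplotype_panel(ceu_population(), 150, seed = s)
    scan <- chi2_scan(panel)
    n <- nrow(panel$haplotypes)
    for (id in scan$id) {
      r2 <- ld_r2(panel, "VNTR", id)
      if (is.na(r2)) next
      expect_equal(scan$chi2[scan$id == id], n * r2, tolerance = 1e-9)
    }
  }
})

test_that("kappa follows the closed form and its boundary behavior", {
  ## table (45,5;5,45): Po 0.9, Pe 0.5, kappa 0.8
  truth <- rep(c("a", "b"), each = 50)
  inferred <- c(rep("a", 45), rep("b", 5), rep("a", 5), rep("b", 45))
  st <- cohens_kappa(truth, inferred)
  expect_equal(st$agreement, 0.9)
  expect_equal(st$kappa, 0.8)
  ## identical vectors with both classes
  st2 <- cohens_kappa(c("a", "b", "a"), c("a", "b", "a"))
  expect_equal(st2$kappa, 1)
  ## chance agreement near zero for independent labels
  set.seed(18)
  t3 <- sample(c("a", "b"), 1e4, replace = TRUE)
  i3 <- sample(c("a", "b"), 1e4, replace = TRUE)
  expect_lt(abs(cohens_kappa(t3, i3)$kappa), 0.05)
  ## degenerate marginals
  st4 <- cohens_kappa(c("a", "a"), c("a", "a"))
  expect_true(is.na(st4$kappa))
  expect_equal(st4$agreement, 1)
})

test_that("kappa never exceeds agreement", {
  for (s in 1:20) {
    set.seed(s)
    t <- sample(c("S", "L"), 200, replace = TRUE, prob = c(0.8, 0.2))
    i <- ifelse(runif(200) < 0.1, sample(c("S", "L"), 200, TRUE), t)
    st <- cohens_kappa(t, i)
    if (!is.na(st$kappa)) expect_lte(st$kappa, st$agreement + 1e-12)
  }
})

test_that("a planted perfect tag pair is recovered with kappa 1", {
  mk <- data.frame(id = c("m1", "m2", "m3"), pos = c(10L, 714L, 2000L),
                   ref = c("G", "A", "C"), alt = c("A", "G", "T"),
                   stringsAsFactors = FALSE)
  set.seed(19)
  nh <- 400L
  long <- runif(nh) < 0.2
  haps <- cbind(m1 = as.integer(long),           # A allele tags Long
                m2 = as.integer(long),           # G allele tags Long
                m3 = as.integer(runif(nh) < 0.5))
  panel <- manual_panel(mk, haps, long)
  res <- select_tag_pair(panel, c("m1", "m2", "m3"))
  expect_identical(sort(c(res$mapping$marker_a, res$mapping$marker_b)),
                   c("m1", "m2"))
  expect_equal(res$stats$kappa, 1)
  expect_identical(res$mapping$long_haplotype, c("A", "G"))
})

test_that("tag recovery under label noise matches the misclassification oracle", {
  flip <- 0.05
  set.seed(20)
  nh <- 4000L
  long <- runif(nh) < 0.2
  noisy_tag <- ifelse(runif(nh) < flip, !long, long)
  mk <- data.frame(id = c("m1", "m2", "m3"), pos = c(10L, 714L, 2000L),
                   ref = "C", alt = "T", stringsAsFactors = FALSE)
  haps <- cbind(m1 = as.integer(noisy_tag), m2 = as.integer(noisy_tag),
                m3 = as.integer(runif(nh) < 0.5))
  panel <- manual_panel(mk, haps, long)
  res <- select_tag_pair(panel, c("m1", "m2", "m3"))
  expect_identical(sort(c(res$mapping$marker_a, res$mapping$marker_b)),
                   c("m1", "m2"))
  ## analytic kappa for a symmetric flip rate on unbalanced classes
  pL <- mean(long)
  po <- 1 - flip
  pe <- pL * (pL * (1 - flip) + (1 - pL) * flip) +
    (1 - pL) * ((1 - pL) * (1 - flip) + pL * flip)
  expect_lt(abs(res$stats$kappa - (po - pe) / (1 - pe)), 0.05)
})

test_that("uninformative candidates raise the no-informative-pair error", {
  set.seed(21)
  nh <- 200L
  long <- runif(nh) < 0.2
  mk <- two_marker_map()
  ## monomorphic candidates: every haplotype assignment gives kappa <= 0
  haps <- cbind(mA = rep(0L, nh), mB = rep(1L, nh))
  panel <- manual_panel(mk, haps, long)
  expect_error(select_tag_pair(panel, c("mA", "mB")), "no informative pair")
})

test_that("tag mapping application follows the carrier rule", {
  panel <- simulate_haplotype_panel(ceu_population(), 800, seed = 22)
  res <- select_tag_pair(panel, c("rs56345976", "rs33961405"))
  out <- apply_tag_mapping(res$mapping, panel)
  hit <- out$haplotype_class == "Long"
  expect_identical(out$genotype_group,
                   ifelse(hit[c(TRUE, FALSE)] | hit[c(FALSE, TRUE)],
                          "Long/any", "Short/Short"))
  ## tag selection recovers the planted proxy pair on default settings
  expect_setequal(c(res$mapping$marker_a, res$mapping$marker_b),
                  c("rs56345976", "rs33961405"))
  expect_identical(res$mapping$long_haplotype[order(c(res$mapping$marker_a,
                                                      res$mapping$marker_b))],
                   c("G", "A")[order(c("rs33961405", "rs56345976"))])
})

test_that("r-squared follows the D-squared arithmetic and its invariances", {
  ## haplotype counts AB 40, Ab 10, aB 10, ab 40
  x <- rep(c(1L, 1L, 0L, 0L), c(40, 10, 10, 40))
  y <- rep(c(1L, 0L, 1L, 0L), c(40, 10, 10, 40))
  expect_equal(vntrproxy:::ld_r2_vec(x, y), 0.15^2 / (0.5 * 0.5 * 0.5 * 0.5))
  ## symmetry and allele-swap invariance
  for (s in 1:10) {
    set.seed(s)
    a <- as.integer(runif(100) < 0.3)
    b <- as.integer(runif(100) < 0.6)
    r <- vntrproxy:::ld_r2_vec(a, b)
    expect_equal(r, vntrproxy:::ld_r2_vec(b, a))
    expect_equal(r, vntrproxy:::ld_r2_vec(1L - a, b))
    expect_gte(r, 0); expect_lte(r, 1)
  }
  ## self-LD is 1; monomorphic markers are undefined
  panel <- simulate_haplotype_panel(ceu_population(), 100, seed = 23)
  expect_equal(ld_r2(panel, "rs2242652", "rs2242652"), 1)
  expect_true(is.na(vntrproxy:::ld_r2_vec(rep(0L, 50), rep(1L, 50))))
})

test_that("the default generator's planted proxy is recovered across replicates", {
  hits <- vapply(1:20, function(s) {
    panel <- simulate_haplotype_panel(ceu_population(), 500, seed = 100 + s)
    res <- select_tag_pair(panel, filter_by_maf(panel, 0.05))
    setequal(c(res$mapping$marker_a, res$mapping$marker_b),
             c("rs56345976", "rs33961405"))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
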