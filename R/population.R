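#' Define a population configuration for haplotype simulation
#'
#' A population configuration couples a SNP map, VNTR allele classes with
#' per-population frequencies, and pairwise linkage-disequilibrium targets
#' between each SNP and the binarized VNTR (Short/Long). Haplotypes are
#' later drawn SNP-by-SNP conditionally on the VNTR class of the same
#' haplotype, which reproduces each configured VNTR-SNP r-squared exactly
#' in expectation (LD between SNPs is induced through the shared VNTR
#' locus).
#'
#' @param snps data.frame with columns `id`, `pos` (bp, strictly
#'   increasing), `ref`, `alt` (single bases).
#' @param populations named list; each element is a list with components
#'   `weight` (sampling weight, default 1), `vntr_freq` (named numeric:
#'   names are repeat copy numbers, values are allele frequencies summing
#'   to 1) and `snp_freq` (named numeric alt-allele frequency per SNP id).
#' @param target_r2 named numeric vector: for each SNP id, the target
#'   r-squared between the SNP alt allele and the VNTR Long class. SNPs
#'   absent from this vector are drawn independently of the VNTR.
#' @param vntr_pos genomic position (bp) used for the VNTR pseudo-marker.
#' @param short_long_threshold copy-number threshold separating Short from
#'   Long alleles (Long if copies >= threshold).
#'
#' @return An object of class `population_config`.
#' @seealso [ceu_population()], [yri_population()],
#'   [simulate_haplotype_panel()]
#' @export
population_config <- function(snps, populations, target_r2 = numeric(0),
                              vntr_pos = 1275400L,
                              short_long_threshold = 34) {
  stopifnot(is.data.frame(snps),
            all(c("id", "pos", "ref", "alt") %in% names(snps)))
  if (is.unsorted(snps$pos, strictly = TRUE)) {
    stop("SNP positions must be strictly increasing", call. = FALSE)
  }
  if (anyDuplicated(snps$id)) stop("duplicate SNP ids", call. = FALSE)
  if (any(target_r2 < 0 | target_r2 > 1)) {
    stop("target r2 values must lie in [0, 1]", call. = FALSE)
  }
  if (!all(names(target_r2) %in% snps$id)) {
    stop("target_r2 names must be SNP ids", call. = FALSE)
  }
  if (is.null(names(populations)) || any(names(populations) == "")) {
    stop("populations must be a named list", call. = FALSE)
  }
  for (nm in names(populations)) {
    pop <- populations[[nm]]
    vf <- pop$vntr_freq
    if (abs(sum(vf) - 1) > 1e-9) {
      stop(sprintf("VNTR allele frequencies for population %s sum to %g, not 1",
                   nm, sum(vf)), call. = FALSE)
    }
    if (any(as.numeric(names(vf)) < 0)) {
      stop("VNTR copy numbers must be >= 0", call. = FALSE)
    }
    if (!all(snps$id %in% names(pop$snp_freq))) {
      stop(sprintf("population %s lacks snp_freq entries for some SNPs", nm),
           call. = FALSE)
    }
    populations[[nm]]$weight <- pop$weight %||% 1
  }
  cfg <- structure(
    list(snps = snps, populations = populations, target_r2 = target_r2,
         vntr_pos = as.integer(vntr_pos),
         short_long_threshold = short_long_threshold),
    class = "population_config")
  ## fail early on infeasible LD targets
  for (nm in names(populations)) check_ld_feasible(cfg, nm)
  cfg
}

## Maximum attainable r2 between a SNP (alt freq pB) and the Long class
## (freq pL) given positive D; classical haplotype-frequency bound.
r2_max <- function(pL, pB) {
  if (pL %in% c(0, 1) || pB %in% c(0, 1)) return(0)
  dmax <- min(pL * (1 - pB), pB * (1 - pL))
  dmax^2 / (pL * (1 - pL) * pB * (1 - pB))
}

check_ld_feasible <- function(config, pop_name) {
  pop <- config$populations[[pop_name]]
  vf <- pop$vntr_freq
  pL <- sum(vf[as.numeric(names(vf)) >= config$short_long_threshold])
  for (id in names(config$target_r2)) {
    r2 <- config$target_r2[[id]]
    if (r2 == 0) next
    pB <- pop$snp_freq[[id]]
    bound <- r2_max(pL, pB)
    if (r2 > bound + 1e-12) {
      stop(sprintf(paste0(
        "LD target r2 = %.3f for %s in population %s exceeds the maximum ",
        "attainable r2 = %.3f at allele frequencies pLong = %.3f, pAlt = %.3f"),
        r2, id, pop_name, bound, pL, pB), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' European-ancestry-like population preset
#'
#' Default single-population configuration mirroring European-ancestry
#' panels: Short alleles (24/25.5/27 copies) at a combined 83.3% frequency
#' with class mean 25.8 copies, a Long 40.5-copy allele at 16.7%, GWAS
#' SNPs rs2242652 (target r2 = 0.62 with the Long class) and rs10069690
#' (r2 = 0.48), the tag pair rs56345976/rs33961405 in strong LD with the
#' VNTR, rs7705526 (r2 = 0.33), and two unlinked filler markers (one below
#' the 5% MAF screen).
#'
#' @return A `population_config`.
#' @export
ceu_population <- function() {
  snps <- data.frame(
    id  = c("rs56345976", "rs33961405", "snpNull1", "snpRare1",
            "rs2736100", "rs7705526", "rs10069690", "rs2242652"),
    pos = c(1274235L, 1274939L, 1275050L, 1275120L,
            1278500L, 1279200L, 1279790L, 1280128L),
    ref = c("G", "A", "C", "T", "C", "C", "C", "G"),
    alt = c("A", "G", "T", "C", "A", "A", "T", "A"),
    stringsAsFactors = FALSE)
  populations <- list(CEU = list(
    weight = 1,
    vntr_freq = c(`24` = 0.2083, `25.5` = 0.2500, `27` = 0.3747,
                  `40.5` = 0.1670),
    snp_freq = c(rs56345976 = 0.17, rs33961405 = 0.17, snpNull1 = 0.50,
                 snpRare1 = 0.04, rs2736100 = 0.49, rs7705526 = 0.33,
                 rs10069690 = 0.26, rs2242652 = 0.21)))
  ## Short-class mass split 0.25/0.30/0.45 of the 83.3% Short total so the
  ## Short-class mean is 25.8 copies.
  target_r2 <- c(rs56345976 = 0.92, rs33961405 = 0.92,
                 rs7705526 = 0.33, rs10069690 = 0.48, rs2242652 = 0.62)
  population_config(snps, populations, target_r2)
}

#' African-ancestry-like population preset
#'
#' Mirrors African-ancestry panels: Short alleles at 80% (class mean 27.0
#' copies), Long alleles at 20% with class mean 43.75 copies, including
#' the uncommon 66.5-repeat allele at 2.5% population frequency. LD with
#' the GWAS SNPs is configured lower than in [ceu_population()], as
#' reported for African-ancestry populations.
#'
#' @return A `population_config`.
#' @export
yri_population <- function() {
  cfg <- ceu_population()
  populations <- list(YRI = list(
    weight = 1,
    vntr_freq = c(`24` = 0.10, `25.5` = 0.10, `27` = 0.30, `28.5` = 0.30,
                  `40.5` = 0.175, `66.5` = 0.025),
    snp_freq = c(rs56345976 = 0.22, rs33961405 = 0.24, snpNull1 = 0.50,
                 snpRare1 = 0.04, rs2736100 = 0.45, rs7705526 = 0.30,
                 rs10069690 = 0.32, rs2242652 = 0.28)))
  target_r2 <- c(rs56345976 = 0.60, rs33961405 = 0.60,
                 rs7705526 = 0.15, rs10069690 = 0.20, rs2242652 = 0.25)
  population_config(cfg$snps, populations, target_r2)
}
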