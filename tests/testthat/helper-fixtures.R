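## Shared fixtures built in code.

## Tiny hand-specified two-population-free config for fast tests.
toy_config <- function(target_r2 = c(snpA = 0.5)) {
  snps <- data.frame(id = c("snpA", "snpB"),
                     pos = c(1275000L, 1276000L),
                     ref = c("C", "G"), alt = c("T", "A"),
                     stringsAsFactors = FALSE)
  population_config(
    snps,
    populations = list(POP = list(
      weight = 1,
      vntr_freq = c(`27` = 0.8, `40.5` = 0.2),
      snp_freq = c(snpA = 0.2, snpB = 0.5))),
    target_r2 = target_r2)
}

## Panel with planted deterministic haplotypes: `long` is a logical vector
## (one per haplotype); each marker column is given explicitly.
manual_panel <- function(markers, haps, long, threshold = 34) {
  n <- length(long) / 2
  individuals <- data.frame(id = sprintf("I%03d", seq_len(n)),
                            population = "POP", sex = 0L, age = 50,
                            stringsAsFactors = FALSE)
  copies <- ifelse(long, 40.5, 27)
  vntrproxy:::new_phased_panel(individuals, markers, haps, copies,
                               1275400L, threshold)
}

two_marker_map <- function() {
  data.frame(id = c("mA", "mB"), pos = c(1275000L, 1275704L),
             ref = c("G", "A"), alt = c("A", "G"), stringsAsFactors = FALSE)
}
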