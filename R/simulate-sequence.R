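## Fixed non-repetitive flanking sequences used on either side of every
## synthesized repeat array. Kept free of G-runs and of periodicity in the
## 10-60 bp range so they neither seed spurious repeat copies nor score as
## G-quadruplex tracts; the array-facing boundary bases differ from the
## consensus unit's terminal bases so the array phase stays unambiguous.
.vntr_flanks <- list(
  left = paste0(
    "AATCTCGAACAATATTAGTTTACTTTAAAACCCTGCATTATCTTCACCGTGTCGTTCACG",
    "ATTTGGACAGATACCCATGTCATCCGTTCCAAATTTAATACTATCTTATCGCTTCTTTTG",
    "TGACATTTATTGCCTCAATTCTAACGTTTTCTTTATGCAGGCTCTTTAATGGATCTGAAC",
    "GTCGGCCCGTATGGATGAGTTTTCCTTTTACCTGGATTCCCCGACAAACAGCACAACGTC",
    "ACCGCTACGTTAAGTATCAACCCAACTGTTCTGTTTAGGAACCCTCTTCATACGATCCAC"),
  right = paste0(
    "CTGAGATAACATTGGCGCTTGTACTAAACTATTCGTACTATTGCTATGAATTAATCCACA",
    "CCCTTCCTCTGGGTTTGTACAGCTCCACTCCCCCACTAAACCAGGTATTAGTCGATTGTG",
    "ATATTCAAACGTCACTTATCAGGTCATAATCTCCGAAGTTCGGCTACACTCCTATATACC",
    "GCTAGAACCCTCATCCTTATAATTCTGGCCAGTAGTGTCGTAAGCAGTTCCTCGTAGACT",
    "TTGTTAATGTTATATTAAGTAGGTAAAGACCGGTATGAAAAATATACCCGTCTAAACTGA"))

#' Synthesize a VNTR allele sequence
#'
#' Builds a repeat-array DNA sequence: `floor(copies)` concatenated copies
#' of the unit, an optional terminal half copy (the first
#' `floor(|unit|/2)` bases of the unit, realizing the `.5` in allele
#' names such as 40.5), i.i.d. substitution noise over the array, and
#' fixed non-repetitive flanks on both sides.
#'
#' @param copies repeat copy number, a non-negative multiple of 0.5.
#' @param unit repeat unit (uppercase ACGT), default the 38-bp consensus.
#' @param substitution_rate per-base substitution probability in the array
#'   (flanks are left intact).
#' @param flank_length flank length in bp on each side (<= 300).
#' @param seed integer seed (only consumed when `substitution_rate > 0`).
#' @return A single DNA string of length
#'   `2 * flank_length + round(copies * nchar(unit))`.
#' @export
#' @examples
#' s <- synthesize_vntr_allele(27, seed = 1)
#' nchar(s)  # 27 * 38 + 200
synthesize_vntr_allele <- function(copies, unit = vntr_consensus_unit(),
                                   substitution_rate = 0, flank_length = 100,
                                   seed = 0) {
  if (!is.numeric(copies) || length(copies) != 1L || is.na(copies) ||
      copies < 0) {
    stop("`copies` must be a single non-negative number", call. = FALSE)
  }
  if (abs(copies * 2 - round(copies * 2)) > 1e-9) {
    stop("`copies` must be a multiple of 0.5", call. = FALSE)
  }
  check_dna(unit)
  if (flank_length > nchar(.vntr_flanks$left)) {
    stop(sprintf("flank_length must be <= %d", nchar(.vntr_flanks$left)),
         call. = FALSE)
  }
  p <- nchar(unit)
  full <- floor(copies)
  half <- (copies - full) > 0
  array <- paste0(strrep(unit, full),
                  if (half) substr(unit, 1L, p %/% 2L) else "")
  if (substitution_rate > 0 && nchar(array) > 0) {
    array <- with_seed(seed, mutate_sequence(array, substitution_rate))
  }
  left <- substr(.vntr_flanks$left,
                 nchar(.vntr_flanks$left) - flank_length + 1L,
                 nchar(.vntr_flanks$left))
  right <- substr(.vntr_flanks$right, 1L, flank_length)
  paste0(left, array, right)
}

## i.i.d. substitutions to one of the three other bases
mutate_sequence <- function(s, rate) {
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(v)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    repl <- vapply(v[hit],
                   function(b) sample(setdiff(bases, b), 1L), character(1))
    v[hit] <- repl
  }
  paste(v, collapse = "")
}

check_dna <- function(s, what = "unit") {
  if (!is.character(s) || length(s) != 1L || nchar(s) < 1L ||
      grepl("[^ACGT]", s)) {
    stop(sprintf("`%s` must be a non-empty uppercase ACGT string", what),
         call. = FALSE)
  }
  invisible(s)
}

#' Reverse complement of a DNA string
#'
#' @param s uppercase ACGT string.
#' @return The reverse complement.
#' @export
revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
}
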