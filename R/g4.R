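#' Per-base G-quadruplex propensity scores
#'
#' Run-length scoring: every base inside a G-run of length k scores
#' `+min(k, 4)`, every base inside a C-run `-min(k, 4)`, and A/T bases
#' score 0. Non-ACGT characters score 0 with a warning.
#'
#' @param sequence DNA string (uppercase).
#' @return Integer vector of per-base scores in `[-4, 4]`; empty for an
#'   empty sequence.
#' @export
#' @examples
#' g4hunter_scores("GGGG")
g4hunter_scores <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) return(integer(0))
  v <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  if (any(!v %in% c("A", "C", "G", "T"))) {
    warning("non-ACGT characters scored 0")
  }
  r <- rle(v)
  val <- integer(length(r$values))
  val[r$values == "G"] <- pmin(r$lengths[r$values == "G"], 4L)
  val[r$values == "C"] <- -pmin(r$lengths[r$values == "C"], 4L)
  rep(val, r$lengths)
}

#' Sliding window means of a score vector
#'
#' @param scores numeric vector (e.g. from [g4hunter_scores()]).
#' @param window window width (>= 1).
#' @return Numeric vector of means at every start position with a full
#'   window (`length = max(0, n - window + 1)`).
#' @export
g4hunter_window_means <- function(scores, window = 25L) {
  stopifnot(window >= 1)
  n <- length(scores)
  if (window > n) return(numeric(0))
  cs <- cumsum(c(0, scores))
  (cs[(window + 1L):(n + 1L)] - cs[seq_len(n - window + 1L)]) / window
}

#' Call G-quadruplex tracts above a window-mean threshold
#'
#' Windows whose mean score reaches the threshold are merged when they
#' overlap or are adjacent; each merged run is reported as one tract
#' spanning the union of its contributing windows.
#'
#' @param sequence DNA string.
#' @param window window width in bp.
#' @param threshold minimum window mean (> 0).
#' @return data.frame with `start`, `end` (0-based half-open span of the
#'   tract) and `max_mean` (largest window mean in the tract); zero rows
#'   when nothing passes.
#' @export
call_g4_tracts <- function(sequence, window = 25L, threshold = 1.2) {
  stopifnot(threshold > 0)
  means <- g4hunter_window_means(g4hunter_scores(sequence), window)
  hit <- which(means >= threshold)
  if (!length(hit)) {
    return(data.frame(start = integer(0), end = integer(0),
                      max_mean = numeric(0)))
  }
  ## windows starting <= `window` apart overlap or touch: merge
  brk <- which(diff(hit) > window)
  grp <- rep(seq_len(length(brk) + 1L),
             diff(c(0L, brk, length(hit))))
  out <- lapply(split(hit, grp), function(ix) {
    data.frame(start = ix[1L] - 1L,
               end = as.integer(ix[length(ix)] - 1L + window),
               max_mean = max(means[ix]))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count G4 tracts in an allele sequence
#'
#' Tract count on the stored (repeat-sense, G-rich) strand; for pure
#' consensus-unit arrays the count is non-decreasing in the repeat copy
#' number at fixed parameters.
#'
#' @param allele_sequence DNA string of the allele (array plus flanks).
#' @param window window width in bp.
#' @param threshold minimum window mean (> 0).
#' @return Integer tract count.
#' @export
count_allele_g4 <- function(allele_sequence, window = 25L, threshold = 1.2) {
  nrow(call_g4_tracts(allele_sequence, window, threshold))
}
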