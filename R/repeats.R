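## Hamming distance between `unit` and every window of the same length in
## `v` (integer-coded sequence). Returns a vector over all start positions.
hamming_profile <- function(v, u) {
  p <- length(u)
  n <- length(v) - p + 1L
  if (n < 1L) return(integer(0))
  d <- integer(n)
  for (j in seq_len(p)) {
    d <- d + (v[j:(n + j - 1L)] != u[j])
  }
  d
}

seq_to_int <- function(s) utf8ToInt(s)

#' Count copies of a known repeat unit in a sequence
#'
#' Greedy tiling anchored at the best-scoring seed: the window with the
#' smallest Hamming distance to the unit (leftmost on ties) fixes the
#' phase, and tiling extends in both directions in steps of the unit
#' length. A window counts as one copy when its Hamming distance is at
#' most `max_mismatch_per_unit`; an isolated window over budget is bridged
#' (still counted as a copy) when the next in-phase window matches, so a
#' local noise burst does not truncate the array. A terminal partial
#' window matching the leading (right end) or trailing (left end)
#' `floor(|unit|/2)` unit bases counts as 0.5 copies.
#'
#' @param sequence DNA string to scan (uppercase ACGT).
#' @param unit repeat unit, length >= 2, uppercase ACGT.
#' @param max_mismatch_per_unit mismatch budget per unit-length window.
#' @return An object of class `repeat_call`: list with `unit`, `copies`
#'   (0.5 resolution), `purity` (fraction of matching bases within the
#'   array span), and `span` (0-based half-open start/end offsets of the
#'   array in the query; `c(0, 0)` when no array is found).
#' @export
#' @examples
#' s <- synthesize_vntr_allele(27)
#' count_repeat_copies(s, vntr_consensus_unit(), 4)$copies
count_repeat_copies <- function(sequence, unit, max_mismatch_per_unit = 4) {
  check_dna(unit)
  if (nchar(unit) < 2L) stop("`unit` must have length >= 2", call. = FALSE)
  check_dna(sequence, "sequence")
  v <- seq_to_int(sequence)
  u <- seq_to_int(unit)
  p <- length(u)
  mm <- max_mismatch_per_unit
  d <- hamming_profile(v, u)
  empty <- structure(list(unit = unit, copies = 0, purity = NA_real_,
                          span = c(0L, 0L)), class = "repeat_call")
  if (!length(d) || min(d) > mm) {
    ## no full copy: a bare leading half-copy still counts 0.5
    h <- p %/% 2L
    half_mm <- max(1L, mm %/% 2L)
    dh <- hamming_profile(v, u[seq_len(h)])
    if (length(dh) && min(dh) <= half_mm) {
      i <- which.min(dh)
      return(structure(list(unit = unit, copies = 0.5,
                            purity = 1 - dh[i] / h,
                            span = c(i - 1L, i + h - 1L)),
                       class = "repeat_call"))
    }
    return(empty)
  }
  seed <- which.min(d)

  ok <- function(i) i >= 1L && i <= length(d) && d[i] <= mm
  bridged <- function(i, step) {
    i >= 1L && i <= length(d) && ok(i + step)
  }
  ## extend left
  first <- seed
  repeat {
    nxt <- first - p
    if (ok(nxt)) first <- nxt
    else if (bridged(nxt, -p)) first <- nxt
    else break
  }
  ## extend right
  last <- seed
  repeat {
    nxt <- last + p
    if (ok(nxt)) last <- nxt
    else if (bridged(nxt, p)) last <- nxt
    else break
  }
  starts <- seq(first, last, by = p)
  full <- length(starts)
  mismatches <- sum(d[starts])
  span_start <- first
  span_end <- last + p  # 1-based position after final window

  h <- p %/% 2L
  half_mm <- max(1L, mm %/% 2L)
  halves <- 0
  ## right terminus: leading h bases of the unit
  if (span_end + h - 1L <= length(v)) {
    dh <- sum(v[span_end:(span_end + h - 1L)] != u[seq_len(h)])
    if (dh <= half_mm) {
      halves <- halves + 0.5
      mismatches <- mismatches + dh
      span_end <- span_end + h
    }
  }
  ## left terminus: trailing h bases of the unit
  if (span_start - h >= 1L) {
    dh <- sum(v[(span_start - h):(span_start - 1L)] != u[(p - h + 1L):p])
    if (dh <= half_mm) {
      halves <- halves + 0.5
      mismatches <- mismatches + dh
      span_start <- span_start - h
    }
  }
  span_len <- span_end - span_start
  structure(list(unit = unit, copies = full + halves,
                 purity = 1 - mismatches / span_len,
                 span = c(span_start - 1L, span_end - 1L)),
            class = "repeat_call")
}

#' @export
print.repeat_call <- function(x, ...) {
  cat(sprintf("repeat_call: %.1f copies of %d-bp unit, purity %.3f, span [%d, %d)\n",
              x$copies, nchar(x$unit), x$purity, x$span[1], x$span[2]))
  invisible(x)
}

#' Infer a repeat unit and its period de novo
#'
#' Scans candidate periods for self-similarity: the period maximizing the
#' base agreement between the sequence and itself shifted by the period
#' (restricted to the detected repeat span) wins; among near-tied periods
#' (within 0.02 agreement, which collapses harmonics and degenerate
#' periodicities such as homopolymers) the smallest is reported. The unit
#' is the per-column majority consensus across tiled copies, and its
#' rotation is canonicalized to the array's phase by occurrence counting:
#' the true phase tiles the array once more than any rotated phase (ties
#' broken by the leftmost first occurrence).
#'
#' @param sequence DNA string, length >= `3 * max_period`.
#' @param min_period,max_period candidate period range in bp
#'   (`max_period >= min_period >= 2`).
#' @return List with `unit`, `period`, `agreement` (span-restricted) and
#'   `note` (non-`NULL` when several periods tied and the smallest was
#'   taken).
#' @export
infer_repeat_unit <- function(sequence, min_period = 10, max_period = 60) {
  stopifnot(max_period >= min_period, min_period >= 2)
  check_dna(sequence, "sequence")
  v <- seq_to_int(sequence)
  n <- length(v)
  if (n < 3 * max_period) {
    stop("sequence must be at least 3 * max_period long", call. = FALSE)
  }
  periods <- seq.int(min_period, max_period)
  agree <- vapply(periods, function(p) {
    mean(v[seq_len(n - p)] == v[(p + 1L):n])
  }, numeric(1))
  near <- which(agree >= max(agree) - 0.02)
  p <- periods[near[1L]]
  note <- if (length(near) > 1L) {
    sprintf("%d candidate periods within 0.02 agreement of the maximum; smallest (%d bp) reported",
            length(near), p)
  }

  m <- v[seq_len(n - p)] == v[(p + 1L):n]
  ## substitutions break at most two adjacent match positions each; a
  ## small fill window bridges them without chaining flank noise
  span <- longest_filled_run(m, max_gap = max(4L, p %/% 8L))
  a <- span[1L]; b <- span[2L]           # match run [a, b]
  span_agree <- mean(m[a:b])
  if (span_agree <= 0.8) stop("no repeat detected", call. = FALSE)
  arr_end <- min(b + p, n)               # array covers matched run + one period

  rows <- floor((arr_end - a + 1L) / p)
  tiles <- matrix(v[a:(a + rows * p - 1L)], ncol = p, byrow = TRUE)
  cons <- apply(tiles, 2L, function(col) {
    tab <- sort(table(col), decreasing = TRUE)
    as.integer(names(tab)[1L])
  })
  unit <- canonical_rotation(v, cons)
  list(unit = intToUtf8(unit), period = p, agreement = span_agree,
       note = note)
}

## Longest run of TRUE values after closing FALSE gaps shorter than
## max_gap; returns c(start, end) indices of the run.
longest_filled_run <- function(m, max_gap) {
  r <- rle(m)
  fill <- !r$values & r$lengths < max_gap
  ## never fill leading/trailing gaps
  fill[c(1L, length(fill))] <- FALSE
  r$values[fill] <- TRUE
  m2 <- inverse.rle(r)
  r2 <- rle(m2)
  ends <- cumsum(r2$lengths)
  starts <- ends - r2$lengths + 1L
  true_runs <- which(r2$values)
  if (!length(true_runs)) stop("no repeat detected", call. = FALSE)
  best <- true_runs[which.max(r2$lengths[true_runs])]
  c(starts[best], ends[best])
}

## Pick the rotation of `cons` matching the array's phase. The true phase
## tiles one more full copy than any rotated phase, so each rotation is
## scored by greedy in-phase tiling from its best seed: most full copies
## wins, ties broken by fewer total mismatches, then by leftmost seed.
canonical_rotation <- function(v, cons) {
  p <- length(cons)
  tol <- max(2L, p %/% 8L)
  best <- NULL; best_score <- NULL
  for (k in seq_len(p) - 1L) {
    rot <- if (k == 0L) cons else c(cons[(k + 1L):p], cons[seq_len(k)])
    d <- hamming_profile(v, rot)
    if (!length(d) || min(d) > tol) next
    seed <- which.min(d)
    pass <- function(i) i >= 1L && i <= length(d) &&
      (d[i] <= tol ||
         (i - p >= 1L && d[i - p] <= tol) && (i + p <= length(d) && d[i + p] <= tol))
    first <- seed
    while (pass(first - p)) first <- first - p
    last <- seed
    while (pass(last + p)) last <- last + p
    starts <- seq(first, last, by = p)
    score <- c(length(starts), -sum(d[starts]), -first)
    if (is.null(best_score) ||
        score[1] > best_score[1] ||
        (score[1] == best_score[1] && score[2] > best_score[2]) ||
        (score[1] == best_score[1] && score[2] == best_score[2] &&
         score[3] > best_score[3])) {
      best <- rot; best_score <- score
    }
  }
  best %||% cons
}

#' Binarize a repeat copy number into Short/Long
#'
#' Alleles cluster into two groups (Short 24-27 copies, Long 40.5-66.5);
#' the default threshold 34 is the midpoint of the empirical gap between
#' 27 and 40.5 copies. Copy numbers falling inside the gap (above 27,
#' below 40.5) are classified by the threshold and flagged as
#' intermediate.
#'
#' @param copies numeric vector of copy numbers (>= 0).
#' @param threshold Long iff `copies >= threshold`.
#' @return data.frame with columns `copies`, `label` (`"Short"`/`"Long"`),
#'   `threshold_used` and `intermediate`.
#' @export
#' @examples
#' classify_allele(c(27, 40.5))$label
classify_allele <- function(copies, threshold = 34) {
  stopifnot(all(copies >= 0))
  data.frame(copies = copies,
             label = ifelse(copies >= threshold, "Long", "Short"),
             threshold_used = threshold,
             intermediate = copies > 27 & copies < 40.5,
             stringsAsFactors = FALSE)
}

#' Check Mendelian consistency of a trio's VNTR genotypes
#'
#' A trio is consistent when some assignment matches one child allele to a
#' paternal allele and the other to a maternal allele, each within
#' `tolerance` copies.
#'
#' @param father,mother,child length-2 numeric copy-number pairs.
#' @param tolerance allowed copy-number deviation per matched allele.
#' @return List with `consistent` (logical) and `assignment` (character,
#'   `NA` when inconsistent).
#' @export
check_mendelian <- function(father, mother, child, tolerance = 0.5) {
  stopifnot(length(father) == 2L, length(mother) == 2L, length(child) == 2L,
            !anyNA(c(father, mother, child)))
  for (ord in list(c(1L, 2L), c(2L, 1L))) {
    cp <- child[ord[1L]]; cm <- child[ord[2L]]
    for (i in 1:2) for (j in 1:2) {
      if (abs(cp - father[i]) <= tolerance && abs(cm - mother[j]) <= tolerance) {
        return(list(consistent = TRUE,
                    assignment = sprintf("child %g<-father %g, child %g<-mother %g",
                                         cp, father[i], cm, mother[j])))
      }
    }
  }
  list(consistent = FALSE, assignment = NA_character_)
}

#' Mendelian consistency across a simulated trio set
#'
#' @param trio_set result of [simulate_trios()].
#' @param tolerance per-allele copy tolerance.
#' @return data.frame with one row per trio (`child`, `consistent`).
#' @export
check_mendelian_trios <- function(trio_set, tolerance = 0.5) {
  stopifnot(inherits(trio_set, "trio_set"))
  panel <- trio_set$panel
  g <- vntr_genotypes(panel)
  res <- vapply(seq_len(nrow(trio_set$trios)), function(i) {
    tr <- trio_set$trios[i, ]
    check_mendelian(g[tr$father, ], g[tr$mother, ], g[tr$child, ],
                    tolerance)$consistent
  }, logical(1))
  data.frame(child = trio_set$trios$child, consistent = res,
             stringsAsFactors = FALSE)
}
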