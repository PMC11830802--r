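#' Per-genotype splice-event mixtures
#'
#' Event probabilities (canonical, INS1, INS1b, unspliced) per rs10069690
#' genotype, plus a sub-threshold intrusion probability for reads that
#' enter the intron by fewer than `min_intrusion` bp and are excluded
#' from totals. Canonical and INS1b defaults follow the per-genotype read
#' fractions reported for this junction (canonical 68.3/63.8/57.3% and
#' INS1b 0/3.8/7.0% across CC/CT/TT); INS1 and unspliced, which are only
#' reported as decreasing/increasing trends, carry small configurable
#' defaults absorbing the remainder.
#'
#' @param probs matrix with genotype rows (`CC`, `CT`, `TT`) and event
#'   columns (`canonical`, `INS1`, `INS1b`, `unspliced`); each row must
#'   sum to at most 1 with non-negative entries.
#' @param sub_threshold probability of a sub-threshold intrusion read,
#'   generated on top of the four events.
#' @return List of class `splice_mixture`.
#' @export
splice_mixture <- function(probs = NULL, sub_threshold = 0.02) {
  if (is.null(probs)) {
    probs <- rbind(
      CC = c(canonical = 0.683, INS1 = 0.030, INS1b = 0.000, unspliced = 0.287),
      CT = c(canonical = 0.638, INS1 = 0.025, INS1b = 0.038, unspliced = 0.299),
      TT = c(canonical = 0.573, INS1 = 0.020, INS1b = 0.070, unspliced = 0.337))
  }
  stopifnot(is.matrix(probs), ncol(probs) == 4L,
            all(colnames(probs) == c("canonical", "INS1", "INS1b", "unspliced")))
  if (any(probs < 0) || any(rowSums(probs) > 1 + 1e-9)) {
    stop("event probabilities must be non-negative and sum to <= 1 per genotype",
         call. = FALSE)
  }
  stopifnot(sub_threshold >= 0, sub_threshold < 1)
  structure(list(probs = probs, sub_threshold = sub_threshold),
            class = "splice_mixture")
}

#' Simulate exon4-exon5 junction-region reads
#'
#' Draws read categories from the genotype's event mixture (multinomial;
#' sub-threshold intrusion reads are generated with probability
#' `sub_threshold` on top and will be excluded by the classifier) and
#' constructs aligned blocks satisfying exactly one category's geometric
#' definition: spliced categories get an exon-4 block ending at the
#' category's donor offset plus an exon-5 block; unspliced reads get a
#' single block intruding at least `min_intrusion` bp into the intron;
#' sub-threshold reads intrude 1 to `min_intrusion - 1` bp.
#'
#' @param mixture a [splice_mixture()].
#' @param genotype one of the mixture's genotype row names.
#' @param n_reads number of reads.
#' @param seed integer seed.
#' @param annot a [splice_annotation()].
#' @return List of class `junction_read_set`: `reads` (block table with
#'   columns `read_id`, `start`, `end`), `truth` (the generating category
#'   per read) and `genotype`.
#' @export
simulate_splice_reads <- function(mixture, genotype, n_reads, seed,
                                  annot = splice_annotation()) {
  stopifnot(inherits(mixture, "splice_mixture"), n_reads >= 1)
  if (!genotype %in% rownames(mixture$probs)) {
    stop(sprintf("unknown genotype label %s (mixture defines: %s)", genotype,
                 paste(rownames(mixture$probs), collapse = ", ")),
         call. = FALSE)
  }
  p <- mixture$probs[genotype, ]
  p_evt <- p / sum(p)
  with_seed(seed, {
    n <- as.integer(n_reads)
    sub <- stats::runif(n) < mixture$sub_threshold
    cat <- character(n)
    cat[sub] <- "sub_threshold"
    cat[!sub] <- sample(names(p_evt), sum(!sub), replace = TRUE, prob = p_evt)

    L <- annot$intron_length
    e4 <- annot$exon4_length
    ext4 <- sample(20:min(100L, e4), n, replace = TRUE)   # exon-4 extent
    ext5 <- sample(20:min(100L, annot$exon5_length), n, replace = TRUE)
    donor <- c(canonical = 0L, INS1 = annot$ins1_offset,
               INS1b = annot$ins1b_offset)

    spliced <- cat %in% names(donor)
    single <- !spliced
    intr <- integer(n)
    intr[cat == "unspliced"] <- sample(
      annot$min_intrusion:min(L, annot$min_intrusion + 180L),
      sum(cat == "unspliced"), replace = TRUE)
    intr[cat == "sub_threshold"] <- sample(
      seq_len(annot$min_intrusion - 1L),
      sum(cat == "sub_threshold"), replace = TRUE)

    ids <- sprintf("r%07d", seq_len(n))
    ## spliced reads contribute two blocks, others one
    b1 <- data.frame(read_id = ids, start = -ext4,
                     end = ifelse(spliced, donor[cat], intr),
                     stringsAsFactors = FALSE)
    b2 <- data.frame(read_id = ids[spliced], start = L,
                     end = L + ext5[spliced], stringsAsFactors = FALSE)
    reads <- rbind(b1, b2)
    reads <- reads[order(reads$read_id, reads$start), , drop = FALSE]
    rownames(reads) <- NULL
    structure(list(reads = reads,
                   truth = stats::setNames(cat, ids),
                   genotype = genotype, annot = annot),
              class = "junction_read_set")
  })
}

#' @export
print.junction_read_set <- function(x, ...) {
  cat(sprintf("junction_read_set: %d reads (%s genotype)\n",
              length(x$truth), x$genotype))
  print(table(x$truth))
  invisible(x)
}
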