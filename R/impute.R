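#' Encode the binarized VNTR as a biallelic pseudo-marker
#'
#' Inserts a pseudo-marker into the panel's marker map at the VNTR
#' position, with allele S (coded 0, placeholder base A) for Short-class
#' haplotypes and L (coded 1, placeholder base T) for Long-class
#' haplotypes, so the VNTR can travel through standard phased-panel
#' machinery.
#'
#' @param panel a `phased_panel`.
#' @param position genomic position for the pseudo-marker (default the
#'   panel's VNTR position); must not collide with an existing marker.
#' @param id marker id for the pseudo-marker.
#' @return A `reference_panel` (also a `phased_panel`) whose haplotype
#'   matrix contains the extra column; the pseudo-marker id is stored in
#'   the `pseudo_id` attribute.
#' @export
encode_vntr_biallelic <- function(panel, position = panel$vntr_pos,
                                  id = "VNTR6-1") {
  stopifnot(inherits(panel, "phased_panel"))
  if (position %in% panel$markers$pos) {
    stop(sprintf("position %d collides with an existing marker", position),
         call. = FALSE)
  }
  allele <- as.integer(vntr_hap_class(panel) == "Long")
  markers <- rbind(panel$markers,
                   data.frame(id = id, pos = as.integer(position),
                              ref = "A", alt = "T", stringsAsFactors = FALSE))
  ord <- order(markers$pos)
  markers <- markers[ord, , drop = FALSE]
  haps <- cbind(panel$haplotypes, allele)
  colnames(haps)[ncol(haps)] <- id
  haps <- haps[, markers$id, drop = FALSE]
  out <- new_phased_panel(panel$individuals, markers, haps,
                          panel$vntr_copies, panel$vntr_pos,
                          panel$short_long_threshold)
  class(out) <- c("reference_panel", class(out))
  attr(out, "pseudo_id") <- id
  out
}

#' Decode the pseudo-marker back to haplotype classes
#'
#' @param reference a `reference_panel`.
#' @return Character vector of `"Short"`/`"Long"` per haplotype.
#' @export
decode_vntr_biallelic <- function(reference) {
  stopifnot(inherits(reference, "reference_panel"))
  id <- attr(reference, "pseudo_id")
  ifelse(reference$haplotypes[, id] == 1, "Long", "Short")
}

#' Impute the VNTR pseudo-marker into a target panel
#'
#' Haplotype-copying by k nearest neighbors: each target haplotype is
#' compared with every reference haplotype by Hamming distance over a
#' window of markers centered on the pseudo-marker; the k closest
#' reference haplotypes (ties broken by reference order) vote with
#' weights `exp(-distance)`, and the posterior dosage is the weighted
#' fraction carrying the L allele. Individual dosages are the sum of the
#' two haplotype dosages; best-guess genotypes round the individual
#' dosage at 0.5 and 1.5.
#'
#' @param reference a `reference_panel` from [encode_vntr_biallelic()].
#' @param target a `phased_panel` sharing the reference's SNP markers
#'   (without the pseudo-marker, or with it masked).
#' @param k number of nearest reference haplotypes (clamped to the
#'   reference size).
#' @param window number of flanking markers used for the distance
#'   (truncated with a warning when fewer are available).
#' @return An object of class `imputation_result`: `hap_dosage` (per
#'   target haplotype, in `[0, 1]`), `dosage` (per individual, in
#'   `[0, 2]`), `genotype` (best guess, 0/1/2 L-allele count), and the
#'   `k`/`window_markers` actually used.
#' @export
impute_biallelic <- function(reference, target, k = 10L, window = 40L) {
  stopifnot(inherits(reference, "reference_panel"),
            inherits(target, "phased_panel"))
  pseudo <- attr(reference, "pseudo_id")
  snp_ids <- setdiff(reference$markers$id, pseudo)
  if (!all(snp_ids %in% colnames(target$haplotypes))) {
    stop("target must share the reference's flanking marker set",
         call. = FALSE)
  }
  if (window > length(snp_ids)) {
    warning(sprintf("window %d exceeds the %d available markers; truncated",
                    window, length(snp_ids)))
    window <- length(snp_ids)
  }
  nref <- nrow(reference$haplotypes)
  if (k > nref) k <- nref
  ## `window` markers nearest to the pseudo-marker position
  pos <- stats::setNames(reference$markers$pos, reference$markers$id)
  vpos <- pos[[pseudo]]
  use <- snp_ids[order(abs(pos[snp_ids] - vpos))][seq_len(window)]

  R <- reference$haplotypes[, use, drop = FALSE]
  A <- reference$haplotypes[, pseudo]
  X <- target$haplotypes[, use, drop = FALSE]
  ## Hamming distances via 0/1 algebra: mismatches = x(1-r) + (1-x)r
  D <- X %*% t(1 - R) + (1 - X) %*% t(R)

  hap_dosage <- vapply(seq_len(nrow(X)), function(i) {
    o <- order(D[i, ], seq_len(nref))[seq_len(k)]
    w <- exp(-D[i, o])
    sum(w * A[o]) / sum(w)
  }, numeric(1))
  dosage <- hap_dosage[c(TRUE, FALSE)] + hap_dosage[c(FALSE, TRUE)]
  genotype <- as.integer(cut(dosage, breaks = c(-Inf, 0.5, 1.5, Inf),
                             right = FALSE)) - 1L
  structure(list(hap_dosage = hap_dosage, dosage = dosage,
                 genotype = stats::setNames(genotype, target$individuals$id),
                 k = k, window_markers = use),
            class = "imputation_result")
}

#' Genotype concordance
#'
#' Fraction of individuals whose (unordered) genotypes agree.
#'
#' @param best_guess,truth equal-length genotype vectors (0/1/2 counts).
#' @return Fraction in `[0, 1]`.
#' @export
genotype_concordance <- function(best_guess, truth) {
  stopifnot(length(best_guess) == length(truth))
  mean(best_guess == truth)
}

#' Imputation quality score (IQS)
#'
#' Chance-corrected genotype concordance over the 3x3 genotype table
#' (kappa form): `IQS = (Po - Pc) / (1 - Pc)` with observed concordance
#' `Po` and chance concordance `Pc` from the marginal products.
#'
#' @param best_guess,truth equal-length genotype vectors coded 0/1/2
#'   (SS/SL/LL).
#' @return List of class `iqs_report`: `po`, `pc`, `iqs` (`NA` with a
#'   `degenerate` flag when `Pc = 1`), and `table`.
#' @export
iqs <- function(best_guess, truth) {
  stopifnot(length(best_guess) == length(truth),
            all(best_guess %in% 0:2), all(truth %in% 0:2))
  g <- factor(best_guess, levels = 0:2)
  t <- factor(truth, levels = 0:2)
  tab <- table(t, g)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pc <- sum(rowSums(tab) * colSums(tab)) / n^2
  degenerate <- abs(1 - pc) < 1e-12
  structure(list(po = po, pc = pc,
                 iqs = if (degenerate) NA_real_ else (po - pc) / (1 - pc),
                 degenerate = degenerate, table = tab),
            class = "iqs_report")
}

#' @export
print.iqs_report <- function(x, ...) {
  cat(sprintf("IQS report: Po %.4f, Pc %.4f, IQS %s\n", x$po, x$pc,
              ifelse(is.na(x$iqs), "NA (degenerate marginals)",
                     sprintf("%.4f", x$iqs))))
  invisible(x)
}

#' Mask the VNTR pseudo-marker in a panel
#'
#' Removes the pseudo-marker column (and, optionally, the true copy
#' numbers) to build an imputation target from an encoded panel.
#'
#' @param reference a `reference_panel`.
#' @return A plain `phased_panel` without the pseudo-marker.
#' @export
mask_pseudo_marker <- function(reference) {
  stopifnot(inherits(reference, "reference_panel"))
  id <- attr(reference, "pseudo_id")
  keep <- reference$markers$id != id
  new_phased_panel(reference$individuals,
                   reference$markers[keep, , drop = FALSE],
                   reference$haplotypes[, reference$markers$id[keep],
                                        drop = FALSE],
                   reference$vntr_copies, reference$vntr_pos,
                   reference$short_long_threshold)
}
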