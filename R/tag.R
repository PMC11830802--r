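#' Filter panel markers by minor allele frequency
#'
#' @param panel a `phased_panel`.
#' @param threshold retain markers with MAF strictly greater than this.
#' @return Character vector of retained marker ids.
#' @export
filter_by_maf <- function(panel, threshold = 0.05) {
  stopifnot(inherits(panel, "phased_panel"))
  p <- colMeans(panel$haplotypes)
  maf <- pmin(p, 1 - p)
  colnames(panel$haplotypes)[maf > threshold]
}

#' Chi-square scan of markers against the VNTR class
#'
#' For every marker, tabulates phased haplotype counts against the
#' Short/Long VNTR class (2x2) and computes the 1-df Pearson chi-square
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`. Tables with a zero margin get
#' statistic 0 and are flagged.
#'
#' @param panel a `phased_panel`.
#' @param markers marker ids to scan (default all).
#' @return data.frame with `id`, `chi2`, `p`, `zero_margin`.
#' @export
chi2_scan <- function(panel, markers = colnames(panel$haplotypes)) {
  stopifnot(inherits(panel, "phased_panel"))
  long <- vntr_hap_class(panel) == "Long"
  if (length(unique(long)) < 2L) {
    stop("both VNTR classes must be present", call. = FALSE)
  }
  n <- length(long)
  res <- lapply(markers, function(id) {
    x <- panel$haplotypes[, id]
    a <- as.numeric(sum(x == 1 & long));  b <- as.numeric(sum(x == 1 & !long))
    cc <- as.numeric(sum(x == 0 & long)); d <- as.numeric(sum(x == 0 & !long))
    denom <- (a + b) * (cc + d) * (a + cc) * (b + d)
    if (denom == 0) {
      data.frame(id = id, chi2 = 0, p = 1, zero_margin = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      chi2 <- n * (a * d - b * cc)^2 / denom
      data.frame(id = id, chi2 = chi2,
                 p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 zero_margin = FALSE, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, res)
}

#' Cohen's kappa between two label vectors
#'
#' `kappa = (Po - Pe) / (1 - Pe)` with the chance agreement `Pe` from the
#' marginal products of the contingency table.
#'
#' @param truth,inferred equal-length label vectors (any comparable type).
#' @return List of class `agreement_stats`: `agreement` (Po), `kappa`
#'   (`NA` when the marginals are degenerate, i.e. `Pe = 1`), and `table`.
#' @export
cohens_kappa <- function(truth, inferred) {
  stopifnot(length(truth) == length(inferred), length(truth) >= 1L)
  lev <- sort(unique(c(as.character(truth), as.character(inferred))))
  t1 <- factor(as.character(truth), levels = lev)
  t2 <- factor(as.character(inferred), levels = lev)
  tab <- table(t1, t2)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (abs(1 - pe) < 1e-12) NA_real_ else (po - pe) / (1 - pe)
  structure(list(agreement = po, kappa = kappa, table = tab),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("agreement %.4f, kappa %s\n", x$agreement,
              ifelse(is.na(x$kappa), "NA (degenerate marginals)",
                     sprintf("%.4f", x$kappa))))
  invisible(x)
}

#' Select the best two-SNP haplotype proxy for the VNTR class
#'
#' Exhaustive search over all candidate marker pairs and all four
#' single-haplotype-to-Long assignments, maximizing Cohen's kappa between
#' the inferred and true haplotype classes. Ties are broken by higher
#' observed agreement, then smaller inter-marker distance, then
#' lexicographic marker ids.
#'
#' @param panel a `phased_panel`.
#' @param candidates candidate marker ids (>= 2), e.g. the output of
#'   [filter_by_maf()] screened by [chi2_scan()].
#' @return List with `mapping` (a `tag_mapping`: markers, the allele pair
#'   mapped to Long both as 0/1 codes and bases) and `stats` (the
#'   winning [cohens_kappa()] report).
#' @export
select_tag_pair <- function(panel, candidates) {
  stopifnot(inherits(panel, "phased_panel"))
  candidates <- sort(candidates)
  if (length(candidates) < 2L) {
    stop("need at least 2 candidate markers", call. = FALSE)
  }
  truth <- vntr_hap_class(panel)
  pos <- stats::setNames(panel$markers$pos, panel$markers$id)
  best <- NULL
  for (i in seq_len(length(candidates) - 1L)) {
    for (j in (i + 1L):length(candidates)) {
      a <- candidates[i]; b <- candidates[j]
      xa <- panel$haplotypes[, a]; xb <- panel$haplotypes[, b]
      for (aa in 0:1) for (ab in 0:1) {
        inferred <- ifelse(xa == aa & xb == ab, "Long", "Short")
        st <- cohens_kappa(truth, inferred)
        if (is.na(st$kappa)) next
        cand <- list(a = a, b = b, aa = aa, ab = ab, stats = st,
                     dist = abs(pos[[a]] - pos[[b]]))
        if (is.null(best) || better_tag(cand, best)) best <- cand
      }
    }
  }
  if (is.null(best) || best$stats$kappa <= 0) {
    stop("no informative pair: all candidate kappas <= 0", call. = FALSE)
  }
  mapping <- new_tag_mapping(panel, best$a, best$b, best$aa, best$ab)
  list(mapping = mapping, stats = best$stats)
}

better_tag <- function(x, y) {
  if (x$stats$kappa != y$stats$kappa) return(x$stats$kappa > y$stats$kappa)
  if (x$stats$agreement != y$stats$agreement)
    return(x$stats$agreement > y$stats$agreement)
  if (x$dist != y$dist) return(x$dist < y$dist)
  paste(x$a, x$b) < paste(y$a, y$b)
}

new_tag_mapping <- function(panel, a, b, aa, ab) {
  mk <- panel$markers
  base_of <- function(id, code) {
    row <- mk[mk$id == id, ]
    if (code == 1) row$alt else row$ref
  }
  structure(list(marker_a = a, marker_b = b,
                 long_code = c(aa, ab),
                 long_haplotype = c(base_of(a, aa), base_of(b, ab))),
            class = "tag_mapping")
}

#' @export
print.tag_mapping <- function(x, ...) {
  cat(sprintf("tag_mapping: %s-%s / %s-%s haplotype -> Long; all others -> Short\n",
              x$marker_a, x$long_haplotype[1], x$marker_b, x$long_haplotype[2]))
  invisible(x)
}

#' Infer VNTR classes from a tag-SNP haplotype mapping
#'
#' Applies a [select_tag_pair()] mapping to a phased panel: the single
#' two-SNP haplotype mapped to Long is called Long, all others Short;
#' individuals carrying at least one inferred Long haplotype form the
#' `"Long/any"` group.
#'
#' @param mapping a `tag_mapping`.
#' @param panel a `phased_panel` containing both mapping markers, phased.
#' @return List with `haplotype_class` (per haplotype, `"Short"`/
#'   `"Long"`) and `genotype_group` (per individual, `"Short/Short"`/
#'   `"Long/any"`).
#' @export
apply_tag_mapping <- function(mapping, panel) {
  stopifnot(inherits(mapping, "tag_mapping"), inherits(panel, "phased_panel"))
  if (!isTRUE(attr(panel, "phased"))) {
    stop("panel must be phased to apply a haplotype mapping", call. = FALSE)
  }
  need <- c(mapping$marker_a, mapping$marker_b)
  if (!all(need %in% colnames(panel$haplotypes))) {
    stop("mapping markers absent from panel", call. = FALSE)
  }
  hit <- panel$haplotypes[, mapping$marker_a] == mapping$long_code[1] &
    panel$haplotypes[, mapping$marker_b] == mapping$long_code[2]
  hap_class <- ifelse(hit, "Long", "Short")
  carrier <- hit[c(TRUE, FALSE)] | hit[c(FALSE, TRUE)]
  list(haplotype_class = hap_class,
       genotype_group = ifelse(carrier, "Long/any", "Short/Short"))
}

## r2 between two 0/1 haplotype vectors
ld_r2_vec <- function(x, y) {
  pa <- mean(x); pb <- mean(y)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
  d <- mean(x == 1 & y == 1) - pa * pb
  d^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' Linkage disequilibrium r-squared between two markers
#'
#' `r2 = D^2 / (pA (1-pA) pB (1-pB))` with `D = pAB - pA pB`, computed
#' from phased haplotype counts. The string `"VNTR"` names the binarized
#' VNTR pseudo-marker (Long-class indicator).
#'
#' @param panel a `phased_panel`.
#' @param marker_a,marker_b marker ids or `"VNTR"`.
#' @return r-squared in `[0, 1]`, or `NA` for a monomorphic marker.
#' @export
#' @examples
#' panel <- simulate_haplotype_panel(ceu_population(), 500, seed = 1)
#' ld_r2(panel, "VNTR", "rs2242652")
ld_r2 <- function(panel, marker_a, marker_b) {
  stopifnot(inherits(panel, "phased_panel"))
  get_vec <- function(id) {
    if (identical(id, "VNTR")) {
      as.integer(vntr_hap_class(panel) == "Long")
    } else {
      if (!id %in% colnames(panel$haplotypes)) {
        stop(sprintf("unknown marker %s", id), call. = FALSE)
      }
      panel$haplotypes[, id]
    }
  }
  ld_r2_vec(get_vec(marker_a), get_vec(marker_b))
}
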