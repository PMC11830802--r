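#' Simulate a phased diploid SNP + VNTR haplotype panel
#'
#' Draws `n_individuals` diploid individuals from a [population_config()].
#' Each haplotype first receives a VNTR allele (copy number) from the
#' population's allele-class frequencies; each SNP allele is then drawn
#' conditionally on the Short/Long class of the same haplotype from the
#' four-haplotype frequency table solved from (pLong, pAlt, target r2),
#' so every configured VNTR-SNP r-squared is matched in expectation and
#' converges as n grows. Individuals are assigned a population (by
#' configured weights), a sex (Bernoulli 0.5) and an age (uniform over
#' `age_range`).
#'
#' @param config a `population_config`.
#' @param n_individuals number of diploid individuals (>= 1).
#' @param seed integer seed; identical `(config, n, seed)` give identical
#'   panels.
#' @param age_range two-element numeric; ages drawn uniformly (years).
#'
#' @return An object of class `phased_panel`: a list with `individuals`
#'   (data.frame id/population/sex/age), `markers` (the SNP map),
#'   `haplotypes` (a `2n x m` 0/1 matrix of alt-allele indicators; rows
#'   `2i-1` and `2i` are individual `i`'s two phased haplotypes),
#'   `vntr_copies` (length-`2n` numeric of repeat copy numbers),
#'   `vntr_pos` and `short_long_threshold`.
#' @export
#' @examples
#' panel <- simulate_haplotype_panel(ceu_population(), 100, seed = 1)
#' table(vntr_hap_class(panel))
simulate_haplotype_panel <- function(config, n_individuals, seed,
                                     age_range = c(38, 73)) {
  stopifnot(inherits(config, "population_config"), n_individuals >= 1)
  n <- as.integer(n_individuals)
  with_seed(seed, {
    pops <- names(config$populations)
    w <- vapply(config$populations, function(p) p$weight, numeric(1))
    pop_of <- if (length(pops) == 1L) rep(pops, n) else
      sample(pops, n, replace = TRUE, prob = w / sum(w))
    nh <- 2L * n
    hap_pop <- rep(pop_of, each = 2L)

    copies <- numeric(nh)
    haps <- matrix(0L, nrow = nh, ncol = nrow(config$snps),
                   dimnames = list(NULL, config$snps$id))
    for (nm in pops) {
      idx <- which(hap_pop == nm)
      if (!length(idx)) next
      pop <- config$populations[[nm]]
      vf <- pop$vntr_freq
      cps <- as.numeric(names(vf))
      copies[idx] <- cps[sample.int(length(cps), length(idx),
                                    replace = TRUE, prob = vf)]
      long <- copies[idx] >= config$short_long_threshold
      pL <- sum(vf[cps >= config$short_long_threshold])
      for (id in config$snps$id) {
        pB <- pop$snp_freq[[id]]
        r2 <- if (id %in% names(config$target_r2)) config$target_r2[[id]] else 0
        if (r2 > 0 && pL > 0 && pL < 1) {
          d <- sqrt(r2 * pL * (1 - pL) * pB * (1 - pB))
          p_given_long <- pB + d / pL
          p_given_short <- pB - d / (1 - pL)
        } else {
          p_given_long <- p_given_short <- pB
        }
        p <- ifelse(long, p_given_long, p_given_short)
        haps[idx, id] <- as.integer(stats::runif(length(idx)) < p)
      }
    }

    ids <- sprintf("S%05d", seq_len(n))
    individuals <- data.frame(
      id = ids, population = pop_of,
      sex = as.integer(stats::runif(n) < 0.5),
      age = stats::runif(n, age_range[1], age_range[2]),
      stringsAsFactors = FALSE)
    rownames(haps) <- paste0(rep(ids, each = 2L), c("_h1", "_h2"))
    new_phased_panel(individuals, config$snps, haps, copies,
                     config$vntr_pos, config$short_long_threshold)
  })
}

new_phased_panel <- function(individuals, markers, haplotypes, vntr_copies,
                             vntr_pos, short_long_threshold) {
  stopifnot(nrow(haplotypes) == 2L * nrow(individuals),
            length(vntr_copies) == nrow(haplotypes),
            all(vntr_copies >= 0))
  structure(list(individuals = individuals, markers = markers,
                 haplotypes = haplotypes, vntr_copies = vntr_copies,
                 vntr_pos = as.integer(vntr_pos),
                 short_long_threshold = short_long_threshold),
            class = "phased_panel", phased = TRUE)
}

#' @export
print.phased_panel <- function(x, ...) {
  cat(sprintf("phased_panel: %d individuals, %d SNP markers + VNTR (pos %d)\n",
              nrow(x$individuals), nrow(x$markers), x$vntr_pos))
  cl <- vntr_hap_class(x)
  cat(sprintf("  VNTR haplotypes: %d Short, %d Long (threshold %g copies)\n",
              sum(cl == "Short"), sum(cl == "Long"), x$short_long_threshold))
  invisible(x)
}

#' Short/Long class of each haplotype in a panel
#'
#' @param panel a `phased_panel`.
#' @return Character vector (`"Short"`/`"Long"`), one entry per haplotype.
#' @export
vntr_hap_class <- function(panel) {
  stopifnot(inherits(panel, "phased_panel"))
  ifelse(panel$vntr_copies >= panel$short_long_threshold, "Long", "Short")
}

#' Per-individual VNTR genotype group
#'
#' @param panel a `phased_panel`.
#' @return Character vector per individual: `"Short/Short"` or
#'   `"Long/any"` (carrier of at least one Long allele).
#' @export
vntr_genotype_group <- function(panel) {
  cl <- vntr_hap_class(panel) == "Long"
  carrier <- cl[c(TRUE, FALSE)] | cl[c(FALSE, TRUE)]
  ifelse(carrier, "Long/any", "Short/Short")
}

#' Number of individuals in a panel
#' @param panel a `phased_panel`.
#' @return Integer count.
#' @export
n_individuals <- function(panel) nrow(panel$individuals)

## Subset a panel to individuals by index; used by trio and split utilities.
panel_subset <- function(panel, idx) {
  hap_idx <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  new_phased_panel(panel$individuals[idx, , drop = FALSE],
                   panel$markers,
                   panel$haplotypes[hap_idx, , drop = FALSE],
                   panel$vntr_copies[hap_idx],
                   panel$vntr_pos, panel$short_long_threshold)
}

#' Simulate parent-offspring trios from a panel
#'
#' Pairs up `2 * n_trios` unused panel individuals as parents and creates
#' one child per pair. The child's first haplotype is one of the father's
#' two haplotypes and the second one of the mother's, each chosen
#' uniformly; no recombination occurs within the simulated interval, so
#' every child allele (SNPs and VNTR copy number alike) is traceable to a
#' parental haplotype.
#'
#' @param panel a `phased_panel` with at least `2 * n_trios` individuals.
#' @param n_trios number of trios.
#' @param seed integer seed.
#' @return A list of class `trio_set`: `trios` (data.frame with father,
#'   mother and child ids plus the transmitted haplotype index, 1 or 2,
#'   for each parent) and `panel` (the input panel with the children
#'   appended).
#' @export
simulate_trios <- function(panel, n_trios, seed) {
  stopifnot(inherits(panel, "phased_panel"), n_trios >= 1)
  n <- n_individuals(panel)
  if (n < 2L * n_trios) {
    stop(sprintf("panel has %d individuals; %d needed for %d trios",
                 n, 2L * n_trios, n_trios), call. = FALSE)
  }
  with_seed(seed, {
    parents <- sample(n, 2L * n_trios)
    fathers <- parents[seq_len(n_trios)]
    mothers <- parents[n_trios + seq_len(n_trios)]
    pat_hap <- sample(1:2, n_trios, replace = TRUE)
    mat_hap <- sample(1:2, n_trios, replace = TRUE)

    pat_row <- 2L * fathers - 2L + pat_hap
    mat_row <- 2L * mothers - 2L + mat_hap
    child_rows <- as.vector(rbind(pat_row, mat_row))
    child_haps <- panel$haplotypes[child_rows, , drop = FALSE]
    child_copies <- panel$vntr_copies[child_rows]

    child_ids <- sprintf("C%05d", seq_len(n_trios))
    rownames(child_haps) <- paste0(rep(child_ids, each = 2L), c("_h1", "_h2"))
    children <- data.frame(
      id = child_ids,
      population = panel$individuals$population[fathers],
      sex = as.integer(stats::runif(n_trios) < 0.5),
      age = NA_real_, stringsAsFactors = FALSE)

    out_panel <- new_phased_panel(
      rbind(panel$individuals, children), panel$markers,
      rbind(panel$haplotypes, child_haps),
      c(panel$vntr_copies, child_copies),
      panel$vntr_pos, panel$short_long_threshold)
    trios <- data.frame(
      father = panel$individuals$id[fathers],
      mother = panel$individuals$id[mothers],
      child = child_ids, pat_hap = pat_hap, mat_hap = mat_hap,
      stringsAsFactors = FALSE)
    structure(list(trios = trios, panel = out_panel), class = "trio_set")
  })
}

#' VNTR copy-number genotype of each individual
#'
#' @param panel a `phased_panel`.
#' @param ids optional character vector of individual ids (default all).
#' @return A two-column matrix of copy numbers (haplotype 1 and 2), with
#'   individual ids as row names.
#' @export
vntr_genotypes <- function(panel, ids = NULL) {
  idx <- if (is.null(ids)) seq_len(n_individuals(panel)) else
    match(ids, panel$individuals$id)
  if (anyNA(idx)) stop("unknown individual id", call. = FALSE)
  out <- cbind(h1 = panel$vntr_copies[2L * idx - 1L],
               h2 = panel$vntr_copies[2L * idx])
  rownames(out) <- panel$individuals$id[idx]
  out
}
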