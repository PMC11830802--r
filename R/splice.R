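#' Splice annotation for the exon4-intron4-exon5 region
#'
#' Local coordinates: 0 is the 3' end of exon 4, the intron occupies
#' `[0, intron_length)`, exon 5 starts at `intron_length`; exon 4 extends
#' to negative coordinates. The cryptic donors sit 38 bp (INS1) and
#' 480 bp (INS1b) into intron 4; reads must extend at least
#' `min_intrusion` bp into the intron to count as unspliced.
#'
#' @param intron_length intron 4 length in bp (> 480).
#' @param exon4_length,exon5_length exon extents in bp.
#' @param ins1_offset,ins1b_offset cryptic donor offsets into the intron.
#' @param min_intrusion minimum intronic intrusion (bp) for a read to be
#'   counted.
#' @return List of class `splice_annotation`.
#' @export
splice_annotation <- function(intron_length = 1326L, exon4_length = 121L,
                              exon5_length = 111L, ins1_offset = 38L,
                              ins1b_offset = 480L, min_intrusion = 20L) {
  stopifnot(0 < ins1_offset, ins1_offset < ins1b_offset,
            ins1b_offset <= intron_length,
            min_intrusion <= ins1_offset)
  structure(list(intron_length = as.integer(intron_length),
                 exon4_length = as.integer(exon4_length),
                 exon5_length = as.integer(exon5_length),
                 ins1_offset = as.integer(ins1_offset),
                 ins1b_offset = as.integer(ins1b_offset),
                 min_intrusion = as.integer(min_intrusion)),
            class = "splice_annotation")
}

splice_categories <- c("canonical", "INS1", "INS1b", "unspliced", "excluded")

## Validate a block table (one read): sorted, non-overlapping, intersects
## exon 4.
check_blocks <- function(blocks, annot) {
  if (!is.matrix(blocks)) blocks <- as.matrix(blocks)
  if (ncol(blocks) != 2L || nrow(blocks) < 1L ||
      any(blocks[, 2] <= blocks[, 1])) {
    stop("malformed blocks: need rows of (start, end) with end > start",
         call. = FALSE)
  }
  if (nrow(blocks) > 1L &&
      (is.unsorted(blocks[, 1]) || any(blocks[-1L, 1] < blocks[-nrow(blocks), 2]))) {
    stop("malformed blocks: must be sorted and non-overlapping", call. = FALSE)
  }
  if (!any(blocks[, 1] < 0 & blocks[, 2] > -annot$exon4_length)) {
    stop("read has no block intersecting exon 4", call. = FALSE)
  }
  blocks
}

#' Classify one junction-region read
#'
#' Coordinate rules with precedence INS1b > INS1 > canonical > unspliced:
#' a splice junction is a pair of consecutive blocks whose gap runs from a
#' donor offset (480, 38 or 0 bp into the intron, within `slack`) to the
#' start of exon 5; reads without a recognized junction are `unspliced`
#' when they intrude at least `min_intrusion` bp into the intron and
#' `excluded` otherwise.
#'
#' @param blocks two-column matrix (or data.frame) of aligned block
#'   `(start, end)` pairs in local coordinates, 0-based half-open.
#' @param annot a [splice_annotation()].
#' @param slack coordinate tolerance in bp for junction matching
#'   (default 0, exact).
#' @return One of `"canonical"`, `"INS1"`, `"INS1b"`, `"unspliced"`,
#'   `"excluded"`.
#' @export
classify_junction_read <- function(blocks, annot = splice_annotation(),
                                   slack = 0L) {
  blocks <- check_blocks(blocks, annot)
  L <- annot$intron_length
  nb <- nrow(blocks)
  if (nb > 1L) {
    donor <- blocks[-nb, 2]
    acceptor <- blocks[-1L, 1]
    junction <- abs(acceptor - L) <= slack
    if (any(junction & abs(donor - annot$ins1b_offset) <= slack)) return("INS1b")
    if (any(junction & abs(donor - annot$ins1_offset) <= slack)) return("INS1")
    if (any(junction & abs(donor) <= slack)) return("canonical")
  }
  intrusion <- max(pmin(blocks[, 2], L) - pmax(blocks[, 1], 0), 0)
  if (intrusion >= annot$min_intrusion) "unspliced" else "excluded"
}

#' Count splice events in a junction read set
#'
#' Classifies every read of a read set (see [simulate_splice_reads()] for
#' the block-table representation) and tallies the four event categories;
#' sub-threshold reads are tallied separately as `excluded` and do not
#' enter the total.
#'
#' @param reads data.frame with columns `read_id`, `start`, `end` (one
#'   row per aligned block, rows of a read sorted by `start`).
#' @param annot a [splice_annotation()].
#' @param slack junction tolerance in bp.
#' @return List of class `event_counts`: `canonical`, `INS1`, `INS1b`,
#'   `unspliced`, `excluded`, `total` (the four counted categories).
#' @export
count_events <- function(reads, annot = splice_annotation(), slack = 0L) {
  stopifnot(all(c("read_id", "start", "end") %in% names(reads)))
  if (nrow(reads) == 0L) {
    counts <- stats::setNames(as.list(integer(5L)), splice_categories)
    counts$total <- 0L
    return(structure(counts, class = "event_counts"))
  }
  if (any(reads$end <= reads$start)) {
    stop("malformed blocks: need end > start", call. = FALSE)
  }
  o <- order(reads$read_id, reads$start)
  id <- reads$read_id[o]; s <- reads$start[o]; e <- reads$end[o]
  L <- annot$intron_length
  last_of_read <- c(id[-1L] != id[-length(id)], TRUE)

  ## junction donors: consecutive block pairs within a read
  pair <- !last_of_read
  donor <- e[pair]; acceptor <- s[which(pair) + 1L]
  jread <- id[pair]
  is_j <- abs(acceptor - L) <= slack
  has <- function(offset) {
    unique(jread[is_j & abs(donor - offset) <= slack])
  }
  r_ins1b <- has(annot$ins1b_offset)
  r_ins1 <- has(annot$ins1_offset)
  r_canon <- has(0)

  intr <- pmax(pmin(e, L) - pmax(s, 0), 0)
  max_intr <- tapply(intr, id, max)

  all_ids <- names(max_intr)
  cat_of <- rep("excluded", length(all_ids))
  names(cat_of) <- all_ids
  cat_of[max_intr >= annot$min_intrusion] <- "unspliced"
  cat_of[all_ids %in% r_canon] <- "canonical"
  cat_of[all_ids %in% r_ins1] <- "INS1"
  cat_of[all_ids %in% r_ins1b] <- "INS1b"

  counts <- as.list(vapply(splice_categories,
                           function(k) sum(cat_of == k), integer(1)))
  counts$total <- counts$canonical + counts$INS1 + counts$INS1b +
    counts$unspliced
  structure(counts, class = "event_counts")
}

#' @export
print.event_counts <- function(x, ...) {
  cat(sprintf(
    "event_counts: canonical %d, INS1 %d, INS1b %d, unspliced %d (total %d; %d excluded)\n",
    x$canonical, x$INS1, x$INS1b, x$unspliced, x$total, x$excluded))
  invisible(x)
}

#' Event fractions from splice-event counts
#'
#' @param counts an `event_counts` object.
#' @return Named numeric vector of the four category fractions (summing
#'   to 1), or all-`NA` with a warning when the total is 0.
#' @export
event_fractions <- function(counts) {
  stopifnot(inherits(counts, "event_counts"))
  cats <- splice_categories[1:4]
  if (counts$total == 0L) {
    warning("total read count is 0; fractions undefined")
    return(stats::setNames(rep(NA_real_, 4L), cats))
  }
  vapply(cats, function(k) counts[[k]] / counts$total, numeric(1))
}

#' Intron retention fraction
#'
#' @param intron_reads reads retained within the intron.
#' @param total_between_exons all reads between the flanking exons.
#' @return Ratio in `[0, 1]`, `NA` with a warning when the total is 0.
#' @export
#' @examples
#' intron_retention_fraction(262, 1000)
intron_retention_fraction <- function(intron_reads, total_between_exons) {
  stopifnot(intron_reads >= 0, total_between_exons >= 0,
            intron_reads <= total_between_exons)
  if (total_between_exons == 0) {
    warning("total read count is 0; retention undefined")
    return(NA_real_)
  }
  intron_reads / total_between_exons
}

#' Full-length isoform fraction from gel band intensities
#'
#' Densitometry summary of a two-band RT-PCR readout (302-bp full-length
#' and 120-bp alternative product).
#'
#' @param intensity_302bp,intensity_120bp non-negative band intensities,
#'   not both zero.
#' @return Percent full-length: `100 * i302 / (i302 + i120)`.
#' @export
fl_fraction_from_bands <- function(intensity_302bp, intensity_120bp) {
  stopifnot(intensity_302bp >= 0, intensity_120bp >= 0)
  if (intensity_302bp + intensity_120bp == 0) {
    warning("both band intensities are 0; fraction undefined")
    return(NA_real_)
  }
  100 * intensity_302bp / (intensity_302bp + intensity_120bp)
}
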