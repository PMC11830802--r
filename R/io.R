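#' Read a FASTA file
#'
#' @param path FASTA file (LF or CRLF line endings).
#' @return Named character vector of uppercase sequences; lowercase input
#'   is uppercased with a warning; duplicate ids are an error.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sequence ids in %s", path), call. = FALSE)
  }
  s <- as.character(x)
  if (any(grepl("[a-z]", s))) {
    warning("lowercase bases uppercased on read")
    s <- toupper(s)
  }
  stats::setNames(s, ids)
}

#' Write sequences to FASTA
#'
#' @param sequences named character vector.
#' @param path output path; lines wrapped at 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("sequences must have unique names", call. = FALSE)
  }
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(sequences), path, width = 60L)
  invisible(path)
}

#' Write a phased panel as minimal VCF plus a VNTR sidecar
#'
#' Emits a VCF v4.2 subset (CHROM/POS/ID/REF/ALT + phased GT) and a
#' sidecar TSV (`<path>.vntr.tsv`) carrying per-individual VNTR copy
#' numbers, population, sex and age. A pseudo-marker column (from
#' [encode_vntr_biallelic()]) is written as a biallelic record with
#' placeholder alleles A/T and the INFO flag `VNTR`.
#'
#' @param panel a `phased_panel` or `reference_panel`.
#' @param path output VCF path.
#' @param chrom chromosome label.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(panel, path, chrom = "chr5") {
  stopifnot(inherits(panel, "phased_panel"))
  pseudo <- attr(panel, "pseudo_id")
  ids <- panel$individuals$id
  gt <- vapply(seq_along(ids), function(i) {
    h1 <- panel$haplotypes[2L * i - 1L, ]
    h2 <- panel$haplotypes[2L * i, ]
    paste0(h1, "|", h2)
  }, character(nrow(panel$markers)))
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(panel$markers))
  info <- ifelse(panel$markers$id %in% pseudo, "VNTR", ".")
  body <- cbind(chrom, panel$markers$pos, panel$markers$id,
                panel$markers$ref, panel$markers$alt, ".", ".", info, "GT", gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=vntrproxy",
               '##INFO=<ID=VNTR,Number=0,Type=Flag,Description="VNTR pseudo-marker">',
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)

  side <- data.frame(id = ids,
                     population = panel$individuals$population,
                     sex = panel$individuals$sex,
                     age = panel$individuals$age,
                     h1_copies = panel$vntr_copies[c(TRUE, FALSE)],
                     h2_copies = panel$vntr_copies[c(FALSE, TRUE)],
                     stringsAsFactors = FALSE)
  utils::write.table(side, paste0(path, ".vntr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phased panel from minimal VCF plus sidecar
#'
#' Inverse of [write_phased_vcf()]. Unphased genotype separators (`/`)
#' are an error naming the offending record.
#'
#' @param path VCF path; the sidecar is read from `<path>.vntr.tsv`.
#' @param vntr_pos,short_long_threshold panel metadata (defaults match
#'   the package presets).
#' @return A `phased_panel` (a `reference_panel` when a `VNTR` INFO
#'   record is present).
#' @export
read_phased_vcf <- function(path, vntr_pos = 1275400L,
                            short_long_threshold = 34) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stop("missing #CHROM header line", call. = FALSE)
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1L]]
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nmark <- length(fields)

  markers <- data.frame(
    id = vapply(fields, `[[`, character(1), 3L),
    pos = as.integer(vapply(fields, `[[`, character(1), 2L)),
    ref = vapply(fields, `[[`, character(1), 4L),
    alt = vapply(fields, `[[`, character(1), 5L),
    stringsAsFactors = FALSE)
  info <- vapply(fields, `[[`, character(1), 8L)
  pseudo <- markers$id[info == "VNTR"]

  haps <- matrix(0L, nrow = 2L * length(samples), ncol = nmark,
                 dimnames = list(NULL, markers$id))
  for (m in seq_len(nmark)) {
    gt <- fields[[m]][-(1:9)]
    bad <- grep("/", gt, fixed = TRUE)
    if (length(bad)) {
      stop(sprintf("unphased genotype '%s' at record %s (line %d, sample %s)",
                   gt[bad[1L]], markers$id[m], hdr + m, samples[bad[1L]]),
           call. = FALSE)
    }
    parts <- strsplit(gt, "|", fixed = TRUE)
    ok <- vapply(parts, function(p) length(p) == 2L &&
                   all(p %in% c("0", "1")), logical(1))
    if (!all(ok)) {
      stop(sprintf("malformed GT at record %s (line %d)", markers$id[m],
                   hdr + m), call. = FALSE)
    }
    a <- vapply(parts, function(p) as.integer(p), integer(2))
    haps[c(TRUE, FALSE), m] <- a[1L, ]
    haps[c(FALSE, TRUE), m] <- a[2L, ]
  }

  side <- utils::read.table(paste0(path, ".vntr.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  side <- side[match(samples, side$id), , drop = FALSE]
  if (anyNA(side$id)) stop("sidecar is missing samples", call. = FALSE)
  individuals <- data.frame(id = side$id, population = side$population,
                            sex = side$sex, age = side$age,
                            stringsAsFactors = FALSE)
  copies <- as.vector(rbind(side$h1_copies, side$h2_copies))
  ord <- order(markers$pos)
  panel <- new_phased_panel(individuals, markers[ord, , drop = FALSE],
                            haps[, ord, drop = FALSE], copies,
                            vntr_pos, short_long_threshold)
  rownames(panel$haplotypes) <- paste0(rep(individuals$id, each = 2L),
                                       c("_h1", "_h2"))
  if (length(pseudo)) {
    class(panel) <- c("reference_panel", class(panel))
    attr(panel, "pseudo_id") <- pseudo[1L]
  }
  panel
}

#' Write repeat calls as TSV and BED
#'
#' @param calls list of `repeat_call` objects named by sequence id.
#' @param tsv_path output TSV (id, unit, copies, purity, span, class).
#' @param bed_path optional BED of array spans (0-based half-open).
#' @param threshold Short/Long classification threshold.
#' @param chrom chromosome label for BED output.
#' @return `tsv_path`, invisibly.
#' @export
write_repeat_calls <- function(calls, tsv_path, bed_path = NULL,
                               threshold = 34, chrom = "chr5") {
  stopifnot(length(names(calls)) == length(calls))
  tab <- do.call(rbind, lapply(names(calls), function(id) {
    rc <- calls[[id]]
    data.frame(id = id, unit = rc$unit, copies = rc$copies,
               purity = rc$purity, span_start = rc$span[1],
               span_end = rc$span[2],
               class = classify_allele(rc$copies, threshold)$label,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = chrom, start = tab$span_start,
                      end = tab$span_end, name = tab$id)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(tsv_path)
}

#' Read a structured run configuration
#'
#' YAML key-value configuration shared by the command-line entry points;
#' returns the parsed list unchanged.
#'
#' @param path YAML file.
#' @return Named list.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)
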