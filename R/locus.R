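# Locus-level ancestry composition: which ancestry each haplotype carries
# across a query interval, tallied over the whole cohort.

#' Ancestry composition of a genomic interval across all haplotypes
#'
#' Each haplotype in the cohort is assigned the ancestry with the largest
#' base-pair overlap with the query interval (majority-by-overlap; ties go
#' to the lower ancestry code; haplotypes with no overlapping window are
#' counted as \code{Unknown}).  Percentages are reported with 1-decimal
#' round-half-up precision.  With \code{per_base = TRUE}, fractional
#' per-base-pair accounting is used instead of the one-call-per-haplotype
#' majority rule.
#'
#' @param msps An \code{msp_table} or a list of per-chromosome
#'   \code{msp_table}s (combined internally).
#' @param interval A region string \code{"CHR:START-END"} or a list with
#'   \code{chrom}, \code{start}, \code{end} (0-based half-open).
#' @param per_base Use per-bp fractional accounting instead of the
#'   majority rule.  Default \code{FALSE}.
#' @return An object of class \code{locus_composition}: list with
#'   \code{interval}, \code{counts} (named integer vector over ancestries
#'   plus \code{Unknown}; sums to 2 x samples; \code{NA} under
#'   \code{per_base}), \code{percent} (same names, 1-decimal percentages),
#'   \code{n_haplotypes} and \code{method}.
#' @export
locus_composition <- function(msps, interval, per_base = FALSE) {
  if (inherits(msps, "msp_table")) msps <- list(msps)
  msp <- if (length(msps) == 1L) msps[[1L]] else combine_msp(msps)
  if (is.character(interval)) interval <- parse_region(interval)
  chrom <- as.character(interval$chrom)
  start <- as.numeric(interval$start)
  end <- as.numeric(interval$end)
  if (start >= end) stop_validation("interval start must be < end")
  if (!chrom %in% msp$windows$chrom) {
    stop_validation(sprintf(
      "chromosome '%s' not present in the data (have: %s)",
      chrom, paste(sort_chroms(unique(msp$windows$chrom)), collapse = ", ")))
  }

  cb <- msp$codebook
  K <- codebook_size(cb)
  n_hap <- 2L * length(msp$samples)
  sel <- msp$windows$chrom == chrom &
    msp$windows$epos > start & msp$windows$spos < end
  ov <- pmin(msp$windows$epos[sel], end) - pmax(msp$windows$spos[sel], start)
  codes <- msp$codes[sel, , drop = FALSE]

  # per-haplotype overlap bp for each ancestry code
  bp <- matrix(0, nrow = K, ncol = n_hap,
               dimnames = list(codebook_names(cb), colnames(msp$codes)))
  for (k in seq_len(K) - 1L) {
    bp[k + 1L, ] <- colSums(ov * (codes == k))
  }

  labels <- c(codebook_names(cb), "Unknown")
  if (per_base) {
    interval_len <- end - start
    known_bp <- rowSums(bp)
    unknown_bp <- n_hap * interval_len - sum(known_bp)
    mass <- c(known_bp, Unknown = unknown_bp)
    counts <- stats::setNames(rep(NA_integer_, K + 1L), labels)
    percent <- round_half_up(100 * mass / (n_hap * interval_len), 1L)
  } else {
    covered <- colSums(bp)
    # which.max returns the first (lowest-code) maximum: the tie rule
    call <- ifelse(covered > 0, apply(bp, 2L, which.max), K + 1L)
    counts <- stats::setNames(
      tabulate(call, nbins = K + 1L), labels)
    percent <- round_half_up(100 * counts / n_hap, 1L)
  }
  names(percent) <- labels
  structure(
    list(interval = list(chrom = chrom, start = start, end = end),
         counts = counts, percent = percent, n_haplotypes = n_hap,
         method = if (per_base) "per_base" else "majority"),
    class = "locus_composition"
  )
}

# one-decimal (or n-decimal) round-half-up, the convention used for all
# reported percentages; a tiny epsilon guards against binary
# representation pushing an exact .x5 just below the half
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' @export
print.locus_composition <- function(x, ...) {
  cat(sprintf("<locus_composition> %s:%d-%d over %d haplotypes (%s rule)\n",
              x$interval$chrom, x$interval$start, x$interval$end,
              x$n_haplotypes, x$method))
  for (nm in names(x$percent)) {
    cat(sprintf("  %-24s %6s  %5.1f%%\n", nm,
                ifelse(is.na(x$counts[[nm]]), "-", x$counts[[nm]]),
                x$percent[[nm]]))
  }
  invisible(x)
}

#' Write a locus-composition report as TSV
#'
#' Columns: ancestry_name, haplotype_count, percent.
#'
#' @param lc A \code{locus_composition}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_locus_report <- function(lc, path) {
  stopifnot(inherits(lc, "locus_composition"))
  header <- sprintf("#region=%s:%d-%d\tn_haplotypes=%d\tmethod=%s",
                    lc$interval$chrom, lc$interval$start, lc$interval$end,
                    lc$n_haplotypes, lc$method)
  rows <- sprintf("%s\t%s\t%.1f", names(lc$percent),
                  ifelse(is.na(lc$counts), "NA", lc$counts), lc$percent)
  writeLines(c(header, "#ancestry_name\thaplotype_count\tpercent", rows),
             path)
  invisible(path)
}
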