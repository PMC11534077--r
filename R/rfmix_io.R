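# Readers/writers for the two RFMIX2 output formats and for the BED files
# this toolkit emits.
#
# Dialects (fixed so that round-trips are bit-exact):
#   *.rfmix.Q  : '#'-prefixed comment lines; the LAST comment line is the
#                column header '#sample<TAB>ANC1<TAB>...<TAB>ANCK'; data rows
#                are '<sample_id>' followed by K decimal fractions, TAB-sep.
#   *.msp.tsv  : line 1 '#Subpopulation order/codes:<TAB>NAME=code<TAB>...';
#                line 2 '#chm spos epos sgpos egpos n snps' followed by
#                '<sample>.0'/'<sample>.1' column pairs, TAB-sep; data rows
#                carry integer ancestry codes.
# Coordinates are treated as 0-based half-open [spos, epos) throughout, so
# adjacent windows (epos_i == spos_{i+1}) tile without gaps, and emitted BED
# uses the same convention unchanged.

Q_ROWSUM_TOL <- 1e-4

# Natural ordering for chromosome labels: "chr" prefix ignored, numeric
# labels first in numeric order, non-numeric labels after, alphabetically.
chrom_order <- function(labels) {
  stripped <- sub("^chr", "", labels)
  num <- suppressWarnings(as.numeric(stripped))
  order(is.na(num), num, stripped)
}

sort_chroms <- function(labels) labels[chrom_order(labels)]

read_nonempty_lines <- function(path) {
  if (!file.exists(path)) {
    stop_format(sprintf("file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  lines[nzchar(lines)]
}

#' Read an RFMIX2 global-ancestry table (.rfmix.Q)
#'
#' Parses one per-chromosome global-ancestry file: one row per sample,
#' one column of ancestry proportions per reference ancestry.  Ancestry
#' names come from the header comment line and their order is preserved.
#' Every row must sum to 1 within \code{1e-4} (RFMIX2 prints rounded
#' decimals).
#'
#' @param path Path to a \code{.rfmix.Q} file.
#' @param chromosome Chromosome label to attach to the table (the file
#'   itself does not record it); default \code{NA}.
#' @return An object of class \code{rfmix_q}: a list with elements
#'   \code{chromosome}, \code{samples} (character), \code{codebook}
#'   (\code{\link{ancestry_codebook}}) and \code{fractions} (numeric
#'   matrix, samples x ancestries, rownames = samples).
#' @seealso \code{\link{write_q}}, \code{\link{read_q_files}}
#' @export
read_q <- function(path, chromosome = NA_character_) {
  lines <- read_nonempty_lines(path)
  is_comment <- startsWith(lines, "#")
  if (!any(is_comment)) {
    stop_format(sprintf("%s: missing '#' header line (line 1)", path))
  }
  header_idx <- max(which(is_comment))
  header <- strsplit(sub("^#", "", lines[header_idx]), "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L || tolower(header[1L]) != "sample") {
    stop_format(sprintf(
      "%s: header line %d must be '#sample<TAB><ancestries...>'",
      path, header_idx))
  }
  cb <- ancestry_codebook(header[-1L])
  K <- codebook_size(cb)

  data_lines <- lines[!is_comment]
  samples <- character(length(data_lines))
  fractions <- matrix(NA_real_, nrow = length(data_lines), ncol = K,
                      dimnames = list(NULL, codebook_names(cb)))
  for (i in seq_along(data_lines)) {
    fields <- strsplit(data_lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != K + 1L) {
      stop_format(sprintf(
        "%s: row %d has %d fields, expected %d (sample + %d ancestries)",
        path, i, length(fields), K + 1L, K))
    }
    samples[i] <- fields[1L]
    vals <- suppressWarnings(as.numeric(fields[-1L]))
    if (anyNA(vals)) {
      stop_format(sprintf("%s: non-numeric fraction for sample '%s'",
                          path, fields[1L]))
    }
    fractions[i, ] <- vals
  }
  new_rfmix_q(chromosome, samples, cb, fractions, source = path)
}

new_rfmix_q <- function(chromosome, samples, codebook, fractions,
                        source = NULL) {
  if (length(samples) < 1L) {
    stop_validation("global-ancestry table has no samples")
  }
  if (anyDuplicated(samples)) {
    stop_validation(sprintf("duplicate sample id(s): %s",
      paste(unique(samples[duplicated(samples)]), collapse = ", ")))
  }
  bad_range <- fractions < 0 | fractions > 1
  if (any(bad_range)) {
    i <- which(rowSums(bad_range) > 0)[1L]
    stop_validation(sprintf(
      "sample '%s': ancestry fraction outside [0, 1]", samples[i]))
  }
  sums <- rowSums(fractions)
  off <- abs(sums - 1) > Q_ROWSUM_TOL
  if (any(off)) {
    i <- which(off)[1L]
    stop_validation(sprintf(
      "sample '%s'%s: ancestry fractions sum to %.6f, expected 1 within %g",
      samples[i],
      if (is.null(source)) "" else sprintf(" in %s", source),
      sums[i], Q_ROWSUM_TOL))
  }
  rownames(fractions) <- samples
  structure(
    list(chromosome = as.character(chromosome), samples = samples,
         codebook = codebook, fractions = fractions),
    class = "rfmix_q"
  )
}

#' Write a global-ancestry table in .rfmix.Q format
#'
#' Fractions are printed with 6 decimals; \code{\link{read_q}} of the
#' result reproduces the values to that precision.
#'
#' @param q An \code{rfmix_q} object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_q <- function(q, path) {
  stopifnot(inherits(q, "rfmix_q"))
  header <- paste(c("#sample", codebook_names(q$codebook)), collapse = "\t")
  rows <- vapply(seq_along(q$samples), function(i) {
    paste(c(q$samples[i], sprintf("%.6f", q$fractions[i, ])), collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

parse_msp_codes_line <- function(line, path) {
  prefix <- "#Subpopulation order/codes:"
  if (!startsWith(line, prefix)) {
    stop_format(sprintf(
      "%s: line 1 must start with '%s'", path, prefix))
  }
  rest <- sub("^\\s*", "", substring(line, nchar(prefix) + 1L))
  pairs <- strsplit(rest, "\t", fixed = TRUE)[[1L]]
  pairs <- pairs[nzchar(pairs)]
  if (length(pairs) < 1L) {
    stop_format(sprintf("%s: no NAME=code pairs on line 1", path))
  }
  m <- regmatches(pairs, regexec("^(.+)=(\\d+)$", pairs))
  if (any(lengths(m) != 3L)) {
    stop_format(sprintf("%s: malformed NAME=code pair on line 1", path))
  }
  nms <- vapply(m, `[`, character(1L), 2L)
  codes <- as.integer(vapply(m, `[`, character(1L), 3L))
  ord <- order(codes)
  if (!identical(codes[ord], seq_along(codes) - 1L)) {
    stop_format(sprintf(
      "%s: subpopulation codes must be exactly 0..K-1", path))
  }
  ancestry_codebook(nms[ord])
}

#' Read an RFMIX2 local-ancestry window table (.msp.tsv)
#'
#' Parses one per-chromosome most-probable-ancestry file: one row per
#' genomic window, two integer ancestry-code columns per sample (one per
#' haplotype, suffixes \code{.0}/\code{.1}), preceded by the subpopulation
#' code line and the column-header line.
#'
#' @param path Path to a \code{.msp.tsv} file.
#' @return An object of class \code{msp_table}: list with \code{codebook},
#'   \code{samples}, \code{windows} (data.frame: \code{chrom}, \code{spos},
#'   \code{epos}, \code{sgpos}, \code{egpos}, \code{nsnps}) and \code{codes}
#'   (integer matrix, windows x haplotypes, colnames \code{<sample>.0},
#'   \code{<sample>.1}).  Coordinates are 0-based half-open.
#' @seealso \code{\link{write_msp}}, \code{\link{read_msp_files}},
#'   \code{\link{combine_msp}}
#' @export
read_msp <- function(path) {
  lines <- read_nonempty_lines(path)
  if (length(lines) < 3L) {
    stop_format(sprintf("%s: expected 2 header lines plus data", path))
  }
  cb <- parse_msp_codes_line(lines[1L], path)

  if (!startsWith(lines[2L], "#")) {
    stop_format(sprintf("%s: line 2 must be the '#chm ...' column header",
                        path))
  }
  header <- strsplit(sub("^#", "", lines[2L]), "\t", fixed = TRUE)[[1L]]
  fixed_cols <- c("chm", "spos", "epos", "sgpos", "egpos", "n snps")
  if (length(header) < 8L ||
      !identical(tolower(header[1:6]), fixed_cols)) {
    stop_format(sprintf(
      "%s: line 2 must begin '#chm\tspos\tepos\tsgpos\tegpos\tn snps'", path))
  }
  hap_cols <- header[-(1:6)]
  if (length(hap_cols) %% 2L != 0L) {
    stop_format(sprintf("%s: odd number of haplotype columns", path))
  }
  base <- sub("\\.[01]$", "", hap_cols)
  suffix <- sub("^.*\\.", "", hap_cols)
  pair_idx <- seq(1L, length(hap_cols), by = 2L)
  ok <- base[pair_idx] == base[pair_idx + 1L] &
    suffix[pair_idx] == "0" & suffix[pair_idx + 1L] == "1"
  if (!all(ok)) {
    bad <- pair_idx[!ok][1L]
    stop_format(sprintf(
      "%s: unpaired haplotype columns '%s'/'%s' (expected <sample>.0/<sample>.1)",
      path, hap_cols[bad], hap_cols[bad + 1L]))
  }
  samples <- base[pair_idx]
  if (anyDuplicated(samples)) {
    stop_format(sprintf("%s: duplicate sample '%s' in header",
                        path, samples[duplicated(samples)][1L]))
  }

  data_lines <- lines[-(1:2)]
  nfield <- 6L + length(hap_cols)
  fields <- strsplit(data_lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != nfield)
  if (length(bad) > 0L) {
    stop_format(sprintf(
      "%s: data row %d has %d fields, expected %d",
      path, bad[1L], lengths(fields)[bad[1L]], nfield))
  }
  mat <- matrix(unlist(fields, use.names = FALSE),
                nrow = length(fields), byrow = TRUE)
  windows <- data.frame(
    chrom = mat[, 1L],
    spos = as.numeric(mat[, 2L]),
    epos = as.numeric(mat[, 3L]),
    sgpos = as.numeric(mat[, 4L]),
    egpos = as.numeric(mat[, 5L]),
    nsnps = as.integer(mat[, 6L]),
    stringsAsFactors = FALSE
  )
  codes <- matrix(as.integer(mat[, -(1:6), drop = FALSE]),
                  nrow = nrow(mat),
                  dimnames = list(NULL, hap_cols))
  new_msp_table(cb, samples, windows, codes, source = path)
}

new_msp_table <- function(codebook, samples, windows, codes, source = NULL) {
  where <- if (is.null(source)) "" else sprintf(" in %s", source)
  K <- codebook_size(codebook)
  if (nrow(windows) < 1L) stop_validation(sprintf("no windows%s", where))
  if (anyNA(windows$spos) || anyNA(windows$epos) ||
      anyNA(windows$sgpos) || anyNA(windows$egpos) || anyNA(windows$nsnps)) {
    stop_format(sprintf("non-numeric window coordinates%s", where))
  }
  if (anyNA(codes)) stop_format(sprintf("non-integer ancestry code%s", where))
  bad <- which(windows$spos >= windows$epos)
  if (length(bad) > 0L) {
    stop_validation(sprintf(
      "window %s:%d-%d%s: spos must be < epos",
      windows$chrom[bad[1L]], windows$spos[bad[1L]], windows$epos[bad[1L]],
      where))
  }
  bad <- which(windows$sgpos > windows$egpos)
  if (length(bad) > 0L) {
    stop_validation(sprintf(
      "window %s:%d-%d%s: sgpos must be <= egpos",
      windows$chrom[bad[1L]], windows$spos[bad[1L]], windows$epos[bad[1L]],
      where))
  }
  if (any(windows$nsnps < 1L)) {
    stop_validation(sprintf("window with n snps < 1%s", where))
  }
  out_of_range <- codes < 0L | codes >= K
  if (any(out_of_range)) {
    i <- which(rowSums(out_of_range) > 0L)[1L]
    stop_validation(sprintf(
      "window %s:%d-%d%s: ancestry code outside 0..%d",
      windows$chrom[i], windows$spos[i], windows$epos[i], where, K - 1L))
  }
  # windows must be sorted by (chromosome, spos) and non-overlapping within
  # a chromosome; chromosome blocks must be contiguous
  chroms <- unique(windows$chrom)
  if (any(diff(match(windows$chrom, chroms)) < 0L)) {
    stop_validation(sprintf(
      "windows of one chromosome are not contiguous%s", where))
  }
  for (ch in chroms) {
    w <- windows[windows$chrom == ch, , drop = FALSE]
    if (nrow(w) > 1L) {
      if (any(diff(w$spos) <= 0)) {
        i <- which(diff(w$spos) <= 0)[1L]
        stop_validation(sprintf(
          "windows out of order on chromosome %s near %s:%d%s",
          ch, ch, w$spos[i + 1L], where))
      }
      if (any(w$spos[-1L] < w$epos[-nrow(w)])) {
        i <- which(w$spos[-1L] < w$epos[-nrow(w)])[1L]
        stop_validation(sprintf(
          "overlapping windows on chromosome %s near %s:%d%s",
          ch, ch, w$spos[i + 1L], where))
      }
    }
  }
  expected_cols <- as.vector(rbind(paste0(samples, ".0"),
                                   paste0(samples, ".1")))
  if (!identical(colnames(codes), expected_cols)) {
    stop_validation(sprintf("code columns do not match sample list%s", where))
  }
  rownames(windows) <- NULL
  structure(
    list(codebook = codebook, samples = samples,
         windows = windows, codes = codes),
    class = "msp_table"
  )
}

#' @export
print.msp_table <- function(x, ...) {
  cat(sprintf(
    "<msp_table> %d windows on %d chromosome(s), %d sample(s), K = %d\n",
    nrow(x$windows), length(unique(x$windows$chrom)),
    length(x$samples), codebook_size(x$codebook)))
  invisible(x)
}

#' Write a local-ancestry table in .msp.tsv format
#'
#' @param msp An \code{msp_table}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_msp <- function(msp, path) {
  stopifnot(inherits(msp, "msp_table"))
  cb <- msp$codebook
  line1 <- paste0("#Subpopulation order/codes:\t",
                  paste(sprintf("%s=%d", names(cb), unclass(cb)),
                        collapse = "\t"))
  line2 <- paste(c("#chm", "spos", "epos", "sgpos", "egpos", "n snps",
                   colnames(msp$codes)), collapse = "\t")
  w <- msp$windows
  rows <- paste(w$chrom, format_bp(w$spos), format_bp(w$epos),
                sprintf("%.6f", w$sgpos), sprintf("%.6f", w$egpos),
                w$nsnps,
                apply(msp$codes, 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(line1, line2, rows), path)
  invisible(path)
}

# Base-pair positions are integral but can exceed .Machine$integer.max is
# not an issue here (< 2.5e8); stored as double for safe arithmetic.
format_bp <- function(x) sprintf("%d", as.integer(round(x)))

#' Read per-chromosome .rfmix.Q files under a common prefix
#'
#' Files are looked up as \code{<prefix>.chr<N>.rfmix.Q} for each requested
#' chromosome.  Missing chromosomes are skipped with a warning; at least
#' one file must exist.
#'
#' @param prefix Path prefix (may include a directory).
#' @param chromosomes Chromosome labels to look for (default \code{1:22}).
#' @return Named list of \code{rfmix_q} tables (names = chromosome labels
#'   found), in the order requested.
#' @export
read_q_files <- function(prefix, chromosomes = 1:22) {
  discover_chrom_files(prefix, chromosomes, "rfmix.Q",
                       function(path, ch) read_q(path, chromosome = ch))
}

#' Read per-chromosome .msp.tsv files under a common prefix
#'
#' @inheritParams read_q_files
#' @return Named list of \code{msp_table} objects.
#' @export
read_msp_files <- function(prefix, chromosomes = 1:22) {
  discover_chrom_files(prefix, chromosomes, "msp.tsv",
                       function(path, ch) read_msp(path))
}

discover_chrom_files <- function(prefix, chromosomes, ext, reader) {
  chromosomes <- as.character(chromosomes)
  paths <- sprintf("%s.chr%s.%s", prefix, chromosomes, ext)
  present <- file.exists(paths)
  if (!any(present)) {
    stop_format(sprintf(
      "no %s files found for prefix '%s' (looked for %s ...)",
      ext, prefix, paths[1L]))
  }
  if (any(!present)) {
    ap_warn(sprintf("skipping missing chromosome(s): %s",
                    paste(chromosomes[!present], collapse = ", ")),
            class = "ap_missing_chromosome")
  }
  out <- lapply(which(present), function(i) reader(paths[i], chromosomes[i]))
  stats::setNames(out, chromosomes[present])
}

#' Concatenate per-chromosome msp tables into one table
#'
#' All tables must share an identical codebook and sample list; windows
#' are concatenated in chromosome order.
#'
#' @param msps Named list of \code{msp_table} objects (names = chromosome
#'   labels, used in mismatch errors).
#' @return A single \code{msp_table} spanning all chromosomes.
#' @export
combine_msp <- function(msps) {
  if (!is.list(msps) || length(msps) < 1L) {
    stop_validation("combine_msp() needs at least one msp table")
  }
  cb <- merge_codebooks(lapply(msps, `[[`, "codebook"))
  samples <- msps[[1L]]$samples
  labels <- names(msps) %||% as.character(seq_along(msps))
  for (i in seq_along(msps)) {
    if (!identical(msps[[i]]$samples, samples)) {
      stop_validation(sprintf(
        "sample list mismatch between chromosomes '%s' and '%s'",
        labels[1L], labels[i]))
    }
  }
  windows <- do.call(rbind, lapply(msps, `[[`, "windows"))
  codes <- do.call(rbind, lapply(msps, `[[`, "codes"))
  new_msp_table(cb, samples, windows, codes)
}

#' Write per-haplotype ancestry tracts as BED files
#'
#' For each sample, writes \code{<sample>_hap1.bed} (haplotype 0) and
#' \code{<sample>_hap2.bed} (haplotype 1) in 4-column BED
#' (chrom, start, end, ancestry name), 0-based half-open, sorted by
#' chromosome then start.
#'
#' @param tracts Tract data.frame as produced by
#'   \code{\link{windows_to_tracts}} (possibly for several samples /
#'   haplotypes rbound together).
#' @param codebook The run's \code{\link{ancestry_codebook}} (maps codes
#'   to the names written in column 4).
#' @param out_dir Output directory (created if absent).
#' @return Character vector of file paths written, invisibly.
#' @export
write_hap_beds <- function(tracts, codebook, out_dir) {
  stopifnot(is.data.frame(tracts))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    ap_stop(sprintf("cannot create directory '%s'", out_dir), "ap_io_error")
  }
  paths <- character(0L)
  for (sample in unique(tracts$sample)) {
    for (hap in 0:1) {
      tr <- tracts[tracts$sample == sample & tracts$haplotype == hap, ,
                   drop = FALSE]
      tr <- tr[order(match(tr$chrom, sort_chroms(unique(tr$chrom))),
                     tr$start), , drop = FALSE]
      path <- file.path(out_dir, sprintf("%s_hap%d.bed", sample, hap + 1L))
      lines <- paste(tr$chrom, format_bp(tr$start), format_bp(tr$end),
                     codebook_names(codebook)[tr$code + 1L], sep = "\t")
      writeLines(lines, path)
      paths <- c(paths, path)
    }
  }
  invisible(paths)
}

#' Read one haplotype BED file back into a tract data.frame
#'
#' Inverse of \code{\link{write_hap_beds}} for a single file; mainly used
#' for round-trip checks and downstream re-use of emitted BEDs.
#'
#' @param path Path to a \code{<sample>_hap<1|2>.bed} file.
#' @param codebook Codebook mapping ancestry names back to codes.
#' @return Tract data.frame (\code{chrom}, \code{start}, \code{end},
#'   \code{code}, \code{haplotype}, \code{sample}); sample and haplotype
#'   are recovered from the file name.
#' @export
read_hap_bed <- function(path, codebook) {
  lines <- read_nonempty_lines(path)
  m <- regmatches(basename(path),
                  regexec("^(.*)_hap([12])\\.bed$", basename(path)))[[1L]]
  if (length(m) != 3L) {
    stop_format(sprintf(
      "'%s' is not named like <sample>_hap<1|2>.bed", basename(path)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 4L)) {
    stop_format(sprintf("%s: expected 4 tab-separated columns", path))
  }
  mat <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  code <- match(mat[, 4L], codebook_names(codebook)) - 1L
  if (anyNA(code)) {
    stop_validation(sprintf(
      "%s: ancestry name '%s' not in codebook",
      path, mat[which(is.na(code))[1L], 4L]))
  }
  data.frame(
    chrom = mat[, 1L],
    start = as.numeric(mat[, 2L]),
    end = as.numeric(mat[, 3L]),
    code = code,
    haplotype = as.integer(m[3L]) - 1L,
    sample = m[2L],
    stringsAsFactors = FALSE
  )
}
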