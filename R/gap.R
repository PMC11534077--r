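# Global Ancestry Painting: per-individual mean ancestry across
# chromosomes, and the stacked bar plot.

#' Combine per-chromosome global-ancestry tables into per-individual means
#'
#' For each sample, the mean of each ancestry component is the unweighted
#' arithmetic mean over the chromosomes on which the sample appears (each
#' chromosome counts equally regardless of length).  Pass
#' \code{weights = "snps"}-style per-table weights via \code{weights} to
#' weight chromosomes unequally.
#'
#' @param tables List of \code{rfmix_q} tables (one per chromosome), all
#'   sharing one codebook.  Names, if present, label chromosomes in error
#'   messages.
#' @param weights Optional numeric vector, one weight per table, for a
#'   weighted chromosome mean.  Default \code{NULL} = unweighted.
#' @return An object of class \code{mean_ancestry}: list with
#'   \code{codebook} and \code{table}, a data.frame with columns
#'   \code{sample}, one column per ancestry (mean fraction), and
#'   \code{n_chroms} (number of chromosomes used per sample).
#' @export
combine_and_average <- function(tables, weights = NULL) {
  if (!is.list(tables) || length(tables) < 1L) {
    stop_validation("combine_and_average() needs at least one table")
  }
  cb <- merge_codebooks(lapply(tables, `[[`, "codebook"))
  K <- codebook_size(cb)
  if (is.null(weights)) {
    weights <- rep(1, length(tables))
  } else if (length(weights) != length(tables) || any(weights <= 0)) {
    stop_validation("weights must be positive, one per table")
  }

  # samples in first-appearance order across tables
  samples <- unique(unlist(lapply(tables, `[[`, "samples")))
  acc <- matrix(0, nrow = length(samples), ncol = K,
                dimnames = list(samples, codebook_names(cb)))
  wsum <- stats::setNames(numeric(length(samples)), samples)
  nchrom <- stats::setNames(integer(length(samples)), samples)
  for (i in seq_along(tables)) {
    tb <- tables[[i]]
    acc[tb$samples, ] <- acc[tb$samples, , drop = FALSE] +
      weights[i] * tb$fractions
    wsum[tb$samples] <- wsum[tb$samples] + weights[i]
    nchrom[tb$samples] <- nchrom[tb$samples] + 1L
  }
  if (any(nchrom < length(tables))) {
    missing_some <- samples[nchrom < length(tables)]
    ap_warn(sprintf(
      "%d sample(s) absent from some chromosomes (averaged over available): %s",
      length(missing_some),
      paste(utils::head(missing_some, 5L), collapse = ", ")))
  }
  means <- acc / wsum
  tab <- data.frame(sample = samples, means, n_chroms = as.integer(nchrom),
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  new_mean_ancestry(cb, tab)
}

new_mean_ancestry <- function(codebook, table) {
  K <- codebook_size(codebook)
  anc_cols <- codebook_names(codebook)
  stopifnot(all(anc_cols %in% colnames(table)), "sample" %in% colnames(table))
  if (nrow(table) < 1L) {
    stop_validation("mean-ancestry table has no records (nothing to plot)")
  }
  if (anyDuplicated(table$sample)) {
    stop_validation("duplicate sample ids in mean-ancestry table")
  }
  frac <- as.matrix(table[, anc_cols, drop = FALSE])
  if (any(frac < 0 | frac > 1) ||
      any(abs(rowSums(frac) - 1) > Q_ROWSUM_TOL)) {
    bad <- which(abs(rowSums(frac) - 1) > Q_ROWSUM_TOL | rowSums(frac < 0 | frac > 1) > 0)[1L]
    stop_validation(sprintf(
      "sample '%s': mean fractions are not a probability vector",
      table$sample[bad]))
  }
  if (any(table$n_chroms < 1L)) {
    stop_validation("n_chroms must be >= 1")
  }
  structure(list(codebook = codebook, table = table),
            class = "mean_ancestry")
}

#' @export
print.mean_ancestry <- function(x, ...) {
  cat(sprintf("<mean_ancestry> %d sample(s), K = %d\n",
              nrow(x$table), codebook_size(x$codebook)))
  print(utils::head(x$table))
  invisible(x)
}

#' Sort individuals by one mean ancestry component
#'
#' Reorders records by the named component, largest first (the
#' \code{--sort-ancestry} behaviour).  Ties are broken by sample id,
#' ascending lexicographic (C collation).
#'
#' @param mat A \code{mean_ancestry} object.
#' @param ancestry_name Name of the component to sort by.
#' @return A new, reordered \code{mean_ancestry}; the input is unchanged.
#' @export
sort_by_ancestry <- function(mat, ancestry_name) {
  stopifnot(inherits(mat, "mean_ancestry"))
  valid <- codebook_names(mat$codebook)
  if (!ancestry_name %in% valid) {
    stop_validation(sprintf(
      "unknown ancestry '%s'; valid names: %s",
      ancestry_name, paste(valid, collapse = ", ")))
  }
  key <- mat$table[[ancestry_name]]
  ord <- order(-key, mat$table$sample, method = "radix")
  mat$table <- mat$table[ord, , drop = FALSE]
  rownames(mat$table) <- NULL
  mat
}

#' Write / read the combined mean-ancestry table
#'
#' The intermediate TSV produced by the GAP combine stage and consumed by
#' the plot stage.  Header: \code{#sample<TAB><anc1>..<ancK><TAB>n_chroms};
#' fractions printed with 6 decimals (round-trip lossless at that
#' precision).
#'
#' @param mat A \code{mean_ancestry} object.
#' @param path File path.
#' @return \code{write_gap_table}: \code{path} invisibly;
#'   \code{read_gap_table}: a \code{mean_ancestry}.
#' @export
write_gap_table <- function(mat, path) {
  stopifnot(inherits(mat, "mean_ancestry"))
  anc <- codebook_names(mat$codebook)
  header <- paste(c("#sample", anc, "n_chroms"), collapse = "\t")
  frac <- as.matrix(mat$table[, anc, drop = FALSE])
  rows <- vapply(seq_len(nrow(mat$table)), function(i) {
    paste(c(mat$table$sample[i], sprintf("%.6f", frac[i, ]),
            mat$table$n_chroms[i]), collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_gap_table
#' @export
read_gap_table <- function(path) {
  lines <- read_nonempty_lines(path)
  if (!startsWith(lines[1L], "#")) {
    stop_format(sprintf("%s: missing '#sample ...' header", path))
  }
  header <- strsplit(sub("^#", "", lines[1L]), "\t", fixed = TRUE)[[1L]]
  n <- length(header)
  if (n < 3L || tolower(header[1L]) != "sample" ||
      header[n] != "n_chroms") {
    stop_format(sprintf(
      "%s: header must be '#sample<TAB><ancestries...><TAB>n_chroms'", path))
  }
  cb <- ancestry_codebook(header[-c(1L, n)])
  K <- codebook_size(cb)
  if (length(lines) < 2L) {
    stop_validation(sprintf("%s: no records (nothing to plot)", path))
  }
  fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
  if (any(lengths(fields) != K + 2L)) {
    stop_format(sprintf("%s: ragged data row", path))
  }
  m <- matrix(unlist(fields), ncol = K + 2L, byrow = TRUE)
  frac <- matrix(as.numeric(m[, 1L + seq_len(K)]), ncol = K,
                 dimnames = list(NULL, codebook_names(cb)))
  tab <- data.frame(sample = m[, 1L], frac,
                    n_chroms = as.integer(m[, K + 2L]),
                    check.names = FALSE, stringsAsFactors = FALSE)
  new_mean_ancestry(cb, tab)
}

#' Render the Global Ancestry Painting bar plot
#'
#' One vertical stacked bar per individual, in table order, segment
#' heights proportional to mean ancestry fractions; per-individual labels
#' below the bars and an ancestry legend on the right.  At most 10
#' ancestry components are drawn (the palette cap); mass of components
#' beyond the 10th is omitted, not renormalized, with a warning.
#'
#' @param mat A \code{mean_ancestry} object (render in its current order;
#'   use \code{\link{sort_by_ancestry}} first if desired).
#' @param out_path Output file path.
#' @param format \code{"pdf"} or \code{"svg"}.
#' @param palette Optional \code{\link{build_palette}} result; default
#'   palette otherwise.
#' @return \code{out_path}, invisibly.
#' @export
render_gap <- function(mat, out_path, format = c("pdf", "svg"),
                       palette = NULL) {
  stopifnot(inherits(mat, "mean_ancestry"))
  format <- match.arg(format)
  if (is.null(palette)) palette <- build_palette(mat$codebook)
  scene <- gap_scene(mat, palette)
  emit_scene(scene, out_path, format)
}

# Canvas: width scales with sample count (40 units per bar, min 800),
# height 600.
gap_scene <- function(mat, palette) {
  n <- nrow(mat$table)
  anc <- codebook_names(mat$codebook)
  shown <- palette$names
  if (length(anc) > length(shown)) {
    ap_warn(sprintf(
      "%d ancestry component(s) beyond the 10th not displayed: %s",
      length(anc) - length(shown),
      paste(setdiff(anc, shown), collapse = ", ")),
      class = "ap_undisplayed_components")
  }
  width <- max(800, 40 * n)
  height <- 600
  mar_top <- 40; mar_bottom <- 140; mar_left <- 70
  legend_w <- 30 + 9 * max(nchar(c(shown, "Ancestry"))) + 40
  plot_w <- width - mar_left - legend_w - 20
  plot_h <- height - mar_top - mar_bottom

  sc <- new_scene(width, height)
  slot <- plot_w / n
  bar_w <- slot * 0.75
  fills <- stats::setNames(palette$colors, shown)

  # y axis (fraction 0..1)
  for (tick in c(0, 0.25, 0.5, 0.75, 1)) {
    y <- mar_top + plot_h * (1 - tick)
    sc <- scene_line(sc, mar_left - 6, y, mar_left, y, "#000000",
                     class = "axis-tick")
    sc <- scene_text(sc, mar_left - 10, y + 4, sprintf("%.2f", tick),
                     size = 12, anchor = "end", class = "axis-label")
  }
  sc <- scene_line(sc, mar_left, mar_top, mar_left, mar_top + plot_h,
                   "#000000", class = "axis")

  for (i in seq_len(n)) {
    x <- mar_left + (i - 1) * slot + (slot - bar_w) / 2
    y_cursor <- mar_top + plot_h
    for (a in shown) {
      f <- mat$table[[a]][i]
      if (f <= 0) next
      seg_h <- f * plot_h
      y_cursor <- y_cursor - seg_h
      sc <- scene_rect(sc, x, y_cursor, bar_w, seg_h, fills[[a]],
                       class = "bar-segment")
    }
    sc <- scene_text(sc, x + bar_w / 2, mar_top + plot_h + 10,
                     mat$table$sample[i], size = 11, anchor = "end",
                     rotate = 90, class = "sample-label")
  }

  # legend
  lx <- width - legend_w
  sc <- scene_text(sc, lx, mar_top + 4, "Ancestry", size = 14,
                   class = "legend-title")
  for (j in seq_along(shown)) {
    ly <- mar_top + 14 + (j - 1) * 26
    sc <- scene_rect(sc, lx, ly, 18, 18, fills[[shown[j]]],
                     class = "legend-entry")
    sc <- scene_text(sc, lx + 26, ly + 14, shown[j], size = 13,
                     class = "legend-label")
  }
  sc
}
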