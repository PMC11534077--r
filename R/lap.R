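# Local Ancestry Painting: msp windows -> maximal ancestry tracts, the
# <=10-color scheme, and the diploid karyogram.

#' Collapse msp windows into maximal ancestry tracts for one haplotype
#'
#' Per chromosome, consecutive windows with the same ancestry code and
#' abutting coordinates (\code{epos == next spos}) are merged into one
#' tract.  A coordinate gap between windows (missing SNP data) starts a
#' new tract even when the codes match, so such regions later render as
#' unknown/background.  The returned tracts exactly cover the union of
#' the window intervals.
#'
#' @param msp An \code{msp_table}.
#' @param sample_id One sample present in \code{msp}.
#' @param haplotype 0 or 1.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{code}, \code{haplotype}, \code{sample}, in genomic order.
#' @export
windows_to_tracts <- function(msp, sample_id, haplotype) {
  stopifnot(inherits(msp, "msp_table"))
  if (!sample_id %in% msp$samples) {
    stop_validation(sprintf("unknown sample '%s'", sample_id))
  }
  if (!haplotype %in% c(0L, 1L)) {
    stop_validation("haplotype must be 0 or 1")
  }
  col <- sprintf("%s.%d", sample_id, haplotype)
  codes <- msp$codes[, col]
  w <- msp$windows
  n <- nrow(w)
  # a new tract starts at window i when the chromosome changes, the code
  # changes, or the previous window does not abut this one
  if (n == 1L) {
    new_start <- TRUE
  } else {
    new_start <- c(TRUE,
                   w$chrom[-1L] != w$chrom[-n] |
                   codes[-1L] != codes[-n] |
                   w$spos[-1L] != w$epos[-n])
  }
  grp <- cumsum(new_start)
  first <- which(new_start)
  last <- c(first[-1L] - 1L, n)
  data.frame(
    chrom = w$chrom[first],
    start = w$spos[first],
    end = w$epos[last],
    code = as.integer(codes[first]),
    haplotype = as.integer(haplotype),
    sample = sample_id,
    stringsAsFactors = FALSE
  )
}

# Default palette, in assignment order.  The first three echo the
# conventional orange (Middle East) / purple (Europe) / blue
# (sub-Saharan Africa) scheme; the remainder are chosen for pairwise
# contrast.  Hard cap of 10 colors: components beyond the 10th are never
# displayed.
DEFAULT_PALETTE <- c("#FF8C00", "#800080", "#1E90FF", "#228B22", "#DC143C",
                     "#8B4513", "#20B2AA", "#FF69B4", "#708090", "#BDB76B")
PALETTE_CAP <- 10L

#' Build the ancestry color scheme
#'
#' Assigns one color per ancestry component in codebook order, up to a
#' maximum of 10.  Components with code >= 10 receive no color and are
#' recorded in the \code{undisplayed} field (a warning is raised when any
#' exist).  Users may supply their own colors; exactly \code{min(K, 10)}
#' distinct hex colors are then required.
#'
#' @param codebook An \code{\link{ancestry_codebook}}.
#' @param user_colors Optional character vector of hex colors
#'   (\code{"#RRGGBB"}), length \code{min(K, 10)}.
#' @param background Background (unknown-ancestry) color; default white.
#' @return An object of class \code{ancestry_palette}: list with
#'   \code{names}, \code{colors}, \code{background}, \code{undisplayed}.
#' @export
build_palette <- function(codebook, user_colors = NULL,
                          background = "#FFFFFF") {
  K <- codebook_size(codebook)
  n_shown <- min(K, PALETTE_CAP)
  shown <- codebook_names(codebook)[seq_len(n_shown)]
  if (is.null(user_colors)) {
    colors <- DEFAULT_PALETTE[seq_len(n_shown)]
  } else {
    if (length(user_colors) != n_shown) {
      stop_validation(sprintf(
        "expected %d color(s) for %d displayed ancestry component(s), got %d",
        n_shown, n_shown, length(user_colors)))
    }
    if (!all(grepl("^#[0-9A-Fa-f]{6}$", user_colors))) {
      stop_validation("colors must be hex '#RRGGBB' strings")
    }
    if (anyDuplicated(toupper(user_colors))) {
      stop_validation("colors must be pairwise distinct")
    }
    colors <- toupper(user_colors)
  }
  undisplayed <- if (K > n_shown) {
    codebook_names(codebook)[(n_shown + 1L):K]
  } else {
    character(0L)
  }
  if (length(undisplayed) > 0L) {
    ap_warn(sprintf(
      "%d ancestry component(s) beyond the 10th will not be displayed: %s",
      length(undisplayed), paste(undisplayed, collapse = ", ")),
      class = "ap_undisplayed_components")
  }
  structure(list(names = shown, colors = colors, background = background,
                 undisplayed = undisplayed),
            class = "ancestry_palette")
}

#' Determine per-chromosome lengths for karyogram scaling
#'
#' The length of each chromosome is the maximum window end observed in
#' the msp tables, unless a chrom-sizes override provides a larger value.
#' An override smaller than the observed maximum is an error (tracts
#' would overrun the drawn chromosome).
#'
#' @param msps An \code{msp_table} or list of them.
#' @param override Optional path to a 2-column TSV (chrom, length_bp) or a
#'   named numeric vector.
#' @return Named numeric vector, chromosome -> length in bp, in natural
#'   chromosome order.
#' @export
chromosome_lengths <- function(msps, override = NULL) {
  if (inherits(msps, "msp_table")) msps <- list(msps)
  if (length(msps) < 1L) stop_validation("need at least one msp table")
  w <- do.call(rbind, lapply(msps, function(m) m$windows[, c("chrom", "epos")]))
  observed <- tapply(w$epos, w$chrom, max)
  lengths <- stats::setNames(as.numeric(observed), names(observed))
  if (!is.null(override)) {
    ov <- if (is.character(override)) read_chrom_sizes(override) else override
    for (ch in intersect(names(ov), names(lengths))) {
      if (ov[[ch]] < lengths[[ch]]) {
        stop_validation(sprintf(
          "chrom-sizes length for '%s' (%d) is smaller than observed window end (%d)",
          ch, as.integer(ov[[ch]]), as.integer(lengths[[ch]])))
      }
      lengths[[ch]] <- ov[[ch]]
    }
  }
  lengths[sort_chroms(names(lengths))]
}

#' @rdname chromosome_lengths
#' @param path Path to a chrom-sizes TSV.
#' @export
read_chrom_sizes <- function(path) {
  lines <- read_nonempty_lines(path)
  lines <- lines[!startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    stop_format(sprintf("%s: expected 2 tab-separated columns", path))
  }
  m <- vapply(fields, `[`, character(2L), 1:2)
  sizes <- suppressWarnings(as.numeric(m[2L, ]))
  if (anyNA(sizes) || any(sizes <= 0)) {
    stop_format(sprintf("%s: non-numeric or non-positive length", path))
  }
  stats::setNames(sizes, m[1L, ])
}

#' Parse a region string \code{CHR:START-END} or \code{CHR:START-END:LABEL}
#'
#' @param spec Region string, e.g. \code{"2:136545000-136594750:MCM6"}.
#' @param require_label If \code{TRUE} a label part is required (highlight
#'   syntax); otherwise the label defaults to the interval itself.
#' @return list(chrom, start, end, label); coordinates 0-based half-open.
#' @export
parse_region <- function(spec, require_label = FALSE) {
  m <- regmatches(spec,
    regexec("^([^:]+):([0-9]+)-([0-9]+)(?::(.+))?$", spec))[[1L]]
  if (length(m) == 0L || !nzchar(m[1L])) {
    stop_usage(sprintf(
      "malformed region '%s' (expected CHR:START-END[:LABEL])", spec))
  }
  start <- as.numeric(m[3L]); end <- as.numeric(m[4L])
  if (start >= end) {
    stop_validation(sprintf("region '%s': start must be < end", spec))
  }
  label <- m[5L]
  if (!nzchar(label)) {
    if (require_label) {
      stop_usage(sprintf("highlight '%s' needs a :LABEL part", spec))
    }
    label <- sprintf("%s:%s-%s", m[2L], m[3L], m[4L])
  }
  list(chrom = m[2L], start = start, end = end, label = label)
}

#' Render the Local Ancestry Painting karyogram for one individual
#'
#' Draws one row per chromosome (ascending natural order), each row two
#' parallel bands -- haplotype 0 above haplotype 1 -- with tract segments
#' colored by the palette.  Regions of a chromosome not covered by any
#' tract keep the background color (unknown ancestry / missing data).  A
#' legend lists the displayed ancestries and the sample identifier; an
#' optional region highlight draws a labeled marker on both bands.  The
#' canvas is exactly 4210 x 1663 units; PNG output has exactly those
#' pixel dimensions.
#'
#' @param tracts Tract data.frame (both haplotypes of exactly one sample),
#'   as from \code{\link{windows_to_tracts}} rbound over haplotypes.
#'   Tracts with codes beyond the palette cap are not drawn.
#' @param palette An \code{ancestry_palette}.
#' @param lengths Named chromosome lengths (see
#'   \code{\link{chromosome_lengths}}).
#' @param out_path Output file path.
#' @param format \code{"pdf"}, \code{"svg"} or \code{"png"}.
#' @param highlight Optional highlight: a string
#'   \code{"CHR:START-END:LABEL"} or the result of
#'   \code{\link{parse_region}}.
#' @return \code{out_path}, invisibly.
#' @export
render_lap <- function(tracts, palette, lengths, out_path,
                       format = c("pdf", "svg", "png"), highlight = NULL) {
  format <- match.arg(format)
  stopifnot(is.data.frame(tracts), inherits(palette, "ancestry_palette"))
  samples <- unique(tracts$sample)
  if (length(samples) != 1L) {
    stop_validation(sprintf(
      "karyogram renders exactly one sample, got %d", length(samples)))
  }
  if (!setequal(unique(tracts$haplotype), 0:1)) {
    stop_validation("tracts for both haplotypes (0 and 1) are required")
  }
  if (is.character(highlight)) {
    highlight <- parse_region(highlight, require_label = TRUE)
  }
  if (!is.null(highlight) && !highlight$chrom %in% names(lengths)) {
    stop_validation(sprintf(
      "highlight chromosome '%s' not present in the data", highlight$chrom))
  }
  scene <- lap_scene(tracts, palette, lengths, samples, highlight)
  emit_scene(scene, out_path, format)
}

LAP_WIDTH <- 4210
LAP_HEIGHT <- 1663

lap_scene <- function(tracts, palette, lengths, sample_id, highlight) {
  chroms <- names(lengths)
  n_chrom <- length(chroms)
  sc <- new_scene(LAP_WIDTH, LAP_HEIGHT, palette$background)

  mar_top <- 90; mar_bottom <- 40; mar_left <- 160
  legend_w <- 60 + 22 * max(nchar(c(palette$names, "Ancestry"))) + 80
  plot_w <- LAP_WIDTH - mar_left - legend_w - 40
  plot_h <- LAP_HEIGHT - mar_top - mar_bottom
  row_h <- plot_h / n_chrom
  band_h <- row_h * 0.30
  band_gap <- row_h * 0.10
  bp_scale <- plot_w / max(lengths)

  sc <- scene_text(sc, mar_left, 50, sprintf("Sample: %s", sample_id),
                   size = 40, class = "title")

  fills <- stats::setNames(palette$colors, palette$names)
  code_fill <- function(code) {
    nm <- codebook_code_name(palette, code)
    if (is.na(nm)) NA_character_ else fills[[nm]]
  }

  for (i in seq_len(n_chrom)) {
    ch <- chroms[i]
    y0 <- mar_top + (i - 1) * row_h + (row_h - 2 * band_h - band_gap) / 2
    chrom_w <- lengths[[ch]] * bp_scale
    sc <- scene_text(sc, mar_left - 16, y0 + band_h + band_gap / 2 + 8,
                     ch, size = 26, anchor = "end", class = "chrom-label")
    for (hap in 0:1) {
      by <- y0 + hap * (band_h + band_gap)
      # background band = unknown ancestry; outlined so uncovered white
      # regions remain visible against the white canvas
      sc <- scene_rect(sc, mar_left, by, chrom_w, band_h,
                       palette$background, stroke = "#B0B0B0",
                       class = "band-bg")
      tr <- tracts[tracts$chrom == ch & tracts$haplotype == hap, ,
                   drop = FALSE]
      if (nrow(tr) > 0L) tr <- tr[order(tr$start), , drop = FALSE]
      for (j in seq_len(nrow(tr))) {
        fill <- code_fill(tr$code[j])
        if (is.na(fill)) next  # component beyond the palette cap
        sc <- scene_rect(sc, mar_left + tr$start[j] * bp_scale, by,
                         (tr$end[j] - tr$start[j]) * bp_scale, band_h,
                         fill, class = "tract")
      }
    }
    if (!is.null(highlight) && highlight$chrom == ch) {
      hx1 <- mar_left + highlight$start * bp_scale
      hx2 <- mar_left + highlight$end * bp_scale
      hy1 <- y0 - 6
      hy2 <- y0 + 2 * band_h + band_gap + 6
      sc <- scene_line(sc, hx1, hy1, hx1, hy2, "#000000", width = 2,
                       class = "highlight")
      sc <- scene_line(sc, hx2, hy1, hx2, hy2, "#000000", width = 2,
                       class = "highlight")
      sc <- scene_line(sc, hx1, hy1, hx2, hy1, "#000000", width = 2,
                       class = "highlight")
      sc <- scene_text(sc, (hx1 + hx2) / 2, hy1 - 8, highlight$label,
                       size = 24, anchor = "middle",
                       class = "highlight-label")
    }
  }

  lx <- LAP_WIDTH - legend_w
  sc <- scene_text(sc, lx, mar_top + 10, "Ancestry", size = 32,
                   class = "legend-title")
  for (j in seq_along(palette$names)) {
    ly <- mar_top + 30 + (j - 1) * 56
    sc <- scene_rect(sc, lx, ly, 40, 40, palette$colors[j],
                     class = "legend-entry")
    sc <- scene_text(sc, lx + 56, ly + 30, palette$names[j], size = 28,
                     class = "legend-label")
  }
  sc
}

# map an integer ancestry code to its palette name (NA if beyond the cap)
codebook_code_name <- function(palette, code) {
  if (code >= 0L && code < length(palette$names)) {
    palette$names[code + 1L]
  } else {
    NA_character_
  }
}
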