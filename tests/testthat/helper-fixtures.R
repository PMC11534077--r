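# Fixture builders and independent brute-force oracles.
#
# The oracles deliberately use plain loops and none of the package's
# vectorized code paths, so that agreement is evidence rather than
# tautology.

# ---- raw-text writers (independent of the package's writers) ----------

raw_q_file <- function(lines, path = tempfile(fileext = ".rfmix.Q")) {
  writeLines(lines, path)
  path
}

raw_msp_file <- function(codes_line, header_line, data_lines,
                         path = tempfile(fileext = ".msp.tsv")) {
  writeLines(c(codes_line, header_line, data_lines), path)
  path
}

# ---- random generators ------------------------------------------------

# rows on the K-simplex (normalized gamma draws)
random_simplex <- function(n, K) {
  m <- matrix(stats::rgamma(n * K, shape = 2), nrow = n)
  m / rowSums(m)
}

random_q_table <- function(chrom, n_samples, ancestries) {
  frac <- random_simplex(n_samples, length(ancestries))
  colnames(frac) <- ancestries
  samples <- sprintf("S%02d", seq_len(n_samples))
  ancestrypaint:::new_rfmix_q(chrom, samples,
                              ancestry_codebook(ancestries), frac)
}

# random msp table: per chromosome, consecutive windows with occasional
# coordinate gaps; codes uniform over 0..K-1
random_msp <- function(n_windows = 30, n_samples = 3, K = 3,
                       chroms = c("1", "2"), gap_prob = 0.15,
                       window_bp = 1e5) {
  ancestries <- paste0("ANC", seq_len(K))
  samples <- sprintf("S%02d", seq_len(n_samples))
  hap_cols <- as.vector(rbind(paste0(samples, ".0"), paste0(samples, ".1")))
  win_list <- list()
  for (ch in chroms) {
    pos <- 0
    spos <- numeric(n_windows); epos <- numeric(n_windows)
    for (i in seq_len(n_windows)) {
      if (i > 1 && stats::runif(1) < gap_prob) {
        pos <- pos + sample(1:3, 1) * window_bp  # coordinate gap
      }
      spos[i] <- pos
      pos <- pos + window_bp
      epos[i] <- pos
    }
    win_list[[ch]] <- data.frame(
      chrom = ch, spos = spos, epos = epos,
      sgpos = spos / 1e6, egpos = epos / 1e6, nsnps = 100L,
      stringsAsFactors = FALSE)
  }
  windows <- do.call(rbind, win_list)
  codes <- matrix(sample(0:(K - 1), nrow(windows) * length(hap_cols),
                         replace = TRUE),
                  nrow = nrow(windows),
                  dimnames = list(NULL, hap_cols))
  ancestrypaint:::new_msp_table(ancestry_codebook(ancestries), samples,
                                windows, codes)
}

# msp table with a single window whose per-haplotype codes are given
single_window_msp <- function(hap_codes, ancestries,
                              chrom = "2", spos = 0, epos = 1e5) {
  n <- length(hap_codes) / 2
  samples <- sprintf("S%02d", seq_len(n))
  hap_cols <- as.vector(rbind(paste0(samples, ".0"), paste0(samples, ".1")))
  windows <- data.frame(chrom = chrom, spos = spos, epos = epos,
                        sgpos = spos / 1e6, egpos = epos / 1e6, nsnps = 50L,
                        stringsAsFactors = FALSE)
  codes <- matrix(as.integer(hap_codes), nrow = 1,
                  dimnames = list(NULL, hap_cols))
  ancestrypaint:::new_msp_table(ancestry_codebook(ancestries), samples,
                                windows, codes)
}

# ---- independent oracles ----------------------------------------------

# linear scan over windows, comparing window i with i+1
oracle_tracts <- function(msp, sample_id, haplotype) {
  col <- sprintf("%s.%d", sample_id, haplotype)
  w <- msp$windows
  codes <- msp$codes[, col]
  out <- NULL
  cur <- NULL
  for (i in seq_len(nrow(w))) {
    if (!is.null(cur) && w$chrom[i] == cur$chrom &&
        codes[i] == cur$code && w$spos[i] == cur$end) {
      cur$end <- w$epos[i]
    } else {
      out <- rbind(out, as.data.frame(cur, stringsAsFactors = FALSE))
      cur <- list(chrom = w$chrom[i], start = w$spos[i], end = w$epos[i],
                  code = as.integer(codes[i]),
                  haplotype = as.integer(haplotype), sample = sample_id)
    }
  }
  out <- rbind(out, as.data.frame(cur, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

# sum-then-divide accumulation per sample/ancestry
oracle_mean <- function(tables) {
  all_samples <- unique(unlist(lapply(tables, function(t) t$samples)))
  anc <- names(tables[[1]]$codebook)
  res <- matrix(NA_real_, length(all_samples), length(anc),
                dimnames = list(all_samples, anc))
  for (s in all_samples) {
    tot <- rep(0, length(anc)); n <- 0
    for (t in tables) {
      if (s %in% t$samples) {
        tot <- tot + t$fractions[s, ]
        n <- n + 1
      }
    }
    res[s, ] <- tot / n
  }
  res
}

# stable selection sort on (-key, sample)
oracle_sort_order <- function(key, ids) {
  remaining <- seq_along(key)
  out <- integer(0)
  while (length(remaining) > 0) {
    best <- remaining[1]
    for (i in remaining[-1]) {
      if (key[i] > key[best] ||
          (key[i] == key[best] && ids[i] < ids[best])) {
        best <- i
      }
    }
    out <- c(out, best)
    remaining <- setdiff(remaining, best)
  }
  out
}

# per-haplotype overlap accumulation, majority with lower-code ties
oracle_locus <- function(msp, chrom, start, end) {
  K <- length(msp$codebook)
  hap_cols <- colnames(msp$codes)
  calls <- character(length(hap_cols))
  for (j in seq_along(hap_cols)) {
    bp <- rep(0, K)
    for (i in seq_len(nrow(msp$windows))) {
      w <- msp$windows[i, ]
      if (w$chrom != chrom) next
      ov <- min(w$epos, end) - max(w$spos, start)
      if (ov > 0) {
        k <- msp$codes[i, j]
        bp[k + 1] <- bp[k + 1] + ov
      }
    }
    calls[j] <- if (sum(bp) == 0) "Unknown" else {
      names(msp$codebook)[which(bp == max(bp))[1]]
    }
  }
  counts <- sapply(c(names(msp$codebook), "Unknown"),
                   function(nm) sum(calls == nm))
  counts
}

# brute-force bp accounting of simulated tracts
oracle_bp_fractions <- function(tracts, K, total_bp) {
  bp <- rep(0, K)
  for (i in seq_len(nrow(tracts))) {
    k <- tracts$code[i]
    bp[k + 1] <- bp[k + 1] + (tracts$end[i] - tracts$start[i])
  }
  bp / total_bp
}

# ---- SVG helpers ------------------------------------------------------

svg_count_class <- function(path, class) {
  doc <- xml2::read_xml(path)
  length(xml2::xml_find_all(
    doc, sprintf("//*[@class='%s']", class)))
}

png_dimensions <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, 16)  # IHDR width/height
  readBin(con, "integer", n = 2, size = 4, endian = "big")
}

small_genome <- function(n_chrom = 4, length_bp = 2e7) {
  stats::setNames(rep(length_bp, n_chrom), as.character(seq_len(n_chrom)))
}
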