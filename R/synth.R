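# Synthetic RFMIX2 output with known ground truth.
#
# The generator lays ancestry tracts left-to-right along each haplotype:
# tract lengths are exponential with mean `mean_tract_bp` (truncated at
# the chromosome end) and each tract's ancestry is drawn independently
# from the ground-truth proportions, with equal-code neighbours merged.
# Drawing ancestries independently (rather than as a no-self-transition
# Markov chain) makes the expected bp share of each ancestry equal the
# proportions exactly, which is what recovery tests check against.
#
# This is NOT a population-genetic simulator: no recombination maps, no
# drift, no admixture dating.  It emulates file structure and marginal
# statistics only.

#' Simulation configuration for the synthetic RFMIX2 generator
#'
#' @param ancestries Character vector of ancestry names (builds the
#'   codebook; more than 10 are allowed, to exercise the palette cap).
#' @param proportions Ground-truth genome-wide ancestry proportions, one
#'   per ancestry, summing to 1 (tolerance 1e-9).
#' @param genome Named numeric vector: chromosome label -> length in bp.
#'   Default 22 chromosomes of 100 Mb.
#' @param n_samples Number of diploid individuals (default 30).
#' @param mean_tract_bp Mean ancestry-tract length in bp (default 5 Mb).
#' @param window_bp msp window size in bp (default 500 kb).
#' @param snps_per_window Constant SNP count written per window
#'   (default 300).
#' @param seed Base random seed (default 1729); every haplotype draws
#'   from its own stream derived from this.
#' @return A validated \code{sim_config} object.
#' @export
sim_config <- function(ancestries = c("MiddleEast", "Europe", "SubSaharanAfrica"),
                       proportions = c(0.55, 0.30, 0.15),
                       genome = stats::setNames(rep(1e8, 22), as.character(1:22)),
                       n_samples = 30L,
                       mean_tract_bp = 5e6,
                       window_bp = 5e5,
                       snps_per_window = 300L,
                       seed = 1729L) {
  cb <- ancestry_codebook(ancestries)
  if (length(proportions) != codebook_size(cb)) {
    stop_validation("need one proportion per ancestry")
  }
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-9) {
    stop_validation("proportions must be non-negative and sum to 1 (tol 1e-9)")
  }
  if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
    stop_validation("genome must be a named vector (chromosome -> length)")
  }
  if (any(genome <= 0) || mean_tract_bp <= 0 || window_bp <= 0) {
    stop_validation("lengths must be positive")
  }
  if (n_samples < 1L) stop_validation("n_samples must be >= 1")
  if (snps_per_window < 1L) stop_validation("snps_per_window must be >= 1")
  structure(
    list(codebook = cb, proportions = as.numeric(proportions),
         genome = genome, n_samples = as.integer(n_samples),
         mean_tract_bp = mean_tract_bp, window_bp = window_bp,
         snps_per_window = as.integer(snps_per_window),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

sample_ids <- function(config) {
  sprintf("S%0*d", max(2L, nchar(config$n_samples)),
          seq_len(config$n_samples))
}

# Deterministic per-haplotype seed stream: unique for sample < 2000,
# chromosome < 100, haplotype 0/1, and always < 2^31.
hap_seed <- function(seed, chrom_index, sample_index, haplotype) {
  as.integer((abs(seed) + 1000003 * sample_index + 10007 * chrom_index +
                3 * haplotype + 1) %% 2147483647)
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Simulate the ancestry tracts of one haplotype on one chromosome
#'
#' Deterministic given (config seed, chromosome, sample index, haplotype):
#' calling it twice with the same arguments yields identical tracts.
#'
#' @param config A \code{\link{sim_config}}.
#' @param chromosome Chromosome label present in \code{config$genome}.
#' @param sample_index Sample number (1-based, default 1).
#' @param haplotype 0 or 1 (default 0).
#' @return Tract data.frame (\code{chrom}, \code{start}, \code{end},
#'   \code{code}, \code{haplotype}, \code{sample}) fully covering
#'   \code{[0, length)}, maximal (no equal-code abutting neighbours).
#' @export
simulate_haplotype <- function(config, chromosome, sample_index = 1L,
                               haplotype = 0L) {
  stopifnot(inherits(config, "sim_config"))
  chromosome <- as.character(chromosome)
  if (!chromosome %in% names(config$genome)) {
    stop_validation(sprintf("chromosome '%s' not in configured genome",
                            chromosome))
  }
  L <- config$genome[[chromosome]]
  K <- codebook_size(config$codebook)
  ci <- match(chromosome, names(config$genome))
  with_seed(hap_seed(config$seed, ci, sample_index, haplotype), {
    lens <- numeric(0L)
    while (sum(lens) < L) {
      need <- max(8L, ceiling((L - sum(lens)) / config$mean_tract_bp * 2))
      lens <- c(lens, stats::rexp(need, rate = 1 / config$mean_tract_bp))
    }
    ends <- pmin(cumsum(lens), L)
    keep <- which(c(TRUE, ends[-length(ends)] < L))
    ends <- round(ends[keep])
    # rounding can produce zero-length tracts on tiny draws; drop them
    starts <- c(0, ends[-length(ends)])
    ok <- ends > starts
    starts <- starts[ok]; ends <- ends[ok]
    codes <- sample.int(K, length(starts), replace = TRUE,
                        prob = config$proportions) - 1L
    merge_equal_tracts(data.frame(
      chrom = chromosome, start = starts, end = ends, code = codes,
      haplotype = as.integer(haplotype),
      sample = sample_ids(config)[sample_index],
      stringsAsFactors = FALSE))
  })
}

# merge abutting equal-code tracts (single chromosome+haplotype, sorted)
merge_equal_tracts <- function(tr) {
  n <- nrow(tr)
  if (n <= 1L) return(tr)
  new_start <- c(TRUE, tr$code[-1L] != tr$code[-n] |
                       tr$start[-1L] != tr$end[-n])
  first <- which(new_start)
  last <- c(first[-1L] - 1L, n)
  out <- tr[first, , drop = FALSE]
  out$end <- tr$end[last]
  rownames(out) <- NULL
  out
}

#' Simulate all haplotypes of the configured cohort
#'
#' @param config A \code{\link{sim_config}}.
#' @return One tract data.frame covering every sample, haplotype and
#'   chromosome in the configuration.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  parts <- vector("list", config$n_samples * 2L * length(config$genome))
  i <- 0L
  for (si in seq_len(config$n_samples)) {
    for (ch in names(config$genome)) {
      for (hap in 0:1) {
        i <- i + 1L
        parts[[i]] <- simulate_haplotype(config, ch, si, hap)
      }
    }
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Discretize ground-truth tracts into an msp window table
#'
#' Each chromosome is tiled into windows of \code{window_bp} (last window
#' truncated at the chromosome end).  A window's code on a haplotype is
#' the majority-by-bp code of the tracts covering it (ties to the lower
#' code).  Genetic positions are mapped at 1 cM per Mb; \code{n snps} is
#' the configured constant.
#'
#' @param tracts Cohort tract data.frame (see
#'   \code{\link{simulate_cohort}}); must cover every chromosome fully.
#' @param config The \code{\link{sim_config}} used to generate them.
#' @return An \code{msp_table} spanning all configured chromosomes.
#' @export
tracts_to_msp <- function(tracts, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$window_bp <= 0) stop_validation("window_bp must be positive")
  ids <- sample_ids(config)
  wbp <- config$window_bp
  K <- codebook_size(config$codebook)
  hap_cols <- as.vector(rbind(paste0(ids, ".0"), paste0(ids, ".1")))

  win_list <- list(); code_list <- list()
  for (ch in names(config$genome)) {
    L <- config$genome[[ch]]
    starts <- seq(0, L - 1, by = wbp)
    ends <- pmin(starts + wbp, L)
    nwin <- length(starts)
    codes <- matrix(NA_integer_, nrow = nwin, ncol = length(hap_cols),
                    dimnames = list(NULL, hap_cols))
    ch_tr <- tracts[tracts$chrom == ch, , drop = FALSE]
    for (si in seq_along(ids)) {
      for (hap in 0:1) {
        tr <- ch_tr[ch_tr$sample == ids[si] & ch_tr$haplotype == hap, ,
                    drop = FALSE]
        codes[, 2L * si - 1L + hap] <- majority_window_codes(
          tr$start, tr$end, tr$code, wbp, nwin, K, L)
      }
    }
    win_list[[ch]] <- data.frame(
      chrom = ch, spos = starts, epos = ends,
      sgpos = starts / 1e6, egpos = ends / 1e6,
      nsnps = config$snps_per_window, stringsAsFactors = FALSE)
    code_list[[ch]] <- codes
  }
  new_msp_table(config$codebook, ids,
                do.call(rbind, win_list), do.call(rbind, code_list))
}

# majority-by-bp code per window for one haplotype's tracts
majority_window_codes <- function(start, end, code, wbp, nwin, K, L) {
  acc <- matrix(0, nrow = K, ncol = nwin)
  for (t in seq_along(start)) {
    i0 <- floor(start[t] / wbp)
    i1 <- ceiling(end[t] / wbp) - 1L
    wi <- i0:i1
    ovl <- pmin(end[t], (wi + 1) * wbp, L) - pmax(start[t], wi * wbp)
    idx <- cbind(code[t] + 1L, wi + 1L)
    acc[idx] <- acc[idx] + ovl
  }
  uncovered <- colSums(acc) <= 0
  if (any(uncovered)) {
    stop_validation("tracts do not cover every window")
  }
  max.col(t(acc), ties.method = "first") - 1L
}

#' Realized per-chromosome global-ancestry tables from ground-truth tracts
#'
#' For each chromosome and sample, the realized fraction of ancestry k is
#' (bp with code k on haplotype 0 + haplotype 1) / (2 x chromosome
#' length).  Rows sum to 1 exactly; this is what an exact global-ancestry
#' caller would report for the simulated genomes.
#'
#' @inheritParams tracts_to_msp
#' @return Named list of \code{rfmix_q} tables, one per chromosome.
#' @export
realized_q <- function(tracts, config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- sample_ids(config)
  K <- codebook_size(config$codebook)
  len <- tracts$end - tracts$start
  agg <- tapply(len,
                list(factor(tracts$sample, levels = ids),
                     factor(tracts$code, levels = 0:(K - 1L)),
                     factor(tracts$chrom, levels = names(config$genome))),
                sum, default = 0)
  out <- list()
  for (ch in names(config$genome)) {
    frac <- agg[, , ch, drop = TRUE]
    frac <- matrix(frac, nrow = length(ids), ncol = K,
                   dimnames = list(ids, codebook_names(config$codebook)))
    frac <- frac / (2 * config$genome[[ch]])
    out[[ch]] <- new_rfmix_q(ch, ids, config$codebook, frac)
  }
  out
}

#' Write a complete synthetic RFMIX2 fixture to disk
#'
#' Simulates the configured cohort and writes, for every chromosome,
#' \code{<prefix>.chr<N>.rfmix.Q} and \code{<prefix>.chr<N>.msp.tsv}
#' (parseable by \code{\link{read_q_files}} / \code{\link{read_msp_files}}
#' with no warnings), plus a ground-truth manifest
#' \code{<prefix>.manifest.tsv} recording the seed, the configuration and
#' each sample's realized genome-wide ancestry fractions.  Identical
#' config + seed produce byte-identical files.
#'
#' @param config A \code{\link{sim_config}}.
#' @param out_dir Output directory (created if absent).
#' @param prefix File-name prefix (default \code{"fixture"}).
#' @return Invisibly, a list with \code{prefix} (path prefix usable with
#'   the readers), \code{tracts}, \code{config} and \code{truth} (the
#'   per-sample realized genome-wide fractions).
#' @export
write_fixture <- function(config, out_dir, prefix = "fixture") {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    ap_stop(sprintf("cannot create directory '%s'", out_dir), "ap_io_error")
  }
  tracts <- simulate_cohort(config)
  qs <- realized_q(tracts, config)
  msp <- tracts_to_msp(tracts, config)
  pfx <- file.path(out_dir, prefix)
  for (ch in names(config$genome)) {
    write_q(qs[[ch]], sprintf("%s.chr%s.rfmix.Q", pfx, ch))
    sub <- msp_subset_chrom(msp, ch)
    write_msp(sub, sprintf("%s.chr%s.msp.tsv", pfx, ch))
  }
  truth <- genome_wide_fractions(tracts, config)
  manifest <- sprintf("%s.manifest.tsv", pfx)
  cfg_lines <- c(
    sprintf("#seed\t%d", config$seed),
    sprintf("#ancestries\t%s",
            paste(codebook_names(config$codebook), collapse = ",")),
    sprintf("#proportions\t%s",
            paste(sprintf("%.9f", config$proportions), collapse = ",")),
    sprintf("#genome\t%s",
            paste(sprintf("%s:%d", names(config$genome),
                          as.integer(config$genome)), collapse = ",")),
    sprintf("#n_samples\t%d", config$n_samples),
    sprintf("#mean_tract_bp\t%d", as.integer(config$mean_tract_bp)),
    sprintf("#window_bp\t%d", as.integer(config$window_bp)),
    sprintf("#snps_per_window\t%d", config$snps_per_window),
    paste(c("#sample", codebook_names(config$codebook)), collapse = "\t"))
  rows <- vapply(seq_len(nrow(truth)), function(i) {
    paste(c(rownames(truth)[i], sprintf("%.9f", truth[i, ])),
          collapse = "\t")
  }, character(1L))
  writeLines(c(cfg_lines, rows), manifest)
  invisible(list(prefix = pfx, tracts = tracts, config = config,
                 truth = truth))
}

msp_subset_chrom <- function(msp, chrom) {
  sel <- msp$windows$chrom == chrom
  new_msp_table(msp$codebook, msp$samples,
                msp$windows[sel, , drop = FALSE],
                msp$codes[sel, , drop = FALSE])
}

# realized genome-wide ancestry fractions per sample (matrix sample x K)
genome_wide_fractions <- function(tracts, config) {
  ids <- sample_ids(config)
  K <- codebook_size(config$codebook)
  len <- tracts$end - tracts$start
  agg <- tapply(len,
                list(factor(tracts$sample, levels = ids),
                     factor(tracts$code, levels = 0:(K - 1L))),
                sum, default = 0)
  frac <- matrix(agg, nrow = length(ids), ncol = K,
                 dimnames = list(ids, codebook_names(config$codebook)))
  frac / (2 * sum(config$genome))
}

#' Read a plain-text simulation configuration file
#'
#' \code{key=value} lines (\code{#} comments allowed).  Keys:
#' \code{ancestries}, \code{proportions} (comma-separated),
#' \code{n_samples}, \code{mean_tract_bp}, \code{window_bp},
#' \code{snps_per_window}, \code{seed}, and either
#' \code{genome=chr:length,...} or \code{chromosomes=N} +
#' \code{chromosome_length_bp=L}.  Missing keys take the
#' \code{\link{sim_config}} defaults.
#'
#' @param path Path to the config file.
#' @return A \code{\link{sim_config}}.
#' @export
read_sim_config <- function(path) {
  lines <- read_nonempty_lines(path)
  lines <- lines[!startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z_]+)\\s*=\\s*(.*?)\\s*$",
                                  lines))
  if (any(lengths(kv) != 3L)) {
    stop_format(sprintf("%s: expected key=value lines", path))
  }
  vals <- stats::setNames(vapply(kv, `[`, character(1L), 3L),
                          vapply(kv, `[`, character(1L), 2L))
  args <- list()
  split1 <- function(x) strsplit(x, ",", fixed = TRUE)[[1L]]
  if ("ancestries" %in% names(vals)) {
    args$ancestries <- split1(vals[["ancestries"]])
  }
  if ("proportions" %in% names(vals)) {
    args$proportions <- as.numeric(split1(vals[["proportions"]]))
  }
  if ("genome" %in% names(vals)) {
    parts <- strsplit(split1(vals[["genome"]]), ":", fixed = TRUE)
    if (any(lengths(parts) != 2L)) {
      stop_format(sprintf("%s: genome entries must be chrom:length", path))
    }
    args$genome <- stats::setNames(
      as.numeric(vapply(parts, `[`, character(1L), 2L)),
      vapply(parts, `[`, character(1L), 1L))
  } else if (all(c("chromosomes", "chromosome_length_bp") %in% names(vals))) {
    n <- as.integer(vals[["chromosomes"]])
    args$genome <- stats::setNames(
      rep(as.numeric(vals[["chromosome_length_bp"]]), n),
      as.character(seq_len(n)))
  }
  for (key in c("n_samples", "snps_per_window", "seed")) {
    if (key %in% names(vals)) args[[key]] <- as.integer(vals[[key]])
  }
  for (key in c("mean_tract_bp", "window_bp")) {
    if (key %in% names(vals)) args[[key]] <- as.numeric(vals[[key]])
  }
  do.call(sim_config, args)
}
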