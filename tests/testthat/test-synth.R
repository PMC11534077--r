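test_that("sim_config validates its inputs", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(proportions = c(0.5, 0.4)),
               class = "ap_validation_error")
  expect_error(sim_config(ancestries = c("A", "B"),
                          proportions = c(0.7, 0.2)),
               class = "ap_validation_error")
  expect_error(sim_config(n_samples = 0), class = "ap_validation_error")
  expect_error(sim_config(window_bp = -1), class = "ap_validation_error")
})

test_that("simulate_haplotype covers the chromosome and is deterministic", {
  cfg <- sim_config(ancestries = "ONLY", proportions = 1,
                    genome = c("1" = 1e7), seed = 3)
  tr <- simulate_haplotype(cfg, "1")
  # degenerate single ancestry -> one tract spanning the chromosome
  expect_identical(nrow(tr), 1L)
  expect_equal(tr$start, 0)
  expect_equal(tr$end, 1e7)
  expect_identical(tr$code, 0L)

  cfg <- sim_config(genome = c("1" = 5e7), seed = 3)
  a <- simulate_haplotype(cfg, "1", 2, 1)
  b <- simulate_haplotype(cfg, "1", 2, 1)
  expect_identical(a, b)
  # distinct streams for distinct haplotypes
  expect_false(identical(a, simulate_haplotype(cfg, "1", 2, 0)))
  # full coverage, in order, maximal
  expect_equal(a$start[1], 0)
  expect_equal(a$end[nrow(a)], 5e7)
  if (nrow(a) > 1) {
    expect_equal(a$start[-1], a$end[-nrow(a)])
    expect_false(any(a$code[-1] == a$code[-nrow(a)]))
  }
  expect_error(simulate_haplotype(cfg, "99"), class = "ap_validation_error")
})

test_that("simulated bp shares recover the ground-truth proportions", {
  # law-of-large-numbers check against brute-force bp accounting
  p <- c(0.55, 0.30, 0.15)
  cfg <- sim_config(proportions = p, n_samples = 10,
                    genome = setNames(rep(5e7, 8), as.character(1:8)),
                    mean_tract_bp = 2e6, seed = 777)
  tracts <- simulate_cohort(cfg)
  total <- 2 * cfg$n_samples * sum(cfg$genome)
  frac <- oracle_bp_fractions(tracts, 3, total)
  expect_true(all(abs(frac - p) <= 0.02))
})

test_that("tracts_to_msp assigns the majority code per window", {
  cfg <- sim_config(ancestries = c("A", "B"), proportions = c(0.5, 0.5),
                    genome = c("1" = 1e6), n_samples = 1,
                    window_bp = 1e5, seed = 1)
  ids <- "S01"
  # one tract per haplotype -> every window carries that code
  tracts <- data.frame(
    chrom = "1", start = 0, end = 1e6,
    code = c(0L, 1L), haplotype = c(0L, 1L), sample = ids,
    stringsAsFactors = FALSE)[c(1, 2), ]
  msp <- tracts_to_msp(tracts, cfg)
  expect_identical(nrow(msp$windows), 10L)
  expect_true(all(msp$codes[, "S01.0"] == 0L))
  expect_true(all(msp$codes[, "S01.1"] == 1L))
  expect_equal(msp$windows$sgpos, msp$windows$spos / 1e6)
  expect_true(all(msp$windows$nsnps == cfg$snps_per_window))

  # breakpoint exactly on a window boundary -> codes flip exactly there
  tracts <- data.frame(
    chrom = "1",
    start = c(0, 3e5, 0), end = c(3e5, 1e6, 1e6),
    code = c(0L, 1L, 0L), haplotype = c(0L, 0L, 1L), sample = ids,
    stringsAsFactors = FALSE)
  msp <- tracts_to_msp(tracts, cfg)
  expect_identical(unname(msp$codes[, "S01.0"]),
                   c(0L, 0L, 0L, rep(1L, 7)))

  # majority rule: 60/40 split inside one window
  tracts <- data.frame(
    chrom = "1", start = c(0, 6e4, 1e5, 0), end = c(6e4, 1e5, 1e6, 1e6),
    code = c(0L, 1L, 1L, 0L), haplotype = c(0L, 0L, 0L, 1L), sample = ids,
    stringsAsFactors = FALSE)
  msp <- tracts_to_msp(tracts, cfg)
  expect_identical(msp$codes[1, "S01.0"], c(S01.0 = 0L))
})

test_that("windowing recovers breakpoints to within one window", {
  cfg <- sim_config(genome = c("1" = 2e7, "2" = 2e7), n_samples = 2,
                    window_bp = 2e5, mean_tract_bp = 3e6, seed = 31)
  tracts <- simulate_cohort(cfg)
  msp <- tracts_to_msp(tracts, cfg)
  for (s in c("S1", "S2")) {
    for (hap in 0:1) {
      got <- windows_to_tracts(msp, sprintf("S%02d", as.integer(sub("S", "", s))), hap)
      truth <- tracts[tracts$sample == sprintf("S%02d", as.integer(sub("S", "", s))) &
                        tracts$haplotype == hap, ]
      # every recovered breakpoint lies within one window of a true one
      for (ch in unique(truth$chrom)) {
        b_got <- got$start[got$chrom == ch][-1]
        b_true <- truth$start[truth$chrom == ch][-1]
        if (length(b_got) > 0) {
          nearest <- vapply(b_got, function(b) min(abs(b_true - b)), 0)
          expect_true(all(nearest <= cfg$window_bp))
        }
      }
    }
  }
})

test_that("realized_q reports exact bp fractions that sum to one", {
  cfg <- sim_config(ancestries = c("A", "B"), proportions = c(0.5, 0.5),
                    genome = c("1" = 1e6), n_samples = 1, seed = 1)
  # hap0 all code 0, hap1 all code 1 -> (0.5, 0.5)
  tracts <- data.frame(
    chrom = "1", start = 0, end = 1e6, code = c(0L, 1L),
    haplotype = c(0L, 1L), sample = "S01", stringsAsFactors = FALSE)
  q <- realized_q(tracts, cfg)[["1"]]
  expect_equal(unname(q$fractions[1, ]), c(0.5, 0.5))

  # single-ancestry genome -> (1, 0)
  tracts$code <- 0L
  q <- realized_q(tracts, cfg)[["1"]]
  expect_equal(unname(q$fractions[1, ]), c(1, 0))

  # random cohort: equals brute-force bp accounting per chromosome/sample
  cfg <- sim_config(n_samples = 3, genome = small_genome(3),
                    mean_tract_bp = 2e6, seed = 41)
  tracts <- simulate_cohort(cfg)
  qs <- realized_q(tracts, cfg)
  for (ch in names(cfg$genome)) {
    expect_true(all(abs(rowSums(qs[[ch]]$fractions) - 1) < 1e-12))
    for (s in qs[[ch]]$samples) {
      sub <- tracts[tracts$chrom == ch & tracts$sample == s, ]
      expect_equal(unname(qs[[ch]]$fractions[s, ]),
                   oracle_bp_fractions(sub, 3, 2 * cfg$genome[[ch]]))
    }
  }
})

test_that("write_fixture emits parseable, deterministic files with a manifest", {
  cfg <- sim_config(n_samples = 2, genome = small_genome(2), seed = 53)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  res1 <- write_fixture(cfg, d1)
  res2 <- write_fixture(cfg, d2)
  # byte-identical under identical config + seed
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_true(file.exists(sprintf("%s.manifest.tsv", res1$prefix)))
  # parseable with no warnings
  expect_no_warning({
    qs <- read_q_files(res1$prefix, 1:2)
    msps <- read_msp_files(res1$prefix, 1:2)
  })
  # end-to-end recovery: file round-trip is the only noise
  mat <- combine_and_average(qs)
  truth_means <- Reduce(`+`, lapply(realized_q(res1$tracts, cfg),
                                    function(q) q$fractions)) / 2
  got <- as.matrix(mat$table[, names(cfg$codebook)])
  rownames(got) <- mat$table$sample
  expect_equal(got, truth_means, tolerance = 1e-6)
})

test_that("most windows carry the code of the tract covering their midpoint", {
  # window_bp well below mean_tract_bp, scaled-down genome for test speed
  cfg <- sim_config(n_samples = 2, genome = small_genome(2, 5e7),
                    window_bp = 5e5, mean_tract_bp = 5e6, seed = 67)
  tracts <- simulate_cohort(cfg)
  msp <- tracts_to_msp(tracts, cfg)
  hits <- 0L; total <- 0L
  for (si in 1:2) {
    for (hap in 0:1) {
      id <- sprintf("S%02d", si)
      col <- sprintf("%s.%d", id, hap)
      tr <- tracts[tracts$sample == id & tracts$haplotype == hap, ]
      for (ch in names(cfg$genome)) {
        w <- msp$windows$chrom == ch
        mid <- (msp$windows$spos[w] + msp$windows$epos[w]) / 2
        trc <- tr[tr$chrom == ch, ]
        midcode <- trc$code[findInterval(mid, trc$start)]
        hits <- hits + sum(midcode == msp$codes[w, col])
        total <- total + length(mid)
      }
    }
  }
  expect_gte(hits / total, 0.99)
})

test_that("read_sim_config parses key=value files", {
  path <- tempfile()
  writeLines(c(
    "# synthetic run",
    "ancestries=AFR,EUR",
    "proportions=0.7,0.3",
    "chromosomes=3",
    "chromosome_length_bp=10000000",
    "n_samples=5",
    "mean_tract_bp=2000000",
    "window_bp=250000",
    "snps_per_window=120",
    "seed=9"), path)
  cfg <- read_sim_config(path)
  expect_identical(names(cfg$codebook), c("AFR", "EUR"))
  expect_equal(cfg$proportions, c(0.7, 0.3))
  expect_identical(names(cfg$genome), c("1", "2", "3"))
  expect_equal(unname(cfg$genome), rep(1e7, 3))
  expect_identical(cfg$n_samples, 5L)
  expect_identical(cfg$seed, 9L)

  writeLines("genome=1:5000000,X:2000000", path)
  cfg <- read_sim_config(path)
  expect_identical(names(cfg$genome), c("1", "X"))
})
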