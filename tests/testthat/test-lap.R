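test_that("windows_to_tracts merges abutting equal-code windows only", {
  codes_line <- "#Subpopulation order/codes:\tA=0\tB=1"
  header <- "#chm\tspos\tepos\tsgpos\tegpos\tn snps\tS1.0\tS1.1"
  # equal codes, abutting -> one tract
  msp <- read_msp(raw_msp_file(codes_line, header,
    c("1\t100\t200\t0.1\t0.2\t5\t0\t1", "1\t200\t300\t0.2\t0.3\t5\t0\t0")))
  tr <- windows_to_tracts(msp, "S1", 0L)
  expect_identical(nrow(tr), 1L)
  expect_equal(tr$start, 100)
  expect_equal(tr$end, 300)
  expect_identical(tr$code, 0L)
  # different codes -> two tracts
  tr <- windows_to_tracts(msp, "S1", 1L)
  expect_identical(nrow(tr), 2L)
  # a coordinate gap breaks the tract even with equal codes
  msp <- read_msp(raw_msp_file(codes_line, header,
    c("1\t100\t200\t0.1\t0.2\t5\t0\t0", "1\t250\t300\t0.25\t0.3\t5\t0\t0")))
  tr <- windows_to_tracts(msp, "S1", 0L)
  expect_identical(nrow(tr), 2L)
  expect_equal(tr$end, c(200, 300))

  expect_error(windows_to_tracts(msp, "nobody", 0L),
               class = "ap_validation_error")
})

test_that("windows_to_tracts matches the linear-scan oracle on random input", {
  withr::with_seed(71, {
    for (rep in 1:5) {
      msp <- random_msp(n_windows = 200, n_samples = 2, K = 3)
      for (hap in 0:1) {
        got <- windows_to_tracts(msp, "S01", hap)
        expect_equal(got, oracle_tracts(msp, "S01", hap))
        # covered length is conserved exactly
        expect_identical(sum(got$end - got$start),
                         sum(msp$windows$epos - msp$windows$spos))
        # maximality: no abutting neighbours share chrom+code
        n <- nrow(got)
        if (n > 1) {
          abut <- got$chrom[-1] == got$chrom[-n] &
            got$start[-1] == got$end[-n]
          expect_false(any(abut & got$code[-1] == got$code[-n]))
        }
      }
    }
  })
})

test_that("build_palette assigns the documented defaults and enforces the cap", {
  cb <- ancestry_codebook(c("MiddleEast", "Europe", "SubSaharanAfrica"))
  pal <- build_palette(cb)
  # orange / purple / blue, in codebook order
  expect_identical(pal$colors, c("#FF8C00", "#800080", "#1E90FF"))
  expect_identical(pal$names, names(cb))
  expect_identical(pal$background, "#FFFFFF")

  cb12 <- ancestry_codebook(sprintf("P%02d", 1:12))
  expect_warning(pal12 <- build_palette(cb12),
                 class = "ap_undisplayed_components")
  expect_length(pal12$colors, 10L)
  expect_identical(pal12$undisplayed, c("P11", "P12"))
  expect_false(anyDuplicated(pal12$colors) > 0)

  # user colors: wrong arity, bad hex, duplicates
  expect_error(build_palette(cb, c("#000000", "#111111")),
               class = "ap_validation_error")
  expect_error(build_palette(cb, c("red", "green", "blue")),
               class = "ap_validation_error")
  expect_error(build_palette(cb, c("#000000", "#000000", "#111111")),
               class = "ap_validation_error")
  pal <- build_palette(cb, c("#010203", "#040506", "#070809"))
  expect_identical(pal$colors, c("#010203", "#040506", "#070809"))
})

test_that("chromosome_lengths takes the observed max unless overridden larger", {
  msp <- random_msp(n_windows = 10, chroms = c("1", "2"), gap_prob = 0)
  len <- chromosome_lengths(msp)
  expect_identical(names(len), c("1", "2"))
  expect_equal(unname(len["1"]), max(msp$windows$epos[msp$windows$chrom == "1"]))
  # larger override wins
  bigger <- c("1" = 5e9)
  len2 <- chromosome_lengths(msp, override = bigger)
  expect_equal(unname(len2["1"]), 5e9)
  # smaller override is an error
  expect_error(chromosome_lengths(msp, override = c("1" = 1)),
               class = "ap_validation_error")
  # chrom-sizes file path
  sizes <- tempfile()
  writeLines("1\t6000000000", sizes)
  expect_equal(unname(chromosome_lengths(msp, override = sizes)["1"]), 6e9)
  # lengths dominate every tract end
  tr <- windows_to_tracts(msp, "S01", 0L)
  expect_true(all(tr$end <= len[tr$chrom]))
})

test_that("parse_region handles CHR:START-END[:LABEL]", {
  r <- parse_region("2:136545000-136594750:MCM6", require_label = TRUE)
  expect_identical(r$chrom, "2")
  expect_equal(r$start, 136545000)
  expect_equal(r$end, 136594750)
  expect_identical(r$label, "MCM6")
  expect_error(parse_region("2:100"), class = "ap_usage_error")
  expect_error(parse_region("2:200-100"), class = "ap_validation_error")
  expect_error(parse_region("2:100-200", require_label = TRUE),
               class = "ap_usage_error")
})

test_that("render_lap draws one row per chromosome with two bands", {
  skip_if_not_installed("xml2")
  cfg <- sim_config(n_samples = 1, genome = small_genome(5), seed = 8)
  msp <- tracts_to_msp(simulate_cohort(cfg), cfg)
  tracts <- rbind(windows_to_tracts(msp, "S01", 0L),
                  windows_to_tracts(msp, "S01", 1L))
  pal <- build_palette(cfg$codebook)
  len <- chromosome_lengths(msp)
  path <- tempfile(fileext = ".svg")
  render_lap(tracts, pal, len, path, format = "svg")
  expect_identical(svg_count_class(path, "chrom-label"), 5L)
  expect_identical(svg_count_class(path, "band-bg"), 10L)
  expect_identical(svg_count_class(path, "legend-entry"), 3L)

  # highlight marker is drawn; absent chromosome errors
  render_lap(tracts, pal, len, path, format = "svg",
             highlight = "2:1000000-2000000:GENE")
  expect_gt(svg_count_class(path, "highlight"), 0L)
  expect_identical(svg_count_class(path, "highlight-label"), 1L)
  expect_error(
    render_lap(tracts, pal, len, path, format = "svg",
               highlight = "99:1-2:X"),
    class = "ap_validation_error")
  expect_error(render_lap(tracts, pal, len, path, format = "tiff"))
  expect_error(render_lap(tracts[tracts$haplotype == 0, ], pal, len, path,
                          format = "svg"),
               class = "ap_validation_error")
})

test_that("uncovered chromosome regions stay background-colored", {
  skip_if_not_installed("xml2")
  # windows cover only the first half of chr1
  msp <- read_msp(raw_msp_file(
    "#Subpopulation order/codes:\tA=0\tB=1",
    "#chm\tspos\tepos\tsgpos\tegpos\tn snps\tS1.0\tS1.1",
    "1\t0\t5000000\t0\t5\t50\t0\t1"))
  tracts <- rbind(windows_to_tracts(msp, "S1", 0L),
                  windows_to_tracts(msp, "S1", 1L))
  pal <- build_palette(msp$codebook)
  path <- tempfile(fileext = ".svg")
  render_lap(tracts, pal, len = c("1" = 1e7), path, format = "svg")
  doc <- xml2::read_xml(path)
  bg <- xml2::xml_find_first(doc, "//*[@class='band-bg']")
  tr <- xml2::xml_find_first(doc, "//*[@class='tract']")
  bg_w <- as.numeric(xml2::xml_attr(bg, "width"))
  tr_w <- as.numeric(xml2::xml_attr(tr, "width"))
  expect_equal(tr_w / bg_w, 0.5, tolerance = 0.01)
  expect_identical(xml2::xml_attr(bg, "fill"), "#FFFFFF")
})

test_that("tract x-extents in the SVG are proportional to coordinates", {
  skip_if_not_installed("xml2")
  cfg <- sim_config(n_samples = 1, genome = c("1" = 2e7), seed = 12)
  tracts <- rbind(simulate_haplotype(cfg, "1", 1, 0),
                  simulate_haplotype(cfg, "1", 1, 1))
  pal <- build_palette(cfg$codebook)
  path <- tempfile(fileext = ".svg")
  render_lap(tracts, pal, c("1" = 2e7), path, format = "svg")
  doc <- xml2::read_xml(path)
  rects <- xml2::xml_find_all(doc, "//*[@class='tract']")
  widths <- as.numeric(xml2::xml_attr(rects, "width"))
  bg <- xml2::xml_find_first(doc, "//*[@class='band-bg']")
  bg_w <- as.numeric(xml2::xml_attr(bg, "width"))
  # both bands fully covered: per-band tract widths sum to the band width
  expect_equal(sum(widths) / 2, bg_w, tolerance = 1e-3)
})
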