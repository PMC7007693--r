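test_that("grid window count and index bijection hold", {
  g <- tiny_grid(c(chr1 = 5000, chr2 = 2500))
  expect_equal(g$window_count, 5 + 3)  # ceil(2500/1000) keeps the partial
  expect_equal(unname(g$offset_index), c(0L, 5L))

  withr::with_seed(11, {
    for (i in 1:50) {
      ch <- sample(g$chrom_names, 1)
      pos <- sample.int(g$chrom_lengths[match(ch, g$chrom_names)], 1) - 1
      idx <- window_of(g, ch, pos)
      loc <- window_location(g, idx)
      expect_identical(loc$chrom, ch)
      expect_true(pos >= loc$start && pos < loc$end)
    }
  })
  # every global index maps back consistently
  all_loc <- window_location(g, 0:(g$window_count - 1))
  expect_equal(window_of(g, all_loc$chrom, all_loc$start),
               0:(g$window_count - 1))
  expect_error(window_of(g, "chrX", 0), "unknown chromosome")
  expect_error(window_location(g, g$window_count), "out of range")
})

test_that("bin_signal computes length-weighted means", {
  g <- tiny_grid()
  full <- bin_signal(data.frame(chrom = "chr1", start = 1000, end = 2000,
                                value = 2), g)
  expect_equal(full$values[2], 2.0)
  half <- bin_signal(data.frame(chrom = "chr1", start = 0, end = 500,
                                value = 4), g)
  expect_equal(half$values[1], 2.0)
  expect_equal(sum(half$values[-1]), 0)
  empty <- bin_signal(data.frame(chrom = character(), start = numeric(),
                                 end = numeric(), value = numeric()), g)
  expect_equal(empty$values, numeric(g$window_count))

  expect_error(bin_signal(data.frame(chrom = "chrX", start = 0, end = 10,
                                     value = 1), g), "unknown chromosome")
  expect_error(bin_signal(data.frame(chrom = "chr1", start = 0, end = 10,
                                     value = -1), g), "negative")
})

test_that("bin_signal conserves signal mass", {
  g <- tiny_grid(c(chr1 = 5000, chr2 = 2500))
  for (seed in 1:3) {
    iv <- withr::with_seed(seed, {
      n <- 40
      ch <- sample(g$chrom_names, n, TRUE)
      len <- g$chrom_lengths[match(ch, g$chrom_names)]
      st <- floor(runif(n, 0, len - 10))
      data.frame(chrom = ch, start = st,
                 end = pmin(st + ceiling(runif(n, 1, 2500)), len),
                 value = rexp(n))
    })
    tr <- bin_signal(iv, g)
    span <- window_location(g, 0:(g$window_count - 1))
    expect_equal(sum(tr$values * (span$end - span$start)),
                 sum(iv$value * (iv$end - iv$start)), tolerance = 1e-9)
  }
})

test_that("load_peaks maps summits, not spans, to windows", {
  g <- tiny_grid()
  cis <- load_peaks(data.frame(chrom = "chr1", start = 1500, end = 1700), g)
  expect_identical(cis$windows, 1L)          # summit at 1600
  expect_equal(cis$summits$pos, 1600)

  # a peak spanning a boundary occupies only the summit's window
  span <- load_peaks(data.frame(chrom = "chr1", start = 900, end = 1500), g)
  expect_identical(span$windows, 1L)         # summit at 1200

  # explicit summit offset wins over the midpoint
  off <- load_peaks(data.frame(chrom = "chr1", start = 900, end = 1500,
                               summit_offset = 10), g)
  expect_identical(off$windows, 0L)

  two <- load_peaks(data.frame(chrom = "chr1", start = c(1100, 1800),
                               end = c(1300, 1900)), g)
  expect_identical(two$windows, 1L)          # both summits in window 1

  # idempotent under record duplication
  dup <- load_peaks(data.frame(chrom = rep("chr1", 4),
                               start = rep(c(1100, 1800), 2),
                               end = rep(c(1300, 1900), 2)), g)
  expect_identical(dup$windows, two$windows)

  expect_error(load_peaks(data.frame(chrom = "chr1", start = 100,
                                     end = 50), g), "line 1")
  expect_error(load_peaks(data.frame(chrom = "chr1", start = 100, end = 200,
                                     summit_offset = 150), g),
               "summit offset")
})

test_that("gene annotation enforces one TSS per gene and BED conventions", {
  expect_error(gene_annotation(c("a", "a"), c("chr1", "chr1"), c(0, 10),
                               c("+", "+")), "duplicate")
  g <- tiny_grid()
  expect_error(gene_annotation("a", "chr1", 6000, "+", grid = g),
               "beyond chromosome end")

  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t900\tgplus\t0\t+",
               "chr1\t2000\t2600\tgminus\t0\t-"), bed)
  ann <- read_gene_annotation(bed, grid = g)
  expect_equal(ann$tss[ann$gene_id == "gplus"], 100)
  expect_equal(ann$tss[ann$gene_id == "gminus"], 2599)
})

test_that("store round-trips losslessly and detects corruption", {
  store <- random_store(42)
  store$rp_cache <- compute_rp_matrix(store)
  path <- tempfile(fileext = ".trisd")
  save_store(store, path)
  back <- load_store(path)
  expect_identical(back, store)  # bitwise, including RP arrays

  expect_error(load_store(tempfile()), "not found")

  # flip one byte in the array section
  raw <- readBin(path, "raw", file.size(path))
  at <- length(raw) - 2000L
  raw[at] <- as.raw(bitwAnd(bitwXor(as.integer(raw[at]), 255L), 255L))
  writeBin(raw, path)
  expect_error(load_store(path), "integrity|corrupt|read")
})
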