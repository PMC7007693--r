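test_that("one-sided rank-sum matches exact enumeration", {
  expect_equal(wilcoxon_one_sided(c(3, 4, 5), c(0, 1, 2)), 1 / 20)

  withr::with_seed(41, {
    for (i in 1:5) {
      q <- rnorm(sample(3:6, 1))
      b <- rnorm(sample(4:8, 1))
      expect_equal(wilcoxon_one_sided(q, b),
                   oracle_wilcoxon_greater(q, b), tolerance = 1e-12)
    }
  })

  # swapping the samples reflects the null: exact tails from enumeration
  q <- c(0.2, 1.7, 2.1, 3.3); b <- c(-1, 0.5, 1.1)
  expect_equal(wilcoxon_one_sided(q, b), oracle_wilcoxon_greater(q, b))
  expect_equal(wilcoxon_one_sided(b, q), oracle_wilcoxon_greater(b, q))

  # identical constant samples carry no evidence of a positive shift
  expect_gte(wilcoxon_one_sided(rep(2, 5), rep(2, 9)), 0.5)
})

test_that("rank-sum p-values are uniform under the null", {
  withr::with_seed(77, {
    ps <- replicate(2000, {
      x <- rnorm(100)
      wilcoxon_one_sided(x[1:50], x[51:100])
    })
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("Cauchy combination satisfies its identities", {
  expect_equal(cauchy_combine(c(0.5, 0.5, 0.5)), 0.5)
  for (p in c(0.001, 0.01, 0.2, 0.5, 0.77, 0.999))
    expect_equal(cauchy_combine(c(p, p)), p, tolerance = 1e-12)

  # direct numeric evaluation of t and its inversion
  p <- c(0.01, 0.5, 0.5)
  t_direct <- sum(tan((0.5 - p) * pi)) / 3
  expect_equal(cauchy_combine(p), 0.5 - atan(t_direct) / pi)
  expect_equal(cauchy_combine(p), 0.0299214, tolerance = 1e-4)

  expect_error(cauchy_combine(numeric()), "no p-values")
  # extreme inputs stay in (0, 1) via clamping
  expect_gt(cauchy_combine(c(0, 1e-20)), 0)
  expect_lt(cauchy_combine(c(1, 1)), 1)
})

channel_fixture <- function() {
  data.frame(
    cistrome_id = sprintf("c%02d", 1:4),
    tr_name = c("TRA", "TRA", "TRB", "TRC"),
    p_peak_rp = c(0.5, 0.001, 0.5, NA),
    p_isd_dnase = c(0.5, 0.001, 0.5, 0.3),
    p_isd_h3k27ac = c(0.5, 0.001, 0.5, 0.2),
    stringsAsFactors = FALSE)
}

test_that("channel combination ranks, skips and summarizes per TR", {
  ch <- channel_fixture()
  expect_warning(tab <- combine_channels(ch, mode = "chipseq"),
                 "missing evidence channel")
  expect_equal(tab$cistrome_id[1], "c02")
  expect_equal(tab$rank, 1:3)
  expect_equal(tab$p_combined[tab$cistrome_id == "c01"], 0.5)
  summ <- attr(tab, "tr_summary")
  expect_equal(summ$tr_name[1], "TRA")
  expect_equal(summ$p_combined[summ$tr_name == "TRA"],
               min(tab$p_combined[tab$tr_name == "TRA"]))

  # motif mode uses only the deletion channels, so the NA peak channel
  # is irrelevant and changing peak p-values changes nothing
  m1 <- combine_channels(ch, mode = "motif")
  ch2 <- ch; ch2$p_peak_rp <- 0.9999
  m2 <- combine_channels(ch2, mode = "motif")
  expect_equal(m1$p_combined, m2$p_combined)
  expect_equal(nrow(m1), 4)

  # input order does not change the ranking
  perm <- combine_channels(ch[c(3, 1, 4, 2), ], mode = "motif")
  expect_equal(perm$cistrome_id, m1$cistrome_id)
})

test_that("promoter-count baseline counts a closed interval", {
  grid <- tiny_grid(c(chr1 = 1e6))
  genes <- gene_annotation(c("q1", "b1", "b2"), rep("chr1", 3),
                           c(50000, 200000, 300000), rep("+", 3))
  sets <- structure(list(query = "q1", background = c("b1", "b2"),
                         seed = 0), class = "gene_set_pair")

  none <- cistrome("none", "t", integer(), grid,
                   summits = data.frame(chrom = character(),
                                        pos = numeric()))
  expect_gte(baseline_promoter_count(none, genes, sets)$p, 0.5)

  # boundary: summit at tss + 5000 is in, tss + 5001 is out
  edge <- cistrome("edge", "t", integer(), grid,
                   summits = data.frame(chrom = "chr1",
                                        pos = c(55000, 55001)))
  counts <- baseline_promoter_count(edge, genes, sets)$counts
  expect_equal(unname(counts["q1"]), 1)

  # distinct counts give the exact enumerated tail
  qheavy <- cistrome("q", "t", integer(), grid,
                     summits = data.frame(chrom = "chr1",
                                          pos = c(50000, 50100, 200000)))
  res <- baseline_promoter_count(qheavy, genes, sets)
  expect_equal(unname(res$counts), c(2, 1, 0))
  expect_equal(res$p, oracle_wilcoxon_greater(2, c(1, 0)))
})

test_that("direct/indirect split partitions the occupied windows", {
  grid <- tiny_grid(c(chr1 = 1e6))
  cis <- cistrome("c", "t", c(5L, 10L, 20L), grid,
                  summits = data.frame(chrom = "chr1",
                                       pos = c(5500, 10500, 20500)))
  hits <- structure(list(motif_id = "m", tr_name = "t", scan_window = 100,
                         threshold_percentile = 99, threshold = 1,
                         hits = c(10L, 20L, 99L),
                         hit_pos = data.frame(chrom = "chr1",
                                              pos = c(10550, 20550, 99550))),
                    class = "motif_hits")
  sp <- split_direct_indirect(cis, hits, grid)
  expect_identical(sp$direct$windows, c(10L, 20L))
  expect_identical(sp$indirect$windows, 5L)
  expect_identical(sort(c(sp$direct$windows, sp$indirect$windows)),
                   cis$windows)
  expect_equal(sp$direct$summits$pos, c(10500, 20500))

  # superset of hits leaves nothing indirect; disjoint leaves nothing direct
  all_hits <- hits; all_hits$hits <- cis$windows
  expect_length(split_direct_indirect(cis, all_hits, grid)$indirect$windows,
                0)
  no_hits <- hits; no_hits$hits <- integer()
  expect_warning(sp0 <- split_direct_indirect(cis, no_hits, grid), "empty")
  expect_identical(sp0$indirect$windows, cis$windows)
})
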