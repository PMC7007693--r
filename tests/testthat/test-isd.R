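# A one-gene, one-track scene where every quantity is hand-computable.
isd_scene <- function(seed = 17) {
  store <- random_store(seed, n_windows = 300, n_tracks = 2, n_genes = 10)
  rp <- compute_rp_matrix(store)
  list(store = store, rp = rp)
}

test_that("deleted_rp subtracts exactly the occupied contributions", {
  sc <- isd_scene()
  gene <- sc$store$genes[4, , drop = FALSE]
  track <- sc$store$tracks[[1]]
  grid <- sc$store$grid
  r <- chrom_rp(track, gene, grid)

  far <- cistrome("far", "t", integer(), grid)
  expect_equal(deleted_rp(track, far, gene, grid), r)

  everything <- cistrome("all", "t", 0:(grid$window_count - 1L), grid)
  expect_equal(deleted_rp(track, everything, gene, grid), 0)

  w10 <- window_of(grid, gene$chrom, gene$tss) + 3L
  one <- cistrome("one", "t", w10, grid)
  mid <- window_location(grid, w10)
  midpt <- (mid$start + mid$end) / 2
  expect_equal(deleted_rp(track, one, gene, grid),
               r - decay_weight(abs(midpt - gene$tss)) *
                 track$values[w10 + 1L])
})

test_that("renormalization reuses the original offsets", {
  expect_equal(renormalize_deleted(exp(1) - 1, 0.5), 0.5)  # no deletion
  expect_equal(renormalize_deleted(0, 0.5), -0.5)          # full deletion
  # offsets do not depend on which cistrome was deleted
  expect_equal(renormalize_deleted(c(3, 3), 1.2),
               rep(log1p(3) - 1.2, 2))
})

test_that("delta_rp matches direct algebra and scales with alpha", {
  sc <- isd_scene()
  gene_ids <- sc$store$genes$gene_id
  model <- structure(list(assay_kind = "dnase",
                          selected_profiles = "t01",
                          alpha = c(t01 = 1), intercept = 0),
                     class = "chrom_model")

  empty <- cistrome("none", "t", integer(), sc$store$grid)
  d0 <- delta_rp(model, sc$store, empty, gene_ids, rp = sc$rp)
  expect_equal(unname(d0$delta_rp), numeric(length(gene_ids)))
  expect_equal(d0$deleted_window_count, 0L)

  gene <- sc$store$genes[6, , drop = FALSE]
  w <- window_of(sc$store$grid, gene$chrom, gene$tss) - 2L
  one <- cistrome("one", "t", w, sc$store$grid)
  d1 <- delta_rp(model, sc$store, one, gene_ids, rp = sc$rp)
  r <- sc$rp$raw[gene$gene_id, "t01"]
  loc <- window_location(sc$store$grid, w)
  wgt <- decay_weight(abs((loc$start + loc$end) / 2 - gene$tss))
  s <- sc$store$tracks[["t01"]]$values[w + 1L]
  expect_equal(d1$delta_rp[[gene$gene_id]],
               log1p(r) - log1p(r - wgt * s))

  model2 <- model; model2$alpha <- c(t01 = 2)
  d2 <- delta_rp(model2, sc$store, one, gene_ids, rp = sc$rp)
  expect_equal(d2$delta_rp, 2 * d1$delta_rp)
})

test_that("delta_rp agrees with physically zeroing the signal", {
  sc <- isd_scene(23)
  gene_ids <- sc$store$genes$gene_id
  model <- structure(list(assay_kind = "dnase",
                          selected_profiles = c("t01", "t02"),
                          alpha = c(t01 = 0.8, t02 = -0.3), intercept = 0),
                     class = "chrom_model")
  cis <- sc$store$cistromes[[1]]
  d <- delta_rp(model, sc$store, cis, gene_ids, rp = sc$rp)
  for (k in seq_along(gene_ids)) {
    gene <- sc$store$genes[k, , drop = FALSE]
    naive <- 0
    for (j in names(model$alpha)) {
      zeroed <- sc$store$tracks[[j]]
      zeroed$values[cis$windows + 1L] <- 0
      naive <- naive + model$alpha[[j]] *
        (log1p(chrom_rp(sc$store$tracks[[j]], gene, sc$store$grid)) -
           log1p(chrom_rp(zeroed, gene, sc$store$grid)))
    }
    expect_equal(d$delta_rp[[k]], naive, tolerance = 1e-9)
  }
})

test_that("deletion effects are non-negative and grow with support", {
  sc <- isd_scene(29)
  gene_ids <- sc$store$genes$gene_id
  model <- structure(list(assay_kind = "dnase",
                          selected_profiles = c("t01", "t02"),
                          alpha = c(t01 = 0.6, t02 = 0.4), intercept = 0),
                     class = "chrom_model")
  grid <- sc$store$grid
  withr::with_seed(2, {
    wa <- sample.int(grid$window_count, 15) - 1L
    wb <- setdiff(sample.int(grid$window_count, 15) - 1L, wa)
  })
  a <- cistrome("a", "t", wa, grid)
  b <- cistrome("b", "t", wb, grid)
  u <- cistrome("u", "t", c(wa, wb), grid)
  da <- delta_rp(model, sc$store, a, gene_ids, rp = sc$rp)$delta_rp
  db <- delta_rp(model, sc$store, b, gene_ids, rp = sc$rp)$delta_rp
  du <- delta_rp(model, sc$store, u, gene_ids, rp = sc$rp)$delta_rp
  expect_true(all(da >= 0 & db >= 0 & du >= 0))
  expect_true(all(du >= da - 1e-12 & du >= db - 1e-12))

  # genes with no occupied window in range are untouched, exactly
  gene <- sc$store$genes[1, , drop = FALSE]
  ctx_win <- window_of(grid, gene$chrom, gene$tss)
  faraway <- cistrome("f", "t",
                      setdiff(0:(grid$window_count - 1L),
                              max(0, ctx_win - 150):(ctx_win + 150)),
                      grid)
  df <- delta_rp(model, sc$store, faraway, gene_ids, rp = sc$rp)
  expect_identical(df$delta_rp[[gene$gene_id]], 0)
})
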