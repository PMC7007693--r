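make_universe <- function(n, seed = 1) {
  withr::with_seed(seed, data.frame(
    gene_id = sprintf("u%05d", seq_len(n)),
    covariate = rnorm(n), stringsAsFactors = FALSE))
}

test_that("background selection returns the right size, disjoint and
           reproducible", {
  uni <- make_universe(20000)
  query <- uni$gene_id[sample.int(20000, 500)]
  sets <- select_background(query, uni, seed = 3)
  expect_length(sets$background, 3000)
  expect_length(intersect(sets$query, sets$background), 0)
  expect_identical(sets$background,
                   select_background(query, uni, seed = 3)$background)
  expect_false(identical(sets$background,
                         select_background(query, uni, seed = 4)$background))

  # small pools fall back to everything, with a warning
  small <- make_universe(100)
  expect_warning(all_bg <- select_background(small$gene_id[1:10], small),
                 "using all")
  expect_length(all_bg$background, 90)
})

test_that("background sampling respects universe stratum proportions", {
  uni <- make_universe(20000, seed = 6)
  sets <- select_background(character(), uni, seed = 1)
  br <- unique(quantile(uni$covariate, seq(0, 1, 0.1)))
  stratum <- function(x) findInterval(x, br, rightmost.closed = TRUE,
                                      all.inside = TRUE)
  got <- table(stratum(uni$covariate[uni$gene_id %in% sets$background]))
  expected <- table(stratum(uni$covariate)) * 3000 / 20000
  expect_true(all(abs(got - expected) <= 1))
})

# RP-like feature set with one planted informative column.
planted_features <- function(seed, n_genes = 300, n_query = 50,
                             n_noise = 49, snr = 3) {
  withr::with_seed(seed, {
    ids <- sprintf("g%04d", seq_len(n_genes))
    query <- sample(ids, n_query)
    X <- matrix(rnorm(n_genes * (n_noise + 1)), n_genes,
                dimnames = list(ids, c("informative",
                                       sprintf("noise%02d",
                                               seq_len(n_noise)))))
    X[, 1] <- X[, 1] + snr * (ids %in% query)
    list(X = X, sets = structure(list(query = query,
                                      background = setdiff(ids, query),
                                      seed = seed),
                                 class = "gene_set_pair"))
  })
}

test_that("the L1 path finds the informative profile under the cap", {
  hits <- 0L
  for (seed in 1:5) {
    pf <- planted_features(seed)
    sel <- fit_l1_path(pf$X, pf$sets)
    expect_lte(sel$n_selected, 10)
    expect_gte(sel$n_selected, 1)
    if ("informative" %in% sel$selected_profiles) hits <- hits + 1L
  }
  expect_gte(hits, 5L)
})

test_that("L1 selected count is non-increasing in penalty strength", {
  pf <- planted_features(2)
  std <- trisd:::standardize_cols(pf$X)
  y <- as.integer(rownames(pf$X) %in% pf$sets$query)
  counts <- vapply(c(1e-4, 1e-3, 1e-2, 0.05, 0.2, 1),
                   function(l) length(trisd:::l1_nonzero(std$X, y, l)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("duplicating a profile cannot inflate its influence", {
  # L1 may split weight across an exactly duplicated column, but the
  # duplicate adds no information: the cap still holds, the pair is
  # found, and the fitted predictions are unchanged by the duplication.
  for (seed in 1:3) {
    pf <- planted_features(seed, n_noise = 20)
    X <- cbind(pf$X, informative2 = pf$X[, "informative"])
    sel <- fit_l1_path(X, pf$sets)
    expect_lte(sel$n_selected, 10)
    expect_true(any(c("informative", "informative2") %in%
                      sel$selected_profiles))

    dup <- fit_final_model(X, pf$sets,
                           c("informative", "informative2"))
    single <- fit_final_model(X, pf$sets, "informative")
    expect_equal(model_rp(dup, X), model_rp(single, X),
                 tolerance = 1e-3)
    expect_equal(sum(dup$alpha), single$alpha[["informative"]],
                 tolerance = 1e-3)
  }
})

test_that("final model handles separable features and label permutations", {
  ids <- sprintf("g%03d", 1:200)
  sets <- structure(list(query = ids[1:40], background = ids[41:200],
                         seed = 0), class = "gene_set_pair")
  X <- matrix(c(rnorm(40, 5), rnorm(160, -5)), 200,
              dimnames = list(ids, "sep"))
  m <- fit_final_model(X, sets, "sep")
  expect_gt(m$alpha[["sep"]], 0)
  expect_equal(m$auc, 1)
  scores <- model_rp(m, X)
  expect_gt(min(scores[sets$query]), max(scores[sets$background]))

  # negating the feature flips the coefficient, not the gene ordering
  Xn <- -X
  mn <- fit_final_model(Xn, sets, "sep")
  expect_lt(mn$alpha[["sep"]], 0)
  expect_equal(order(model_rp(mn, Xn)), order(scores))

  # permuted labels carry no signal
  withr::with_seed(13, {
    big_ids <- sprintf("b%04d", 1:3000)
    Xb <- matrix(rnorm(3000), 3000, dimnames = list(big_ids, "f"))
    aucs <- replicate(20, {
      q <- sample(big_ids, 500)
      s <- structure(list(query = q, background = setdiff(big_ids, q),
                          seed = 0), class = "gene_set_pair")
      fit_final_model(Xb, s, "f")$auc
    })
  })
  expect_true(all(abs(aucs - 0.5) < 0.05))
})

test_that("model AUC equals the brute-force pair count", {
  sets <- structure(list(query = c("q1", "q2"),
                         background = c("b1", "b2"), seed = 0),
                    class = "gene_set_pair")
  expect_equal(model_auc(c(q1 = 3, q2 = 2, b1 = 1, b2 = 0), sets), 1)
  expect_equal(model_auc(c(q1 = 0, q2 = 1, b1 = 2, b2 = 3), sets), 0)

  withr::with_seed(31, {
    for (i in 1:5) {
      nq <- sample(3:50, 1); nb <- sample(3:50, 1)
      # integer scores force ties through the 1/2 convention
      sc <- c(sample(0:9, nq, TRUE), sample(0:9, nb, TRUE))
      names(sc) <- c(sprintf("q%02d", 1:nq), sprintf("b%02d", 1:nb))
      s <- structure(list(query = names(sc)[1:nq],
                          background = names(sc)[-(1:nq)], seed = 0),
                     class = "gene_set_pair")
      pairs <- outer(sc[1:nq], sc[-(1:nq)],
                     function(a, b) (a > b) + 0.5 * (a == b))
      expect_equal(model_auc(sc, s), mean(pairs))
    }
  })
})
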