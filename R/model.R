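#' Evaluate an expression with a private RNG state
#'
#' Seeds the generator locally and restores the caller's `.Random.seed`,
#' so stochastic steps are reproducible without disturbing the session.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

#' Stratified background gene selection
#'
#' Samples background genes from the non-query universe so that the sample's
#' distribution over promoter-activity strata matches the universe's:
#' the covariate is cut into quantile bins over the whole universe, the
#' requested size is allocated to strata by largest-remainder proportional
#' rounding, and genes are drawn without replacement within each stratum.
#' This matches the query's chromatin context in aggregate without any
#' gene-ontology filtering.
#'
#' @param query character vector of query gene ids.
#' @param universe data.frame with columns `gene_id` and `covariate`
#'   (finite per-gene promoter activity), or a [compendium_store()].
#' @param n background size (default 3000). If fewer non-query genes
#'   exist, all are returned with a warning.
#' @param bins number of covariate quantile strata (default 10).
#' @param seed integer seed; the same seed always yields the same set.
#' @return list of class `gene_set_pair`: `query`, `background`, `seed`.
#' @export
select_background <- function(query, universe, n = 3000L, bins = 10L,
                              seed = 0L) {
  if (inherits(universe, "compendium_store"))
    universe <- data.frame(gene_id = universe$genes$gene_id,
                           covariate = unname(universe$covariates),
                           stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "covariate") %in% names(universe)),
            all(is.finite(universe$covariate)))
  query <- unique(as.character(query))
  if (nrow(universe) < length(query))
    stop("universe smaller than the query set")
  pool <- universe[!(universe$gene_id %in% query), , drop = FALSE]
  if (nrow(pool) == 0) stop("no non-query genes to sample from")
  if (nrow(pool) <= n) {
    if (nrow(pool) < n)
      warning("only ", nrow(pool), " non-query genes available; ",
              "using all of them as background")
    return(structure(list(query = query, background = pool$gene_id,
                          seed = as.integer(seed)),
                     class = "gene_set_pair"))
  }
  br <- unique(stats::quantile(universe$covariate,
                               probs = seq(0, 1, length.out = bins + 1)))
  stratum_of <- function(x)
    findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  uni_str <- stratum_of(universe$covariate)
  pool_str <- stratum_of(pool$covariate)
  levels <- sort(unique(uni_str))
  want <- n * tabulate(uni_str, max(levels))[levels] / nrow(universe)
  alloc <- floor(want)
  rem <- n - sum(alloc)
  if (rem > 0) {
    extra <- order(want - alloc, decreasing = TRUE)[seq_len(rem)]
    alloc[extra] <- alloc[extra] + 1
  }
  # repair: strata whose pool is too small spill into the others
  avail <- tabulate(match(pool_str, levels), length(levels))
  short <- pmax(alloc - avail, 0)
  alloc <- pmin(alloc, avail)
  deficit <- sum(short)
  while (deficit > 0) {
    room <- which(avail - alloc > 0)
    take <- room[order(avail[room] - alloc[room],
                       decreasing = TRUE)][1]
    alloc[take] <- alloc[take] + 1
    deficit <- deficit - 1
  }
  background <- with_seed(seed, {
    unlist(lapply(seq_along(levels), function(s) {
      ids <- pool$gene_id[pool_str == levels[s]]
      if (alloc[s] == 0) character() else ids[sample.int(length(ids),
                                                         alloc[s])]
    }), use.names = FALSE)
  })
  structure(list(query = query, background = sort(background),
                 seed = as.integer(seed)),
            class = "gene_set_pair")
}

# Standardize feature columns over the fitted genes; constant columns get
# unit scale so they drop out of the fit without dividing by zero.
standardize_cols <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(X = sweep(sweep(X, 2, mu), 2, sd, `/`), mean = mu, sd = sd)
}

l1_nonzero <- function(X, y, lambda) {
  # short warm-start path ending at the requested penalty
  lam_seq <- exp(seq(log(lambda * 32), log(lambda), length.out = 6))
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                        lambda = lam_seq, standardize = FALSE,
                        thresh = 1e-9)
  b <- as.numeric(stats::coef(fit, s = lambda, exact = FALSE))[-1]
  which(b != 0)
}

#' L1 penalty search for chromatin-profile selection
#'
#' Binary search over the L1 penalty of a logistic regression of
#' query-membership on normalized chrom-RP columns, returning the weakest
#' penalty whose number of nonzero coefficients is at most `max_profiles`
#' (and at least 1). Features are standardized internally so the penalty is
#' comparable across profiles. Bounds are auto-expanded; at most 50
#' bisection steps.
#'
#' @param rp_norm genes-by-profiles matrix of normalized chrom-RPs, rows
#'   named by gene id (query and background genes).
#' @param sets a `gene_set_pair` from [select_background()].
#' @param max_profiles cap on selected profiles (default 10).
#' @return list: `penalty` (the chosen lambda), `selected_profiles`,
#'   `n_selected`.
#' @export
fit_l1_path <- function(rp_norm, sets, max_profiles = 10L) {
  genes <- c(sets$query, sets$background)
  stopifnot(length(sets$query) > 0, length(sets$background) > 0,
            all(genes %in% rownames(rp_norm)), ncol(rp_norm) >= 1)
  X <- rp_norm[genes, , drop = FALSE]
  y <- as.integer(rownames(X) %in% sets$query)
  std <- standardize_cols(X)
  nz <- function(l) l1_nonzero(std$X, y, l)

  lo <- 1e-4  # weak penalty: typically selects too many
  hi <- 1     # strong penalty: typically selects none
  for (i in 1:20) {
    if (length(nz(lo)) > max_profiles) break
    lo <- lo / 4
    if (lo < 1e-12) break
  }
  sel_lo <- nz(lo)
  if (length(sel_lo) == 0) {
    # even a vanishing penalty keeps everything at zero
    stop("no informative profiles: the L1 path never selects a feature")
  }
  if (length(sel_lo) <= max_profiles) {
    return(list(penalty = lo,
                selected_profiles = colnames(X)[sel_lo],
                n_selected = length(sel_lo)))
  }
  for (i in 1:20) {
    k <- length(nz(hi))
    if (k >= 1 && k <= max_profiles) break
    if (k > max_profiles) hi <- hi * 4 else hi <- hi / 2
    if (hi > 1e6) stop("no penalty satisfies the profile cap")
  }
  sel_hi <- nz(hi)
  if (length(sel_hi) < 1 || length(sel_hi) > max_profiles)
    stop("no penalty yields between 1 and ", max_profiles,
         " selected profiles")
  # invariant: lo selects too many, hi selects within [1, max_profiles];
  # shrink toward the weakest admissible penalty
  for (i in 1:50) {
    mid <- sqrt(lo * hi)
    k <- length(nz(mid))
    if (k >= 1 && k <= max_profiles) hi <- mid else lo <- mid
    if (hi / lo < 1.01) break
  }
  sel <- nz(hi)
  list(penalty = hi, selected_profiles = colnames(X)[sel],
       n_selected = length(sel))
}

#' Final chromatin landscape model
#'
#' Refits an (essentially unpenalized) logistic regression of
#' query-membership on the selected profiles' normalized chrom-RPs, using a
#' very weak ridge (1e-6) so separable fits stay finite. Coefficients are
#' reported on the normalized-RP scale, so the model regulatory potential is
#' `model_RP_k = intercept + sum_j alpha_j R'_jk`.
#'
#' @param rp_norm genes-by-profiles normalized chrom-RP matrix (rows named
#'   by gene id).
#' @param sets a `gene_set_pair`.
#' @param selected_profiles profile ids to include (e.g. from
#'   [fit_l1_path()]).
#' @param assay_kind label carried through to reports.
#' @param penalty the L1 strength found by the path search (recorded only).
#' @return list of class `chrom_model`: `assay_kind`, `selected_profiles`,
#'   `alpha` (named coefficients on the normalized-RP scale), `intercept`,
#'   `penalty`, `auc` (query-vs-background ROC AUC of the model-RP).
#' @export
fit_final_model <- function(rp_norm, sets, selected_profiles,
                            assay_kind = "dnase", penalty = NA_real_) {
  stopifnot(length(selected_profiles) >= 1,
            all(selected_profiles %in% colnames(rp_norm)))
  genes <- c(sets$query, sets$background)
  X <- rp_norm[genes, selected_profiles, drop = FALSE]
  y <- as.integer(rownames(X) %in% sets$query)
  std <- standardize_cols(X)
  fit <- glmnet::glmnet(cbind(std$X, `..aux` = 0), y, family = "binomial",
                        alpha = 0, lambda = 1e-6, standardize = FALSE,
                        thresh = 1e-10, maxit = 1e6)
  b <- as.numeric(stats::coef(fit, s = 1e-6))
  if (!fit$jerr == 0)
    stop("final logistic fit did not converge (glmnet error ", fit$jerr, ")")
  b0 <- b[1]
  beta_std <- b[-1][seq_along(selected_profiles)]
  alpha <- beta_std / std$sd
  intercept <- b0 - sum(beta_std * std$mean / std$sd)
  model <- structure(list(assay_kind = assay_kind,
                          selected_profiles = selected_profiles,
                          alpha = stats::setNames(alpha,
                                                  selected_profiles),
                          intercept = intercept, penalty = penalty,
                          auc = NA_real_),
                     class = "chrom_model")
  scores <- model_rp(model, rp_norm)
  model$auc <- model_auc(scores, sets)
  model
}

#' Model regulatory potential
#'
#' The per-gene weighted sum of normalized chrom-RPs under a fitted
#' chromatin model.
#'
#' @param model a `chrom_model`.
#' @param rp_norm normalized chrom-RP matrix containing the model's
#'   profiles.
#' @return named numeric vector of model-RPs over the matrix's genes.
#' @export
model_rp <- function(model, rp_norm) {
  drop(rp_norm[, model$selected_profiles, drop = FALSE] %*%
         model$alpha) + model$intercept
}

#' Rank-based ROC AUC of a score on query vs background genes
#'
#' Mann-Whitney form: the probability a random query gene outscores a
#' random background gene, ties counting one half.
#'
#' @param scores named numeric vector covering both gene sets.
#' @param sets a `gene_set_pair`.
#' @return AUC in `[0, 1]`.
#' @export
model_auc <- function(scores, sets) {
  q <- scores[sets$query]
  b <- scores[sets$background]
  stopifnot(length(q) > 0, length(b) > 0, !anyNA(q), !anyNA(b))
  r <- rank(c(q, b), ties.method = "average")
  nq <- length(q)
  (sum(r[seq_len(nq)]) - nq * (nq + 1) / 2) / (nq * length(b))
}
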