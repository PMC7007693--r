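#' Specification for a synthetic chromatin compendium
#'
#' Desk-scale synthetic data with a planted true regulator, emulating the
#' structure the framework assumes: the true regulator's peaks sit close to
#' the query genes' TSSs and coincide with elevated chromatin signal in a
#' subset of "informative" profiles, while decoy cistromes and profiles are
#' unstructured noise.
#'
#' `effect_size` is the multiplicative signal enrichment at planted peaks.
#' At `effect_size = 1` no causal structure is planted at all: the "true"
#' cistrome is drawn exactly like a decoy, every profile is pure noise and
#' the query is a simple random gene sample — so the planted cistrome is
#' exchangeable with the decoys and its p-values are calibrated-null.
#'
#' @param n_chroms number of chromosomes (default 2).
#' @param chrom_length chromosome length in bp (default 5 Mb).
#' @param n_genes genes genome-wide (default 400), on a uniform grid with
#'   jitter.
#' @param n_profiles chromatin profiles per assay (default 12).
#' @param n_cistromes candidate cistromes including the planted one
#'   (default 30).
#' @param n_query query gene set size (default 60).
#' @param effect_size signal enrichment at planted peaks (default 5; must
#'   be >= 1).
#' @param noise_sd log-scale SD of the log-normal background signal
#'   (default 1).
#' @param peak_rate decoy peak probability per 1-kb window (default 0.01).
#' @param n_informative informative profiles per assay (default 3).
#' @param window_size grid window in bp (default 1000).
#' @param seed integer seed; generation is deterministic given the spec.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_chroms = 2L, chrom_length = 5e6, n_genes = 400L,
                         n_profiles = 12L, n_cistromes = 30L,
                         n_query = 60L, effect_size = 5, noise_sd = 1,
                         peak_rate = 0.01, n_informative = 3L,
                         window_size = 1000L, seed = 0L) {
  stopifnot(n_chroms >= 1, chrom_length >= 10 * window_size,
            n_genes >= 10, n_profiles >= 1, n_cistromes >= 1,
            n_query >= 1, n_query < n_genes, effect_size >= 1,
            noise_sd > 0, peak_rate > 0, peak_rate <= 1,
            n_informative >= 1, n_informative <= n_profiles)
  if (n_genes * window_size > n_chroms * chrom_length)
    stop("infeasible geometry: more genes than grid windows")
  structure(as.list(environment()), class = "fixture_spec")
}

#' Generate a synthetic compendium with a planted regulator
#'
#' See [fixture_spec()] for the generative model. The truth record names
#' the planted cistrome, its TR, the informative profiles per assay and
#' the query genes — sufficient to score rank-of-true-regulator for any
#' downstream ranking.
#'
#' @param spec a [fixture_spec()].
#' @param params an [rp_params()] (only `delta` is used, to place planted
#'   peaks within the high-weight neighborhood of query TSSs).
#' @return list of class `fixture_bundle`: `store`
#'   (a [compendium_store()] with RP cache), `query` (gene ids), `truth`
#'   (list: `planted_cistrome`, `tr_name`, `informative_profiles`,
#'   `query_genes`), `spec`.
#' @export
generate_fixtures <- function(spec = fixture_spec(), params = rp_params()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    chroms <- sprintf("chr%d", seq_len(spec$n_chroms))
    grid <- genome_grid(chroms, rep(spec$chrom_length, spec$n_chroms),
                        window_size = spec$window_size)
    total <- spec$n_chroms * spec$chrom_length
    spacing <- total / spec$n_genes
    gpos <- (seq_len(spec$n_genes) - 0.5) * spacing +
      stats::runif(spec$n_genes, -0.2, 0.2) * spacing
    ci <- pmin(floor(gpos / spec$chrom_length) + 1, spec$n_chroms)
    tss <- floor(gpos - (ci - 1) * spec$chrom_length)
    tss <- pmax(pmin(tss, spec$chrom_length - 1), 0)
    genes <- gene_annotation(sprintf("gene%04d", seq_len(spec$n_genes)),
                             chroms[ci], tss,
                             sample(c("+", "-"), spec$n_genes,
                                    replace = TRUE), grid = grid)

    planted <- sample.int(spec$n_cistromes, 1)
    tr_names <- sprintf("TR%02d", seq_len(spec$n_cistromes))
    cist_ids <- sprintf("cistrome%02d", seq_len(spec$n_cistromes))
    query <- sort(genes$gene_id[sample.int(spec$n_genes, spec$n_query)])

    rand_peaks <- function(n) {
      pos <- floor(stats::runif(n, 100, total - 100))
      data.frame(chrom = chroms[pos %/% spec$chrom_length + 1],
                 pos = pos %% spec$chrom_length,
                 stringsAsFactors = FALSE)
    }
    peak_df <- function(summits) {
      start <- pmax(summits$pos - 100, 0)
      data.frame(chrom = summits$chrom, start = start,
                 end = pmin(summits$pos + 100, spec$chrom_length),
                 summit_offset = summits$pos - start,
                 stringsAsFactors = FALSE)
    }

    cistromes <- vector("list", spec$n_cistromes)
    for (i in seq_len(spec$n_cistromes)) {
      if (i == planted && spec$effect_size > 1) {
        qi <- match(query, genes$gene_id)
        npk <- sample(1:3, length(qi), replace = TRUE)
        summits <- data.frame(
          chrom = rep(genes$chrom[qi], npk),
          pos = rep(genes$tss[qi], npk) +
            round(stats::runif(sum(npk), -params$delta, params$delta)),
          stringsAsFactors = FALSE)
        summits$pos <- pmax(pmin(summits$pos, spec$chrom_length - 101), 100)
        summits <- rbind(summits, rand_peaks(20))
      } else {
        npk <- max(1, stats::rpois(1, spec$peak_rate * grid$window_count))
        summits <- rand_peaks(npk)
      }
      cistromes[[i]] <- load_peaks(peak_df(summits), grid,
                                   cistrome_id = cist_ids[i],
                                   tr_name = tr_names[i])
    }

    informative <- lapply(c(dnase = "dnase", h3k27ac = "h3k27ac"),
                          function(a) sprintf("%s%02d", a,
                                              seq_len(spec$n_informative)))
    boxcar <- integer()
    if (spec$effect_size > 1) {
      w <- cistromes[[planted]]$windows
      boxcar <- unique(pmax(pmin(c(w - 1L, w, w + 1L),
                                 grid$window_count - 1L), 0L))
    }
    tracks <- list()
    for (assay in c("dnase", "h3k27ac")) {
      for (j in seq_len(spec$n_profiles)) {
        id <- sprintf("%s%02d", assay, j)
        v <- stats::rlnorm(grid$window_count, 0, spec$noise_sd)
        if (length(boxcar) && id %in% informative[[assay]])
          v[boxcar + 1L] <- v[boxcar + 1L] * spec$effect_size
        tracks[[id]] <- structure(list(profile_id = id,
                                       assay_kind = assay, values = v),
                                  class = "binned_track")
      }
    }

    # promoter activity: mean accessibility in TSS +/- 5 windows
    dn_ids <- grep("^dnase", names(tracks), value = TRUE)
    dn_mean <- rowMeans(vapply(tracks[dn_ids], `[[`,
                               numeric(grid$window_count), "values"))
    gi_win <- window_of(grid, genes$chrom, genes$tss)
    cov <- vapply(gi_win, function(w) {
      rng <- max(0, w - 5):min(grid$window_count - 1, w + 5)
      log1p(mean(dn_mean[rng + 1]))
    }, numeric(1))

    store <- compendium_store(grid, genes, tracks, cistromes,
                              covariates = cov)
    store$rp_cache <- compute_rp_matrix(store, params)
    truth <- list(planted_cistrome = cist_ids[planted],
                  tr_name = tr_names[planted],
                  informative_profiles =
                    if (spec$effect_size > 1) informative
                  else list(dnase = character(), h3k27ac = character()),
                  query_genes = query)
    structure(list(store = store, query = query, truth = truth,
                   spec = spec),
              class = "fixture_bundle")
  })
}

#' Generate genome FASTA with planted motif occurrences
#'
#' Uniform-random background sequence with the consensus embedded at the
#' planted cistrome's peak summits (random strand), so a motif scan can be
#' validated against known plant positions.
#'
#' @param fixture a `fixture_bundle` from [generate_fixtures()].
#' @param consensus DNA consensus string (length <= 100).
#' @param revcomp_fraction fraction of plants embedded on the minus strand.
#' @return list: `sequences` (named `DNAStringSet`), `plant_pos`
#'   (data.frame `chrom`, `pos`, `strand` of embedded occurrences).
#' @export
generate_sequences <- function(fixture, consensus,
                               revcomp_fraction = 0.5) {
  stopifnot(nchar(consensus) <= 100, nchar(consensus) >= 4)
  grid <- fixture$store$grid
  with_seed(fixture$spec$seed + 104729L, {
    seqs <- lapply(grid$chrom_lengths, function(len)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""))
    names(seqs) <- grid$chrom_names
    planted <- fixture$store$cistromes[[fixture$truth$planted_cistrome]]
    s <- planted$summits
    strand <- ifelse(stats::runif(nrow(s)) < revcomp_fraction, "-", "+")
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(consensus)))
    m <- nchar(consensus)
    for (i in seq_len(nrow(s))) {
      at <- min(max(s$pos[i], 0),
                grid$chrom_lengths[chrom_index(grid, s$chrom[i])] - m)
      ins <- if (strand[i] == "-") rc else consensus
      substr(seqs[[s$chrom[i]]], at + 1, at + m) <- ins
    }
    list(sequences = Biostrings::DNAStringSet(unlist(seqs)),
         plant_pos = data.frame(chrom = s$chrom, pos = s$pos,
                                strand = strand,
                                stringsAsFactors = FALSE))
  })
}

#' Write a fixture bundle as standard-format files
#'
#' Emits chrom.sizes, a gene-annotation TSV, per-track bedGraph, per-
#' cistrome BED (with summit offsets), the query gene list, the covariate
#' table and the truth record — everything [cmd_build()] needs, in plain
#' text.
#'
#' @param fixture a `fixture_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly; files as described above.
#' @export
write_fixture_bundle <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "tracks"), showWarnings = FALSE)
  dir.create(file.path(dir, "cistromes"), showWarnings = FALSE)
  store <- fixture$store
  grid <- store$grid
  utils::write.table(
    data.frame(grid$chrom_names,
               format(grid$chrom_lengths, scientific = FALSE, trim = TRUE)),
    file.path(dir, "chrom.sizes"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(store$genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = names(store$covariates),
               covariate = unname(store$covariates)),
    file.path(dir, "covariates.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  for (tr in store$tracks)
    write_bedgraph(tr, grid,
                   file.path(dir, "tracks",
                             sprintf("%s.bedgraph", tr$profile_id)))
  for (cs in store$cistromes) {
    df <- data.frame(cs$summits$chrom,
                     format(pmax(cs$summits$pos - 100, 0),
                            scientific = FALSE, trim = TRUE),
                     format(pmin(cs$summits$pos + 100,
                                 grid$chrom_lengths[chrom_index(
                                   grid, cs$summits$chrom)]),
                            scientific = FALSE, trim = TRUE),
                     cs$tr_name,
                     cs$summits$pos - pmax(cs$summits$pos - 100, 0))
    utils::write.table(df,
                       file.path(dir, "cistromes",
                                 sprintf("%s.bed", cs$cistrome_id)),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  writeLines(fixture$query, file.path(dir, "query_genes.txt"))
  truth <- fixture$truth
  utils::write.table(
    data.frame(key = c("planted_cistrome", "tr_name",
                       "informative_dnase", "informative_h3k27ac",
                       "query_genes"),
               value = c(truth$planted_cistrome, truth$tr_name,
                         paste(truth$informative_profiles$dnase,
                               collapse = ","),
                         paste(truth$informative_profiles$h3k27ac,
                               collapse = ","),
                         paste(truth$query_genes, collapse = ","))),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
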