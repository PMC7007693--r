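# Shared builders for small in-code fixtures.

tiny_grid <- function(lengths = c(chr1 = 5000, chr2 = 2500),
                      window_size = 1000) {
  genome_grid(names(lengths), unname(lengths), window_size = window_size)
}

# A gene centered mid-chromosome so the +/-L interval fits comfortably.
tiny_gene <- function(chrom = "chr1", tss = 500, id = "g1",
                      strand = "+") {
  gene_annotation(id, chrom, tss, strand)
}

# Random small store: one chromosome, random log-normal tracks, random
# cistromes; geometry small enough for brute-force oracles.
random_store <- function(seed, n_windows = 400, n_tracks = 3,
                         n_genes = 25, n_cistromes = 2,
                         window_size = 1000) {
  withr::with_seed(seed, {
    len <- n_windows * window_size
    grid <- genome_grid("chr1", len, window_size = window_size)
    genes <- gene_annotation(sprintf("g%03d", seq_len(n_genes)),
                             rep("chr1", n_genes),
                             sort(sample.int(len, n_genes) - 1),
                             sample(c("+", "-"), n_genes, TRUE))
    tracks <- lapply(seq_len(n_tracks), function(j)
      structure(list(profile_id = sprintf("t%02d", j),
                     assay_kind = "dnase",
                     values = rlnorm(n_windows)),
                class = "binned_track"))
    cistromes <- lapply(seq_len(n_cistromes), function(i)
      cistrome(sprintf("c%02d", i), sprintf("TR%02d", i),
               sample.int(n_windows, max(3, rbinom(1, n_windows, 0.05))) -
                 1L, grid))
    compendium_store(grid, genes, tracks, cistromes,
                     covariates = runif(n_genes))
  })
}

# Independent per-window oracle for the chrom-RP: loops over every window
# of the gene's chromosome and sums weight * signal for midpoints within
# [tss - L, tss + L]. Deliberately naive.
oracle_chrom_rp <- function(values, gene, grid, params) {
  ci <- match(gene$chrom, grid$chrom_names)
  total <- 0
  off <- grid$offset_index[ci]
  for (m in seq_len(grid$windows_per_chrom[ci])) {
    st <- (m - 1) * grid$window_size
    en <- min(st + grid$window_size, grid$chrom_lengths[ci])
    mid <- (st + en) / 2
    if (mid >= gene$tss - params$L && mid <= gene$tss + params$L) {
      d <- abs(mid - gene$tss) / params$L
      w <- 2 * exp(-params$mu * d) / (1 + exp(-params$mu * d))
      total <- total + w * values[off + m]
    }
  }
  total
}

# Exact one-sided rank-sum p-value by enumeration of all assignments.
oracle_wilcoxon_greater <- function(q, b) {
  all <- c(q, b)
  n <- length(q)
  obs <- sum(rank(all)[seq_len(n)])
  picks <- utils::combn(length(all), n)
  stat <- apply(picks, 2, function(ix) sum(rank(all)[ix]))
  mean(stat >= obs)
}
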