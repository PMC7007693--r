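#' Construct a gene annotation table
#'
#' One representative TSS per gene: duplicate gene identifiers are an error
#' (collapsing multi-isoform annotations to a single TSS is the caller's
#' job, so that each gene's regulatory potential is well defined).
#'
#' @param gene_id character, unique gene identifiers.
#' @param chrom chromosome per gene.
#' @param tss 0-based TSS position per gene.
#' @param strand "+" or "-" per gene.
#' @param grid optional [genome_grid()]; when given, chromosomes and TSS
#'   bounds are validated against it.
#' @return data.frame of class `gene_annotation` with the four columns.
#' @export
gene_annotation <- function(gene_id, chrom, tss, strand, grid = NULL) {
  stopifnot(length(gene_id) == length(chrom),
            length(gene_id) == length(tss),
            length(gene_id) == length(strand))
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id(s): ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  tss <- as.numeric(tss)
  if (any(tss < 0)) stop("negative TSS position")
  if (!is.null(grid)) {
    ci <- chrom_index(grid, chrom)
    bad <- tss >= grid$chrom_lengths[ci]
    if (any(bad))
      stop("TSS beyond chromosome end for: ",
           paste(gene_id[bad], collapse = ", "))
  }
  structure(data.frame(gene_id = as.character(gene_id),
                       chrom = as.character(chrom),
                       tss = tss, strand = as.character(strand),
                       stringsAsFactors = FALSE),
            class = c("gene_annotation", "data.frame"))
}

#' Read a gene annotation file
#'
#' Accepts either a four-column TSV (`gene_id`, `chrom`, `tss`, `strand`;
#' header optional) or BED6, in which case the TSS is the interval start for
#' `+` genes and `end - 1` for `-` genes (0-based, half-open convention).
#'
#' @param path file path.
#' @param format `"tsv"` or `"bed"`; `"auto"` picks BED when the file has
#'   six columns with numeric start/end.
#' @param grid optional [genome_grid()] for validation.
#' @return a [gene_annotation()] table.
#' @export
read_gene_annotation <- function(path, format = c("auto", "tsv", "bed"),
                                 grid = NULL) {
  format <- match.arg(format)
  first <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, nrows = 5)
  if (format == "auto") {
    format <- if (ncol(first) >= 6 && is.numeric(first[[2]]) &&
                  is.numeric(first[[3]])) "bed" else "tsv"
  }
  if (format == "bed") {
    x <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
    gene_annotation(gene_id = x[[4]], chrom = x[[1]],
                    tss = ifelse(x[[6]] == "+", x[[2]], x[[3]] - 1),
                    strand = x[[6]], grid = grid)
  } else {
    header <- identical(first[1, 1], "gene_id")
    x <- utils::read.table(path, sep = "\t", header = header,
                           stringsAsFactors = FALSE,
                           col.names = c("gene_id", "chrom", "tss", "strand"))
    gene_annotation(x$gene_id, x$chrom, x$tss, x$strand, grid = grid)
  }
}

#' Read a two-column chrom.sizes file into a genome grid
#'
#' @param path tab-separated file of (chromosome, length).
#' @param window_size window width in bp.
#' @return a [genome_grid()].
#' @export
read_chrom_sizes <- function(path, window_size = 1000L) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(x) < 2 || !is.numeric(x[[2]]))
    stop("chrom.sizes must have two columns: chromosome, length")
  genome_grid(x[[1]], x[[2]], window_size = window_size)
}
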