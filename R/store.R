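#' Assemble a compendium store
#'
#' The store bundles everything one analysis needs on a single genome grid:
#' gene annotation, binned chromatin signal tracks, regulator cistromes, a
#' per-gene promoter-activity covariate (used to stratify background gene
#' sampling) and, optionally, a precomputed regulatory-potential matrix.
#'
#' @param grid a [genome_grid()].
#' @param genes a [gene_annotation()] table.
#' @param tracks list of `binned_track` objects (see [bin_signal()]).
#' @param cistromes list of [cistrome()] objects.
#' @param covariates numeric vector of per-gene promoter activity, named by
#'   or aligned with `genes$gene_id`. Defaults to zero (single stratum).
#' @param rp_cache optional [rp_matrix()] aligned with `genes` and `tracks`.
#' @return list of class `compendium_store`.
#' @export
compendium_store <- function(grid, genes, tracks = list(),
                             cistromes = list(), covariates = NULL,
                             rp_cache = NULL) {
  stopifnot(inherits(grid, "genome_grid"),
            inherits(genes, "gene_annotation"))
  chrom_index(grid, unique(genes$chrom))  # errors on unknown chromosome
  if (any(genes$tss >= grid$chrom_lengths[chrom_index(grid, genes$chrom)]))
    stop("gene TSS beyond chromosome end")
  for (tr in tracks) {
    if (length(tr$values) != grid$window_count)
      stop("track '", tr$profile_id, "' is not binned on this grid")
    if (any(!is.finite(tr$values)) || any(tr$values < 0))
      stop("track '", tr$profile_id, "' has negative or non-finite values")
  }
  ids <- vapply(tracks, `[[`, "", "profile_id")
  if (anyDuplicated(ids)) stop("duplicate track profile_id")
  names(tracks) <- ids
  cids <- vapply(cistromes, `[[`, "", "cistrome_id")
  if (anyDuplicated(cids)) stop("duplicate cistrome_id")
  names(cistromes) <- cids
  if (is.null(covariates)) {
    covariates <- stats::setNames(numeric(nrow(genes)), genes$gene_id)
  } else {
    if (!is.null(names(covariates))) {
      if (!all(genes$gene_id %in% names(covariates)))
        stop("covariates missing for some genes")
      covariates <- covariates[genes$gene_id]
    } else {
      stopifnot(length(covariates) == nrow(genes))
      names(covariates) <- genes$gene_id
    }
    if (any(!is.finite(covariates))) stop("non-finite covariates")
  }
  if (!is.null(rp_cache)) {
    if (!identical(rp_cache$gene_ids, genes$gene_id) ||
        !identical(rp_cache$profile_ids, unname(ids)))
      stop("rp_cache is not aligned with genes and tracks")
  }
  structure(list(grid = grid, genes = genes, tracks = tracks,
                 cistromes = cistromes, covariates = covariates,
                 rp_cache = rp_cache),
            class = "compendium_store")
}

#' @export
print.compendium_store <- function(x, ...) {
  cat(sprintf(paste0("compendium_store: %d genes, %d tracks, ",
                     "%d cistromes on %d windows%s\n"),
              nrow(x$genes), length(x$tracks), length(x$cistromes),
              x$grid$window_count,
              if (is.null(x$rp_cache)) "" else " (RP cache present)"))
  invisible(x)
}

STORE_FORMAT  <- "trisd-store"
STORE_VERSION <- 1L

md5_of_raw <- function(raw) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(raw, tmp)
  unname(tools::md5sum(tmp))
}

#' Save / load a compendium store
#'
#' Single-file persistent form of the store: a versioned container holding
#' the serialized payload plus an MD5 checksum, written uncompressed so that
#' corruption of the array section is caught at load time. Round-trips are
#' lossless and numeric arrays bit-identical.
#'
#' @param store a [compendium_store()].
#' @param path file path (conventionally `.trisd`).
#' @return `save_store` returns `path` invisibly; `load_store` the store.
#' @export
save_store <- function(store, path) {
  stopifnot(inherits(store, "compendium_store"))
  payload <- serialize(store, NULL, xdr = FALSE)
  saveRDS(list(format = STORE_FORMAT, version = STORE_VERSION,
               md5 = md5_of_raw(payload), payload = payload),
          path, compress = FALSE)
  invisible(path)
}

#' @rdname save_store
#' @export
load_store <- function(path) {
  if (!file.exists(path)) stop("store file not found: ", path)
  wrap <- tryCatch(readRDS(path),
                   error = function(e) stop("cannot read store file ", path,
                                            ": ", conditionMessage(e)))
  if (!is.list(wrap) || !identical(wrap$format, STORE_FORMAT))
    stop("not a compendium store file: ", path)
  if (!identical(wrap$version, STORE_VERSION))
    stop("store version mismatch: file has ", wrap$version,
         ", this build reads ", STORE_VERSION)
  if (!identical(md5_of_raw(wrap$payload), wrap$md5))
    stop("store integrity failure: checksum mismatch (file ", path,
         " is corrupt or truncated)")
  store <- unserialize(wrap$payload)
  if (!inherits(store, "compendium_store"))
    stop("store payload is not a compendium_store")
  store
}
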