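#' Read a PACDataset from disk
#'
#' Two count layouts are accepted: a MatrixMarket coordinate file (`.mtx`)
#' whose rows/columns follow the order of the site/observation metadata
#' sidecars, or a dense TSV with a `site_id` first column and one column per
#' observation. Metadata files are TSV with a header row (columns as
#' documented in [PACDataset()]). Counts are reordered to match the metadata
#' key order.
#'
#' @param counts_path path to `.mtx` or dense `.tsv` counts.
#' @param site_meta_path path to the site metadata TSV.
#' @param obs_meta_path path to the observation metadata TSV.
#' @return a validated [PACDataset].
#' @export
read_pac <- function(counts_path, site_meta_path, obs_meta_path) {
  for (p in c(counts_path, site_meta_path, obs_meta_path)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  site_meta <- read_tsv_strict(site_meta_path)
  obs_meta <- read_tsv_strict(obs_meta_path)
  check_columns(site_meta, c("site_id", "chrom", "strand", "coord"),
                basename(site_meta_path))
  check_columns(obs_meta, c("obs_id", "group"), basename(obs_meta_path))

  if (grepl("\\.mtx$", counts_path, ignore.case = TRUE)) {
    counts <- methods::as(Matrix::readMM(counts_path), "generalMatrix")
    if (nrow(counts) != nrow(site_meta) || ncol(counts) != nrow(obs_meta)) {
      stop(sprintf(
        "matrix file is %d x %d; sidecars describe %d sites x %d observations",
        nrow(counts), ncol(counts), nrow(site_meta), nrow(obs_meta)),
        call. = FALSE)
    }
    dimnames(counts) <- list(as.character(site_meta$site_id),
                             as.character(obs_meta$obs_id))
  } else {
    tab <- read_tsv_strict(counts_path)
    if (colnames(tab)[1] != "site_id") {
      stop("dense counts TSV must have 'site_id' as its first column",
           call. = FALSE)
    }
    counts <- as.matrix(tab[, -1, drop = FALSE])
    rownames(counts) <- as.character(tab$site_id)
  }
  PACDataset(counts, site_meta, obs_meta)
}

#' Write a PACDataset to a directory
#'
#' Writes `sites.tsv`, `obs.tsv` and either `counts.mtx` (default) or a
#' dense `counts.tsv`. The files round-trip exactly through [read_pac()].
#'
#' @param pac a [PACDataset].
#' @param out_dir output directory (created if absent).
#' @param format `"mtx"` for MatrixMarket sparse output, `"tsv"` for dense.
#' @return `out_dir`, invisibly.
#' @export
write_pac <- function(pac, out_dir, format = c("mtx", "tsv")) {
  stopifnot(inherits(pac, "PACDataset"))
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  write_tsv_strict(pac$site_meta, file.path(out_dir, "sites.tsv"))
  write_tsv_strict(pac$obs_meta, file.path(out_dir, "obs.tsv"))
  if (format == "mtx") {
    Matrix::writeMM(pac$counts, file.path(out_dir, "counts.mtx"))
  } else {
    tab <- data.frame(site_id = pac$site_meta$site_id,
                      as.matrix(pac$counts),
                      check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv_strict(tab, file.path(out_dir, "counts.tsv"))
  }
  invisible(out_dir)
}

# TSV dialect used throughout: tab-separated, header row, UTF-8, no quoting.
read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "")
}

write_tsv_strict <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}
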