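#' Unified poly(A)-site dataset container
#'
#' A `PACDataset` couples a sites x observations count matrix with a site
#' metadata table (genomic position of each cleavage site, plus gene/region
#' assignment once annotated) and an observation metadata table (cell or
#' sample group labels). Observations are cells for single-cell data and
#' samples for bulk data. Counts are held sparse internally
#' (`Matrix::dgCMatrix`) but all operations are defined on values, never on
#' the storage format.
#'
#' @param counts non-negative integer matrix or sparse Matrix,
#'   sites x observations. Dimnames, if present, must agree with the
#'   metadata ids.
#' @param site_meta data.frame with columns `site_id`, `chrom`, `strand`
#'   (`"+"` or `"-"`), `coord` (1-based cleavage position); optional
#'   `gene_id` and `region` columns added by [annotate_sites()].
#' @param obs_meta data.frame with columns `obs_id` and `group`.
#' @return an object of class `PACDataset`.
#' @examples
#' pac <- PACDataset(
#'   counts = matrix(0:5, nrow = 3,
#'                   dimnames = list(paste0("s", 1:3), c("c1", "c2"))),
#'   site_meta = data.frame(site_id = paste0("s", 1:3), chrom = "chr1",
#'                          strand = "+", coord = c(100L, 200L, 300L)),
#'   obs_meta = data.frame(obs_id = c("c1", "c2"), group = "A"))
#' dim(pac)
#' @export
PACDataset <- function(counts, site_meta, obs_meta) {
  site_meta <- as.data.frame(site_meta, stringsAsFactors = FALSE)
  obs_meta <- as.data.frame(obs_meta, stringsAsFactors = FALSE)
  check_columns(site_meta, c("site_id", "chrom", "strand", "coord"),
                "site_meta")
  check_columns(obs_meta, c("obs_id", "group"), "obs_meta")
  site_meta$site_id <- as.character(site_meta$site_id)
  site_meta$chrom <- as.character(site_meta$chrom)
  site_meta$strand <- as.character(site_meta$strand)
  site_meta$coord <- as.integer(site_meta$coord)
  obs_meta$obs_id <- as.character(obs_meta$obs_id)
  rownames(site_meta) <- NULL
  rownames(obs_meta) <- NULL

  counts <- as_count_matrix(counts)
  if (nrow(counts) != nrow(site_meta) || ncol(counts) != nrow(obs_meta)) {
    stop(sprintf(
      "counts is %d x %d but site_meta has %d rows and obs_meta has %d rows",
      nrow(counts), ncol(counts), nrow(site_meta), nrow(obs_meta)),
      call. = FALSE)
  }
  if (!is.null(rownames(counts)) &&
      !identical(rownames(counts), site_meta$site_id)) {
    counts <- reorder_rows(counts, site_meta$site_id, "site")
  }
  if (!is.null(colnames(counts)) &&
      !identical(colnames(counts), obs_meta$obs_id)) {
    counts <- reorder_cols(counts, obs_meta$obs_id, "observation")
  }
  dimnames(counts) <- list(site_meta$site_id, obs_meta$obs_id)

  pac <- structure(
    list(counts = counts, site_meta = site_meta, obs_meta = obs_meta),
    class = "PACDataset")
  validate_pac(pac)
  pac
}

as_count_matrix <- function(counts) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (is.matrix(counts)) {
    storage.mode(counts) <- "double"
    counts <- Matrix::Matrix(counts, sparse = TRUE)
  }
  # normalize any Matrix flavor (symmetric, triplet, pattern) to dgCMatrix
  counts <- methods::as(counts, "generalMatrix")
  counts <- methods::as(counts, "dMatrix")
  methods::as(counts, "CsparseMatrix")
}

reorder_rows <- function(m, ids, what) {
  idx <- match(ids, rownames(m))
  if (anyNA(idx)) {
    miss <- ids[is.na(idx)]
    stop(sprintf("%s ids in metadata but not in counts: %s",
                 what, paste(utils::head(miss, 5), collapse = ", ")),
         call. = FALSE)
  }
  m[idx, , drop = FALSE]
}

reorder_cols <- function(m, ids, what) {
  idx <- match(ids, colnames(m))
  if (anyNA(idx)) {
    miss <- ids[is.na(idx)]
    stop(sprintf("%s ids in metadata but not in counts: %s",
                 what, paste(utils::head(miss, 5), collapse = ", ")),
         call. = FALSE)
  }
  m[, idx, drop = FALSE]
}

check_columns <- function(df, required, table_name) {
  missing_cols <- setdiff(required, colnames(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s is missing required column(s): %s",
                 table_name, paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

validate_pac <- function(pac) {
  sm <- pac$site_meta
  om <- pac$obs_meta
  if (anyDuplicated(sm$site_id)) {
    stop("site ids are not unique: ",
         paste(utils::head(unique(sm$site_id[duplicated(sm$site_id)]), 5),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(om$obs_id)) {
    stop("observation ids are not unique: ",
         paste(utils::head(unique(om$obs_id[duplicated(om$obs_id)]), 5),
               collapse = ", "), call. = FALSE)
  }
  if (nrow(sm) > 0) {
    if (!all(sm$strand %in% c("+", "-"))) {
      stop("site_meta strand values must be '+' or '-'", call. = FALSE)
    }
    if (anyNA(sm$coord) || any(sm$coord < 1)) {
      stop("site_meta coord values must be integers >= 1", call. = FALSE)
    }
  }
  if (nrow(om) > 0 && (anyNA(om$group) || any(om$group == ""))) {
    bad <- om$obs_id[is.na(om$group) | om$group == ""]
    stop("observations without a group label are not allowed: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  x <- pac$counts@x
  if (length(x) > 0 && any(x < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  invisible(pac)
}

#' @export
dim.PACDataset <- function(x) dim(x$counts)

#' @export
print.PACDataset <- function(x, ...) {
  cat(sprintf("PACDataset: %d poly(A) sites x %d observations\n",
              nrow(x$counts), ncol(x$counts)))
  if (nrow(x$obs_meta) > 0) {
    grp <- table(x$obs_meta$group)
    cat("groups:", paste(sprintf("%s (%d)", names(grp), grp),
                         collapse = ", "), "\n")
  }
  if ("region" %in% colnames(x$site_meta)) {
    reg <- table(x$site_meta$region, useNA = "ifany")
    cat("regions:", paste(sprintf("%s (%d)", names(reg), reg),
                          collapse = ", "), "\n")
  } else {
    cat("sites not yet annotated (run annotate_sites)\n")
  }
  cat(sprintf("total counts: %.0f\n", sum(x$counts)))
  invisible(x)
}

#' Subset a PACDataset by site and/or observation ids
#'
#' Output order follows the requested id order.
#'
#' @param pac a [PACDataset].
#' @param site_ids character vector of site ids, or `NULL` for all sites.
#' @param obs_ids character vector of observation ids, or `NULL` for all
#'   observations.
#' @return a [PACDataset] restricted to the requested ids.
#' @export
subset_pac <- function(pac, site_ids = NULL, obs_ids = NULL) {
  stopifnot(inherits(pac, "PACDataset"))
  if (is.null(site_ids)) site_ids <- pac$site_meta$site_id
  if (is.null(obs_ids)) obs_ids <- pac$obs_meta$obs_id
  si <- match(site_ids, pac$site_meta$site_id)
  if (anyNA(si)) {
    stop("unknown site id(s): ",
         paste(utils::head(site_ids[is.na(si)], 5), collapse = ", "),
         call. = FALSE)
  }
  oi <- match(obs_ids, pac$obs_meta$obs_id)
  if (anyNA(oi)) {
    stop("unknown observation id(s): ",
         paste(utils::head(obs_ids[is.na(oi)], 5), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(counts = pac$counts[si, oi, drop = FALSE],
         site_meta = pac$site_meta[si, , drop = FALSE],
         obs_meta = pac$obs_meta[oi, , drop = FALSE]),
    class = "PACDataset")
}

#' Aggregate observations into pseudo-bulk groups
#'
#' Sums counts over all observations sharing a group label, producing one
#' output observation per group (pseudo-bulk). Group order follows first
#' appearance in `obs_meta`.
#'
#' @param pac a [PACDataset].
#' @return a [PACDataset] with one observation per group; the group label is
#'   kept as both `obs_id` and `group`.
#' @export
aggregate_by_group <- function(pac) {
  stopifnot(inherits(pac, "PACDataset"))
  groups <- unique(pac$obs_meta$group)
  design <- Matrix::sparseMatrix(
    i = seq_len(nrow(pac$obs_meta)),
    j = match(pac$obs_meta$group, groups),
    x = 1,
    dims = c(nrow(pac$obs_meta), length(groups)))
  agg <- pac$counts %*% design
  agg <- methods::as(methods::as(agg, "CsparseMatrix"), "generalMatrix")
  colnames(agg) <- groups
  rownames(agg) <- pac$site_meta$site_id
  structure(
    list(counts = agg,
         site_meta = pac$site_meta,
         obs_meta = data.frame(obs_id = groups, group = groups,
                               stringsAsFactors = FALSE)),
    class = "PACDataset")
}
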