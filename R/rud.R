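#' Relative Usage of the Distal poly(A) site (RUD)
#'
#' For each gene with at least two usable poly(A) sites (sites annotated
#' `UTR3` or `ext_UTR3`), RUD in an observation is the fraction of the
#' gene's usable-site counts falling on the distal site — the usable site
#' farthest 3' in strand-aware order:
#' \deqn{RUD = n_{distal} / \sum_{s \in usable} n_s}
#' Low RUD indicates 3'UTR shortening. For genes with more than two sites
#' the denominator is the sum over all usable sites, which keeps RUD in
#' \[0, 1\] and reduces to the usual two-site definition. The value is
#' missing (`NA`) where the denominator is below `min_counts`; no smoothing
#' or imputation is applied.
#'
#' @param pac an annotated [PACDataset] (see [annotate_sites()]).
#' @param min_counts minimum usable-site total per gene/observation for a
#'   defined RUD value (default 5).
#' @return an object of class `RUDMatrix`: `values` (genes x observations,
#'   `NA` where undefined), `gene_index`, `site_partition` (per gene, the
#'   proximal site set and the distal site), `params`.
#' @export
compute_rud <- function(pac, min_counts = 5) {
  stopifnot(inherits(pac, "PACDataset"))
  stopifnot(is.numeric(min_counts), length(min_counts) == 1, min_counts >= 1)
  sm <- pac$site_meta
  if (!all(c("gene_id", "region") %in% colnames(sm))) {
    stop("PACDataset is not annotated; run annotate_sites() first",
         call. = FALSE)
  }
  usable <- !is.na(sm$gene_id) & sm$region %in% c("UTR3", "ext_UTR3")
  idx <- which(usable)
  genes <- split(idx, sm$gene_id[idx])
  genes <- genes[vapply(genes, length, integer(1)) >= 2]
  if (length(genes) == 0) {
    warning("no gene has >= 2 usable (UTR3/ext_UTR3) sites; RUD matrix is empty",
            call. = FALSE)
    return(structure(
      list(values = matrix(numeric(0), nrow = 0, ncol = ncol(pac$counts),
                           dimnames = list(NULL, pac$obs_meta$obs_id)),
           gene_index = character(0),
           site_partition = list(),
           params = list(min_counts = min_counts)),
      class = "RUDMatrix"))
  }
  gene_ids <- sort(names(genes))
  n_obs <- ncol(pac$counts)
  values <- matrix(NA_real_, nrow = length(gene_ids), ncol = n_obs,
                   dimnames = list(gene_ids, pac$obs_meta$obs_id))
  partition <- vector("list", length(gene_ids))
  names(partition) <- gene_ids
  counts <- pac$counts
  for (k in seq_along(gene_ids)) {
    g <- gene_ids[k]
    rows <- genes[[g]]
    strand_g <- sm$strand[rows[1]]
    # distal = farthest 3': highest coord on +, lowest on -
    distal_row <- if (strand_g == "+") rows[which.max(sm$coord[rows])] else
      rows[which.min(sm$coord[rows])]
    prox_rows <- setdiff(rows, distal_row)
    total <- Matrix::colSums(counts[rows, , drop = FALSE])
    distal <- as.numeric(counts[distal_row, ])
    v <- distal / total
    v[total < min_counts] <- NA_real_
    values[k, ] <- v
    partition[[k]] <- list(proximal = sm$site_id[prox_rows],
                           distal = sm$site_id[distal_row])
  }
  structure(
    list(values = values,
         gene_index = gene_ids,
         site_partition = partition,
         params = list(min_counts = min_counts)),
    class = "RUDMatrix")
}

#' @export
print.RUDMatrix <- function(x, ...) {
  cat(sprintf("RUDMatrix: %d genes x %d observations (min_counts = %s)\n",
              nrow(x$values), ncol(x$values), x$params$min_counts))
  cat(sprintf("defined values: %.1f%%\n",
              100 * mean(!is.na(x$values))))
  invisible(x)
}

#' @export
dim.RUDMatrix <- function(x) dim(x$values)

#' Mean RUD per observation
#'
#' Per observation, the mean over genes with a defined RUD value; `NA` for
#' observations where no gene has a defined value. Used as a per-cell
#' summary of global 3'UTR usage (e.g. as an embedding overlay).
#'
#' @param rud a `RUDMatrix` from [compute_rud()].
#' @return named numeric vector over observations.
#' @export
mean_rud_per_obs <- function(rud) {
  stopifnot(inherits(rud, "RUDMatrix"))
  out <- colMeans(rud$values, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Write a RUDMatrix as TSV (genes x observations, NA for undefined)
#'
#' @param rud a `RUDMatrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rud <- function(rud, path) {
  stopifnot(inherits(rud, "RUDMatrix"))
  tab <- data.frame(gene_id = rud$gene_index, rud$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_strict(tab, path)
  invisible(path)
}

#' Read a RUDMatrix written by [write_rud()]
#'
#' @param path TSV path (first column `gene_id`, then one column per
#'   observation).
#' @param min_counts value recorded into `params` (the threshold used when
#'   the matrix was computed; not re-applied).
#' @return a `RUDMatrix` (without `site_partition`, which is not serialized).
#' @export
read_rud <- function(path, min_counts = NA) {
  tab <- read_tsv_strict(path)
  if (colnames(tab)[1] != "gene_id") {
    stop("RUD TSV must have 'gene_id' as its first column", call. = FALSE)
  }
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- as.character(tab$gene_id)
  structure(
    list(values = values,
         gene_index = rownames(values),
         site_partition = NULL,
         params = list(min_counts = min_counts)),
    class = "RUDMatrix")
}
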