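#' 2D embedding of observations from their APA profiles
#'
#' Embeds observations (cells/samples) with UMAP, either from poly(A)-site
#' expression (`source = "site_expression"`: counts normalized per
#' observation to 10,000, log1p-transformed, reduced to at most 50
#' principal components before the neighbor graph) or from RUD usage
#' (`source = "rud_usage"`: missing values imputed with the per-gene median
#' for the embedding only; the RUDMatrix itself is never modified).
#'
#' Observations with byte-identical profiles are embedded once and share
#' coordinates, so duplicates map exactly together. All randomness is
#' controlled by `seed`; the same input and seed reproduce the coordinates
#' exactly.
#'
#' @param x a [PACDataset] (for `source = "site_expression"`) or a
#'   `RUDMatrix` (for `source = "rud_usage"`).
#' @param source profile selector; defaults to the natural source for the
#'   class of `x`.
#' @param n_neighbors UMAP neighborhood size (default 15).
#' @param min_dist UMAP minimum distance (default 0.1).
#' @param seed integer seed (default 42).
#' @return an `Embedding2D`: `coords` (observations x 2, rownames are
#'   observation ids), `source`, `params`, and an initially empty `overlay`.
#' @export
compute_embedding <- function(x, source = NULL, n_neighbors = 15,
                              min_dist = 0.1, seed = 42) {
  if (is.null(source)) {
    source <- if (inherits(x, "PACDataset")) "site_expression" else "rud_usage"
  }
  source <- match.arg(source, c("site_expression", "rud_usage"))
  if (source == "site_expression") {
    stopifnot(inherits(x, "PACDataset"))
    m <- Matrix::t(x$counts)   # observations x sites
    libsize <- Matrix::rowSums(m)
    libsize[libsize == 0] <- 1
    m <- log1p(as.matrix(m / libsize * 1e4))
  } else {
    stopifnot(inherits(x, "RUDMatrix"))
    m <- t(x$values)           # observations x genes
    med <- apply(x$values, 1, stats::median, na.rm = TRUE)
    med[is.na(med)] <- 0.5
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      if (any(nas)) m[nas, j] <- med[j]
    }
  }
  n_obs <- nrow(m)
  if (n_obs < n_neighbors + 1) {
    stop(sprintf("need at least n_neighbors + 1 = %d observations, have %d",
                 n_neighbors + 1, n_obs), call. = FALSE)
  }
  n_pc <- min(50, n_obs - 1, ncol(m))
  scores <- if (ncol(m) > n_pc) {
    stats::prcomp(m, center = TRUE, scale. = FALSE, rank. = n_pc)$x
  } else m

  key <- apply(scores, 1, paste, collapse = "\r")
  first <- !duplicated(key)
  uniq <- scores[first, , drop = FALSE]
  k <- min(n_neighbors, nrow(uniq) - 1)
  if (k < 2) {
    # degenerate: all profiles identical (or a single pair); spread on a line
    coords_uniq <- cbind(seq_len(nrow(uniq)) - 1, 0)
  } else {
    coords_uniq <- with_sim_seed(seed,
      uwot::umap(uniq, n_neighbors = k, min_dist = min_dist,
                 n_threads = 1, n_sgd_threads = 0))
  }
  coords <- coords_uniq[match(key, key[first]), , drop = FALSE]
  dimnames(coords) <- list(rownames(m), c("UMAP1", "UMAP2"))
  structure(
    list(coords = coords,
         source = source,
         params = list(n_neighbors = n_neighbors, min_dist = min_dist,
                       seed = seed),
         overlay = NULL),
    class = "Embedding2D")
}

#' @export
print.Embedding2D <- function(x, ...) {
  cat(sprintf("Embedding2D: %d observations (source = %s, n_neighbors = %d, min_dist = %g, seed = %d)\n",
              nrow(x$coords), x$source, x$params$n_neighbors,
              x$params$min_dist, x$params$seed))
  if (!is.null(x$overlay)) {
    cat(sprintf("overlay: %s\n",
                if (is.numeric(x$overlay)) "scalar" else "categorical"))
  }
  invisible(x)
}

#' Attach a per-observation overlay to an embedding
#'
#' The overlay (e.g. per-cell mean RUD, or group labels) is stored for use
#' by [viz_embedding()]; missing values are allowed and rendered in a
#' neutral color downstream.
#'
#' @param emb an `Embedding2D`.
#' @param values numeric or categorical vector named by observation id, or
#'   unnamed with one value per observation in embedding order.
#' @return the `Embedding2D` with `overlay` set.
#' @export
attach_overlay <- function(emb, values) {
  stopifnot(inherits(emb, "Embedding2D"))
  obs <- rownames(emb$coords)
  if (is.null(names(values))) {
    if (length(values) != length(obs)) {
      stop("unnamed overlay must have one value per observation",
           call. = FALSE)
    }
    names(values) <- obs
  }
  idx <- match(obs, names(values))
  if (anyNA(idx)) {
    stop("overlay has no value for observation(s): ",
         paste(utils::head(obs[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  emb$overlay <- stats::setNames(values[idx], obs)
  emb
}

#' Write an embedding as TSV (obs_id, x, y, overlay)
#' @param emb an `Embedding2D`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(emb, path) {
  stopifnot(inherits(emb, "Embedding2D"))
  tab <- data.frame(obs_id = rownames(emb$coords),
                    x = emb$coords[, 1], y = emb$coords[, 2],
                    stringsAsFactors = FALSE)
  if (!is.null(emb$overlay)) tab$overlay <- as.vector(emb$overlay)
  write_tsv_strict(tab, path)
  invisible(path)
}
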