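#' Detect genes with differential APA usage between two cell groups
#'
#' For every gene with at least `min_cells` observations with a defined RUD
#' value in each group, compares the per-observation RUD values of
#' `group_x` against `group_y` with a two-sided Wilcoxon rank-sum test
#' (exact when both groups have at most 25 defined values and no ties;
#' normal approximation with tie and continuity correction otherwise).
#' P-values are Benjamini-Hochberg adjusted within this one comparison.
#' APA markers are genes with `q_value <= alpha` and
#' `|delta_rud| >= min_delta`; a positive marker has higher mean RUD in
#' `group_x` than in `group_y`.
#'
#' @param rud a `RUDMatrix` from [compute_rud()].
#' @param obs_meta observation metadata: a data.frame with `obs_id` and
#'   `group`, or a group vector named by observation id.
#' @param group_x,group_y group labels to compare (`x` vs `y`).
#' @param min_cells minimum defined RUD values per group for a gene to be
#'   tested (default 10).
#' @param alpha adjusted-significance cutoff for markers (default 0.05).
#' @param min_delta minimum |mean RUD difference| for markers (default 0.1).
#' @param keep `"markers"` (default) returns marker rows only; `"all"`
#'   returns every tested gene with a logical `marker` column.
#' @return a `MarkerTable` data.frame with columns `gene_id`, `group_x`,
#'   `group_y`, `delta_rud` (mean RUD(x) - mean RUD(y)), `p_value`,
#'   `q_value`, `direction` (`"positive"`/`"negative"`), `n_x`, `n_y`,
#'   sorted by `q_value` then `p_value`.
#' @export
get_apa_markers <- function(rud, obs_meta, group_x, group_y,
                            min_cells = 10, alpha = 0.05, min_delta = 0.1,
                            keep = c("markers", "all")) {
  stopifnot(inherits(rud, "RUDMatrix"))
  keep <- match.arg(keep)
  stopifnot(alpha > 0, alpha < 1, min_delta >= 0, min_delta <= 1,
            min_cells >= 1)
  groups <- as_group_vector(obs_meta, colnames(rud$values))
  for (g in c(group_x, group_y)) {
    if (!g %in% groups) stop("group label not found: ", g, call. = FALSE)
  }
  x_cols <- which(groups == group_x)
  y_cols <- which(groups == group_y)
  rows <- lapply(seq_len(nrow(rud$values)), function(i) {
    xv <- rud$values[i, x_cols]
    yv <- rud$values[i, y_cols]
    xv <- xv[!is.na(xv)]
    yv <- yv[!is.na(yv)]
    if (length(xv) < min_cells || length(yv) < min_cells) return(NULL)
    data.frame(gene_id = rud$gene_index[i],
               group_x = group_x, group_y = group_y,
               delta_rud = mean(xv) - mean(yv),
               p_value = ranksum_p(xv, yv),
               n_x = length(xv), n_y = length(yv),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    warning("no gene passes the min_cells filter in both groups; ",
            "empty marker table", call. = FALSE)
    return(empty_marker_table())
  }
  tab <- do.call(rbind, rows)
  tab$q_value <- stats::p.adjust(tab$p_value, method = "BH")
  tab$direction <- ifelse(tab$delta_rud > 0, "positive", "negative")
  tab$marker <- tab$q_value <= alpha & abs(tab$delta_rud) >= min_delta
  tab <- tab[order(tab$q_value, tab$p_value, tab$gene_id), , drop = FALSE]
  tab <- tab[, c("gene_id", "group_x", "group_y", "delta_rud", "p_value",
                 "q_value", "direction", "n_x", "n_y", "marker")]
  rownames(tab) <- NULL
  if (keep == "markers") {
    tab <- tab[tab$marker, , drop = FALSE]
    rownames(tab) <- NULL
  }
  class(tab) <- c("MarkerTable", "data.frame")
  tab
}

empty_marker_table <- function() {
  tab <- data.frame(gene_id = character(0), group_x = character(0),
                    group_y = character(0), delta_rud = numeric(0),
                    p_value = numeric(0), q_value = numeric(0),
                    direction = character(0), n_x = integer(0),
                    n_y = integer(0), marker = logical(0),
                    stringsAsFactors = FALSE)
  class(tab) <- c("MarkerTable", "data.frame")
  tab
}

# two-sided rank-sum p-value. Small groups (<= 10 each) get full
# enumeration over rank assignments (midranks, so ties are exact too);
# tie-free groups up to 25 use the exact null distribution; larger samples
# use the normal approximation with tie and continuity correction.
ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) return(1)
  n <- length(x); m <- length(y)
  if (n <= 10 && m <= 10) {
    r <- rank(pooled)
    u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
    u_all <- colSums(matrix(r[utils::combn(n + m, n)], nrow = n)) -
      n * (n + 1) / 2
    eps <- 1e-9
    p <- 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps))
    return(min(1, p))
  }
  exact <- n <= 25 && m <= 25 && anyDuplicated(pooled) == 0
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value)
  if (is.nan(p)) p <- 1   # zero-variance tie structure
  p
}

as_group_vector <- function(obs_meta, obs_ids) {
  if (is.data.frame(obs_meta)) {
    check_columns(obs_meta, c("obs_id", "group"), "obs_meta")
    groups <- stats::setNames(as.character(obs_meta$group),
                              as.character(obs_meta$obs_id))
  } else {
    if (is.null(names(obs_meta))) {
      if (length(obs_meta) != length(obs_ids)) {
        stop("unnamed group vector must match the number of observations",
             call. = FALSE)
      }
      return(as.character(obs_meta))
    }
    groups <- stats::setNames(as.character(obs_meta), names(obs_meta))
  }
  idx <- match(obs_ids, names(groups))
  if (anyNA(idx)) {
    stop("observations without a group label: ",
         paste(utils::head(obs_ids[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  unname(groups[idx])
}

#' Count APA markers for every group pair
#'
#' Runs [get_apa_markers()] for each unordered pair of groups, taking
#' `group_x` as the group appearing earlier in `group_order` (by default the
#' order of first appearance in `obs_meta`). With this ordering, a
#' progressive loss of distal-site usage along `group_order` (global 3'UTR
#' shortening, as in a differentiation time course) shows up as an excess of
#' positive markers for early-vs-late pairs.
#'
#' @inheritParams get_apa_markers
#' @param group_order optional character vector fixing the group order.
#' @return data.frame with one row per pair: `group_x`, `group_y`,
#'   `n_positive`, `n_negative`.
#' @export
count_markers_pairwise <- function(rud, obs_meta, min_cells = 10,
                                   alpha = 0.05, min_delta = 0.1,
                                   group_order = NULL) {
  groups <- as_group_vector(obs_meta, colnames(rud$values))
  if (is.null(group_order)) group_order <- unique(groups)
  if (length(group_order) < 2) {
    stop("at least two groups are required", call. = FALSE)
  }
  out <- list()
  for (i in seq_len(length(group_order) - 1)) {
    for (j in seq(i + 1, length(group_order))) {
      mk <- suppressWarnings(
        get_apa_markers(rud, obs_meta, group_order[i], group_order[j],
                        min_cells = min_cells, alpha = alpha,
                        min_delta = min_delta, keep = "markers"))
      out[[length(out) + 1L]] <- data.frame(
        group_x = group_order[i], group_y = group_order[j],
        n_positive = sum(mk$direction == "positive"),
        n_negative = sum(mk$direction == "negative"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write a MarkerTable as TSV
#' @param markers a `MarkerTable`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_markers <- function(markers, path) {
  write_tsv_strict(as.data.frame(markers), path)
  invisible(path)
}
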