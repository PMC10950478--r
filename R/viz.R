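#' Genome-browser-like track figure for one gene
#'
#' Composes, top to bottom: the merged gene model (exons as boxes, introns
#' as a line, 3'UTR highlighted, strand arrow), a pA track with one mark
#' per poly(A) site (height proportional to aggregated expression), one
#' read-coverage track per group when alignments are supplied, and a
#' sites x cells heatmap of single-cell counts (cells ordered by group,
#' then total count, descending). The plotted region is the gene span plus
#' an `ext3utr` margin on the 3' side; every track shares the same genomic
#' x-limits.
#'
#' The figure is built as an inspectable specification object
#' (`TrackFigure`) first; `plot()` renders it and [save_figure()] writes
#' PNG/PDF. Inputs are never modified.
#'
#' @param pac a [PACDataset].
#' @param anno a `GenomeAnnotation`.
#' @param gene focus gene id.
#' @param alignments_by_group optional named vector of BAM paths, one per
#'   group, in display order.
#' @param cells_track include the single-cell heatmap track (default TRUE).
#' @param ext3utr 3'-side margin in bp (default 1000).
#' @param strand_mode coverage strandedness, see [compute_coverage()].
#' @param out optional image path (`.png` or `.pdf`); when given the figure
#'   is rendered and saved.
#' @return a `TrackFigure` specification object.
#' @export
viz_tracks <- function(pac, anno, gene, alignments_by_group = NULL,
                       cells_track = TRUE, ext3utr = 1000,
                       strand_mode = "both", out = NULL) {
  stopifnot(inherits(pac, "PACDataset"), inherits(anno, "GenomeAnnotation"))
  gi <- anno$genes[anno$genes$gene_id == gene, , drop = FALSE]
  if (nrow(gi) == 0) stop("gene not found in annotation: ", gene,
                          call. = FALSE)
  rs <- if (gi$strand == "+") gi$start else max(1L, gi$start - ext3utr)
  re <- if (gi$strand == "+") gi$end + ext3utr else gi$end
  xlim <- c(rs, re)
  region <- list(chrom = gi$chrom, start = rs, end = re,
                 strand = gi$strand, gene = gene)

  feat_df <- function(type) {
    fg <- anno$features[[type]]
    fg <- fg[fg$gene_id == gene]
    data.frame(start = GenomicRanges::start(fg),
               end = GenomicRanges::end(fg))
  }
  gene_model <- list(kind = "gene_model", xlim = xlim,
                     exons = feat_df("exon"), introns = feat_df("intron"),
                     utr3 = feat_df("UTR3"),
                     span = c(gi$start, gi$end), strand = gi$strand)

  in_region <- pac$site_meta$chrom == gi$chrom &
    pac$site_meta$coord >= rs & pac$site_meta$coord <= re
  sm <- pac$site_meta[in_region, , drop = FALSE]
  heights <- if (nrow(sm) > 0)
    Matrix::rowSums(pac$counts[which(in_region), , drop = FALSE]) else numeric(0)
  if (nrow(sm) == 0) {
    message("no poly(A) sites fall in the plotted region of gene ", gene)
  }
  pa <- list(kind = "pA", xlim = xlim,
             sites = data.frame(site_id = sm$site_id, coord = sm$coord,
                                strand = sm$strand, height = as.numeric(heights),
                                stringsAsFactors = FALSE))

  tracks <- list(gene_model = gene_model, pA = pa)
  if (!is.null(alignments_by_group)) {
    for (grp in names(alignments_by_group)) {
      prof <- compute_coverage(alignments_by_group[[grp]], gi$chrom, rs, re,
                               strand_mode = strand_mode,
                               gene_strand = gi$strand, group = grp)
      tracks[[paste0("coverage_", grp)]] <-
        list(kind = "coverage", xlim = xlim, group = grp, profile = prof)
    }
  }
  if (cells_track) {
    cnt <- as.matrix(pac$counts[which(in_region), , drop = FALSE])
    ord <- order(match(pac$obs_meta$group, unique(pac$obs_meta$group)),
                 -colSums(cnt))
    tracks$cells <- list(kind = "cells", xlim = xlim,
                         counts = cnt[, ord, drop = FALSE],
                         coords = sm$coord,
                         groups = pac$obs_meta$group[ord])
  }
  fig <- structure(list(region = region, tracks = tracks),
                   class = "TrackFigure")
  if (!is.null(out)) save_figure(plot(fig), out, height = 2 + 1.5 * length(tracks))
  fig
}

#' @export
print.TrackFigure <- function(x, ...) {
  cat(sprintf("TrackFigure: %s (%s:%d-%d, %s strand), %d tracks: %s\n",
              x$region$gene, x$region$chrom, x$region$start, x$region$end,
              x$region$strand, length(x$tracks),
              paste(names(x$tracks), collapse = ", ")))
  invisible(x)
}

#' Render a TrackFigure to a patchwork of ggplots
#' @param x a `TrackFigure`.
#' @param ... unused.
#' @return a patchwork object.
#' @export
plot.TrackFigure <- function(x, ...) {
  panels <- lapply(names(x$tracks), function(nm) {
    tr <- x$tracks[[nm]]
    p <- switch(tr$kind,
      gene_model = render_gene_model(tr, x$region),
      pA = render_pa_track(tr),
      coverage = render_coverage_track(tr),
      cells = render_cells_track(tr))
    p + ggplot2::coord_cartesian(xlim = tr$xlim, expand = FALSE) +
      ggplot2::labs(title = NULL, y = nm) +
      ggplot2::theme_minimal(base_size = 9) +
      ggplot2::theme(axis.title.x = ggplot2::element_blank())
  })
  patchwork::wrap_plots(panels, ncol = 1) +
    patchwork::plot_annotation(
      title = sprintf("%s (%s:%d-%d %s)", x$region$gene, x$region$chrom,
                      x$region$start, x$region$end, x$region$strand))
}

render_gene_model <- function(tr, region) {
  p <- ggplot2::ggplot() +
    ggplot2::annotate("segment", x = tr$span[1], xend = tr$span[2],
                      y = 0, yend = 0, linewidth = 0.4)
  if (nrow(tr$exons) > 0) {
    p <- p + ggplot2::geom_rect(
      data = tr$exons,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -0.35, ymax = 0.35, fill = "grey35")
  }
  if (nrow(tr$utr3) > 0) {
    p <- p + ggplot2::geom_rect(
      data = tr$utr3,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -0.35, ymax = 0.35, fill = "steelblue")
  }
  arrow_x <- if (tr$strand == "+") tr$span[2] else tr$span[1]
  arrow_dx <- 0.02 * (region$end - region$start + 1) *
    if (tr$strand == "+") 1 else -1
  p + ggplot2::annotate("segment", x = arrow_x, xend = arrow_x + arrow_dx,
                        y = 0.6, yend = 0.6,
                        arrow = grid::arrow(length = grid::unit(2, "mm"))) +
    ggplot2::scale_y_continuous(limits = c(-1, 1), breaks = NULL)
}

render_pa_track <- function(tr) {
  p <- ggplot2::ggplot(tr$sites)
  if (nrow(tr$sites) > 0) {
    p <- p +
      ggplot2::geom_segment(ggplot2::aes(x = .data$coord, xend = .data$coord,
                                         y = 0, yend = .data$height),
                            color = "firebrick", linewidth = 1) +
      ggplot2::geom_point(ggplot2::aes(x = .data$coord, y = .data$height),
                          color = "firebrick", size = 1.5)
  }
  p
}

render_coverage_track <- function(tr) {
  prof <- tr$profile
  df <- data.frame(pos = seq(prof$start, length.out = length(prof$depth)),
                   depth = prof$depth)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_area(fill = "darkolivegreen4") +
    ggplot2::labs(subtitle = tr$group)
}

render_cells_track <- function(tr) {
  cnt <- tr$counts
  if (nrow(cnt) == 0 || ncol(cnt) == 0) return(ggplot2::ggplot())
  width <- max(1, round(0.01 * (tr$xlim[2] - tr$xlim[1])))
  df <- expand.grid(site = seq_len(nrow(cnt)), cell = seq_len(ncol(cnt)))
  df$coord <- tr$coords[df$site]
  df$count <- cnt[cbind(df$site, df$cell)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$coord, y = .data$cell,
                                   fill = .data$count)) +
    ggplot2::geom_tile(width = width) +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred")
}

#' Save a plot to PNG or PDF, chosen by file extension
#' @param p a ggplot/patchwork object.
#' @param out output path ending in `.png` or `.pdf`.
#' @param width,height figure size in inches.
#' @return `out`, invisibly.
#' @export
save_figure <- function(p, out, width = 8, height = 6) {
  ext <- tolower(tools::file_ext(out))
  if (!ext %in% c("png", "pdf")) {
    stop("unsupported figure format '.", ext, "'; use .png or .pdf",
         call. = FALSE)
  }
  if (ext == "png") {
    grDevices::png(out, width = width, height = height, units = "in",
                   res = 150, type = "cairo")
  } else {
    grDevices::pdf(out, width = width, height = height)
  }
  on.exit(grDevices::dev.off())
  print(p)
  invisible(out)
}

#' Summary chart of site expression or RUD for one gene
#'
#' `level = "site_expression"` charts per-site count distributions per
#' group (requires an annotated [PACDataset]); `level = "rud"` charts
#' per-observation RUD per group (requires a `RUDMatrix` plus `obs_meta`).
#' Chart types: `violin`, `box`, `dot` (mean as color, fraction of
#' observations with signal as size), `bubble` (dot with the two encodings
#' swapped), `heatmap`.
#'
#' @param x a [PACDataset] or `RUDMatrix`, matching `level`.
#' @param gene gene id.
#' @param chart one of `"violin"`, `"box"`, `"dot"`, `"bubble"`,
#'   `"heatmap"`.
#' @param level `"site_expression"` or `"rud"`.
#' @param obs_meta observation metadata (required for `level = "rud"`).
#' @param out optional image path.
#' @return a ggplot object; its `data` holds the long-format table plotted.
#' @export
viz_stats <- function(x, gene, chart = c("violin", "box", "dot", "bubble",
                                         "heatmap"),
                      level = c("site_expression", "rud"), obs_meta = NULL,
                      out = NULL) {
  chart <- match.arg(chart)
  level <- match.arg(level)
  if (level == "site_expression") {
    stopifnot(inherits(x, "PACDataset"))
    if (!"gene_id" %in% colnames(x$site_meta)) {
      stop("PACDataset is not annotated; run annotate_sites() first",
           call. = FALSE)
    }
    rows <- which(!is.na(x$site_meta$gene_id) & x$site_meta$gene_id == gene)
    if (length(rows) == 0) stop("gene has no sites: ", gene, call. = FALSE)
    cnt <- as.matrix(x$counts[rows, , drop = FALSE])
    df <- data.frame(
      unit = rep(x$site_meta$site_id[rows], times = ncol(cnt)),
      obs_id = rep(x$obs_meta$obs_id, each = length(rows)),
      group = rep(x$obs_meta$group, each = length(rows)),
      value = as.vector(cnt),
      stringsAsFactors = FALSE)
    ylab <- "site count"
  } else {
    stopifnot(inherits(x, "RUDMatrix"))
    if (is.null(obs_meta)) {
      stop("obs_meta is required for level = 'rud'", call. = FALSE)
    }
    if (!gene %in% x$gene_index) {
      stop("gene not present in RUDMatrix: ", gene, call. = FALSE)
    }
    groups <- as_group_vector(obs_meta, colnames(x$values))
    df <- data.frame(unit = gene, obs_id = colnames(x$values),
                     group = groups, value = x$values[gene, ],
                     stringsAsFactors = FALSE)
    df <- df[!is.na(df$value), , drop = FALSE]
    ylab <- "RUD"
  }
  p <- switch(chart,
    violin = ggplot2::ggplot(df, ggplot2::aes(x = .data$unit, y = .data$value,
                                              fill = .data$group)) +
      ggplot2::geom_violin(position = ggplot2::position_dodge(width = 0.8),
                           scale = "width"),
    box = ggplot2::ggplot(df, ggplot2::aes(x = .data$unit, y = .data$value,
                                           fill = .data$group)) +
      ggplot2::geom_boxplot(position = ggplot2::position_dodge(width = 0.8)),
    dot = dot_chart(df, swap = FALSE),
    bubble = dot_chart(df, swap = TRUE),
    heatmap = {
      df$obs_id <- factor(df$obs_id,
                          levels = unique(df$obs_id[order(df$group)]))
      ggplot2::ggplot(df, ggplot2::aes(x = .data$obs_id, y = .data$unit,
                                       fill = .data$value)) +
        ggplot2::geom_tile() +
        ggplot2::scale_fill_gradient(low = "white", high = "darkred") +
        ggplot2::theme(axis.text.x = ggplot2::element_blank())
    })
  p <- p + ggplot2::labs(x = NULL, y = ylab, title = gene) +
    ggplot2::theme_minimal(base_size = 10)
  if (!is.null(out)) save_figure(p, out)
  p
}

dot_chart <- function(df, swap = FALSE) {
  agg <- stats::aggregate(value ~ unit + group, data = df,
                          FUN = function(v) c(mean = mean(v),
                                              frac = mean(v > 0)))
  agg <- data.frame(agg[c("unit", "group")],
                    mean = agg$value[, "mean"], frac = agg$value[, "frac"])
  if (!swap) {
    ggplot2::ggplot(agg, ggplot2::aes(x = .data$group, y = .data$unit,
                                      color = .data$mean,
                                      size = .data$frac)) +
      ggplot2::geom_point() +
      ggplot2::scale_size_area(limits = c(0, 1), max_size = 8)
  } else {
    ggplot2::ggplot(agg, ggplot2::aes(x = .data$group, y = .data$unit,
                                      color = .data$frac,
                                      size = .data$mean)) +
      ggplot2::geom_point()
  }
}

#' Scatter plot of a 2D embedding
#'
#' @param emb an `Embedding2D`, see [compute_embedding()].
#' @param color_by `"group"` (categorical; taken from `groups` or from a
#'   categorical overlay) or `"overlay"` (continuous gradient with a
#'   colorbar; requires [attach_overlay()] first). Missing overlay values
#'   are drawn in neutral grey.
#' @param groups optional per-observation group labels (named vector or
#'   `obs_meta` data.frame) for `color_by = "group"`.
#' @param out optional image path.
#' @return a ggplot object.
#' @export
viz_embedding <- function(emb, color_by = c("group", "overlay"),
                          groups = NULL, out = NULL) {
  stopifnot(inherits(emb, "Embedding2D"))
  color_by <- match.arg(color_by)
  df <- data.frame(obs_id = rownames(emb$coords),
                   x = emb$coords[, 1], y = emb$coords[, 2],
                   stringsAsFactors = FALSE)
  if (color_by == "overlay") {
    if (is.null(emb$overlay)) {
      stop("no overlay attached; call attach_overlay() first", call. = FALSE)
    }
    df$color <- as.vector(emb$overlay)
  } else {
    if (!is.null(groups)) {
      df$color <- as_group_vector(groups, df$obs_id)
    } else if (!is.null(emb$overlay) && !is.numeric(emb$overlay)) {
      df$color <- as.vector(emb$overlay)
    } else {
      stop("color_by = 'group' needs group labels (groups argument or a ",
           "categorical overlay)", call. = FALSE)
    }
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        color = .data$color)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "UMAP1", y = "UMAP2", color = color_by) +
    ggplot2::theme_minimal(base_size = 10)
  if (is.numeric(df$color)) {
    lims <- if (all(df$color >= 0 & df$color <= 1, na.rm = TRUE)) c(0, 1)
            else range(df$color, na.rm = TRUE)
    p <- p + ggplot2::scale_color_viridis_c(limits = lims,
                                            na.value = "grey80")
  }
  if (!is.null(out)) save_figure(p, out)
  p
}

#' Multi-gene panel of APA markers
#'
#' `violin`: per-gene RUD distribution by group, one panel per gene (the
#' classic marker panel). `dot`: mean RUD (color) and fraction of
#' observations with defined RUD (size) per gene and group. `heatmap`:
#' gene x group mean RUD.
#'
#' @param rud a `RUDMatrix`.
#' @param markers a `MarkerTable` from [get_apa_markers()].
#' @param genes either a number k (top k marker genes by q-value) or an
#'   explicit character vector of gene ids.
#' @param chart `"violin"`, `"dot"` or `"heatmap"`.
#' @param obs_meta observation metadata with group labels.
#' @param out optional image path.
#' @return a ggplot object.
#' @export
viz_apa_markers <- function(rud, markers, genes = 6,
                            chart = c("violin", "dot", "heatmap"),
                            obs_meta, out = NULL) {
  stopifnot(inherits(rud, "RUDMatrix"))
  chart <- match.arg(chart)
  if (is.numeric(genes)) {
    genes <- utils::head(unique(markers$gene_id), genes)
  } else {
    absent <- setdiff(genes, markers$gene_id)
    if (length(absent) > 0) {
      stop("gene(s) not in the marker table: ",
           paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
    }
  }
  absent <- setdiff(genes, rud$gene_index)
  if (length(absent) > 0) {
    stop("gene(s) not in the RUD matrix: ",
         paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
  }
  if (length(genes) == 0) stop("no genes to plot", call. = FALSE)
  groups <- as_group_vector(obs_meta, colnames(rud$values))
  df <- do.call(rbind, lapply(genes, function(g) {
    data.frame(gene_id = g, obs_id = colnames(rud$values), group = groups,
               rud = rud$values[g, ], stringsAsFactors = FALSE)
  }))
  p <- switch(chart,
    violin = ggplot2::ggplot(df[!is.na(df$rud), ],
                             ggplot2::aes(x = .data$group, y = .data$rud,
                                          fill = .data$group)) +
      ggplot2::geom_violin(scale = "width") +
      ggplot2::facet_wrap(~gene_id) +
      ggplot2::labs(y = "RUD", x = NULL),
    dot = {
      agg <- marker_gene_summary(df)
      ggplot2::ggplot(agg, ggplot2::aes(x = .data$group, y = .data$gene_id,
                                        color = .data$mean_rud,
                                        size = .data$frac_defined)) +
        ggplot2::geom_point() +
        ggplot2::scale_size_area(limits = c(0, 1), max_size = 8) +
        ggplot2::scale_color_viridis_c(limits = c(0, 1))
    },
    heatmap = {
      agg <- marker_gene_summary(df)
      ggplot2::ggplot(agg, ggplot2::aes(x = .data$group, y = .data$gene_id,
                                        fill = .data$mean_rud)) +
        ggplot2::geom_tile() +
        ggplot2::scale_fill_viridis_c(limits = c(0, 1))
    })
  p <- p + ggplot2::theme_minimal(base_size = 10)
  if (!is.null(out)) save_figure(p, out)
  p
}

marker_gene_summary <- function(df) {
  out <- do.call(rbind, lapply(split(df, list(df$gene_id, df$group)),
    function(d) data.frame(gene_id = d$gene_id[1], group = d$group[1],
                           mean_rud = mean(d$rud, na.rm = TRUE),
                           frac_defined = mean(!is.na(d$rud)),
                           stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
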