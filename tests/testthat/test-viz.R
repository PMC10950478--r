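# shared fixture: a small simulated dataset with annotation and alignments
viz_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- sim_config(n_genes = 6, n_cells_per_group = 8, depth_mean = 20,
                      seed = 21)
    sim <- simulate_pac(cfg)
    gtf <- tempfile(fileext = ".gtf")
    simulate_gtf(cfg, gtf)
    anno <- load_annotation(gtf)
    pac <- annotate_sites(sim$pac, anno)
    dir <- tempfile()
    bams <- simulate_alignments(cfg, pac, dir)
    rud <- compute_rud(pac, min_counts = 2)
    cache <<- list(cfg = cfg, pac = pac, anno = anno, bams = bams,
                   rud = rud)
    cache
  }
})

test_that("track figures carry the planted marks and shared x-limits", {
  fx <- viz_fixture()
  fig <- viz_tracks(fx$pac, fx$anno, "g0001", alignments_by_group = fx$bams)
  expect_s3_class(fig, "TrackFigure")
  # gene, pA, one coverage track per group (in group order), cells
  expect_identical(names(fig$tracks),
                   c("gene_model", "pA", "coverage_G1", "coverage_G2",
                     "coverage_G3", "cells"))
  # the pA track marks exactly the two planted site coordinates
  lay_coords <- fx$pac$site_meta$coord[fx$pac$site_meta$gene_id == "g0001"]
  expect_setequal(fig$tracks$pA$sites$coord, lay_coords)
  expect_equal(nrow(fig$tracks$pA$sites), 2)
  # every track shares identical x-limits
  lims <- lapply(fig$tracks, `[[`, "xlim")
  expect_length(unique(lims), 1)
  expect_equal(lims[[1]], c(fig$region$start, fig$region$end))
  # coverage arrays span the whole region
  expect_length(fig$tracks$coverage_G1$profile$depth,
                fig$region$end - fig$region$start + 1)
  # region is the gene span plus the 3' margin (+ strand gene here)
  g <- fx$anno$genes[fx$anno$genes$gene_id == "g0001", ]
  expect_equal(c(fig$region$start, fig$region$end),
               c(g$start, g$end + 1000))
  # without alignments the coverage tracks are simply absent
  fig2 <- viz_tracks(fx$pac, fx$anno, "g0001")
  expect_identical(names(fig2$tracks), c("gene_model", "pA", "cells"))
  # cells track: cells ordered by group, counts matrix sites x cells
  expect_identical(dim(fig2$tracks$cells$counts),
                   c(2L, nrow(fx$pac$obs_meta)))
  expect_identical(unique(fig2$tracks$cells$groups), c("G1", "G2", "G3"))
  # rendering and saving works for both formats
  expect_s3_class(plot(fig2), "patchwork")
  out <- tempfile(fileext = ".pdf")
  viz_tracks(fx$pac, fx$anno, "g0002", out = out)
  expect_true(file.size(out) > 0)
})

test_that("figure construction does not mutate its inputs", {
  fx <- viz_fixture()
  pac_before <- list(counts = as.matrix(fx$pac$counts),
                     site_meta = fx$pac$site_meta,
                     obs_meta = fx$pac$obs_meta)
  rud_before <- fx$rud$values
  invisible(viz_tracks(fx$pac, fx$anno, "g0001",
                       alignments_by_group = fx$bams))
  invisible(viz_stats(fx$pac, "g0001", "box", "site_expression"))
  invisible(viz_apa_markers(
    fx$rud,
    suppressWarnings(get_apa_markers(fx$rud, fx$pac$obs_meta, "G1", "G3",
                                     min_cells = 3, keep = "all")),
    genes = 2, chart = "heatmap", obs_meta = fx$pac$obs_meta))
  expect_equal(as.matrix(fx$pac$counts), pac_before$counts)
  expect_identical(fx$pac$site_meta, pac_before$site_meta)
  expect_identical(fx$rud$values, rud_before)
})

test_that("stats charts have the expected cardinality per chart type", {
  fx <- viz_fixture()
  p_box <- viz_stats(fx$pac, "g0001", "box", "site_expression")
  # 2 sites x 3 groups -> 6 site-group boxes
  expect_equal(nrow(unique(p_box$data[, c("unit", "group")])), 6)
  p_violin <- viz_stats(fx$rud, "g0001", "violin", "rud",
                        obs_meta = fx$pac$obs_meta)
  expect_equal(length(unique(p_violin$data$group)), 3)
  expect_true(all(p_violin$data$value >= 0 & p_violin$data$value <= 1))
  p_heat <- viz_stats(fx$pac, "g0001", "heatmap", "site_expression")
  expect_equal(nrow(p_heat$data), 2 * nrow(fx$pac$obs_meta))
  # dot and bubble aggregate to site x group
  for (chart in c("dot", "bubble")) {
    p <- viz_stats(fx$pac, "g0001", chart, "site_expression")
    expect_equal(nrow(p$data), 6)
    expect_true(all(p$data$frac > 0 & p$data$frac <= 1))
  }
  expect_error(viz_stats(fx$pac, "g0001", "pie", "site_expression"),
               "violin")
  expect_error(viz_stats(fx$pac, "missing_gene", "box", "site_expression"),
               "missing_gene")
})

test_that("embedding plots color by group or continuous overlay", {
  fx <- viz_fixture()
  emb <- compute_embedding(fx$pac, n_neighbors = 8, seed = 3)
  p_grp <- viz_embedding(emb, "group", groups = fx$pac$obs_meta)
  expect_equal(length(unique(p_grp$data$color)), 3)
  expect_error(viz_embedding(emb, "overlay"), "overlay")
  emb <- attach_overlay(emb, mean_rud_per_obs(fx$rud))
  p_ov <- viz_embedding(emb, "overlay")
  expect_true(is.numeric(p_ov$data$color))
  expect_true(all(p_ov$data$color >= 0 & p_ov$data$color <= 1, na.rm = TRUE))
  out <- tempfile(fileext = ".png")
  viz_embedding(emb, "overlay", out = out)
  expect_true(file.size(out) > 0)
})

test_that("marker panels cover the requested genes and stay in [0,1]", {
  fx <- viz_fixture()
  mk <- suppressWarnings(get_apa_markers(fx$rud, fx$pac$obs_meta, "G1", "G3",
                                         min_cells = 3, keep = "all"))
  p_violin <- viz_apa_markers(fx$rud, mk, genes = 2, chart = "violin",
                              obs_meta = fx$pac$obs_meta)
  expect_equal(length(unique(p_violin$data$gene_id)), 2)
  expect_equal(length(unique(paste(p_violin$data$gene_id,
                                   p_violin$data$group))), 6)
  p_dot <- viz_apa_markers(fx$rud, mk, genes = c("g0001", "g0002"),
                           chart = "dot", obs_meta = fx$pac$obs_meta)
  expect_true(all(p_dot$data$frac_defined > 0 & p_dot$data$frac_defined <= 1))
  p_heat <- viz_apa_markers(fx$rud, mk, genes = 2, chart = "heatmap",
                            obs_meta = fx$pac$obs_meta)
  expect_true(all(p_heat$data$mean_rud >= 0 & p_heat$data$mean_rud <= 1,
                  na.rm = TRUE))
  expect_error(viz_apa_markers(fx$rud, mk, genes = "not_a_gene",
                               obs_meta = fx$pac$obs_meta), "not_a_gene")
})
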