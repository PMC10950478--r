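#' Configuration for the synthetic APA data generator
#'
#' The generator emulates a multi-group single-cell poly(A)-site experiment
#' (e.g. a differentiation time course): `n_genes` two-site genes laid out
#' on a toy chromosome, each with a proximal and a distal cleavage site in
#' its 3'UTR. Per cell, the gene total is negative binomial with mean
#' `depth_mean` and dispersion `dispersion` (variance mu + mu^2/dispersion)
#' and the distal count is binomial given the gene's true RUD in that
#' cell's group. A fraction `frac_shifted` of genes shifts its true RUD
#' linearly across the group order by a total of `delta_rud` (downwards by
#' default: progressive 3'UTR shortening); the remaining genes stay at
#' `base_rud`.
#'
#' @param n_genes number of simulated genes.
#' @param groups ordered character vector of group labels.
#' @param n_cells_per_group cells per group.
#' @param frac_shifted fraction of genes with a planted RUD shift.
#' @param delta_rud total true-RUD shift from the first to the last group.
#' @param base_rud true RUD of unshifted genes (and of shifted genes in the
#'   first group).
#' @param depth_mean mean reads per gene per cell.
#' @param dispersion negative binomial dispersion (size) parameter.
#' @param read_len simulated read length in bp.
#' @param seed integer seed; all generator randomness derives from it.
#' @param shift_dir `"down"` (RUD decreases along the group order, the
#'   default) or `"up"`.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 200,
                       groups = c("G1", "G2", "G3"),
                       n_cells_per_group = 100,
                       frac_shifted = 0.3,
                       delta_rud = 0.4,
                       base_rud = 0.7,
                       depth_mean = 10,
                       dispersion = 2,
                       read_len = 50,
                       seed = 42,
                       shift_dir = c("down", "up")) {
  shift_dir <- match.arg(shift_dir)
  cfg <- list(n_genes = as.integer(n_genes), groups = as.character(groups),
              n_cells_per_group = as.integer(n_cells_per_group),
              frac_shifted = frac_shifted, delta_rud = delta_rud,
              base_rud = base_rud, depth_mean = depth_mean,
              dispersion = dispersion, read_len = as.integer(read_len),
              seed = as.integer(seed), shift_dir = shift_dir)
  if (cfg$n_genes < 0 || cfg$n_cells_per_group < 1 ||
      length(cfg$groups) < 1 || anyDuplicated(cfg$groups)) {
    stop("invalid simulation config: need n_genes >= 0, ",
         "n_cells_per_group >= 1 and distinct group labels", call. = FALSE)
  }
  if (cfg$frac_shifted < 0 || cfg$frac_shifted > 1 ||
      cfg$delta_rud < 0 || cfg$delta_rud > 1 ||
      cfg$base_rud < 0 || cfg$base_rud > 1) {
    stop("frac_shifted, delta_rud and base_rud must lie in [0, 1]",
         call. = FALSE)
  }
  if (cfg$depth_mean <= 0 || cfg$dispersion <= 0 || cfg$read_len < 1) {
    stop("depth_mean, dispersion and read_len must be positive",
         call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Named simulation presets
#'
#' `"strong"`: 3 groups x 100 cells, 200 genes, 30% shifted by a total
#' delta RUD of 0.4 downwards, depth 10 — strong planted signal for
#' marker-recovery and embedding tests. `"null"`: same layout with 50 cells
#' per group and no shift (`delta_rud = 0`), for type-I-error checks.
#'
#' @param name `"strong"` or `"null"`.
#' @param seed integer seed.
#' @return a `sim_config`.
#' @export
sim_preset <- function(name = c("strong", "null"), seed = 42) {
  name <- match.arg(name)
  switch(name,
    strong = sim_config(seed = seed),
    null = sim_config(n_cells_per_group = 50, frac_shifted = 0,
                      delta_rud = 0, seed = seed))
}

# run code under a seed without disturbing the caller's RNG state
with_sim_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic toy genome layout: one chromosome, 2000 bp genes spaced
# 3000 bp apart, alternating strands; two 3'UTR sites per gene
sim_layout <- function(cfg) {
  n <- cfg$n_genes
  if (n == 0) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), prox = integer(0), dist = integer(0),
                      stringsAsFactors = FALSE))
  }
  i <- seq_len(n)
  s <- 1L + (i - 1L) * 3000L
  strand <- ifelse(i %% 2 == 1, "+", "-")
  data.frame(
    gene_id = sprintf("g%04d", i),
    chrom = "chrS",
    strand = strand,
    start = s,
    end = s + 1999L,
    # + strand: UTR3 is [s+1500, s+1999]; - strand: UTR3 is [s, s+499]
    utr3_start = ifelse(strand == "+", s + 1500L, s),
    utr3_end = ifelse(strand == "+", s + 1999L, s + 499L),
    prox = ifelse(strand == "+", s + 1600L, s + 399L),
    dist = ifelse(strand == "+", s + 1900L, s + 99L),
    stringsAsFactors = FALSE)
}

sim_true_rud <- function(cfg) {
  G <- length(cfg$groups)
  step <- if (G > 1) seq(0, 1, length.out = G) else 0
  shift <- cfg$delta_rud * step * if (cfg$shift_dir == "down") -1 else 1
  n_shift <- round(cfg$frac_shifted * cfg$n_genes)
  shifted <- seq_len(cfg$n_genes) <= n_shift
  rud <- matrix(cfg$base_rud, nrow = cfg$n_genes, ncol = G,
                dimnames = list(NULL, cfg$groups))
  if (n_shift > 0) {
    rud[shifted, ] <- pmin(1, pmax(0, rep(cfg$base_rud + shift,
                                          each = n_shift)))
  }
  list(rud = rud, shifted = shifted)
}

#' Simulate a single-cell poly(A)-site dataset with planted APA shifts
#'
#' @param cfg a [sim_config()].
#' @return list with `pac` (a [PACDataset]; two sites per gene, cells
#'   labeled by group) and `truth` (data.frame: `gene_id`, `shifted`, one
#'   true-RUD column per group).
#' @export
simulate_pac <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  lay <- sim_layout(cfg)
  tr <- sim_true_rud(cfg)
  G <- length(cfg$groups)
  n_cells <- G * cfg$n_cells_per_group
  obs_meta <- data.frame(
    obs_id = sprintf("%s_c%03d", rep(cfg$groups, each = cfg$n_cells_per_group),
                     rep(seq_len(cfg$n_cells_per_group), times = G)),
    group = rep(cfg$groups, each = cfg$n_cells_per_group),
    stringsAsFactors = FALSE)
  site_meta <- data.frame(
    site_id = c(rbind(paste0(lay$gene_id, "_prox"),
                      paste0(lay$gene_id, "_dist"))),
    chrom = rep(lay$chrom, each = 2),
    strand = rep(lay$strand, each = 2),
    coord = c(rbind(lay$prox, lay$dist)),
    stringsAsFactors = FALSE)
  counts <- matrix(0, nrow = nrow(site_meta), ncol = n_cells,
                   dimnames = list(site_meta$site_id, obs_meta$obs_id))
  if (cfg$n_genes > 0) {
    with_sim_seed(cfg$seed, {
      for (k in seq_len(G)) {
        cols <- which(obs_meta$group == cfg$groups[k])
        for (g in seq_len(cfg$n_genes)) {
          total <- stats::rnbinom(length(cols), size = cfg$dispersion,
                                  mu = cfg$depth_mean)
          distal <- stats::rbinom(length(cols), size = total,
                                  prob = tr$rud[g, k])
          counts[2 * g - 1, cols] <- total - distal
          counts[2 * g, cols] <- distal
        }
      }
    })
  }
  truth <- data.frame(gene_id = lay$gene_id, shifted = tr$shifted,
                      stringsAsFactors = FALSE)
  for (grp in cfg$groups) truth[[grp]] <- tr$rud[, grp]
  list(pac = PACDataset(counts, site_meta, obs_meta), truth = truth)
}

#' Write the toy-genome GTF matching [simulate_pac()]
#'
#' Genes alternate strands; each gene has two exons, one intron and an
#' explicit `three_prime_utr` containing both simulated sites, so
#' annotating the simulated dataset against this file labels every site
#' `UTR3` with its generating gene.
#'
#' @param cfg a [sim_config()].
#' @param path output GTF path.
#' @return `path`, invisibly.
#' @export
simulate_gtf <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  lay <- sim_layout(cfg)
  lines <- character(0)
  for (i in seq_len(nrow(lay))) {
    g <- lay[i, ]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s.t1";',
                     g$gene_id, g$gene_id)
    rec <- function(type, start, end) {
      sprintf("chrS\tapaviz_sim\t%s\t%d\t%d\t.\t%s\t.\t%s",
              type, start, end, g$strand, attrs)
    }
    # exon layout: [start, start+799] and [start+1000, end]
    lines <- c(lines,
               sprintf('chrS\tapaviz_sim\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                       g$start, g$end, g$strand, g$gene_id),
               rec("transcript", g$start, g$end),
               rec("exon", g$start, g$start + 799L),
               rec("exon", g$start + 1000L, g$end),
               rec("three_prime_utr", g$utr3_start, g$utr3_end))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate per-group alignment files from a PACDataset
#'
#' For each group, counts are aggregated (pseudo-bulk) and each site with
#' aggregated count k yields k reads of length `read_len` whose strand-aware
#' 3' ends sit exactly at the site coordinate — the stacked-read geometry of
#' 3' tag data. Output is one sorted, indexed BAM per group.
#'
#' @param cfg a [sim_config()].
#' @param pac a [PACDataset] from [simulate_pac()].
#' @param out_dir output directory.
#' @return named character vector of BAM paths, one per group.
#' @export
simulate_alignments <- function(cfg, pac, out_dir) {
  stopifnot(inherits(cfg, "sim_config"), inherits(pac, "PACDataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  agg <- aggregate_by_group(pac)
  chrom_len <- max(cfg$n_genes, 1L) * 3000L + 10000L
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:chrS\tLN:%d", chrom_len))
  seqs <- strrep("A", cfg$read_len)
  quals <- strrep("I", cfg$read_len)
  out <- character(0)
  for (grp in agg$obs_meta$obs_id) {
    cnt <- round(as.numeric(agg$counts[, grp]))
    idx <- rep.int(seq_along(cnt), cnt)
    if (length(idx) > 0) {
      coord <- agg$site_meta$coord[idx]
      plus <- agg$site_meta$strand[idx] == "+"
      pos <- ifelse(plus, pmax(1L, coord - cfg$read_len + 1L), coord)
      flag <- ifelse(plus, 0L, 16L)
      reads <- sprintf("%s_read%06d\t%d\tchrS\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                       agg$site_meta$site_id[idx], seq_along(idx), flag,
                       pos, cfg$read_len, seqs, quals)
    } else {
      reads <- character(0)
    }
    sam <- file.path(out_dir, paste0(grp, ".sam"))
    writeLines(c(header, reads), sam)
    raw_bam <- Rsamtools::asBam(sam, file.path(out_dir, paste0(grp, ".unsorted")),
                                overwrite = TRUE, indexDestination = FALSE)
    sorted <- Rsamtools::sortBam(raw_bam, file.path(out_dir, grp))
    Rsamtools::indexBam(sorted)
    file.remove(raw_bam)
    out[grp] <- sorted
  }
  out
}
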