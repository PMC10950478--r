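# Hand-built fixtures and independent brute-force oracles used across tests.
# The oracles deliberately avoid the package's own code paths (GRanges
# overlap machinery, wilcox.test, GenomicAlignments coverage).

# tiny PACDataset with explicit (already-annotated) site metadata
make_pac <- function(counts, site_meta, groups) {
  obs_meta <- data.frame(obs_id = colnames(counts), group = groups,
                         stringsAsFactors = FALSE)
  pac <- PACDataset(counts, site_meta[, c("site_id", "chrom", "strand",
                                          "coord")], obs_meta)
  if ("gene_id" %in% colnames(site_meta)) {
    pac$site_meta$gene_id <- site_meta$gene_id
    pac$site_meta$region <- site_meta$region
  }
  pac
}

# a 2-site + strand gene and a 2-site - strand gene, counts chosen by hand
two_gene_fixture <- function() {
  site_meta <- data.frame(
    site_id = c("a_p", "a_d", "b_p", "b_d"),
    chrom = "chr1",
    strand = c("+", "+", "-", "-"),
    coord = c(900L, 990L, 2990L, 2900L),   # b: distal is the LOWER coord
    gene_id = c("gA", "gA", "gB", "gB"),
    region = "UTR3",
    stringsAsFactors = FALSE)
  counts <- matrix(0, nrow = 4, ncol = 3,
                   dimnames = list(site_meta$site_id, c("c1", "c2", "c3")))
  counts["a_p", ] <- c(8, 2, 1)
  counts["a_d", ] <- c(2, 8, 2)
  counts["b_p", ] <- c(3, 0, 6)   # b_p at 2990 is the proximal site
  counts["b_d", ] <- c(1, 5, 2)
  make_pac(counts, site_meta, groups = c("X", "X", "Y"))
}

# ---- GTF writing ----------------------------------------------------------

gtf_line <- function(chrom, type, start, end, strand, gene, tx = NULL) {
  attrs <- if (is.null(tx)) sprintf('gene_id "%s";', gene) else
    sprintf('gene_id "%s"; transcript_id "%s";', gene, tx)
  sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, type, start, end,
          strand, attrs)
}

# one transcript per gene; exons and utr3 given as data.frames per gene
write_toy_gtf <- function(path, genes, exons, utr3 = NULL, cds = NULL) {
  lines <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    tx <- paste0(g$gene_id, ".t1")
    lines <- c(lines,
               gtf_line(g$chrom, "gene", g$start, g$end, g$strand, g$gene_id),
               gtf_line(g$chrom, "transcript", g$start, g$end, g$strand,
                        g$gene_id, tx))
    ex <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, gtf_line(g$chrom, "exon", ex$start[j], ex$end[j],
                                 g$strand, g$gene_id, tx))
    }
    if (!is.null(utr3)) {
      u <- utr3[utr3$gene_id == g$gene_id, , drop = FALSE]
      for (j in seq_len(nrow(u))) {
        lines <- c(lines, gtf_line(g$chrom, "three_prime_utr", u$start[j],
                                   u$end[j], g$strand, g$gene_id, tx))
      }
    }
    if (!is.null(cds)) {
      cc <- cds[cds$gene_id == g$gene_id, , drop = FALSE]
      for (j in seq_len(nrow(cc))) {
        lines <- c(lines, gtf_line(g$chrom, "CDS", cc$start[j], cc$end[j],
                                   g$strand, g$gene_id, cc$tx[j]))
      }
    }
  }
  writeLines(lines, path)
  path
}

# ---- brute-force site annotation oracle -----------------------------------
# all-pairs containment with the documented priority and tie-breaks,
# written with plain vector arithmetic over the raw interval tables
oracle_annotate <- function(sites, genes, exons, utr3, ext3utr) {
  gi <- match(exons$gene_id, genes$gene_id)
  ex_chrom <- genes$chrom[gi]; ex_strand <- genes$strand[gi]
  ui <- match(utr3$gene_id, genes$gene_id)
  ut_chrom <- genes$chrom[ui]; ut_strand <- genes$strand[ui]
  exmin <- tapply(exons$start, exons$gene_id, min)[genes$gene_id]
  exmax <- tapply(exons$end, exons$gene_id, max)[genes$gene_id]
  three_end <- ifelse(genes$strand == "+", genes$end, genes$start)
  ext_lo <- ifelse(genes$strand == "+", genes$end + 1,
                   pmax(1, genes$start - ext3utr))
  ext_hi <- ifelse(genes$strand == "+", genes$end + ext3utr,
                   genes$start - 1)

  n <- nrow(sites)
  out_gene <- rep(NA_character_, n)
  out_region <- rep("intergenic", n)
  for (i in seq_len(n)) {
    pos <- sites$coord[i]
    chrom <- sites$chrom[i]; strand <- sites$strand[i]
    gm <- genes$chrom == chrom & genes$strand == strand
    utr_genes <- unique(utr3$gene_id[ut_chrom == chrom &
                                     ut_strand == strand &
                                     utr3$start <= pos & utr3$end >= pos])
    in_any_span <- any(gm & genes$start <= pos & genes$end >= pos)
    ext_genes <- if (in_any_span) character(0) else
      genes$gene_id[gm & ext_lo <= pos & ext_hi >= pos]
    exon_genes <- unique(exons$gene_id[ex_chrom == chrom &
                                       ex_strand == strand &
                                       exons$start <= pos &
                                       exons$end >= pos])
    intron_genes <- setdiff(
      genes$gene_id[gm & !is.na(exmin) & exmin <= pos & exmax >= pos],
      exon_genes)
    cand <- rbind(
      if (length(utr_genes)) data.frame(gene_id = utr_genes, prio = 4,
                                        region = "UTR3"),
      if (length(ext_genes)) data.frame(gene_id = ext_genes, prio = 3,
                                        region = "ext_UTR3"),
      if (length(exon_genes)) data.frame(gene_id = exon_genes, prio = 2,
                                         region = "exon"),
      if (length(intron_genes)) data.frame(gene_id = intron_genes, prio = 1,
                                           region = "intron"))
    if (is.null(cand) || nrow(cand) == 0) next
    cand$dist3 <- abs(pos - three_end[match(cand$gene_id, genes$gene_id)])
    best <- cand[order(-cand$prio, cand$dist3, cand$gene_id)[1], ]
    out_gene[i] <- best$gene_id
    out_region[i] <- best$region
  }
  data.frame(gene_id = out_gene, region = out_region,
             stringsAsFactors = FALSE)
}

# run the CLI workflow (simulate -> annotate -> rud -> markers -> umap)
# into `root`; used by the CLI and determinism tests
cli_pipeline <- function(root, seed, preset = "strong") {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  steps <- list(
    c("simulate", "--preset", preset, "--seed", as.character(seed),
      "--out-dir", file.path(root, "sim")),
    c("annotate", "--pac", file.path(root, "sim", "pac"),
      "--gtf", file.path(root, "sim", "annotation.gtf"),
      "--out", file.path(root, "anno")),
    c("rud", "--pac", file.path(root, "anno"),
      "--out", file.path(root, "rud.tsv")),
    c("markers", "--rud", file.path(root, "rud.tsv"),
      "--obs", file.path(root, "sim", "pac", "obs.tsv"),
      "--pairs", "all", "--out", file.path(root, "markers.tsv")),
    c("umap", "--rud", file.path(root, "rud.tsv"),
      "--seed", as.character(seed), "--out", file.path(root, "umap.tsv")))
  codes <- vapply(steps, apaviz_main, integer(1))
  stopifnot(all(codes == 0L))
  invisible(root)
}

# random annotation instance: genes (single transcript, 2 exons, a 3'UTR in
# the 3' exon) plus random sites, returned with the GTF on disk
random_annotation_instance <- function(n_genes, n_sites, path) {
  chroms <- c("c1", "c2")
  starts <- sample.int(50000, n_genes)
  widths <- sample(500:3000, n_genes, replace = TRUE)
  genes <- data.frame(
    gene_id = sprintf("rg%03d", seq_len(n_genes)),
    chrom = sample(chroms, n_genes, replace = TRUE),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    start = starts, end = starts + widths,
    stringsAsFactors = FALSE)
  exons <- do.call(rbind, lapply(seq_len(n_genes), function(k) {
    g <- genes[k, ]
    mid <- g$start + (g$end - g$start) %/% 2
    gap <- min(100L, (g$end - g$start) %/% 4)
    data.frame(gene_id = g$gene_id,
               start = c(g$start, mid + gap),
               end = c(mid - gap, g$end))
  }))
  utr3 <- do.call(rbind, lapply(seq_len(n_genes), function(k) {
    g <- genes[k, ]
    ulen <- max(50L, (g$end - g$start) %/% 5)
    if (g$strand == "+") {
      data.frame(gene_id = g$gene_id, start = g$end - ulen, end = g$end)
    } else {
      data.frame(gene_id = g$gene_id, start = g$start, end = g$start + ulen)
    }
  }))
  write_toy_gtf(path, genes, exons, utr3)
  sites <- data.frame(
    site_id = sprintf("s%04d", seq_len(n_sites)),
    chrom = sample(chroms, n_sites, replace = TRUE),
    strand = sample(c("+", "-"), n_sites, replace = TRUE),
    coord = sample.int(max(genes$end) + 2000L, n_sites),
    stringsAsFactors = FALSE)
  list(genes = genes, exons = exons, utr3 = utr3, sites = sites)
}

# ---- exhaustive rank-sum oracle -------------------------------------------
# two-sided Mann-Whitney p by enumerating all rank assignments (no ties)
oracle_ranksum_p <- function(x, y) {
  n <- length(x); m <- length(y); N <- n + m
  stopifnot(anyDuplicated(c(x, y)) == 0)
  r <- rank(c(x, y))
  U_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(N, n)
  U_all <- colSums(matrix(combs, nrow = n)) - n * (n + 1) / 2
  mu <- n * m / 2
  p <- if (U_obs > mu) 2 * mean(U_all >= U_obs) else 2 * mean(U_all <= U_obs)
  min(1, p)
}

# ---- brute-force coverage oracle ------------------------------------------
# per-read CIGAR walk: M/=/X/D consume reference and add depth, N consumes
# reference only, I/S/H consume none
oracle_coverage <- function(reads, start, end) {
  depth <- rep(0L, max(0L, end - start + 1L))
  for (i in seq_len(nrow(reads))) {
    ref <- reads$pos[i]
    ops <- regmatches(reads$cigar[i],
                      gregexpr("[0-9]+[MIDNSHP=X]", reads$cigar[i]))[[1]]
    for (op in ops) {
      len <- as.integer(sub("[A-Z=]$", "", op))
      code <- sub("^[0-9]+", "", op)
      if (code %in% c("M", "=", "X", "D")) {
        lo <- max(ref, start); hi <- min(ref + len - 1L, end)
        if (lo <= hi) depth[(lo - start + 1L):(hi - start + 1L)] <-
            depth[(lo - start + 1L):(hi - start + 1L)] + 1L
        ref <- ref + len
      } else if (code == "N") {
        ref <- ref + len
      }
    }
  }
  depth
}

# write reads (qname, flag, pos, cigar) as a sorted indexed BAM
write_toy_bam <- function(reads, dir, chrom = "c1", chrom_len = 100000L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  qlen <- vapply(reads$cigar, function(cg) {
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    sum(vapply(ops, function(op) {
      if (sub("^[0-9]+", "", op) %in% c("M", "I", "S", "=", "X"))
        as.integer(sub("[A-Z=]$", "", op)) else 0L
    }, integer(1)))
  }, integer(1))
  lines <- c("@HD\tVN:1.6",
             sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len),
             sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                     reads$qname, reads$flag, chrom, reads$pos, reads$cigar,
                     strrep("A", qlen), strrep("I", qlen)))
  sam <- file.path(dir, "toy.sam")
  writeLines(lines, sam)
  raw <- Rsamtools::asBam(sam, file.path(dir, "toy.unsorted"),
                          overwrite = TRUE, indexDestination = FALSE)
  sorted <- Rsamtools::sortBam(raw, file.path(dir, "toy"))
  Rsamtools::indexBam(sorted)
  sorted
}

# nearest-centroid group recovery on 2D coordinates
centroid_recovery <- function(coords, groups) {
  cents <- rowsum(coords, groups) / as.vector(table(groups)[sort(unique(groups))])
  labs <- rownames(cents)
  assign <- vapply(seq_len(nrow(coords)), function(i) {
    d <- sqrt(rowSums((cents - matrix(coords[i, ], nrow(cents), 2,
                                      byrow = TRUE))^2))
    labs[which.min(d)]
  }, character(1))
  mean(assign == groups)
}
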