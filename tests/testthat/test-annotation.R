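test_that("exon merging, intron derivation and 3'UTR parsing", {
  dir <- withr::local_tempdir()
  # single-transcript gene: exons (1,100), (201,300) -> intron (101,200)
  genes <- data.frame(gene_id = "g1", chrom = "c1", strand = "+",
                      start = 1L, end = 300L)
  exons <- data.frame(gene_id = "g1", start = c(1L, 201L),
                      end = c(100L, 300L))
  utr3 <- data.frame(gene_id = "g1", start = 251L, end = 300L)
  anno <- load_annotation(write_toy_gtf(file.path(dir, "a.gtf"),
                                        genes, exons, utr3))
  intr <- anno$features$intron
  expect_equal(GenomicRanges::start(intr), 101)
  expect_equal(GenomicRanges::end(intr), 200)
  expect_equal(nrow(anno$genes), 1)

  # two transcripts with exons (1,100) and (51,150) merge to (1,150)
  lines <- c(gtf_line("c1", "gene", 1, 150, "+", "g2"),
             gtf_line("c1", "transcript", 1, 100, "+", "g2", "g2.t1"),
             gtf_line("c1", "exon", 1, 100, "+", "g2", "g2.t1"),
             gtf_line("c1", "transcript", 51, 150, "+", "g2", "g2.t2"),
             gtf_line("c1", "exon", 51, 150, "+", "g2", "g2.t2"))
  writeLines(lines, file.path(dir, "b.gtf"))
  anno2 <- load_annotation(file.path(dir, "b.gtf"))
  ex <- anno2$features$exon
  expect_equal(length(ex), 1)
  expect_equal(c(GenomicRanges::start(ex), GenomicRanges::end(ex)),
               c(1, 150))
  expect_equal(length(anno2$features$intron), 0)
})

test_that("3'UTR is derived from CDS + exon when not annotated explicitly", {
  dir <- withr::local_tempdir()
  # + strand: CDS ends at 250 inside exon (201,300) -> UTR3 = (251,300)
  genes <- data.frame(gene_id = "g1", chrom = "c1", strand = "+",
                      start = 1L, end = 300L)
  exons <- data.frame(gene_id = "g1", start = c(1L, 201L),
                      end = c(100L, 300L))
  cds <- data.frame(gene_id = "g1", start = c(10L, 201L),
                    end = c(100L, 250L), tx = "g1.t1")
  anno <- load_annotation(write_toy_gtf(file.path(dir, "c.gtf"),
                                        genes, exons, utr3 = NULL,
                                        cds = cds))
  u <- anno$features$UTR3
  expect_equal(length(u), 1)
  expect_equal(c(GenomicRanges::start(u), GenomicRanges::end(u)),
               c(251, 300))

  # - strand: CDS starts at 120, exon (1,200) -> UTR3 = (1,119)
  genes2 <- data.frame(gene_id = "g2", chrom = "c1", strand = "-",
                       start = 1L, end = 200L)
  exons2 <- data.frame(gene_id = "g2", start = 1L, end = 200L)
  cds2 <- data.frame(gene_id = "g2", start = 120L, end = 190L, tx = "g2.t1")
  anno2 <- load_annotation(write_toy_gtf(file.path(dir, "d.gtf"),
                                         genes2, exons2, utr3 = NULL,
                                         cds = cds2))
  u2 <- anno2$features$UTR3
  expect_equal(c(GenomicRanges::start(u2), GenomicRanges::end(u2)),
               c(1, 119))
})

test_that("gene without exons is kept with a warning", {
  dir <- withr::local_tempdir()
  lines <- c(gtf_line("c1", "gene", 1, 500, "+", "g1"),
             gtf_line("c1", "gene", 1000, 1500, "+", "g2"),
             gtf_line("c1", "transcript", 1000, 1500, "+", "g2", "g2.t1"),
             gtf_line("c1", "exon", 1000, 1500, "+", "g2", "g2.t1"))
  writeLines(lines, file.path(dir, "e.gtf"))
  expect_warning(anno <- load_annotation(file.path(dir, "e.gtf")),
                 "without exon")
  expect_setequal(anno$genes$gene_id, c("g1", "g2"))
})

make_single_gene_anno <- function(dir) {
  genes <- data.frame(gene_id = "gA", chrom = "c1", strand = "+",
                      start = 1L, end = 1000L)
  exons <- data.frame(gene_id = "gA", start = c(1L, 501L),
                      end = c(400L, 1000L))
  utr3 <- data.frame(gene_id = "gA", start = 901L, end = 1000L)
  load_annotation(write_toy_gtf(file.path(dir, "g.gtf"), genes, exons, utr3))
}

test_that("site assignment follows the region priority and strand", {
  dir <- withr::local_tempdir()
  anno <- make_single_gene_anno(dir)
  sm <- data.frame(
    site_id = c("in_utr", "in_ext", "in_exon", "in_intron", "wrong_strand",
                "far_away", "other_chrom"),
    chrom = c(rep("c1", 6), "c9"),
    strand = c("+", "+", "+", "+", "-", "+", "+"),
    coord = c(950L, 1200L, 100L, 450L, 950L, 5000L, 950L))
  pac <- PACDataset(matrix(0, 7, 1, dimnames = list(sm$site_id, "c1")),
                    sm, data.frame(obs_id = "c1", group = "A"))
  expect_warning(ann <- annotate_sites(pac, anno, ext3utr = 1000),
                 "intergenic")
  got <- ann$site_meta
  expect_identical(got$region,
                   c("UTR3", "ext_UTR3", "exon", "intron", "intergenic",
                     "intergenic", "intergenic"))
  expect_identical(got$gene_id[1:4], rep("gA", 4))
  expect_true(all(is.na(got$gene_id[5:7])))
  # every site has exactly one region label
  expect_false(anyNA(got$region))

  # idempotence: annotating again changes nothing
  again <- suppressWarnings(annotate_sites(ann, anno, ext3utr = 1000))
  expect_identical(again$site_meta, ann$site_meta)
})

test_that("ext_UTR3 windows are trimmed at same-strand downstream genes", {
  dir <- withr::local_tempdir()
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "c1",
                      strand = "+", start = c(1L, 1301L),
                      end = c(1000L, 2300L))
  exons <- data.frame(gene_id = c("gA", "gB"), start = c(1L, 1301L),
                      end = c(1000L, 2300L))
  utr3 <- data.frame(gene_id = c("gA", "gB"), start = c(901L, 2201L),
                     end = c(1000L, 2300L))
  anno <- load_annotation(write_toy_gtf(file.path(dir, "h.gtf"),
                                        genes, exons, utr3))
  sm <- data.frame(site_id = c("between", "inside_gB"),
                   chrom = "c1", strand = "+", coord = c(1100L, 1400L))
  pac <- PACDataset(matrix(0, 2, 1, dimnames = list(sm$site_id, "c1")),
                    sm, data.frame(obs_id = "c1", group = "A"))
  ann <- annotate_sites(pac, anno, ext3utr = 1000)
  # 1100 is in gA's extended window; 1400 falls inside gB's span, so the
  # window is trimmed there and the site is gB exon instead
  expect_identical(ann$site_meta$region, c("ext_UTR3", "exon"))
  expect_identical(ann$site_meta$gene_id, c("gA", "gB"))
})

test_that("assignment matches the brute-force all-pairs oracle", {
  withr::local_seed(20240901)
  dir <- withr::local_tempdir()
  for (rep in 1:5) {
    inst <- random_annotation_instance(n_genes = 25, n_sites = 120,
                                       file.path(dir, paste0(rep, ".gtf")))
    anno <- load_annotation(file.path(dir, paste0(rep, ".gtf")))
    pac <- PACDataset(
      matrix(0, nrow(inst$sites), 1,
             dimnames = list(inst$sites$site_id, "c1")),
      inst$sites, data.frame(obs_id = "c1", group = "A"))
    ann <- suppressWarnings(annotate_sites(pac, anno, ext3utr = 1000))
    expected <- oracle_annotate(inst$sites, inst$genes, inst$exons,
                                inst$utr3, ext3utr = 1000)
    expect_identical(ann$site_meta$region, expected$region)
    expect_identical(ann$site_meta$gene_id, expected$gene_id)
  }
})
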