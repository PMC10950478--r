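#' Parsed gene models for poly(A)-site annotation
#'
#' `load_annotation` parses a GTF or GFF3 file into a `GenomeAnnotation`:
#' a gene table (span, strand) plus, per gene, merged feature intervals for
#' the 3'UTR, exons and introns. Features are merged per gene across
#' transcripts (union), because poly(A) sites are gene-level points; introns
#' are the within-gene gaps between merged exons. When the file carries no
#' explicit `three_prime_utr` records, the 3'UTR is derived per transcript
#' as the exonic region strand-downstream of the CDS 3' end, then unioned
#' across transcripts.
#'
#' @param gtf_path path to a GTF (`gene_id "x"`) or GFF3 (`gene_id=x` or
#'   `ID`/`Parent` chains) annotation file.
#' @return an object of class `GenomeAnnotation` with elements `genes`
#'   (data.frame: `gene_id`, `chrom`, `strand`, `start`, `end`) and
#'   `features` (named list of `GRanges` for `UTR3`, `exon`, `intron`, each
#'   carrying a `gene_id` metadata column).
#' @export
load_annotation <- function(gtf_path) {
  if (!file.exists(gtf_path)) {
    stop("annotation file not found: ", gtf_path, call. = FALSE)
  }
  gr <- tryCatch(
    rtracklayer::import(gtf_path),
    error = function(e) {
      stop("failed to parse annotation ", gtf_path, ": ",
           conditionMessage(e), call. = FALSE)
    })
  if (!"type" %in% colnames(S4Vectors::mcols(gr))) {
    stop("annotation has no feature type column: ", gtf_path, call. = FALSE)
  }
  gr$gene_id <- resolve_gene_ids(gr)
  type <- tolower(as.character(gr$type))

  exons <- gr[type == "exon" & !is.na(gr$gene_id)]
  utr3 <- gr[type %in% c("three_prime_utr", "3utr", "three_prime_utr") &
               !is.na(gr$gene_id)]

  gene_rec <- gr[type == "gene" & !is.na(gr$gene_id)]
  if (length(gene_rec) > 0) {
    genes <- data.frame(
      gene_id = gene_rec$gene_id,
      chrom = as.character(GenomicRanges::seqnames(gene_rec)),
      strand = as.character(GenomicRanges::strand(gene_rec)),
      start = GenomicRanges::start(gene_rec),
      end = GenomicRanges::end(gene_rec),
      stringsAsFactors = FALSE)
  } else {
    # no explicit gene records: span = range over the gene's features
    feat <- gr[!is.na(gr$gene_id)]
    spl <- split(feat, feat$gene_id)
    rng <- unlist(range(spl))
    genes <- data.frame(
      gene_id = names(rng),
      chrom = as.character(GenomicRanges::seqnames(rng)),
      strand = as.character(GenomicRanges::strand(rng)),
      start = GenomicRanges::start(rng),
      end = GenomicRanges::end(rng),
      stringsAsFactors = FALSE)
  }
  genes <- genes[!duplicated(genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL

  no_exon <- setdiff(genes$gene_id, unique(exons$gene_id))
  if (length(no_exon) > 0) {
    warning(length(no_exon), " gene(s) without exon records kept with span only: ",
            paste(utils::head(no_exon, 5), collapse = ", "), call. = FALSE)
  }

  exon_merged <- merge_by_gene(exons)
  if (length(utr3) == 0) {
    utr3_merged <- derive_utr3(gr, type)
  } else {
    utr3_merged <- merge_by_gene(utr3)
  }
  intron_merged <- intron_gaps(exon_merged)

  structure(
    list(genes = genes,
         features = list(UTR3 = utr3_merged,
                         exon = exon_merged,
                         intron = intron_merged)),
    class = "GenomeAnnotation")
}

# gene_id attribute if present; else walk exon Parent -> transcript ID ->
# transcript Parent -> gene ID (GFF3 without gene_id attributes).
resolve_gene_ids <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  gid <- if ("gene_id" %in% colnames(mc)) as.character(mc$gene_id) else
    rep(NA_character_, length(gr))
  if (!anyNA(gid)) return(gid)
  if (!all(c("ID", "Parent") %in% colnames(mc))) return(gid)
  id <- as.character(mc$ID)
  parent <- vapply(mc$Parent, function(p)
    if (length(p) > 0) as.character(p[1]) else NA_character_, character(1))
  parent_of <- stats::setNames(parent, id)
  need <- which(is.na(gid) & !is.na(parent))
  for (i in need) {
    p <- parent[i]
    # climb at most two levels (feature -> transcript -> gene)
    for (step in 1:2) {
      if (is.na(p)) break
      up <- parent_of[p]
      if (is.na(up)) break
      p <- unname(up)
    }
    gid[i] <- p
  }
  gid
}

merge_by_gene <- function(gr) {
  if (length(gr) == 0) {
    out <- GenomicRanges::GRanges()
    out$gene_id <- character(0)
    return(out)
  }
  spl <- GenomicRanges::split(gr, gr$gene_id)
  red <- GenomicRanges::reduce(spl)
  out <- unlist(red, use.names = TRUE)
  out$gene_id <- names(out)
  names(out) <- NULL
  out
}

intron_gaps <- function(exon_merged) {
  if (length(exon_merged) == 0) {
    out <- GenomicRanges::GRanges()
    out$gene_id <- character(0)
    return(out)
  }
  spl <- GenomicRanges::split(exon_merged, exon_merged$gene_id)
  gaps <- S4Vectors::endoapply(spl, function(g) {
    GenomicRanges::setdiff(range(g), g)
  })
  out <- unlist(gaps, use.names = TRUE)
  out$gene_id <- names(out)
  names(out) <- NULL
  out
}

# per transcript: exonic bases strand-downstream of the CDS 3' end,
# unioned over transcripts of each gene
derive_utr3 <- function(gr, type) {
  mc <- S4Vectors::mcols(gr)
  tx_col <- if ("transcript_id" %in% colnames(mc)) "transcript_id" else NULL
  cds <- gr[type == "cds"]
  exons <- gr[type == "exon"]
  if (length(cds) == 0 || is.null(tx_col)) {
    out <- GenomicRanges::GRanges()
    out$gene_id <- character(0)
    return(out)
  }
  cds_tx <- split(cds, as.character(S4Vectors::mcols(cds)[[tx_col]]))
  ex_tx <- split(exons, as.character(S4Vectors::mcols(exons)[[tx_col]]))
  pieces <- list()
  for (tx in names(cds_tx)) {
    if (!tx %in% names(ex_tx)) next
    cr <- range(cds_tx[[tx]])
    ex <- GenomicRanges::reduce(ex_tx[[tx]])
    strand_tx <- as.character(GenomicRanges::strand(cr))[1]
    chrom_tx <- as.character(GenomicRanges::seqnames(cr))[1]
    gid <- as.character(S4Vectors::mcols(cds_tx[[tx]])$gene_id[1])
    ex_end <- max(GenomicRanges::end(ex))
    ex_start <- min(GenomicRanges::start(ex))
    if (strand_tx == "+") {
      lo <- GenomicRanges::end(cr) + 1
      hi <- ex_end
    } else {
      lo <- ex_start
      hi <- GenomicRanges::start(cr) - 1
    }
    if (lo > hi) next
    win <- GenomicRanges::GRanges(chrom_tx,
                                  IRanges::IRanges(lo, hi),
                                  strand = strand_tx)
    u <- GenomicRanges::intersect(ex, win)
    if (length(u) > 0) {
      u$gene_id <- gid
      pieces[[length(pieces) + 1L]] <- u
    }
  }
  if (length(pieces) == 0) {
    out <- GenomicRanges::GRanges()
    out$gene_id <- character(0)
    return(out)
  }
  merge_by_gene(do.call(c, pieces))
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat(sprintf("GenomeAnnotation: %d genes\n", nrow(x$genes)))
  for (f in names(x$features)) {
    cat(sprintf("  %s intervals: %d\n", f, length(x$features[[f]])))
  }
  invisible(x)
}

#' Assign each poly(A) site to a gene and genomic region
#'
#' Strand-matched assignment with region priority
#' `UTR3 > ext_UTR3 > exon > intron > intergenic`. The extended 3'UTR
#' (`ext_UTR3`) of a gene is the window of `ext3utr` bp strand-downstream of
#' its 3' end, minus any overlap with a same-strand gene span; it captures
#' distal cleavage sites beyond the annotated gene end. A site matching two
#' genes at equal priority goes to the gene with the nearer 3' end, then to
#' the lexicographically smaller `gene_id`. Sites matching no gene get
#' `region = "intergenic"` and a missing `gene_id`; re-annotating with the
#' same inputs is a no-op.
#'
#' @param pac a [PACDataset] with `chrom`, `strand`, `coord` site metadata.
#' @param anno a `GenomeAnnotation` from [load_annotation()].
#' @param ext3utr extended-3'UTR window length in bp (default 1000).
#' @return the [PACDataset] with `gene_id` and `region` columns filled in.
#' @export
annotate_sites <- function(pac, anno, ext3utr = 1000) {
  stopifnot(inherits(pac, "PACDataset"), inherits(anno, "GenomeAnnotation"))
  stopifnot(is.numeric(ext3utr), length(ext3utr) == 1, ext3utr >= 0)
  sm <- pac$site_meta
  n <- nrow(sm)
  gene_id <- rep(NA_character_, n)
  region <- rep("intergenic", n)
  if (n > 0 && nrow(anno$genes) > 0) {
    sites <- GenomicRanges::GRanges(sm$chrom,
                                    IRanges::IRanges(sm$coord, sm$coord),
                                    strand = sm$strand)
    feats <- list(UTR3 = anno$features$UTR3,
                  ext_UTR3 = ext_utr3_windows(anno, ext3utr),
                  exon = anno$features$exon,
                  intron = anno$features$intron)
    priority <- c(UTR3 = 4L, ext_UTR3 = 3L, exon = 2L, intron = 1L)
    three_end <- ifelse(anno$genes$strand == "+",
                        anno$genes$end, anno$genes$start)
    names(three_end) <- anno$genes$gene_id

    cand <- list()
    for (f in names(feats)) {
      fg <- feats[[f]]
      if (length(fg) == 0) next
      hits <- GenomicRanges::findOverlaps(sites, fg, ignore.strand = FALSE)
      if (length(hits) == 0) next
      cand[[f]] <- data.frame(
        site = S4Vectors::queryHits(hits),
        gene = fg$gene_id[S4Vectors::subjectHits(hits)],
        region = f,
        prio = priority[[f]],
        stringsAsFactors = FALSE)
    }
    if (length(cand) > 0) {
      cand <- do.call(rbind, cand)
      cand$dist3 <- abs(sm$coord[cand$site] - three_end[cand$gene])
      # order: per site, highest priority first, then nearer 3' end,
      # then smaller gene_id; keep the first row per site
      o <- order(cand$site, -cand$prio, cand$dist3, cand$gene)
      cand <- cand[o, , drop = FALSE]
      keep <- cand[!duplicated(cand$site), , drop = FALSE]
      gene_id[keep$site] <- keep$gene
      region[keep$site] <- keep$region
    }
    unseen <- !(sm$chrom %in% unique(anno$genes$chrom))
    if (any(unseen)) {
      warning(sum(unseen),
              " site(s) on chromosomes absent from the annotation were ",
              "labeled intergenic", call. = FALSE)
    }
  }
  pac$site_meta$gene_id <- gene_id
  pac$site_meta$region <- region
  pac
}

# strand-downstream windows past each gene's 3' end, clipped against all
# same-strand gene spans
ext_utr3_windows <- function(anno, ext3utr) {
  g <- anno$genes
  if (ext3utr == 0 || nrow(g) == 0) {
    out <- GenomicRanges::GRanges()
    out$gene_id <- character(0)
    return(out)
  }
  plus <- g$strand == "+"
  lo <- ifelse(plus, g$end + 1, pmax(1, g$start - ext3utr))
  hi <- ifelse(plus, g$end + ext3utr, g$start - 1)
  ok <- lo <= hi
  win <- GenomicRanges::GRanges(g$chrom[ok],
                                IRanges::IRanges(lo[ok], hi[ok]),
                                strand = g$strand[ok])
  win$gene_id <- g$gene_id[ok]
  spans <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end),
                                  strand = g$strand)
  pieces <- GenomicRanges::subtract(win, spans, ignore.strand = FALSE)
  out <- unlist(pieces, use.names = FALSE)
  if (length(out) == 0) {
    out <- GenomicRanges::GRanges()
    out$gene_id <- character(0)
    return(out)
  }
  out$gene_id <- rep(win$gene_id, S4Vectors::elementNROWS(pieces))
  out
}
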