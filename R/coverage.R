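#' Per-base read coverage over a genomic region
#'
#' Depth at each base of `[start, end]` counting aligned (match or
#' deletion) bases of reads overlapping the region, from a sorted, indexed
#' BAM file. With `strand_mode = "same_as_gene"` only reads whose
#' orientation matches `gene_strand` are counted; the default `"both"` is
#' unstranded.
#'
#' @param bam_path path to a sorted BAM with a `.bai` index.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive region bounds; `end < start` yields a
#'   length-0 profile.
#' @param strand_mode `"both"` or `"same_as_gene"`.
#' @param gene_strand focus-gene strand, required for
#'   `strand_mode = "same_as_gene"`.
#' @param group optional group label recorded in the profile.
#' @return a `CoverageProfile`: integer `depth` of length
#'   `end - start + 1`, plus `chrom`, `start`, `end`, `group`,
#'   `strand_mode`.
#' @export
compute_coverage <- function(bam_path, chrom, start, end,
                             strand_mode = c("both", "same_as_gene"),
                             gene_strand = NULL, group = NA_character_) {
  strand_mode <- match.arg(strand_mode)
  if (!file.exists(bam_path)) {
    stop("alignment file not found: ", bam_path, call. = FALSE)
  }
  if (!file.exists(paste0(bam_path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam_path))) {
    stop("alignment file is not indexed (no .bai): ", bam_path,
         call. = FALSE)
  }
  if (strand_mode == "same_as_gene" && is.null(gene_strand)) {
    stop("gene_strand is required for strand_mode = 'same_as_gene'",
         call. = FALSE)
  }
  new_profile <- function(depth) {
    structure(list(depth = as.integer(depth), chrom = chrom,
                   start = start, end = end, group = group,
                   strand_mode = strand_mode),
              class = "CoverageProfile")
  }
  if (end < start) return(new_profile(integer(0)))

  hdr_seqs <- names(Rsamtools::scanBamHeader(bam_path)[[1]]$targets)
  if (!chrom %in% hdr_seqs) return(new_profile(rep(0L, end - start + 1)))

  which_gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  galn <- GenomicAlignments::readGAlignments(
    bam_path, param = Rsamtools::ScanBamParam(which = which_gr))
  if (strand_mode == "same_as_gene") {
    galn <- galn[as.character(GenomicRanges::strand(galn)) == gene_strand]
  }
  cov <- GenomicAlignments::coverage(galn)
  depth <- rep(0L, end - start + 1)
  if (chrom %in% names(cov)) {
    rle <- cov[[chrom]]
    pos <- start:end
    inside <- pos <= length(rle) & pos >= 1
    if (any(inside)) {
      depth[inside] <- as.integer(rle[pos[inside]])
    }
  }
  new_profile(depth)
}

#' @export
print.CoverageProfile <- function(x, ...) {
  cat(sprintf("CoverageProfile: %s:%d-%d (%d bp), max depth %d%s\n",
              x$chrom, x$start, x$end, length(x$depth),
              if (length(x$depth)) max(x$depth) else 0L,
              if (is.na(x$group)) "" else paste0(", group ", x$group)))
  invisible(x)
}
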