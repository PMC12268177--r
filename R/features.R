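#' Strand-aware promoter windows
#'
#' The promoter covers 1 kb upstream through 0.5 kb downstream of the TSS.
#' In 0-based half-open coordinates the window is `[TSS - up, TSS + down)`
#' on the plus strand and `[TSS - down, TSS + up)` on the minus strand, so
#' the two windows are exact mirror images through the TSS. Windows are
#' clipped to chromosome bounds when lengths are known.
#'
#' @param genes gene `GRanges` (strand set).
#' @param up,down extent upstream / downstream of the TSS (bp).
#' @return Unstranded `GRanges` of promoter windows, one per gene, carrying
#'   `gene_id` when present in `genes`.
#' @examples
#' g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, 12000), "+")
#' promoter_windows(g)  # 1-based 9001..10500 == 0-based [9000, 10500)
#' @export
promoter_windows <- function(genes, up = 1000, down = 500) {
  minus <- as.character(GenomicRanges::strand(genes)) == "-"
  tss <- tss_positions(genes)
  start <- ifelse(minus, tss - down, tss - up)
  end <- ifelse(minus, tss + up - 1L, tss + down - 1L)
  sl <- GenomeInfoDb::seqlengths(genes)[
    as.character(GenomicRanges::seqnames(genes))]
  start <- pmax(start, 1L)
  if (!anyNA(sl)) end <- pmin(end, sl)
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                                IRanges::IRanges(start, end),
                                seqlengths = GenomeInfoDb::seqlengths(genes))
  if (!is.null(genes$gene_id)) out$gene_id <- genes$gene_id
  out
}

# strand-aware 1 kb window past the transcription termination site
downstream_windows <- function(genes, len = 1000) {
  minus <- as.character(GenomicRanges::strand(genes)) == "-"
  start <- ifelse(minus, GenomicRanges::start(genes) - len,
                  GenomicRanges::end(genes) + 1L)
  end <- ifelse(minus, GenomicRanges::start(genes) - 1L,
                GenomicRanges::end(genes) + len)
  keep <- end >= start & end >= 1
  sl <- GenomeInfoDb::seqlengths(genes)[
    as.character(GenomicRanges::seqnames(genes))]
  start <- pmax(start, 1L)
  if (!anyNA(sl)) end <- pmin(end, sl)
  GenomicRanges::GRanges(GenomicRanges::seqnames(genes)[keep],
                         IRanges::IRanges(start[keep], end[keep]),
                         seqlengths = GenomeInfoDb::seqlengths(genes))
}

# absolute exon coordinates from the BED12-style blocks column
exon_granges <- function(genes) {
  if (length(genes) == 0L)
    return(GenomicRanges::GRanges(
      seqlengths = GenomeInfoDb::seqlengths(genes)))
  blocks <- genes$blocks
  n <- lengths(blocks)
  starts <- unlist(IRanges::start(blocks)) +
    rep(GenomicRanges::start(genes), n) - 1L
  widths <- unlist(IRanges::width(blocks))
  GenomicRanges::GRanges(rep(GenomicRanges::seqnames(genes), n),
                         IRanges::IRanges(starts, width = widths),
                         seqlengths = GenomeInfoDb::seqlengths(genes))
}

#' Priority partition of the genome into genomic features
#'
#' Every base is labelled exactly once, by the priority
#' promoter > exon > intron > downstream > distal: promoters are 1 kb
#' upstream / 0.5 kb downstream of the TSS; exons and introns exclude
#' promoter bases; "downstream" is the 1 kb past the transcription
#' termination site minus all higher-priority features; everything left is
#' distal. Overlaps between genes are resolved by the same priority.
#'
#' @param genes gene `GRanges` with a `blocks` exon column.
#' @param genome named vector of chromosome lengths.
#' @param up,down promoter window extent (bp).
#' @param downstream_len downstream window length (bp).
#' @return `GRanges` covering the genome, sorted and disjoint, with a
#'   `label` factor metadata column (levels in priority order).
#' @export
partition_genome <- function(genes, genome, up = 1000, down = 500,
                             downstream_len = 1000) {
  chroms <- GenomicRanges::GRanges(names(genome),
                                   IRanges::IRanges(1L, as.integer(genome)),
                                   seqlengths = genome)
  strip <- function(gr) {
    gr <- GenomicRanges::granges(gr)
    GenomicRanges::strand(gr) <- "*"
    suppressWarnings(GenomeInfoDb::seqlevels(gr) <- names(genome))
    GenomeInfoDb::seqlengths(gr) <- genome
    GenomicRanges::reduce(gr)
  }
  if (length(genes) == 0L) {
    prom <- exon <- intron <- downs <- GenomicRanges::GRanges(
      seqlengths = genome)
  } else {
    prom <- strip(promoter_windows(genes, up, down))
    exons_all <- strip(exon_granges(genes))
    spans <- strip(genes)
    dwin <- strip(downstream_windows(genes, downstream_len))
    exon <- GenomicRanges::setdiff(exons_all, prom)
    intron <- GenomicRanges::setdiff(
      GenomicRanges::setdiff(spans, prom), exons_all)
    downs <- GenomicRanges::setdiff(
      dwin, GenomicRanges::union(prom, spans))
  }
  distal <- chroms
  for (gr in list(prom, exon, intron, downs))
    distal <- GenomicRanges::setdiff(distal, gr)
  pieces <- list(promoter = prom, exon = exon, intron = intron,
                 downstream = downs, distal = distal)
  out <- unlist(methods::as(lapply(pieces, GenomicRanges::granges),
                            "GRangesList"), use.names = FALSE)
  out$label <- factor(rep(names(pieces), lengths(pieces)),
                      levels = feature_levels())
  sort(out)
}

#' Feature labels in priority order
#' @return Character vector of the five feature labels, highest priority
#'   first.
#' @export
feature_levels <- function() {
  c("promoter", "exon", "intron", "downstream", "distal")
}

#' Assign a genomic feature to each region
#'
#' A region gets the label of the highest-priority feature it overlaps by
#' at least 1 bp (`method = "priority"`, matching the partition hierarchy),
#' or of the feature covering most of its bases with priority as tie-break
#' (`method = "majority"`).
#'
#' @param regions `GRanges` to annotate.
#' @param partition a [partition_genome()] result.
#' @param method `"priority"` or `"majority"`.
#' @return Factor of feature labels, one per region.
#' @export
assign_feature <- function(regions, partition,
                           method = c("priority", "majority")) {
  method <- match.arg(method)
  lv <- feature_levels()
  if (length(regions) == 0L) return(factor(character(0), levels = lv))
  hits <- GenomicRanges::findOverlaps(regions, partition,
                                      ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits)
  lab <- partition$label[S4Vectors::subjectHits(hits)]
  rank <- as.integer(lab)
  if (method == "priority") {
    best <- tapply(rank, q, min)
  } else {
    w <- GenomicRanges::width(GenomicRanges::pintersect(
      GenomicRanges::granges(regions)[q],
      GenomicRanges::granges(partition)[S4Vectors::subjectHits(hits)]))
    best <- vapply(split(seq_along(q), q), function(ii) {
      bp <- tapply(w[ii], rank[ii], sum)
      r <- as.integer(names(bp))
      r[order(-bp, r)][1L]  # most bases, priority breaks ties
    }, integer(1))
  }
  out <- rep(NA_integer_, length(regions))
  out[as.integer(names(best))] <- as.integer(best)
  factor(lv[out], levels = lv)
}

#' Fractions of genomic features among DHSs
#'
#' @param dhs `GRanges` of DHSs (or any regions).
#' @param partition a [partition_genome()] result.
#' @param method passed to [assign_feature()].
#' @return Named numeric vector over the five features, summing to 1 (all
#'   zero for an empty input).
#' @export
feature_fractions <- function(dhs, partition,
                              method = c("priority", "majority")) {
  lv <- feature_levels()
  if (length(dhs) == 0L) return(stats::setNames(rep(0, length(lv)), lv))
  tab <- table(assign_feature(dhs, partition, method))
  out <- stats::setNames(as.numeric(tab[lv]) / length(dhs), lv)
  out[is.na(out)] <- 0
  out
}

#' Count DHSs in each gene's linked enhancers
#'
#' Every (DHS, enhancer) overlap of at least 1 bp counts once, so a DHS
#' spanning two enhancers linked to the same gene contributes 2 — matching
#' per-enhancer annotation of enhancer-atlas-style link tables.
#'
#' @param dhs `GRanges` of DHSs.
#' @param links enhancer link table: data.frame `enh_chrom`, `enh_start`,
#'   `enh_end` (0-based half-open), `gene_id`.
#' @return Named integer vector: DHS count per linked gene (genes with
#'   linked enhancers but no overlapping DHS report 0).
#' @export
enhancer_overlap <- function(dhs, links) {
  if (nrow(links) == 0L)
    return(stats::setNames(integer(0), character(0)))
  enh <- GenomicRanges::GRanges(links$enh_chrom,
                                IRanges::IRanges(links$enh_start + 1L,
                                                 links$enh_end))
  cnt <- GenomicRanges::countOverlaps(enh, dhs, ignore.strand = TRUE)
  out <- tapply(cnt, links$gene_id, sum)
  stats::setNames(as.integer(out), names(out))
}
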