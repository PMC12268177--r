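#' Per-gene, per-stage promoter DHS status
#'
#' A gene is DHS-positive at a stage iff at least one DHS overlaps its
#' promoter window at that stage. The pattern code concatenates the
#' per-stage flags (`"0011"` = accessible at the last two of four stages);
#' genes with the all-zero pattern are flagged `no_dhs` and excluded from
#' the pattern gene-set family.
#'
#' @param genes gene `GRanges` with `gene_id`.
#' @param dhs_by_stage named list of DHS `GRanges`, one per stage, in
#'   temporal order.
#' @param up,down promoter window extent (bp).
#' @return data.frame with `gene_id`, one logical column per stage,
#'   `pattern` (character code) and `no_dhs` (logical).
#' @export
promoter_dhs_status <- function(genes, dhs_by_stage, up = 1000, down = 500) {
  stopifnot(!is.null(names(dhs_by_stage)))
  if (length(genes) == 0L) {
    out <- data.frame(gene_id = character(0), stringsAsFactors = FALSE)
    for (s in names(dhs_by_stage)) out[[s]] <- logical(0)
    out$pattern <- character(0)
    out$no_dhs <- logical(0)
    return(out)
  }
  prom <- promoter_windows(genes, up, down)
  status <- vapply(dhs_by_stage, function(dhs) {
    GenomicRanges::countOverlaps(prom, dhs, ignore.strand = TRUE) > 0
  }, logical(length(genes)))
  if (length(genes) == 1L) status <- matrix(status, nrow = 1L)
  colnames(status) <- names(dhs_by_stage)
  out <- data.frame(gene_id = genes$gene_id, status,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out$pattern <- apply(status, 1L, function(x) paste(as.integer(x),
                                                     collapse = ""))
  out$no_dhs <- !rowSums(status)
  out
}

#' The presence/absence pattern gene sets
#'
#' Partitions DHS-positive genes by their stage pattern: with `k` stages
#' there are at most `2^k - 1` sets (the all-absent pattern is excluded),
#' i.e. the 15 gene sets of a four-stage time course. Every gene with at
#' least one positive stage lands in exactly one set.
#'
#' @param status a [promoter_dhs_status()] table.
#' @return Named list of character vectors of gene ids, names are pattern
#'   codes, ordered from all-present downwards.
#' @export
pattern_gene_sets <- function(status) {
  keep <- !status$no_dhs
  sets <- split(status$gene_id[keep], status$pattern[keep])
  sets[order(names(sets), decreasing = TRUE)]
}

#' Classify opening/closing dynamics between two endpoint stages
#'
#' Regions: a last-stage DHS with no overlapping first-stage DHS is
#' `opening`; a first-stage DHS with no overlapping last-stage DHS is
#' `closing` (regions correspond across stages by >= 1 bp overlap). Genes
#' are lifted through their endpoint promoter statuses: absent-then-present
#' is `opening`, present-then-absent `closing`, present at both endpoints
#' `stable_open`, absent at both `stable_closed`.
#'
#' @param dhs_first,dhs_last DHS `GRanges` at the first and last stages.
#' @param status optional [promoter_dhs_status()] table for the gene-level
#'   calls (its first and last stage columns are used).
#' @return A list with `opening`/`closing` region `GRanges` and, when
#'   `status` is given, a data.frame `genes` with `gene_id` and `class`.
#' @export
classify_dynamics <- function(dhs_first, dhs_last, status = NULL) {
  out <- list(
    opening = IRanges::subsetByOverlaps(dhs_last, dhs_first, invert = TRUE),
    closing = IRanges::subsetByOverlaps(dhs_first, dhs_last, invert = TRUE)
  )
  if (!is.null(status)) {
    stage_cols <- setdiff(names(status), c("gene_id", "pattern", "no_dhs"))
    first <- status[[stage_cols[1L]]]
    last <- status[[stage_cols[length(stage_cols)]]]
    cls <- ifelse(!first & last, "opening",
                  ifelse(first & !last, "closing",
                         ifelse(first & last, "stable_open",
                                "stable_closed")))
    out$genes <- data.frame(gene_id = status$gene_id, class = cls,
                            stringsAsFactors = FALSE)
  }
  out
}

#' Promoter histone-mark status and bivalency
#'
#' Reuses the both-replicate reproducibility rule on ChIP peak sets for
#' H3K4me3 and H3K27me3: a mark flag is set iff a reproducible peak
#' overlaps the gene's promoter window. Genes carrying both marks are
#' bivalent; the category is the deterministic function of the two flags.
#'
#' @param genes gene `GRanges` with `gene_id`.
#' @param k4_peaks list of two peak `GRanges` (H3K4me3, one per replicate).
#' @param k27_peaks list of two peak `GRanges` (H3K27me3).
#' @param up,down promoter window extent (bp).
#' @return data.frame `gene_id`, `k4`, `k27`, `category` with category in
#'   `neither`, `K4_only`, `K27_only`, `bivalent`.
#' @export
promoter_mark_status <- function(genes, k4_peaks, k27_peaks,
                                 up = 1000, down = 500) {
  stopifnot(length(k4_peaks) == 2L, length(k27_peaks) == 2L)
  prom <- promoter_windows(genes, up, down)
  flag <- function(peaks) {
    rep_dhs <- reproducible_dhs(peaks[[1L]], peaks[[2L]])
    GenomicRanges::countOverlaps(prom, rep_dhs, ignore.strand = TRUE) > 0
  }
  k4 <- flag(k4_peaks)
  k27 <- flag(k27_peaks)
  category <- ifelse(k4 & k27, "bivalent",
                     ifelse(k4, "K4_only",
                            ifelse(k27, "K27_only", "neither")))
  data.frame(gene_id = genes$gene_id, k4 = k4, k27 = k27,
             category = factor(category, levels = c("neither", "K4_only",
                                                    "K27_only", "bivalent")),
             stringsAsFactors = FALSE)
}
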