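#' Call cut-density peaks on a cut-site track
#'
#' The F-Seq-style caller: per chromosome, the KDE profile
#' ([kde_profile()]) is thresholded at the analytic uniform-background
#' quantile ([background_threshold()]) for the requested tail probability
#' `p`; maximal runs of above-threshold grid points become candidate peaks,
#' runs separated by less than `merge_gap` bp are merged, and merged runs
#' shorter than `min_length` bp are dropped. Each peak carries its maximum
#' density and the Gaussian-null tail probability of that maximum.
#'
#' Tracks with fewer than `min_cuts` cuts on a chromosome return no peaks
#' there: the Gaussian null degenerates as `n -> 0` (at `n = 0` any positive
#' density would exceed the zero threshold).
#'
#' @param cuts cut-site track: data.frame `chrom`, `pos` (0-based).
#' @param genome named vector of chromosome lengths (bp).
#' @param bandwidth KDE bandwidth (bp); 100 resolves promoter-scale windows
#'   for DNase, 200 is the ChIP default used by [promoter_mark_status()].
#' @param p null tail probability for calling (default `1e-6`).
#' @param grid_step KDE grid spacing (bp).
#' @param min_length minimum peak length (bp).
#' @param merge_gap runs closer than this many bp are merged.
#' @param exclusion optional `GRanges` of excluded regions (blacklist, sex
#'   chromosomes): cuts inside are removed first and excluded bases shrink
#'   the effective length of the null.
#' @param min_cuts minimum per-chromosome cut count for calling.
#' @param null_method null-quantile method for [background_threshold()];
#'   the skew-corrected default keeps the far-tail false-positive rate at
#'   its nominal level.
#' @return `GRanges` of peaks with metadata columns `max_density` and
#'   `tail_prob`.
#' @export
call_peaks <- function(cuts, genome, bandwidth = 100, p = 1e-6,
                       grid_step = 10, min_length = 50, merge_gap = 50,
                       exclusion = NULL, min_cuts = 10,
                       null_method = c("cornish_fisher", "gaussian")) {
  null_method <- match.arg(null_method)
  stopifnot(!is.null(names(genome)))
  if (!is.null(exclusion)) cuts <- filter_excluded(cuts, exclusion)
  out <- list()
  for (chrom in names(genome)) {
    pos <- cuts$pos[cuts$chrom == chrom]
    if (length(pos) < min_cuts) next
    L_eff <- genome[[chrom]]
    if (!is.null(exclusion)) {
      excl <- GenomicRanges::reduce(
        exclusion[as.character(GenomicRanges::seqnames(exclusion)) == chrom])
      L_eff <- L_eff - sum(GenomicRanges::width(excl))
    }
    prof <- kde_profile(pos, genome[[chrom]], bandwidth, grid_step)
    thr <- background_threshold(length(pos), L_eff, bandwidth, p,
                                method = null_method)
    pk <- profile_peaks(prof, thr, min_length, merge_gap)
    if (nrow(pk) == 0L) next
    out[[chrom]] <- GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = pk$start0 + 1L, end = pk$end0),
      max_density = pk$max_density,
      tail_prob = density_tail_prob(pk$max_density, length(pos), L_eff,
                                    bandwidth, method = null_method),
      seqlengths = genome
    )
  }
  if (length(out) == 0L)
    return(GenomicRanges::GRanges(max_density = numeric(0),
                                  tail_prob = numeric(0),
                                  seqlengths = genome))
  sort(unlist(methods::as(out, "GRangesList"), use.names = FALSE))
}

# above-threshold runs -> merge close runs -> drop short ones
profile_peaks <- function(prof, thr, min_length, merge_gap) {
  above <- prof$values > thr
  if (!any(above))
    return(data.frame(start0 = integer(0), end0 = integer(0),
                      max_density = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  run_start <- starts[keep]; run_end <- ends[keep]
  # grid index j covers bp [j*step, j*step + step) ; index is 1-based here
  step <- prof$grid_step
  s0 <- (run_start - 1L) * step
  e0 <- run_end * step
  # merge runs whose gap is smaller than merge_gap
  if (length(s0) > 1L) {
    gap <- s0[-1L] - e0[-length(e0)]
    grp <- cumsum(c(TRUE, gap >= merge_gap))
    s0 <- tapply(s0, grp, min)
    e0 <- tapply(e0, grp, max)
  }
  keep_len <- (e0 - s0) >= min_length
  s0 <- s0[keep_len]; e0 <- e0[keep_len]
  maxd <- vapply(seq_along(s0), function(i) {
    j <- seq.int(s0[i] %/% step + 1L, ((e0[i] - 1L) %/% step) + 1L)
    j <- j[j <= length(prof$values)]
    max(prof$values[j])
  }, numeric(1))
  data.frame(start0 = as.integer(s0), end0 = as.integer(pmin(e0, prof$chrom_length)),
             max_density = maxd)
}

#' Replicate-reproducible DNase-hypersensitive sites
#'
#' Applies the both-replicate rule: a DHS is reported wherever a peak from
#' replicate 1 overlaps (by at least 1 bp) a peak from replicate 2. Peaks
#' private to one replicate are discarded. By default each overlapping pair
#' contributes its union span (conservative inclusion for downstream
#' overlap tests); `mode = "intersection"` keeps only the shared bases.
#' Overlapping emitted spans are merged, so the result is sorted and
#' non-overlapping.
#'
#' @param peaks_rep1,peaks_rep2 peak `GRanges` from the two replicates of
#'   one stage.
#' @param mode `"union"` (default) or `"intersection"` span per overlapping
#'   pair.
#' @return `GRanges` of DHSs.
#' @export
reproducible_dhs <- function(peaks_rep1, peaks_rep2,
                             mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  hits <- GenomicRanges::findOverlaps(peaks_rep1, peaks_rep2)
  if (length(hits) == 0L) return(GenomicRanges::granges(peaks_rep1[0]))
  a <- peaks_rep1[S4Vectors::queryHits(hits)]
  b <- peaks_rep2[S4Vectors::subjectHits(hits)]
  spans <- if (mode == "union") {
    GenomicRanges::punion(GenomicRanges::granges(a),
                          GenomicRanges::granges(b), fill.gap = TRUE)
  } else {
    GenomicRanges::pintersect(GenomicRanges::granges(a),
                              GenomicRanges::granges(b))
  }
  GenomicRanges::reduce(sort(spans))
}

#' Remove cuts or regions falling in excluded regions
#'
#' Emulates the removal of ENCODE-blacklist and sex-chromosome signal: cut
#' sites inside an exclusion region are dropped; regions (`GRanges`)
#' overlapping an exclusion region by at least 1 bp are dropped entirely.
#'
#' @param x a cut-site track (data.frame `chrom`, `pos`) or a `GRanges`.
#' @param exclusion `GRanges` of regions to exclude.
#' @return Object of the same type as `x`.
#' @export
filter_excluded <- function(x, exclusion) {
  if (length(exclusion) == 0L) return(x)
  exclusion <- GenomicRanges::reduce(exclusion)
  if (methods::is(x, "GRanges")) {
    return(IRanges::subsetByOverlaps(x, exclusion, invert = TRUE))
  }
  stopifnot(is.data.frame(x), all(c("chrom", "pos") %in% names(x)))
  if (nrow(x) == 0L) return(x)
  gr <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$pos + 1L,
                                                         width = 1L))
  drop <- IRanges::overlapsAny(gr, exclusion)
  x[!drop, , drop = FALSE]
}
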