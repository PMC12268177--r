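#' Simulate a DNase cut-site track for one stage and replicate
#'
#' Cut sites are drawn from an inhomogeneous Poisson process: rate
#' `background_rate` everywhere, raised to
#' `background_rate * accessible_enrichment` inside the promoter windows of
#' genes whose planted dynamic class makes them accessible at the requested
#' stage, and inside enhancers planted as open. The replicate-specific seed
#' is derived from `(seed, stage, replicate)`, so each track is reproducible
#' in isolation.
#'
#' @param truth truth table from [generate_genome()].
#' @param genes gene `GRanges` from [generate_genome()].
#' @param stage stage label (must be one of `config$stages`).
#' @param replicate replicate index (1-based).
#' @param config the [sim_config()] used to build the genome.
#' @param enhancers optional enhancer table; open enhancers receive the
#'   enriched rate at every stage.
#' @return A cut-site track: data.frame `chrom`, `pos` (0-based bp, sorted
#'   within chromosome).
#' @export
simulate_cut_sites <- function(truth, genes, stage, replicate, config,
                               enhancers = NULL) {
  stopifnot(inherits(config, "sim_config"))
  s <- match(stage, config$stages)
  if (is.na(s)) stop("unknown stage: ", stage)
  if (replicate < 1L || replicate > config$n_replicates)
    stop("replicate out of range: ", replicate)

  windows <- accessible_windows(truth, genes, s, config, enhancers)
  genome <- stats::setNames(
    rep(config$chrom_length, config$n_chroms),
    paste0("chr", seq_len(config$n_chroms))
  )
  poisson_track(genome, windows,
                rate = config$background_rate,
                enrichment = config$accessible_enrichment,
                seed = child_seed(config$seed, "dnase", s, replicate))
}

#' Simulate a ChIP cut-site track for one histone mark and replicate
#'
#' Enriched windows of width `2 * peak_halfwidth` are centred on the TSS of
#' every gene whose truth record carries the mark (bivalent genes carry
#' both H3K4me3 and H3K27me3); everywhere else the track is background.
#' Replicates differ only in their derived seed, so both realise the same
#' enriched windows.
#'
#' @inheritParams simulate_cut_sites
#' @param mark `"H3K4me3"` or `"H3K27me3"`.
#' @return A cut-site track data.frame (`chrom`, `pos`).
#' @export
simulate_mark_track <- function(truth, genes, mark, replicate, config) {
  stopifnot(inherits(config, "sim_config"))
  flag <- switch(mark,
                 H3K4me3 = truth$k4,
                 H3K27me3 = truth$k27,
                 stop("unknown mark: ", mark, " (expected H3K4me3 or H3K27me3)"))
  tss <- tss_positions(genes)
  marked <- genes[flag]
  windows <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(marked),
    ranges = IRanges::IRanges(
      start = pmax(1L, tss[flag] - as.integer(config$peak_halfwidth)),
      end = pmin(as.integer(config$chrom_length),
                 tss[flag] + as.integer(config$peak_halfwidth))
    )
  )
  genome <- stats::setNames(
    rep(config$chrom_length, config$n_chroms),
    paste0("chr", seq_len(config$n_chroms))
  )
  poisson_track(genome, windows,
                rate = config$background_rate,
                enrichment = config$accessible_enrichment,
                seed = child_seed(config$seed, paste0("chip_", mark),
                                  0L, replicate))
}

# promoter windows of genes accessible at stage s, plus open enhancers
accessible_windows <- function(truth, genes, s, config, enhancers = NULL) {
  if (nrow(truth) == 0L) {
    win <- GenomicRanges::GRanges()
  } else {
    flags <- accessibility_flags(truth$dynamic_class, config$stages)
    win <- promoter_windows(genes[flags[, s]],
                            up = config$promoter_up,
                            down = config$promoter_down)
  }
  if (!is.null(enhancers) && any(enhancers$open)) {
    e <- enhancers[enhancers$open, , drop = FALSE]
    win <- c(GenomicRanges::granges(win),
             GenomicRanges::GRanges(e$enh_chrom,
                                    IRanges::IRanges(e$enh_start + 1L,
                                                     e$enh_end)))
  }
  win
}

# homogeneous background + extra (enrichment - 1) x rate cuts in windows
poisson_track <- function(genome, windows, rate, enrichment, seed) {
  set.seed(seed)
  out <- vector("list", length(genome))
  win_chrom <- as.character(GenomicRanges::seqnames(windows))
  for (i in seq_along(genome)) {
    chrom <- names(genome)[i]
    L <- genome[[i]]
    n_bg <- stats::rpois(1L, rate * L)
    pos <- floor(stats::runif(n_bg, 0, L))
    w <- windows[win_chrom == chrom]
    if (length(w) > 0 && enrichment > 1) {
      widths <- GenomicRanges::width(w)
      extra <- stats::rpois(length(w), widths * rate * (enrichment - 1))
      if (sum(extra) > 0) {
        starts0 <- rep(GenomicRanges::start(w) - 1L, extra)
        ww <- rep(widths, extra)
        pos <- c(pos, starts0 + floor(stats::runif(sum(extra), 0, ww)))
      }
    }
    out[[i]] <- data.frame(chrom = rep(chrom, length(pos)),
                           pos = sort(as.integer(pos)),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' TSS positions of gene models (1-based)
#'
#' The TSS is the first transcribed base: `start` on the plus strand and
#' `end` on the minus strand.
#'
#' @param genes gene `GRanges`.
#' @return Integer vector of 1-based TSS coordinates.
#' @export
tss_positions <- function(genes) {
  ifelse(as.character(GenomicRanges::strand(genes)) == "-",
         GenomicRanges::end(genes),
         GenomicRanges::start(genes))
}
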