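#' Call per-stage reproducible DHS sets from a simulated bundle
#'
#' Runs the peak caller on every stage/replicate DNase track and applies
#' the both-replicate rule per stage.
#'
#' @param bundle a `sim_bundle`.
#' @param bandwidth,p,grid_step,min_length,merge_gap passed to
#'   [call_peaks()].
#' @param exclusion optional exclusion `GRanges` applied to every track.
#' @return Named list of DHS `GRanges`, one per stage in temporal order.
#' @export
call_stage_dhs <- function(bundle, bandwidth = 100, p = 1e-6,
                           grid_step = 10, min_length = 50, merge_gap = 50,
                           exclusion = NULL) {
  cfg <- bundle$config
  out <- list()
  for (stage in cfg$stages) {
    peaks <- lapply(seq_len(cfg$n_replicates), function(r) {
      call_peaks(bundle$cuts[[paste0(stage, "_rep", r)]], bundle$genome,
                 bandwidth = bandwidth, p = p, grid_step = grid_step,
                 min_length = min_length, merge_gap = merge_gap,
                 exclusion = exclusion)
    })
    dhs <- peaks[[1L]]
    for (r in seq_along(peaks)[-1L]) dhs <- reproducible_dhs(dhs, peaks[[r]])
    out[[stage]] <- dhs
  }
  out
}

#' Precision and recall of a called gene set against the planted truth
#'
#' @param called character vector of called gene ids.
#' @param truth_set character vector of planted gene ids.
#' @return Named numeric vector `precision`, `recall`, `n_called`,
#'   `n_truth`.
#' @export
recovery_metrics <- function(called, truth_set) {
  tp <- length(intersect(called, truth_set))
  c(precision = if (length(called) > 0) tp / length(called) else NA_real_,
    recall = if (length(truth_set) > 0) tp / length(truth_set) else NA_real_,
    n_called = length(called), n_truth = length(truth_set))
}

#' End-to-end analysis of a simulated bundle with truth-based scoring
#'
#' The full accessibility arm of the pipeline on synthetic data: per-stage
#' peak calling and reproducible DHSs, promoter DHS status and pattern gene
#' sets, endpoint opening/closing gene calls, ChIP peak calling (bandwidth
#' `chip_bandwidth`) with bivalency classification, and — because the
#' generator plants the ground truth — precision/recall of the recovered
#' opening, closing and bivalent gene sets.
#'
#' @param bundle a `sim_bundle` from [simulate_bundle()].
#' @param bandwidth DNase KDE bandwidth (bp).
#' @param chip_bandwidth ChIP KDE bandwidth (bp).
#' @param p peak-calling tail probability.
#' @return A list: `dhs_by_stage`, `status`, `pattern_sets`, `dynamics`,
#'   `marks` (gene mark table), `metrics` (named vector with opening /
#'   closing / bivalent precision and recall plus per-stage DHS counts).
#' @export
analyze_bundle <- function(bundle, bandwidth = 100, chip_bandwidth = 200,
                           p = 1e-6) {
  cfg <- bundle$config
  dhs <- call_stage_dhs(bundle, bandwidth = bandwidth, p = p)
  status <- promoter_dhs_status(bundle$genes, dhs,
                                up = cfg$promoter_up,
                                down = cfg$promoter_down)
  sets <- pattern_gene_sets(status)
  dyn <- classify_dynamics(dhs[[1L]], dhs[[length(dhs)]], status)

  mark_tables <- list()
  metrics <- c()
  if (length(bundle$marks) > 0) {
    chip_peaks <- lapply(bundle$marks, function(track)
      call_peaks(track, bundle$genome, bandwidth = chip_bandwidth, p = p))
    k4 <- chip_peaks[grep("^H3K4me3_", names(chip_peaks))]
    k27 <- chip_peaks[grep("^H3K27me3_", names(chip_peaks))]
    if (length(k4) == 2L && length(k27) == 2L) {
      mark_tables <- promoter_mark_status(bundle$genes, k4, k27,
                                          up = cfg$promoter_up,
                                          down = cfg$promoter_down)
    }
  }

  truth <- bundle$truth
  opening_truth <- truth$gene_id[startsWith(truth$dynamic_class,
                                            "opening_at_")]
  closing_truth <- truth$gene_id[startsWith(truth$dynamic_class,
                                            "closing_at_")]
  opening_called <- dyn$genes$gene_id[dyn$genes$class == "opening"]
  closing_called <- dyn$genes$gene_id[dyn$genes$class == "closing"]
  m <- c(stats::setNames(recovery_metrics(opening_called, opening_truth),
                         paste0("opening_", c("precision", "recall",
                                              "n_called", "n_truth"))),
         stats::setNames(recovery_metrics(closing_called, closing_truth),
                         paste0("closing_", c("precision", "recall",
                                              "n_called", "n_truth"))))
  if (length(mark_tables) > 0) {
    bivalent_called <- mark_tables$gene_id[mark_tables$category ==
                                             "bivalent"]
    bivalent_truth <- truth$gene_id[truth$bivalent]
    m <- c(m, stats::setNames(
      recovery_metrics(bivalent_called, bivalent_truth),
      paste0("bivalent_", c("precision", "recall", "n_called", "n_truth"))))
  }
  m <- c(m, stats::setNames(vapply(dhs, length, integer(1)),
                            paste0("n_dhs_", names(dhs))))

  list(dhs_by_stage = dhs, status = status, pattern_sets = sets,
       dynamics = dyn, marks = mark_tables, metrics = m)
}
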