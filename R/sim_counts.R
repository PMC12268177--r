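#' Per-stage mean expression (per kb, per million fragments) of the planted
#' trajectory shapes
#'
#' `flat` genes keep a constant mean; `up` and `down` double or halve per
#' sampled stage; `transient` genes rise at the middle stages and return to
#' baseline. Multiplied by each gene's lognormal baseline from the truth
#' table.
#'
#' @param n_stages number of stages.
#' @return Numeric matrix, rows = trajectory classes, columns = stages.
#' @export
trajectory_means <- function(n_stages) {
  ramp_up <- 2^(seq(0, 3, length.out = n_stages))
  mid <- c(1, rep(6, n_stages - 2L), 1)
  rbind(flat = rep(4, n_stages),
        up = 2 * ramp_up,
        down = 16 / ramp_up,
        transient = mid)
}

#' Simulate the RNA-seq count matrix
#'
#' Counts are negative binomial with mean
#' `trajectory mean x gene length (kb) x effective library depth (millions)`
#' and dispersion `nb_dispersion` (`variance = mu + dispersion * mu^2`).
#' Library depth per sample is `library_size x library_factors[replicate]`,
#' so replicates differ in depth and normalisation is exercised. Sample
#' columns are named `<stage>_rep<r>`.
#'
#' @inheritParams simulate_cut_sites
#' @return A list of class `count_matrix`:
#' \describe{
#'   \item{counts}{integer matrix, genes x samples.}
#'   \item{lengths}{named vector of gene lengths (bp).}
#'   \item{samples}{data.frame `sample`, `stage`, `replicate`,
#'     `library_size`.}
#' }
#' @export
simulate_counts <- function(truth, genes, config) {
  stopifnot(inherits(config, "sim_config"))
  n_stages <- length(config$stages)
  reps <- seq_len(config$n_replicates)
  samples <- expand.grid(replicate = reps, stage = config$stages,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- samples[, c("stage", "replicate")]
  samples$sample <- paste0(samples$stage, "_rep", samples$replicate)
  lib_fac <- rep_len(config$library_factors, config$n_replicates)
  samples$library_size <- config$library_size * lib_fac[samples$replicate]

  n <- nrow(truth)
  len <- stats::setNames(GenomicRanges::width(genes), truth$gene_id)
  counts <- matrix(0L, nrow = n, ncol = nrow(samples),
                   dimnames = list(truth$gene_id, samples$sample))
  if (n > 0L) {
    tm <- trajectory_means(n_stages)
    set.seed(child_seed(config$seed, "counts"))
    for (j in seq_len(nrow(samples))) {
      s <- match(samples$stage[j], config$stages)
      mu <- tm[truth$trajectory_class, s] * truth$baseline *
        (len / 1000) * (samples$library_size[j] / 1e6)
      counts[, j] <- as.integer(if (config$nb_dispersion > 0) {
        stats::rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
      } else {
        stats::rpois(n, mu)
      })
    }
  }
  structure(list(counts = counts, lengths = len,
                 samples = samples[, c("sample", "stage", "replicate",
                                       "library_size")]),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n")
  invisible(x)
}
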