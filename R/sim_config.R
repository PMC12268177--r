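#' Configuration for the synthetic differentiation experiment
#'
#' Builds and validates the parameter set for the miniature genome and the
#' planted ground truth that emulate a DNase-seq / RNA-seq time course over
#' four stages of cortical neuron differentiation (E12.0 NPCs and E13.0,
#' E14.0, E16.0 neurons; two replicates each).
#'
#' The dynamic-accessibility classes are `always_open`, `never_open`,
#' `opening_at_<stage>` and `closing_at_<stage>` for every stage after the
#' first. `opening_at_s` genes have an inaccessible promoter before stage
#' `s` and an accessible one from `s` onwards; `closing_at_s` is the
#' converse. Class fractions are applied by exact quota (largest-remainder
#' rounding, then a seeded shuffle), so planted class counts are
#' deterministic.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length length of each chromosome (bp).
#' @param n_genes total number of genes across the genome.
#' @param stages character vector of stage labels; times for the expression
#'   model are parsed from the trailing digits (E12 -> day 12), honouring the
#'   unequal spacing of the sampled days.
#' @param n_replicates replicates per stage.
#' @param class_fractions named numeric vector over the dynamic classes,
#'   summing to 1.
#' @param trajectory_fractions named fractions over expression trajectory
#'   shapes (`flat`, `up`, `down`, `transient`), summing to 1.
#' @param mark_fractions named fractions of genes planted as `bivalent`,
#'   `k4_only`, `k27_only` (the remainder carries neither mark).
#' @param dmrt_bound_fraction fraction of genes planted as bound by a
#'   Dmrt-family repressor in precursor cells.
#' @param coupling probability that a planted opening (closing) gene is
#'   preferentially given an `up` (`down`) expression trajectory, and that
#'   bivalent / Dmrt-bound flags concentrate on opening genes, emulating the
#'   association between promoter opening and gene activation.
#' @param background_rate DNase cut rate outside accessible windows
#'   (cuts per bp per replicate).
#' @param accessible_enrichment fold enrichment of the cut rate inside
#'   accessible promoter/enhancer windows (> 1).
#' @param peak_halfwidth half-width (bp) of the enriched window planted
#'   around the TSS for ChIP mark tracks.
#' @param nb_dispersion negative-binomial dispersion of the simulated counts
#'   (`variance = mu + dispersion * mu^2`).
#' @param library_size nominal sequenced fragments per RNA-seq sample.
#' @param library_factors per-replicate depth factors (recycled across
#'   stages) so that library sizes differ and normalisation is exercised.
#' @param gene_length_range min/max transcript length (bp).
#' @param n_enhancers number of intergenic enhancers to plant.
#' @param enhancer_open_fraction fraction of enhancers accessible at every
#'   stage.
#' @param promoter_up,promoter_down promoter window extent around the TSS
#'   (bp upstream / downstream), shared with the analysis defaults.
#' @param seed master seed; all randomness derives from it via
#'   [child_seed()].
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_genome()], [simulate_cut_sites()], [simulate_counts()]
#' @export
sim_config <- function(n_chroms = 2L,
                       chrom_length = 5e6,
                       n_genes = 1000L,
                       stages = c("E12", "E13", "E14", "E16"),
                       n_replicates = 2L,
                       class_fractions = NULL,
                       trajectory_fractions = c(flat = 0.40, up = 0.25,
                                                down = 0.20, transient = 0.15),
                       mark_fractions = c(bivalent = 0.10, k4_only = 0.40,
                                          k27_only = 0.05),
                       dmrt_bound_fraction = 0.15,
                       coupling = 0.7,
                       background_rate = 0.01,
                       accessible_enrichment = 8,
                       peak_halfwidth = 750,
                       nb_dispersion = 0.05,
                       library_size = 2e6,
                       library_factors = c(1, 1.25),
                       gene_length_range = c(1500, 4000),
                       n_enhancers = 200L,
                       enhancer_open_fraction = 0.5,
                       promoter_up = 1000,
                       promoter_down = 500,
                       seed = 1L) {
  n_stages <- length(stages)
  if (is.null(class_fractions)) {
    later <- stages[-1]
    class_fractions <- c(
      always_open = 0.40, never_open = 0.20,
      stats::setNames(c(0.05, 0.05, 0.10), paste0("opening_at_", later)),
      stats::setNames(c(0.05, 0.05, 0.10), paste0("closing_at_", later))
    )
  }
  cfg <- list(
    n_chroms = as.integer(n_chroms), chrom_length = as.numeric(chrom_length),
    n_genes = as.integer(n_genes), stages = as.character(stages),
    n_replicates = as.integer(n_replicates),
    class_fractions = class_fractions,
    trajectory_fractions = trajectory_fractions,
    mark_fractions = mark_fractions,
    dmrt_bound_fraction = dmrt_bound_fraction,
    coupling = coupling,
    background_rate = background_rate,
    accessible_enrichment = accessible_enrichment,
    peak_halfwidth = peak_halfwidth,
    nb_dispersion = nb_dispersion,
    library_size = library_size,
    library_factors = library_factors,
    gene_length_range = as.numeric(gene_length_range),
    n_enhancers = as.integer(n_enhancers),
    enhancer_open_fraction = enhancer_open_fraction,
    promoter_up = promoter_up, promoter_down = promoter_down,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg, n_stages)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg, n_stages) {
  stopifnot(cfg$n_chroms >= 1L, cfg$chrom_length > 0, cfg$n_genes >= 0L,
            n_stages >= 2L, cfg$n_replicates >= 1L)
  if (abs(sum(cfg$class_fractions) - 1) > 1e-9)
    stop("class_fractions must sum to 1 (got ", sum(cfg$class_fractions), ")")
  if (abs(sum(cfg$trajectory_fractions) - 1) > 1e-9)
    stop("trajectory_fractions must sum to 1")
  if (any(cfg$class_fractions < 0) || any(cfg$trajectory_fractions < 0))
    stop("fractions must be non-negative")
  if (sum(cfg$mark_fractions) > 1 + 1e-9 || any(cfg$mark_fractions < 0))
    stop("mark_fractions must be non-negative and sum to at most 1")
  if (cfg$accessible_enrichment <= 1)
    stop("accessible_enrichment must exceed 1")
  if (cfg$background_rate < 0 || cfg$nb_dispersion < 0)
    stop("rates and dispersion must be non-negative")
  if (cfg$gene_length_range[1] > cfg$gene_length_range[2] ||
      cfg$gene_length_range[1] <= 0)
    stop("invalid gene_length_range")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_chroms, "chrom x", format(x$chrom_length, big.mark = ","),
      "bp;", x$n_genes, "genes;", length(x$stages), "stages x",
      x$n_replicates, "reps; enrichment", x$accessible_enrichment,
      "; seed", x$seed, "\n")
  invisible(x)
}

#' Stage sampling times implied by the stage labels
#'
#' Parses embryonic-day labels (`E12`, `E13.5`, ...) to numeric times so the
#' time-course regression honours unequal spacing between sampled days.
#' Labels without digits fall back to their rank.
#'
#' @param stages character vector of stage labels.
#' @return Numeric vector of times, one per stage.
#' @export
stage_times <- function(stages) {
  t <- suppressWarnings(as.numeric(sub("^[^0-9]*", "", stages)))
  if (anyNA(t)) t <- seq_along(stages)
  t
}

#' Exact-quota assignment of class labels
#'
#' Turns a named fraction vector into per-class counts by largest-remainder
#' rounding (counts always sum to `n`), then deals the labels out in a
#' seeded shuffle. Used for every planted categorical truth so class counts
#' are deterministic and testable.
#'
#' @param n number of items.
#' @param fractions named non-negative fractions summing to 1.
#' @param seed integer seed for the shuffle.
#' @return Character vector of length `n`.
#' @export
quota_assign <- function(n, fractions, seed) {
  stopifnot(n >= 0, abs(sum(fractions) - 1) < 1e-9)
  if (n == 0L) return(character(0))
  raw <- fractions * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  labels <- rep(names(fractions), times = counts)
  set.seed(seed)
  sample(labels)
}

#' Per-stage accessibility flags implied by a dynamic class
#'
#' @param dynamic_class character vector of class labels
#'   (`always_open`, `never_open`, `opening_at_<stage>`,
#'   `closing_at_<stage>`).
#' @param stages stage labels in temporal order.
#' @return Logical matrix, one row per element of `dynamic_class`, one
#'   column per stage: `TRUE` where the promoter is accessible.
#' @export
accessibility_flags <- function(dynamic_class, stages) {
  n_stages <- length(stages)
  flags <- matrix(FALSE, nrow = length(dynamic_class), ncol = n_stages,
                  dimnames = list(NULL, stages))
  for (i in seq_along(dynamic_class)) {
    cl <- dynamic_class[i]
    if (cl == "always_open") {
      flags[i, ] <- TRUE
    } else if (cl == "never_open") {
      flags[i, ] <- FALSE
    } else if (startsWith(cl, "opening_at_")) {
      s <- match(sub("opening_at_", "", cl), stages)
      if (is.na(s)) stop("unknown stage in class: ", cl)
      flags[i, s:n_stages] <- TRUE
    } else if (startsWith(cl, "closing_at_")) {
      s <- match(sub("closing_at_", "", cl), stages)
      if (is.na(s)) stop("unknown stage in class: ", cl)
      flags[i, seq_len(s - 1L)] <- TRUE
    } else {
      stop("unknown dynamic class: ", cl)
    }
  }
  flags
}
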