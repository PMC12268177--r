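#' Generate the miniature genome, gene models and planted truth
#'
#' Lays out non-overlapping genes (each in its own slot, with enough
#' clearance that promoter and downstream windows of neighbouring genes
#' never collide), plants one intergenic enhancer per selected gene, and
#' draws a per-gene truth record: dynamic accessibility class, expression
#' trajectory shape, histone-mark state (bivalent promoters carry both
#' H3K4me3 and H3K27me3) and Dmrt-repressor binding. All categorical truths
#' are assigned by exact quota (see [quota_assign()]); the `coupling`
#' parameter biases trajectory/mark/Dmrt assignment towards opening genes so
#' that the planted genome reproduces the association between promoter
#' opening, bivalency and gene activation that the analysis is designed to
#' detect.
#'
#' @param config a [sim_config()] object.
#' @return A list with components:
#' \describe{
#'   \item{genome}{named numeric vector of chromosome lengths (bp).}
#'   \item{genes}{`GRanges` (1-based) with metadata columns `gene_id` and
#'     `blocks` (exon ranges relative to the transcript start, BED12-style);
#'     strand set.}
#'   \item{enhancers}{data.frame `enh_chrom, enh_start, enh_end, gene_id,
#'     open` with 0-based half-open coordinates.}
#'   \item{truth}{data.frame, one row per gene: `gene_id`, `dynamic_class`,
#'     `trajectory_class`, `bivalent`, `k4`, `k27`, `dmrt_bound`,
#'     `baseline` (lognormal expression baseline).}
#' }
#' @examples
#' cfg <- sim_config(n_chroms = 1, chrom_length = 2e5, n_genes = 10,
#'                   n_enhancers = 5)
#' g <- generate_genome(cfg)
#' table(g$truth$dynamic_class)
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genome <- stats::setNames(rep(config$chrom_length, config$n_chroms),
                            paste0("chr", seq_len(config$n_chroms)))
  if (config$n_genes == 0L) {
    return(list(genome = genome,
                genes = empty_genes(genome),
                enhancers = empty_enhancers(),
                truth = empty_truth()))
  }

  max_len <- config$gene_length_range[2]
  pad <- 2500  # clearance for promoter/downstream windows + KDE spill
  per_chrom <- diff(round(seq(0, config$n_genes,
                              length.out = config$n_chroms + 1L)))
  margin <- 10000
  slot_width <- floor((config$chrom_length - 2 * margin) / max(per_chrom))
  if (slot_width < max_len + 2 * pad)
    stop("infeasible sizing: ", config$n_genes, " genes x ",
         max_len + 2 * pad, " bp spacing exceeds the ",
         config$n_chroms, " x ", config$chrom_length, " bp genome")

  set.seed(child_seed(config$seed, "gene_layout"))
  chrom <- rep(names(genome), per_chrom)
  slot_idx <- unlist(lapply(per_chrom, seq_len)) - 1L
  slot_start <- margin + slot_idx * slot_width
  len <- round(stats::runif(config$n_genes, config$gene_length_range[1],
                            config$gene_length_range[2]))
  offset <- floor(stats::runif(config$n_genes, pad,
                               slot_width - pad - len + 1))
  start0 <- slot_start + offset             # 0-based tx start
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  gene_id <- sprintf("gene%04d", seq_len(config$n_genes))

  blocks <- lapply(len, function(L) {
    k <- sample(2:4, 1L)
    cuts <- sort(sample.int(L - 1L, 2L * k - 2L))
    w <- diff(c(0L, cuts, L))
    s <- cumsum(c(0L, w[-length(w)]))
    IRanges::IRanges(start = s[seq(1L, 2L * k - 1L, by = 2L)] + 1L,
                     width = w[seq(1L, 2L * k - 1L, by = 2L)])
  })
  genes <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, width = len),
    strand = strand,
    gene_id = gene_id,
    blocks = methods::as(blocks, "IRangesList"),
    seqlengths = genome
  )
  names(genes) <- gene_id

  enhancers <- plant_enhancers(genes, config)
  truth <- plant_truth(gene_id, config)
  list(genome = genome, genes = genes, enhancers = enhancers, truth = truth)
}

empty_genes <- function(genome) {
  GenomicRanges::GRanges(gene_id = character(0),
                         blocks = IRanges::IRangesList(),
                         seqlengths = genome)
}

empty_enhancers <- function() {
  data.frame(enh_chrom = character(0), enh_start = integer(0),
             enh_end = integer(0), gene_id = character(0),
             open = logical(0), stringsAsFactors = FALSE)
}

empty_truth <- function() {
  data.frame(gene_id = character(0), dynamic_class = character(0),
             trajectory_class = character(0), bivalent = logical(0),
             k4 = logical(0), k27 = logical(0), dmrt_bound = logical(0),
             baseline = numeric(0), stringsAsFactors = FALSE)
}

# one enhancer in the intergenic clearance right of each selected gene
plant_enhancers <- function(genes, config) {
  n <- min(config$n_enhancers, length(genes))
  if (n == 0L) return(empty_enhancers())
  set.seed(child_seed(config$seed, "enhancers"))
  idx <- sort(sample(length(genes), n))
  gene_end0 <- GenomicRanges::end(genes)[idx]  # 0-based half-open end
  enh_start <- gene_end0 + 1800L
  width <- 400L
  open <- quota_assign(n, c(open = config$enhancer_open_fraction,
                            closed = 1 - config$enhancer_open_fraction),
                       child_seed(config$seed, "enhancer_open")) == "open"
  data.frame(enh_chrom = as.character(GenomicRanges::seqnames(genes))[idx],
             enh_start = enh_start, enh_end = enh_start + width,
             gene_id = genes$gene_id[idx], open = open,
             stringsAsFactors = FALSE)
}

# quota-based truth with coupled assignment of trajectories and marks
plant_truth <- function(gene_id, config) {
  n <- length(gene_id)
  dynamic <- quota_assign(n, config$class_fractions,
                          child_seed(config$seed, "dynamic_class"))
  opening <- startsWith(dynamic, "opening_at_")
  closing <- startsWith(dynamic, "closing_at_")

  traj <- coupled_labels(
    n, config$trajectory_fractions,
    prefer = list(up = which(opening), down = which(closing)),
    coupling = config$coupling,
    seed = child_seed(config$seed, "trajectory")
  )

  mf <- config$mark_fractions
  mark_fr <- c(mf, none = 1 - sum(mf))
  mark <- coupled_labels(
    n, mark_fr,
    prefer = list(bivalent = which(opening)),
    coupling = config$coupling,
    seed = child_seed(config$seed, "marks")
  )
  bivalent <- mark == "bivalent"
  k4 <- bivalent | mark == "k4_only"
  k27 <- bivalent | mark == "k27_only"

  dmrt <- coupled_labels(
    n, c(bound = config$dmrt_bound_fraction,
         unbound = 1 - config$dmrt_bound_fraction),
    prefer = list(bound = which(bivalent)),
    coupling = config$coupling,
    seed = child_seed(config$seed, "dmrt")
  ) == "bound"

  set.seed(child_seed(config$seed, "baseline"))
  baseline <- stats::rlnorm(n, meanlog = 0, sdlog = 0.5)

  data.frame(gene_id = gene_id, dynamic_class = dynamic,
             trajectory_class = traj, bivalent = bivalent, k4 = k4,
             k27 = k27, dmrt_bound = dmrt, baseline = baseline,
             stringsAsFactors = FALSE)
}

# Deal quota labels to n items; labels named in `prefer` are handed with
# probability `coupling` to the preferred items first (sampled without
# replacement), the rest at random. Counts per label stay exactly the quota.
coupled_labels <- function(n, fractions, prefer, coupling, seed) {
  counts <- table(factor(quota_assign(n, fractions, seed),
                         levels = names(fractions)))
  set.seed(seed + 1L)
  out <- rep(NA_character_, n)
  for (lab in names(prefer)) {
    k <- counts[[lab]]
    if (k == 0L) next
    cand <- setdiff(prefer[[lab]], which(!is.na(out)))
    take <- stats::rbinom(1L, min(k, length(cand)), coupling)
    if (take > 0) out[sample_vec(cand, take)] <- lab
    counts[[lab]] <- k - take
  }
  rest <- which(is.na(out))
  pool <- sample(rep(names(counts), times = as.integer(counts)))
  out[rest] <- pool
  out
}

# sample() without the length-1 surprise
sample_vec <- function(x, k) x[sample.int(length(x), k)]
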