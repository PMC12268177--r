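#' Simulate a complete fixture bundle in memory
#'
#' Runs [generate_genome()], [simulate_cut_sites()] for every stage and
#' replicate, [simulate_mark_track()] for both histone marks, and
#' [simulate_counts()], returning everything in one list.
#'
#' @param config a [sim_config()].
#' @param marks histone marks to simulate (both by default).
#' @return A list of class `sim_bundle` with components `config`, `genome`,
#'   `genes`, `enhancers`, `truth`, `cuts` (named list `<stage>_rep<r>`),
#'   `marks` (named list `<mark>_rep<r>`), `counts`.
#' @export
simulate_bundle <- function(config, marks = c("H3K4me3", "H3K27me3")) {
  g <- generate_genome(config)
  cuts <- list()
  for (stage in config$stages) {
    for (r in seq_len(config$n_replicates)) {
      cuts[[paste0(stage, "_rep", r)]] <-
        simulate_cut_sites(g$truth, g$genes, stage, r, config, g$enhancers)
    }
  }
  mk <- list()
  for (m in marks) {
    for (r in seq_len(config$n_replicates)) {
      mk[[paste0(m, "_rep", r)]] <-
        simulate_mark_track(g$truth, g$genes, m, r, config)
    }
  }
  structure(list(config = config, genome = g$genome, genes = g$genes,
                 enhancers = g$enhancers, truth = g$truth, cuts = cuts,
                 marks = mk,
                 counts = simulate_counts(g$truth, g$genes, config)),
            class = "sim_bundle")
}

#' Write a fixture bundle to disk in plain-text formats
#'
#' Cut-site tracks are written as BED3 (one cut per line, 0-based half-open,
#' `end = start + 1`), gene models as BED12, enhancer links / truth / counts
#' / sample sheet as TSV, and the configuration as YAML. A manifest listing
#' every file with its data row count is written as `manifest.tsv` and
#' returned.
#'
#' @param bundle a `sim_bundle` from [simulate_bundle()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest data.frame (`file`, `rows`).
#' @seealso [read_fixture_bundle()]
#' @export
write_fixture_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- list()
  add <- function(file, rows) manifest[[length(manifest) + 1L]] <<-
    data.frame(file = file, rows = rows, stringsAsFactors = FALSE)

  write_bed3 <- function(track, file) {
    path <- file.path(dir, file)
    dt <- data.table::data.table(chrom = track$chrom, start = track$pos,
                                 end = track$pos + 1L)
    data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
    add(file, nrow(dt))
  }
  for (nm in names(bundle$cuts))
    write_bed3(bundle$cuts[[nm]], paste0("dnase_", nm, ".bed"))
  for (nm in names(bundle$marks))
    write_bed3(bundle$marks[[nm]], paste0("chip_", nm, ".bed"))

  if (length(bundle$genes) > 0) {
    gr <- bundle$genes
    gr$thick <- GenomicRanges::ranges(gr)
    rtracklayer::export(gr, file.path(dir, "genes.bed"), format = "bed")
  } else {
    file.create(file.path(dir, "genes.bed"))
  }
  add("genes.bed", length(bundle$genes))

  write_tsv <- function(df, file) {
    data.table::fwrite(df, file.path(dir, file), sep = "\t")
    add(file, nrow(df))
  }
  write_tsv(bundle$enhancers, "enhancers.tsv")
  write_tsv(bundle$truth, "truth.tsv")
  counts_df <- data.frame(gene_id = rownames(bundle$counts$counts),
                          length_bp = as.integer(bundle$counts$lengths),
                          bundle$counts$counts, check.names = FALSE,
                          stringsAsFactors = FALSE)
  write_tsv(counts_df, "counts.tsv")
  write_tsv(bundle$counts$samples, "samples.tsv")

  cfg <- unclass(bundle$config)
  cfg$class_fractions <- as.list(cfg$class_fractions)
  cfg$trajectory_fractions <- as.list(cfg$trajectory_fractions)
  cfg$mark_fractions <- as.list(cfg$mark_fractions)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  add("config.yaml", length(cfg))

  manifest <- do.call(rbind, manifest)
  data.table::fwrite(manifest, file.path(dir, "manifest.tsv"), sep = "\t")
  invisible(manifest)
}

#' Read a fixture bundle back from disk
#'
#' Inverse of [write_fixture_bundle()]: reconstructs the in-memory bundle
#' (configuration, gene models, tracks, truth and counts) from the
#' plain-text files.
#'
#' @param dir directory written by [write_fixture_bundle()].
#' @return A `sim_bundle` list.
#' @export
read_fixture_bundle <- function(dir) {
  cfg_raw <- yaml::read_yaml(file.path(dir, "config.yaml"))
  for (f in c("class_fractions", "trajectory_fractions", "mark_fractions"))
    cfg_raw[[f]] <- unlist(cfg_raw[[f]])
  cfg_raw$library_factors <- unlist(cfg_raw$library_factors)
  cfg_raw$gene_length_range <- unlist(cfg_raw$gene_length_range)
  config <- do.call(sim_config, cfg_raw)
  genome <- stats::setNames(rep(config$chrom_length, config$n_chroms),
                            paste0("chr", seq_len(config$n_chroms)))

  read_bed3 <- function(file) {
    path <- file.path(dir, file)
    if (file.size(path) == 0)
      return(data.frame(chrom = character(0), pos = integer(0),
                        stringsAsFactors = FALSE))
    dt <- data.table::fread(path, header = FALSE,
                            col.names = c("chrom", "start", "end"))
    data.frame(chrom = dt$chrom, pos = dt$start, stringsAsFactors = FALSE)
  }
  track_files <- list.files(dir, pattern = "^(dnase|chip)_.*\\.bed$")
  cuts <- list(); mk <- list()
  for (f in track_files) {
    nm <- sub("\\.bed$", "", sub("^(dnase|chip)_", "", f))
    if (startsWith(f, "dnase_")) cuts[[nm]] <- read_bed3(f)
    else mk[[nm]] <- read_bed3(f)
  }
  expected <- unlist(lapply(config$stages, function(s)
    paste0(s, "_rep", seq_len(config$n_replicates))))
  cuts <- cuts[expected[expected %in% names(cuts)]]

  genes_path <- file.path(dir, "genes.bed")
  if (file.size(genes_path) > 0) {
    genes <- rtracklayer::import(genes_path, format = "bed")
    genes$gene_id <- genes$name
    names(genes) <- genes$name
    genes$name <- NULL
    genes$score <- NULL
    genes$thick <- NULL
    genes$itemRgb <- NULL
    GenomeInfoDb::seqlevels(genes) <- names(genome)
    GenomeInfoDb::seqlengths(genes) <- genome
  } else {
    genes <- empty_genes(genome)
  }

  enhancers <- as.data.frame(data.table::fread(file.path(dir, "enhancers.tsv")))
  if (nrow(enhancers) == 0L) enhancers <- empty_enhancers()
  truth <- as.data.frame(data.table::fread(file.path(dir, "truth.tsv")))
  if (nrow(truth) == 0L) truth <- empty_truth()

  counts_df <- as.data.frame(data.table::fread(file.path(dir, "counts.tsv")))
  samples <- as.data.frame(data.table::fread(file.path(dir, "samples.tsv")))
  m <- as.matrix(counts_df[, -(1:2), drop = FALSE])
  rownames(m) <- counts_df$gene_id
  storage.mode(m) <- "integer"
  counts <- structure(list(counts = m,
                           lengths = stats::setNames(counts_df$length_bp,
                                                     counts_df$gene_id),
                           samples = samples),
                      class = "count_matrix")

  structure(list(config = config, genome = genome, genes = genes,
                 enhancers = enhancers, truth = truth, cuts = cuts,
                 marks = mk, counts = counts),
            class = "sim_bundle")
}
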