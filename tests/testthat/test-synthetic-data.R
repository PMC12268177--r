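test_that("an empty simulation yields empty genes, truth and files", {
  cfg <- sim_config(n_genes = 0L, n_enhancers = 0L, n_chroms = 1L,
                    chrom_length = 1e5, background_rate = 0)
  g <- generate_genome(cfg)
  expect_length(g$genes, 0L)
  expect_equal(nrow(g$truth), 0L)
  expect_equal(nrow(g$enhancers), 0L)

  b <- simulate_bundle(cfg, marks = character(0))
  dir <- withr::local_tempdir()
  manifest <- write_fixture_bundle(b, dir)
  # everything except the config and the sample sheet is empty
  data_files <- manifest[!manifest$file %in% c("config.yaml",
                                               "samples.tsv"), ]
  expect_true(all(data_files$rows == 0L))
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- small_config(seed = 11L)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$truth, g2$truth)
  expect_identical(as.data.frame(g1$genes), as.data.frame(g2$genes))
  expect_identical(g1$enhancers, g2$enhancers)

  t1 <- simulate_cut_sites(g1$truth, g1$genes, "E14", 2L, cfg)
  t2 <- simulate_cut_sites(g2$truth, g2$genes, "E14", 2L, cfg)
  expect_identical(t1, t2)
  c1 <- simulate_counts(g1$truth, g1$genes, cfg)
  c2 <- simulate_counts(g2$truth, g2$genes, cfg)
  expect_identical(c1$counts, c2$counts)
})

test_that("class fractions are applied by exact quota", {
  fr <- c(always_open = 0.4, never_open = 0.2, opening_at_E16 = 0.2,
          closing_at_E16 = 0.2)
  cfg <- sim_config(n_chroms = 1L, chrom_length = 1e7, n_genes = 1000L,
                    class_fractions = fr, seed = 3L)
  g <- generate_genome(cfg)
  counts <- table(g$truth$dynamic_class)
  expect_equal(as.integer(counts[["opening_at_E16"]]), 200L)
  expect_equal(as.integer(counts[["always_open"]]), 400L)
  expect_equal(sum(counts), 1000L)
})

test_that("quota assignment resolves fractional counts deterministically", {
  lab <- quota_assign(10L, c(a = 0.33, b = 0.33, c = 0.34), seed = 5L)
  expect_equal(sort(as.integer(table(lab))), c(3L, 3L, 4L))
  expect_identical(lab, quota_assign(10L, c(a = 0.33, b = 0.33, c = 0.34),
                                     seed = 5L))
})

test_that("cut-site tracks follow the planted inhomogeneous Poisson rates", {
  cfg <- sim_config(n_chroms = 1L, chrom_length = 2e6, n_genes = 100L,
                    n_enhancers = 0L, background_rate = 0.01,
                    accessible_enrichment = 8, seed = 13L)
  g <- generate_genome(cfg)
  track <- simulate_cut_sites(g$truth, g$genes, "E12", 1L, cfg)
  expect_true(all(track$pos >= 0 & track$pos < cfg$chrom_length))
  expect_false(is.unsorted(track$pos))

  flags <- accessibility_flags(g$truth$dynamic_class, cfg$stages)
  prom <- promoter_windows(g$genes, cfg$promoter_up, cfg$promoter_down)
  open_w <- prom[flags[, 1L]]
  closed_w <- prom[!flags[, 1L]]
  in_open <- sum(IRanges::overlapsAny(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(track$pos + 1L, width = 1L)),
    open_w))
  open_bp <- sum(GenomicRanges::width(open_w))
  closed_bp <- sum(GenomicRanges::width(closed_w))
  rate_open <- in_open / open_bp
  expected_open <- cfg$background_rate * cfg$accessible_enrichment
  # Poisson 3-sigma band around the planted enriched rate
  expect_lt(abs(rate_open - expected_open),
            3 * sqrt(expected_open / open_bp))

  # genome-wide mass: background everywhere + (enrichment-1) in open windows
  expected_total <- cfg$background_rate * cfg$chrom_length +
    (cfg$accessible_enrichment - 1) * cfg$background_rate * open_bp
  expect_lt(abs(nrow(track) - expected_total), 3 * sqrt(expected_total))
})

test_that("mark tracks enrich promoters of flagged genes in both replicates", {
  b <- small_bundle()
  cfg <- b$config
  biv <- b$truth$gene_id[b$truth$bivalent]
  prom <- promoter_windows(b$genes[biv], cfg$promoter_up, cfg$promoter_down)
  for (track_name in c("H3K4me3_rep1", "H3K4me3_rep2", "H3K27me3_rep1")) {
    track <- b$marks[[track_name]]
    gr <- GenomicRanges::GRanges(track$chrom,
                                 IRanges::IRanges(track$pos + 1L, width = 1L))
    per_prom <- GenomicRanges::countOverlaps(prom, gr)
    # every bivalent promoter overlaps an enriched mark window
    expect_true(all(per_prom >
                      2 * cfg$background_rate *
                        sum(GenomicRanges::width(prom)) / length(prom)))
  }
  expect_false(identical(b$marks$H3K4me3_rep1, b$marks$H3K4me3_rep2))
  expect_error(simulate_mark_track(b$truth, b$genes, "H3K9me3", 1L, cfg),
               "unknown mark")
})

test_that("flat-trajectory counts have equal per-stage means", {
  cfg <- sim_config(n_chroms = 1L, chrom_length = 2e6, n_genes = 200L,
                    trajectory_fractions = c(flat = 1, up = 0, down = 0,
                                             transient = 0),
                    library_factors = c(1, 1), seed = 17L)
  g <- generate_genome(cfg)
  cm <- simulate_counts(g$truth, g$genes, cfg)
  stage_tot <- tapply(colSums(cm$counts), cm$samples$stage, mean)
  grand <- mean(stage_tot)
  se <- stats::sd(colSums(cm$counts)) / sqrt(2)
  expect_true(all(abs(stage_tot - grand) < 3 * se + 3 * sqrt(grand)))
})

test_that("counts are reproducible and non-negative integers", {
  b <- small_bundle()
  expect_true(all(b$counts$counts >= 0))
  expect_type(b$counts$counts[1, 1], "integer")
  cm2 <- simulate_counts(b$truth, b$genes, b$config)
  expect_identical(b$counts$counts, cm2$counts)
})

test_that("the fixture bundle round-trips through disk exactly", {
  b <- small_bundle()
  dir <- withr::local_tempdir()
  manifest <- write_fixture_bundle(b, dir)
  b2 <- read_fixture_bundle(dir)

  expect_equal(unclass(b2$config), unclass(b$config))
  expect_equal(b2$truth, b$truth)
  expect_equal(b2$enhancers, b$enhancers)
  expect_identical(b2$counts$counts, b$counts$counts)
  expect_equal(b2$counts$lengths, b$counts$lengths)
  for (nm in names(b$cuts)) expect_equal(b2$cuts[[nm]], b$cuts[[nm]])
  expect_equal(as.character(GenomicRanges::seqnames(b2$genes)),
               as.character(GenomicRanges::seqnames(b$genes)))
  expect_equal(GenomicRanges::start(b2$genes), GenomicRanges::start(b$genes))
  expect_equal(as.character(GenomicRanges::strand(b2$genes)),
               as.character(GenomicRanges::strand(b$genes)))
  expect_equal(lapply(b2$genes$blocks, as.data.frame),
               lapply(b$genes$blocks, as.data.frame))

  # manifest row counts match the files on disk (wc-style recount)
  for (i in seq_len(nrow(manifest))) {
    f <- manifest$file[i]
    if (!grepl("\\.(bed|tsv)$", f)) next
    n_lines <- length(readLines(file.path(dir, f)))
    header <- if (grepl("\\.tsv$", f)) 1L else 0L
    expect_equal(manifest$rows[i], max(0L, n_lines - header), info = f)
  }
})

test_that("infeasible gene packing raises a sizing error", {
  expect_error(generate_genome(sim_config(n_chroms = 1L, chrom_length = 1e5,
                                          n_genes = 500L)),
               "infeasible sizing")
})
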