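gene_gr <- function(start1, end1, strand, chrom = "chr1", L = 1e5,
                    gene_id = "g1") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start1, end1), strand,
                         gene_id = gene_id,
                         seqlengths = stats::setNames(L, chrom))
}

test_that("promoter windows follow the 1 kb up / 0.5 kb down rule", {
  # + strand, 0-based TSS 10000 -> 0-based window [9000, 10500)
  g <- gene_gr(10001, 12000, "+")
  w <- promoter_windows(g)
  expect_equal(GenomicRanges::start(w), 9001)
  expect_equal(GenomicRanges::end(w), 10500)

  # - strand, 0-based half-open end 10001 (TSS base 10000) -> [9500, 11000)
  g <- gene_gr(8001, 10001, "-")
  w <- promoter_windows(g)
  expect_equal(GenomicRanges::start(w), 9501)
  expect_equal(GenomicRanges::end(w), 11000)

  # clipping at the chromosome start: 0-based TSS 500 -> [0, 1000)
  g <- gene_gr(501, 3000, "+")
  w <- promoter_windows(g)
  expect_equal(GenomicRanges::start(w), 1)
  expect_equal(GenomicRanges::end(w), 1000)
})

test_that("plus- and minus-strand windows are mirror images through the TSS", {
  set.seed(9)
  for (i in 1:25) {
    tss0 <- sample.int(5e4, 1) + 2e4   # 0-based TSS, away from the edges
    plus <- promoter_windows(gene_gr(tss0 + 1, tss0 + 3000, "+"))
    minus <- promoter_windows(gene_gr(tss0 - 2999, tss0 + 1, "-"))
    # 0-based endpoint mirror: [s,e) reflects to [2*tss - e, 2*tss - s)
    s_plus <- GenomicRanges::start(plus) - 1
    e_plus <- GenomicRanges::end(plus)
    expect_equal(GenomicRanges::start(minus) - 1, 2 * tss0 - e_plus)
    expect_equal(GenomicRanges::end(minus), 2 * tss0 - s_plus)
  }
})

test_that("an empty gene list leaves the whole genome distal", {
  genome <- c(chr1 = 5e4, chr2 = 2e4)
  part <- partition_genome(GenomicRanges::GRanges(), genome)
  expect_true(all(part$label == "distal"))
  expect_equal(sum(GenomicRanges::width(part)), 7e4)
})

test_that("a single two-exon gene partitions by the priority rules", {
  L <- 1e5
  # + strand gene, 0-based span [20000, 26000), exons [20000,21000) and
  # [25000, 26000); hand-computed feature lengths below
  g <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(20001, 26000), "+", gene_id = "g1",
    blocks = IRanges::IRangesList(IRanges::IRanges(c(1, 5001),
                                                   width = 1000)),
    seqlengths = c(chr1 = L))
  part <- partition_genome(g, c(chr1 = L))
  bp <- tapply(GenomicRanges::width(part), part$label, sum)
  bp[is.na(bp)] <- 0
  expect_equal(sum(bp), L)
  expect_equal(as.numeric(bp["promoter"]), 1500)     # [19000, 20500)
  expect_equal(as.numeric(bp["exon"]), 1500)         # exons minus promoter
  expect_equal(as.numeric(bp["intron"]), 4000)       # [21000, 25000)
  expect_equal(as.numeric(bp["downstream"]), 1000)   # [26000, 27000)
  expect_equal(as.numeric(bp["distal"]), L - 8000)
  expect_true(all(GenomicRanges::width(GenomicRanges::reduce(part)) ==
                    sum(bp)))  # disjoint pieces merge into the chromosome
})

test_that("overlapping genes resolve by promoter-first priority", {
  L <- 1e5
  a <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(30001, 35000), "+", gene_id = "a",
    blocks = IRanges::IRangesList(IRanges::IRanges(c(1, 4001),
                                                   width = 1000)),
    seqlengths = c(chr1 = L))
  # gene b's promoter covers part of a's exon/intron
  bgene <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(33001, 38000), "+", gene_id = "b",
    blocks = IRanges::IRangesList(IRanges::IRanges(c(1, 4001),
                                                   width = 1000)),
    seqlengths = c(chr1 = L))
  part <- partition_genome(c(a, bgene), c(chr1 = L))
  # bases of b's promoter window [32000, 33500) must be labelled promoter
  probe <- GenomicRanges::GRanges("chr1", IRanges::IRanges(32001, 33500))
  hit <- part[IRanges::overlapsAny(part, probe)]
  expect_true(all(hit$label == "promoter"))
})

test_that("feature assignment uses highest overlapped priority", {
  L <- 1e5
  g <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(20001, 26000), "+", gene_id = "g1",
    blocks = IRanges::IRangesList(IRanges::IRanges(c(1, 5001),
                                                   width = 1000)),
    seqlengths = c(chr1 = L))
  part <- partition_genome(g, c(chr1 = L))
  regions <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = c(19500, 20400, 22000, 50000),
    end = c(19800, 23000, 23000, 50100)))
  lab <- assign_feature(regions, part)
  expect_equal(as.character(lab),
               c("promoter", "promoter", "intron", "distal"))
  # bp-majority assigns the long promoter+intron straddler to intron
  lab2 <- assign_feature(regions, part, method = "majority")
  expect_equal(as.character(lab2[2]), "intron")
})

test_that("feature fractions sum to one and match a 1 bp tiling oracle", {
  genome <- c(chr1 = 2e4)
  g <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(5001, 9000), "+", gene_id = "g1",
    blocks = IRanges::IRangesList(IRanges::IRanges(c(1, 3001),
                                                   width = 500)),
    seqlengths = genome)
  part <- partition_genome(g, genome)
  tiles <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1:2e4, width = 1))
  fr <- feature_fractions(tiles, part)
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  bp <- tapply(GenomicRanges::width(part), part$label, sum)
  bp[is.na(bp)] <- 0
  expect_equal(as.numeric(fr[names(bp)]), as.numeric(bp) / 2e4,
               tolerance = 1e-12)

  empty <- feature_fractions(GenomicRanges::GRanges(), part)
  expect_true(all(empty == 0))
})

test_that("enhancer overlaps count once per (DHS, enhancer) pair", {
  expect_length(enhancer_overlap(GenomicRanges::GRanges(),
                                 data.frame(enh_chrom = character(0),
                                            enh_start = integer(0),
                                            enh_end = integer(0),
                                            gene_id = character(0))), 0L)
  links <- data.frame(enh_chrom = "chr1",
                      enh_start = c(1000L, 1500L, 5000L),
                      enh_end = c(1400L, 1900L, 5400L),
                      gene_id = c("g1", "g1", "g2"),
                      stringsAsFactors = FALSE)
  one <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5101, 5200))
  expect_equal(enhancer_overlap(one, links),
               c(g1 = 0L, g2 = 1L))
  # one DHS spanning both g1 enhancers counts twice
  wide <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1301, 1600))
  expect_equal(enhancer_overlap(wide, links), c(g1 = 2L, g2 = 0L))
})
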