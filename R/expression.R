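#' Trimmed-mean-of-M-values scaling factors
#'
#' Between-library scaling factors in the TMM family. The reference sample
#' is the one whose upper quartile (of depth-scaled counts) is closest to
#' the mean upper quartile. For every other sample, genes with a zero count
#' in either library are dropped; M-values are log2 ratios of the raw
#' counts against the reference and A-values their mean log2 abundance.
#' After rank-trimming `trim_M` from each M tail and `trim_A` from each A
#' tail, the factor is 2 to the abundance-weighted mean of the surviving
#' M-values (weights `sqrt(x * r)`, which keep the factors exactly
#' equivariant under library scaling). Factors are rescaled to geometric
#' mean 1.
#'
#' Because M is taken on raw counts, a factor absorbs both relative
#' sequencing depth and composition bias; `factor * geometric-mean library
#' size` is the effective library size used by [expression_values()]. Two
#' libraries where one is exactly twice the other therefore give factors
#' `(1/sqrt(2), sqrt(2))`.
#'
#' @param counts integer matrix, genes x samples (a `count_matrix`'s
#'   `counts` component is accepted too).
#' @param trim_M,trim_A tail fractions trimmed from the M and A ranks.
#' @return Named numeric vector of per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  stopifnot(is.matrix(counts), ncol(counts) >= 1L)
  lib <- colSums(counts)
  if (any(lib == 0)) stop("all-zero sample(s): ",
                          paste(colnames(counts)[lib == 0], collapse = ", "))
  uq <- vapply(seq_len(ncol(counts)), function(j)
    stats::quantile(counts[, j], 0.75) / lib[j], numeric(1))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    x <- counts[, j]; r <- counts[, ref]
    keep <- x > 0 & r > 0
    x <- x[keep]; r <- r[keep]
    if (length(x) == 0L) return(1)
    M <- log2(x / r)
    A <- 0.5 * (log2(x) + log2(r))
    n <- length(M)
    loM <- stats::quantile(M, trim_M, type = 1)
    hiM <- stats::quantile(M, 1 - trim_M, type = 1)
    loA <- stats::quantile(A, trim_A, type = 1)
    hiA <- stats::quantile(A, 1 - trim_A, type = 1)
    keep2 <- M >= loM & M <= hiM & A >= loA & A <= hiA
    if (!any(keep2)) keep2 <- rep(TRUE, n)
    # abundance weights sqrt(x * r): higher-abundance ratios are more
    # precise, and scaling a library rescales every weight by the same
    # constant, keeping the factors exactly equivariant under depth changes
    w <- sqrt(x[keep2] * r[keep2])
    2^(sum(w * M[keep2]) / sum(w))
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' Length- and depth-normalised expression values
#'
#' The per-gene expression unit of the analysis:
#' `value = count / (effective library size) * 1e6 / (length_bp / 1000)`,
#' where the effective library size of a sample is its TMM factor times the
#' geometric-mean library size across samples. Scaling every count of one
#' library by a constant leaves its values unchanged (the factor absorbs
#' the scaling), and values are comparable between genes because of the
#' length normalisation.
#'
#' @param counts a `count_matrix` (from [simulate_counts()] or
#'   [read_fixture_bundle()]) or an integer matrix.
#' @param factors per-sample scaling factors from [tmm_factors()]; computed
#'   if missing.
#' @param lengths gene lengths in bp (taken from the `count_matrix` if not
#'   given).
#' @return Numeric matrix of expression values, genes x samples.
#' @export
expression_values <- function(counts, factors = NULL, lengths = NULL) {
  if (inherits(counts, "count_matrix")) {
    if (is.null(lengths)) lengths <- counts$lengths
    counts <- counts$counts
  }
  stopifnot(is.matrix(counts), !is.null(lengths),
            length(lengths) == nrow(counts))
  if (is.null(factors)) factors <- tmm_factors(counts)
  lib <- colSums(counts)
  base <- exp(mean(log(lib)))
  eff <- base * factors
  sweep(counts, 2L, eff, "/") * 1e6 / (as.numeric(lengths) / 1000)
}

#' Display transform for log-scale expression plots
#'
#' Adds the plotting pseudocount (`value + 1` by default) so genes with
#' zero expression are representable on a log axis; monotone, so gene order
#' is preserved.
#'
#' @param values numeric vector or matrix of non-negative expression values.
#' @param offset pseudocount (0 returns the input unchanged).
#' @return Transformed values.
#' @export
log_display <- function(values, offset = 1) {
  stopifnot(all(values >= 0, na.rm = TRUE))
  values + offset
}

#' Time-course differential expression by polynomial regression
#'
#' The maSigPro-style test reduced to its regression core: per gene,
#' `log(value + 1)` is regressed on a polynomial in stage time of degree
#' `min(max_degree, n_distinct_times - 1)` and the full model is compared
#' with the intercept-only model by an F-test; p-values are BH-adjusted
#' across genes and `is_deg = q < alpha`. Genes with zero variance (no
#' trend, no noise) get `p = 1` by convention.
#'
#' @param expr expression matrix, genes x samples (from
#'   [expression_values()]).
#' @param times numeric time per sample (e.g. embryonic day, so unequal
#'   stage spacing is honoured); see [stage_times()].
#' @param max_degree maximum polynomial degree.
#' @param alpha FDR threshold for calling DEGs.
#' @return data.frame `gene_id`, `F`, `p`, `q`, `is_deg`.
#' @export
timecourse_deg <- function(expr, times, max_degree = 3, alpha = 0.05) {
  stopifnot(is.matrix(expr), length(times) == ncol(expr))
  if (max(table(times)) < 2L)
    stop("at least one time point needs >= 2 replicates for the ",
         "variance estimate")
  d <- min(max_degree, length(unique(times)) - 1L)
  n <- ncol(expr)
  if (n - d - 1L <= 0L) stop("not enough samples for degree ", d)
  X <- stats::poly(times, degree = d, raw = TRUE)
  X <- cbind(Intercept = 1, X)
  Y <- t(log(expr + 1))                     # samples x genes
  fit <- stats::lm.fit(X, Y)
  rss1 <- colSums(fit$residuals^2)
  rss0 <- colSums(scale(Y, scale = FALSE)^2)
  Fstat <- ((rss0 - rss1) / d) / (rss1 / (n - d - 1L))
  p <- stats::pf(Fstat, d, n - d - 1L, lower.tail = FALSE)
  null_gene <- rss0 <= .Machine$double.eps * n
  p[null_gene] <- 1
  Fstat[null_gene] <- 0
  # saturated fit: residuals at machine zero mean an exact polynomial trend
  p[!null_gene & rss1 <= .Machine$double.eps * n] <- 0
  q <- stats::p.adjust(p, method = "BH")
  data.frame(gene_id = rownames(expr), F = Fstat, p = p, q = q,
             is_deg = q < alpha, row.names = NULL, stringsAsFactors = FALSE)
}

#' Cluster DEG temporal profiles
#'
#' k-means (25 restarts, fixed seed) on per-gene z-scored mean stage
#' profiles of `log(value + 1)` — the nine-cluster categorisation of the
#' time-course DEGs.
#'
#' @param expr expression matrix, genes x samples.
#' @param stages stage label per sample (replicates are averaged within
#'   stage).
#' @param genes gene ids to cluster (the DEGs); default all rows.
#' @param k number of clusters (default 9).
#' @param seed RNG seed for the restarts.
#' @param nstart number of k-means restarts.
#' @return A list with `cluster` (named integer vector), `centers` (k x
#'   n_stages matrix of mean z-scored profiles) and `sizes`.
#' @export
cluster_profiles <- function(expr, stages, genes = rownames(expr), k = 9,
                             seed = 1L, nstart = 25) {
  expr <- expr[genes, , drop = FALSE]
  if (nrow(expr) < k)
    stop("fewer profiles (", nrow(expr), ") than clusters (", k,
         "); choose a smaller k")
  logv <- log(expr + 1)
  stage_means <- t(apply(logv, 1L, function(x) tapply(x, stages, mean)))
  stage_means <- stage_means[, unique(stages), drop = FALSE]
  z <- t(apply(stage_means, 1L, function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  set.seed(seed)
  km <- stats::kmeans(z, centers = k, nstart = nstart, iter.max = 100)
  list(cluster = stats::setNames(km$cluster, rownames(expr)),
       centers = km$centers, sizes = as.integer(km$size))
}

#' Twofold-change DEG rule for single-replicate comparisons
#'
#' With only one replicate per condition no variance is estimable, so genes
#' are called by fold change with the display pseudocount: up iff
#' `(b + 1) / (a + 1) > threshold`, down iff the reciprocal exceeds it.
#'
#' @param values_a,values_b named expression vectors for the two conditions
#'   (same gene order).
#' @param threshold fold-change threshold (default 2).
#' @param pseudocount added to both sides before the ratio.
#' @return A list with character vectors `up` and `down` (gene names, or
#'   indices when unnamed).
#' @export
fold_change_deg <- function(values_a, values_b, threshold = 2,
                            pseudocount = 1) {
  stopifnot(length(values_a) == length(values_b))
  ratio <- (values_b + pseudocount) / (values_a + pseudocount)
  ids <- names(values_a)
  if (is.null(ids)) ids <- as.character(seq_along(values_a))
  list(up = ids[ratio > threshold], down = ids[1 / ratio > threshold])
}

#' Per-gene two-group Student's t-test with BH correction
#'
#' The microarray-style comparison: unpaired, two-tailed, pooled-variance t
#' per gene between two groups of samples, BH q-values across genes, DEGs
#' at `q < alpha`. Genes with zero variance in both groups get `p = 1` when
#' the means agree and `p = 0` otherwise.
#'
#' @param values_a,values_b numeric matrices (genes x replicates) for the
#'   two groups; at least 2 replicates each.
#' @param alpha FDR threshold.
#' @return data.frame `gene_id`, `t`, `p`, `q`, `is_deg`.
#' @export
two_group_test <- function(values_a, values_b, alpha = 0.05) {
  stopifnot(is.matrix(values_a), is.matrix(values_b),
            nrow(values_a) == nrow(values_b),
            ncol(values_a) >= 2L, ncol(values_b) >= 2L)
  na <- ncol(values_a); nb <- ncol(values_b)
  ma <- rowMeans(values_a); mb <- rowMeans(values_b)
  va <- apply(values_a, 1L, stats::var)
  vb <- apply(values_b, 1L, stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tstat <- (ma - mb) / se
  p <- 2 * stats::pt(-abs(tstat), df = na + nb - 2)
  degenerate <- se == 0
  p[degenerate & ma == mb] <- 1
  p[degenerate & ma != mb] <- 0
  tstat[degenerate & ma == mb] <- 0
  ids <- rownames(values_a)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(values_a)))
  q <- stats::p.adjust(p, method = "BH")
  data.frame(gene_id = ids, t = tstat, p = p, q = q, is_deg = q < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}
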