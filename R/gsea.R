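#' Enrichment score of a gene set in a ranked list
#'
#' The weighted Kolmogorov-Smirnov running sum: walking down the list
#' sorted by decreasing score, hits increment the sum by
#' `|score|^weight / sum over hits of |score|^weight` and misses decrement
#' it by `1 / (N - m)`; the enrichment score (ES) is the deviation of
#' maximal magnitude. `weight = 0` gives the classic KS statistic; if every
#' hit score is zero under a positive weight, equal hit increments are
#' used.
#'
#' @param scores numeric vector of ranking scores, sorted decreasing.
#' @param hit logical vector marking gene-set members at each rank.
#' @param weight exponent on `|score|` for hit increments.
#' @return A list with `es`, `peak` (rank of the extremum) and `running`
#'   (the full running sum).
#' @export
enrichment_score <- function(scores, hit, weight = 1) {
  N <- length(scores)
  m <- sum(hit)
  stopifnot(length(hit) == N, m > 0, m < N)
  w <- abs(scores[hit])^weight
  inc <- if (sum(w) == 0) rep(1 / m, m) else w / sum(w)
  steps <- numeric(N)
  steps[hit] <- inc
  steps[!hit] <- -1 / (N - m)
  running <- cumsum(steps)
  peak <- which.max(abs(running))
  list(es = running[peak], peak = peak, running = running)
}

#' Preranked gene-set enrichment analysis
#'
#' GSEA on a precomputed ranking (e.g. a fold change between two
#' conditions): the enrichment score is computed with
#' [enrichment_score()], and the null is built by permuting gene labels —
#' redrawing which ranks are hits — `n_perm` times under a fixed seed. The
#' normalised enrichment score (NES) divides ES by the mean magnitude of
#' same-sign null scores, and the p-value is the same-sign null tail
#' frequency (with the +1 continuity correction).
#'
#' @param scores named numeric vector of ranking scores (sorted internally
#'   by decreasing score).
#' @param gene_set character vector of gene ids; the intersection with the
#'   ranked list must be non-empty and proper.
#' @param weight exponent on `|score|` for hit increments.
#' @param n_perm number of label permutations.
#' @param seed RNG seed for the permutations.
#' @return A list of class `gsea_result`: `es`, `nes`, `p`,
#'   `leading_edge` (gene ids up to / from the ES extremum), `n_hits`,
#'   `null_es`.
#' @export
gsea_preranked <- function(scores, gene_set, weight = 1, n_perm = 1000,
                           seed = 1L) {
  stopifnot(!is.null(names(scores)), all(is.finite(scores)))
  ord <- order(scores, decreasing = TRUE)
  scores <- scores[ord]
  N <- length(scores)
  hit <- names(scores) %in% gene_set
  m <- sum(hit)
  if (m == 0L) stop("gene set does not intersect the ranked list")
  if (m == N) stop("gene set covers the whole ranked list; ES is degenerate")

  obs <- enrichment_score(scores, hit, weight)
  es <- obs$es

  set.seed(seed)
  null_es <- vapply(seq_len(n_perm), function(b) {
    ph <- logical(N)
    ph[sample.int(N, m)] <- TRUE
    enrichment_score(scores, ph, weight)$es
  }, numeric(1))

  same_sign <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  nes <- if (length(same_sign) > 0) es / mean(abs(same_sign)) else NA_real_
  p <- (1 + sum(abs(same_sign) >= abs(es))) / (1 + length(same_sign))

  leading <- if (es >= 0) {
    names(scores)[seq_len(obs$peak)][hit[seq_len(obs$peak)]]
  } else {
    idx <- obs$peak:N
    names(scores)[idx][hit[idx]]
  }
  structure(list(es = es, nes = nes, p = p, leading_edge = leading,
                 n_hits = m, null_es = null_es),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("gsea_result: ES = %.3f, NES = %.3f, p = %.4g, %d hits, %d leading-edge genes\n",
              x$es, x$nes, x$p, x$n_hits, length(x$leading_edge)))
  invisible(x)
}
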