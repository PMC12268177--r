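#' Fisher's exact test for a 2x2 overlap table
#'
#' Exact hypergeometric tail probability for the overlap of two gene sets
#' in a common universe. The table is `a` (in both sets), `b` (set 1
#' only), `c` (set 2 only), `d` (neither). `alternative = "greater"` (the
#' enrichment default) is the upper hypergeometric tail `P(X >= a)`;
#' `"less"` the lower tail; `"two.sided"` sums the probabilities of all
#' outcomes no more likely than the observed one (the standard convention).
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @return The p-value.
#' @examples
#' fisher_exact(5, 0, 0, 5)   # 1 / choose(10, 5)
#' @export
fisher_exact <- function(a, b, c, d,
                         alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (any(c(a, b, c, d) < 0)) stop("negative counts")
  K <- a + b          # size of set 1
  n <- a + c          # size of set 2
  N <- a + b + c + d
  switch(alternative,
    greater = stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE),
    less = stats::phyper(a, K, N - K, n),
    two.sided = {
      support <- max(0, n - (N - K)):min(K, n)
      pmf <- stats::dhyper(support, K, N - K, n)
      obs <- stats::dhyper(a, K, N - K, n)
      sum(pmf[pmf <= obs * (1 + 1e-7)])
    })
}

#' Build the 2x2 table for two gene sets in a universe
#'
#' @param set1,set2 character vectors of gene ids.
#' @param universe character vector containing every gene under
#'   consideration.
#' @return Named integer vector `a`, `b`, `c`, `d`.
#' @export
overlap_table <- function(set1, set2, universe) {
  s1 <- unique(set1); s2 <- unique(set2)
  bad <- c(setdiff(s1, universe), setdiff(s2, universe))
  if (length(bad) > 0)
    stop("genes outside the universe: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "")
  a <- length(intersect(s1, s2))
  c(a = a, b = length(s1) - a, c = length(s2) - a,
    d = length(unique(universe)) - length(s1) - length(s2) + a)
}

#' Fisher overlap matrix between two gene-set families
#'
#' The overlap-enrichment heatmap machinery: one Fisher test per cell
#' (family-1 set x family-2 set) against the shared universe, with BH
#' correction applied jointly over all cells of the matrix. Raw p, q, odds
#' ratios and overlap counts are all returned; `-log10(p)` is what the
#' heatmaps display.
#'
#' @param family1,family2 named lists of character gene-id vectors.
#' @param universe character vector; every set must be contained in it.
#' @param alternative sidedness, passed to [fisher_exact()].
#' @return A list of class `overlap_matrix` with numeric matrices `p`, `q`,
#'   `odds_ratio`, `overlap` (rows = family 1, cols = family 2) and the
#'   `alternative` used.
#' @export
overlap_matrix <- function(family1, family2, universe,
                           alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(family1) > 0, length(family2) > 0,
            !is.null(names(family1)), !is.null(names(family2)))
  dims <- list(names(family1), names(family2))
  p <- ov <- orat <- matrix(NA_real_, length(family1), length(family2),
                            dimnames = dims)
  for (i in seq_along(family1)) {
    for (j in seq_along(family2)) {
      tab <- overlap_table(family1[[i]], family2[[j]], universe)
      p[i, j] <- fisher_exact(tab["a"], tab["b"], tab["c"], tab["d"],
                              alternative)
      ov[i, j] <- tab["a"]
      orat[i, j] <- (tab["a"] * tab["d"]) / (tab["b"] * tab["c"])
    }
  }
  q <- matrix(bh_fdr(as.vector(p)), nrow(p), ncol(p), dimnames = dims)
  structure(list(p = p, q = q, odds_ratio = orat, overlap = ov,
                 alternative = alternative),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat("overlap_matrix:", nrow(x$p), "x", ncol(x$p), "cells,",
      sum(x$q < 0.05), "with q < 0.05 (", x$alternative, ")\n")
  invisible(x)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment (wraps [stats::p.adjust()]): q-values are
#' monotone in the sorted p-values, never below their p, and capped at 1.
#'
#' @param pvals numeric vector of p-values in `[0, 1]` (NAs preserved).
#' @return Numeric vector of q-values.
#' @export
bh_fdr <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "BH")
}
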