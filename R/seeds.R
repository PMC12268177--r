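#' Derive a child seed from a master seed and a purpose label
#'
#' Every stochastic step in the package draws its own RNG stream from the
#' single master seed in [sim_config()], keyed by what the stream is for
#' (e.g. `"dnase"`, `"chip_H3K4me3"`, `"counts"`) and, where relevant, the
#' stage and replicate indices. Distinct purposes map to distinct seeds with
#' overwhelming probability, so regenerating one track never perturbs
#' another.
#'
#' @param master integer master seed.
#' @param purpose character label naming the consumer of the stream.
#' @param stage,replicate optional integer indices mixed into the hash.
#' @return An integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' child_seed(1L, "dnase", stage = 2, replicate = 1)
#' @export
child_seed <- function(master, purpose, stage = 0L, replicate = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(purpose))
  p <- 2147483647 # 2^31 - 1, prime
  key <- paste(purpose, as.integer(stage), as.integer(replicate), sep = ":")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% p
  # mix the master seed in with a Lehmer-style multiplier; all intermediate
  # products stay below 2^53 so double arithmetic is exact
  as.integer((h + (as.numeric(master) %% p) * 48271) %% p)
}
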