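#' Derive a deterministic sub-stream seed
#'
#' One master integer seed drives every stochastic operation; independent
#' sub-streams are derived by stable string hashing of an operation tag
#' and an optional unit id (for example a sample id), so that adding or
#' reordering units never perturbs the draws of the others.
#'
#' @param seed master integer seed.
#' @param op short operation tag, e.g. `"counts"`.
#' @param id optional unit identifier.
#' @return an integer in \[0, 2^31 - 2\] suitable for [set.seed()].
#' @export
#' @examples
#' streamSeed(1L, "counts", "sampleA")
streamSeed <- function(seed, op, id = "") {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  key <- paste(op, id, sep = "\r")
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer((h + (abs(seed) %% 2147483647) * 48271) %% 2147483647)
}

withStream <- function(seed, op, id = "", code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(streamSeed(seed, op, id))
  force(code)
}
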