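#' Derive a reproducible stage seed
#'
#' Deterministically mixes a master seed with a string tag and an integer
#' index (e.g. replicate number) into a positive 31-bit integer, so that
#' every pipeline stage draws from its own independent stream.
#'
#' @param master integer master seed.
#' @param tag character tag (scenario name, stage name, ...).
#' @param k integer index.
#' @return integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, tag = "", k = 0L) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- as.numeric(master) %% m
  mix <- function(s, x) ((s * 69069) %% m + (x * 2654435761) %% m + 1013904223) %% m
  for (ch in utf8ToInt(as.character(tag))) s <- mix(s, ch)
  s <- mix(s, as.numeric(k))
  s <- mix(s, 97531)
  as.integer(s %% (m - 2) + 1)
}
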