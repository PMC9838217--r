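# shared internal helpers

.BASES <- c("A", "C", "G", "T")

`%||%` <- function(x, y) if (is.null(x)) y else x

# Run `code` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Derive a reproducible per-stream seed
#'
#' Maps a master seed plus a (sample, replicate) pair to a seed below
#' 2^31 - 1 via a fixed polynomial string hash, so that every simulated
#' SELEX stream has its own independent, reproducible random stream.
#'
#' @param master integer master seed.
#' @param sample sample label.
#' @param replicate replicate number.
#' @return a single integer seed.
#' @export
stream_seed <- function(master, sample, replicate) {
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(paste(sample, replicate, sep = "/"))) {
    h <- (h * 31 + ch) %% m
  }
  as.integer((((master %% m) * 48271) %% m + h) %% m)
}
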