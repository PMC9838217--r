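#' Collect read windows matching seed k-mers within one mismatch
#'
#' Every length-k window of every read is compared against each seed k-mer
#' in both the seed's orientation and its reverse complement. A window is
#' emitted once if its minimal Hamming distance over all (seed,
#' orientation) pairs is at most `max_mismatch`, and it is oriented to the
#' pair achieving that minimum (reverse-complemented when the best match is
#' to the seed's reverse complement), so the resulting matrix represents an
#' oriented motif. Ties are broken by the earlier seed in the list, then by
#' forward orientation. Windows containing non-ACGT characters are skipped.
#'
#' @param reads a [read_set()] or character vector of reads.
#' @param seeds character vector of seed k-mers, all the same length,
#'   no duplicates (typically the top-abundance k-mers of a SELEX cycle).
#' @param max_mismatch maximum Hamming distance (default 1).
#' @return character vector of matched, oriented windows, in read-major
#'   left-to-right order.
#' @export
match_windows <- function(reads, seeds, max_mismatch = 1) {
  rs <- .as_read_set(reads)
  assert_dna(seeds, "seeds")
  if (anyDuplicated(seeds)) stop("duplicate seeds", call. = FALSE)
  k <- unique(nchar(seeds))
  if (length(k) != 1L) stop("seeds must all have the same length", call. = FALSE)
  k <- as.integer(k)
  .check_table_k(k)

  rc_t <- rc_code_table(k)
  N <- 4^k
  seed_codes <- kmer_to_code(seeds)
  # reference columns ordered seed1-fwd, seed1-rc, seed2-fwd, ... so that
  # "first minimal column" encodes the tie rule
  refs <- as.vector(rbind(seed_codes, rc_t[seed_codes + 1]))
  digits <- code_digits(0:(N - 1), k)
  D <- vapply(refs, function(r) {
    rd <- code_digits(r, k)
    rowSums(digits != matrix(rd, nrow = N, ncol = k, byrow = TRUE))
  }, numeric(N))
  D <- matrix(D, nrow = N)
  best_col <- max.col(-D, ties.method = "first")
  best_d <- D[cbind(seq_len(N), best_col)]
  matched <- best_d <= max_mismatch
  # orient to the seed: reverse-complement the window when the best match
  # is against the seed's reverse complement (even-numbered columns)
  emit <- ifelse(best_col %% 2 == 0, rc_t[(0:(N - 1)) + 1], 0:(N - 1))

  keep <- rs$reads[nchar(rs$reads) >= k]
  out_codes <- numeric(0)
  for (grp in split(keep, nchar(keep))) {
    m <- seq_code_matrix(grp)
    W <- window_codes(m, k)
    w <- as.vector(t(W))            # read-major, left-to-right
    w <- w[!is.na(w)]
    w <- w[matched[w + 1]]
    out_codes <- c(out_codes, emit[w + 1])
  }
  if (length(out_codes) == 0L) character(0) else code_to_kmer(out_codes, k)
}

#' Build a position frequency matrix
#'
#' Counts the base at each position over a set of equal-length windows
#' (e.g. from [match_windows()]). Every column of the resulting matrix
#' sums to the number of windows.
#'
#' @param windows character vector of equal-length DNA windows.
#' @return 4 x k integer matrix of class `pfm`, rows A, C, G, T, with
#'   attribute `n_windows`.
#' @export
build_pfm <- function(windows) {
  if (length(windows) == 0L) stop("empty window list", call. = FALSE)
  assert_dna(windows, "windows")
  k <- unique(nchar(windows))
  if (length(k) != 1L) stop("windows must all have the same length", call. = FALSE)
  m <- seq_code_matrix(windows)
  counts <- vapply(seq_len(k),
                   function(j) tabulate(m[, j] + 1L, nbins = 4L),
                   integer(4))
  counts <- matrix(counts, nrow = 4L,
                   dimnames = list(.BASES, paste0("pos", seq_len(k))))
  structure(counts, n_windows = length(windows), class = c("pfm", "matrix"))
}

#' Probabilities and information content from a PFM
#'
#' Normalises a position frequency matrix to per-column probabilities
#' (optionally with a pseudocount) and computes each column's information
#' content in bits as 2 minus its Shannon entropy -- the quantities drawn
#' by sequence-logo tools.
#'
#' @param pfm a [build_pfm()] matrix.
#' @param pseudocount non-negative count added to every cell before
#'   normalisation (default 0, reporting raw frequencies).
#' @return list of class `ppm_ic` with elements `ppm` (4 x k probability
#'   matrix, columns summing to 1) and `ic` (per-column bits in \[0, 2\]).
#' @export
to_ppm_ic <- function(pfm, pseudocount = 0) {
  stopifnot(inherits(pfm, "pfm"))
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  n <- attr(pfm, "n_windows")
  if (is.null(n) || n <= 0) stop("PFM has no windows", call. = FALSE)
  p <- (unclass(pfm) + pseudocount) / (n + 4 * pseudocount)
  plogp <- ifelse(p > 0, p * log2(p), 0)
  ic <- 2 + colSums(plogp)
  structure(list(ppm = p, ic = ic, pseudocount = pseudocount),
            class = "ppm_ic")
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("<pfm> %d windows, %d positions\n",
              attr(x, "n_windows"), ncol(x)))
  print(unclass(x))
  invisible(x)
}

#' Consensus sequence of a PFM
#'
#' @param pfm a [build_pfm()] matrix.
#' @return single consensus string (most frequent base per column; ties go
#'   to the alphabetically first base).
#' @export
pfm_consensus <- function(pfm) {
  stopifnot(inherits(pfm, "pfm"))
  paste(rownames(pfm)[apply(unclass(pfm), 2L, which.max)], collapse = "")
}
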