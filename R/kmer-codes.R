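# Internal integer encoding of fixed-length DNA.
#
# A k-mer is encoded base-4 (A=0, C=1, G=2, T=3), most significant digit
# first, stored as a double (exact up to k = 26; table-based operations are
# capped at k = 12 for memory). Under this encoding the numeric order of
# codes equals lexicographic order of sequences with A < C < G < T, and the
# complement of a base code b is 3 - b.

.MAX_TABLE_K <- 12L

.code_cache <- new.env(parent = emptyenv())

# character vector of equal-length sequences -> integer matrix (n x L),
# entries 0..3, NA for any non-ACGT character
seq_code_matrix <- function(reads) {
  L <- unique(nchar(reads))
  stopifnot(length(L) == 1L)
  codes <- match(unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE),
                 .BASES) - 1L
  matrix(codes, nrow = length(reads), ncol = L, byrow = TRUE)
}

# base-code matrix -> window code matrix (n x (L - k + 1)); windows that
# touch an NA base are NA
window_codes <- function(m, k) {
  n <- nrow(m)
  W <- ncol(m) - k + 1L
  out <- matrix(NA_real_, n, W)
  for (i in seq_len(W)) {
    v <- as.numeric(m[, i])
    if (k > 1L) {
      for (j in 2:k) v <- v * 4 + m[, i + j - 1L]
    }
    out[, i] <- v
  }
  out
}

# digits of codes, length(codes) x k, column j = base code at position j
code_digits <- function(codes, k) {
  d <- vapply(seq_len(k),
              function(j) (codes %/% 4^(k - j)) %% 4,
              numeric(length(codes)))
  matrix(d, ncol = k)
}

code_to_kmer <- function(codes, k) {
  d <- code_digits(codes, k)
  do.call(paste0, lapply(seq_len(k), function(j) .BASES[d[, j] + 1L]))
}

kmer_to_code <- function(kmers) {
  m <- seq_code_matrix(kmers)
  v <- as.numeric(m[, 1L])
  if (ncol(m) > 1L) {
    for (j in 2:ncol(m)) v <- v * 4 + m[, j]
  }
  v
}

.check_table_k <- function(k) {
  if (k > .MAX_TABLE_K) {
    stop("k = ", k, " exceeds the supported maximum of ", .MAX_TABLE_K,
         " for exhaustive canonical k-mer tables", call. = FALSE)
  }
}

# reverse-complement code for every code 0 .. 4^k - 1 (cached)
rc_code_table <- function(k) {
  .check_table_k(k)
  key <- paste0("rc", k)
  if (is.null(.code_cache[[key]])) {
    codes <- 0:(4^k - 1)
    d <- code_digits(codes, k)
    rc <- numeric(length(codes))
    for (j in seq_len(k)) rc <- rc * 4 + (3 - d[, k - j + 1L])
    .code_cache[[key]] <- rc
  }
  .code_cache[[key]]
}

# canonical (min of code and its reverse complement) for every code (cached)
canonical_code_table <- function(k) {
  key <- paste0("canon", k)
  if (is.null(.code_cache[[key]])) {
    .code_cache[[key]] <- pmin(0:(4^k - 1), rc_code_table(k))
  }
  .code_cache[[key]]
}

# sorted codes of the distinct canonical k-mers (cached)
canonical_codes <- function(k) {
  key <- paste0("set", k)
  if (is.null(.code_cache[[key]])) {
    .code_cache[[key]] <- sort(unique(canonical_code_table(k)))
  }
  .code_cache[[key]]
}

# data.frame(kmer, total_at, max_run_at) for all canonical k-mers (cached)
canonical_annotation <- function(k) {
  key <- paste0("anno", k)
  if (is.null(.code_cache[[key]])) {
    kmers <- code_to_kmer(canonical_codes(k), k)
    comp <- kmer_composition(kmers)
    .code_cache[[key]] <- comp
  }
  .code_cache[[key]]
}
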