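#' DNA sequence primitives for canonical k-mer analysis
#'
#' Double-stranded DNA makes a k-mer and its reverse complement
#' experimentally indistinguishable in a SELEX library, so all enrichment
#' accounting is done on *canonical* k-mers: the lexicographically smaller
#' member of each reverse-complement pair under base order A < C < G < T.
#' These primitives validate sequences, reverse-complement them,
#' canonicalise k-mers, measure Hamming distance and summarise A/T
#' composition.
#'
#' @name kmer-core
NULL

# validate a character vector of strictly-ACGT sequences
assert_dna <- function(x, arg = "sequence") {
  if (length(x) == 0L) {
    stop("empty ", arg, " input", call. = FALSE)
  }
  bad <- is.na(x) | nchar(x) < 1L | grepl("[^ACGT]", x)
  if (any(bad)) {
    stop("invalid ", arg, ": characters outside {A,C,G,T} (first offender: ",
         deparse(x[bad][1L]), ")", call. = FALSE)
  }
  invisible(x)
}

#' Reverse complement of DNA sequences
#'
#' @param x character vector of sequences over the alphabet A, C, G, T.
#' @return character vector of the reverse complements. Applying the
#'   function twice returns the input; palindromic sequences map to
#'   themselves.
#' @examples
#' reverse_complement("ATATT")        # "AATAT"
#' reverse_complement("GATATTAATATC") # palindrome: itself
#' @export
reverse_complement <- function(x) {
  assert_dna(x)
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(b) paste(rev(b), collapse = ""),
         character(1))
}

#' Canonical form of k-mers
#'
#' The canonical sequence of a k-mer pair is the lexicographically smaller
#' of the two reverse-complementary sequences (A < C < G < T). Palindromes
#' are their own canonical form.
#'
#' @param x character vector of k-mers (any lengths; each element is
#'   canonicalised independently).
#' @return character vector of canonical k-mers.
#' @examples
#' canonical_kmer("TAATAT") # "ATATTA"
#' canonical_kmer("ATATT")  # "AATAT"
#' @export
canonical_kmer <- function(x) {
  rc <- reverse_complement(x)
  # uppercase ACGT compares identically in the C locale and common locales;
  # numeric base-4 codes would give the same order
  ifelse(rc < x, rc, x)
}

#' A/T composition of k-mers
#'
#' Computes, per k-mer, the total number of A/T bases and the length of the
#' longest contiguous run of A/T bases -- the two composition statistics by
#' which enrichment is grouped.
#'
#' @param x character vector of k-mers.
#' @return data.frame with columns `kmer`, `total_at`, `max_run_at`.
#' @examples
#' kmer_composition("ATGATA") # total_at 5, max_run_at 3
#' @export
kmer_composition <- function(x) {
  assert_dna(x)
  total_at <- nchar(x) - nchar(gsub("[AT]", "", x))
  runs <- gregexpr("[AT]+", x)
  max_run <- vapply(runs, function(r) {
    len <- attr(r, "match.length")
    if (r[1L] == -1L) 0L else max(len)
  }, integer(1))
  data.frame(kmer = x, total_at = as.integer(total_at),
             max_run_at = as.integer(max_run),
             stringsAsFactors = FALSE)
}

#' Hamming distance between equal-length sequences
#'
#' @param a,b character vectors of equal-length sequences (recycled against
#'   each other as usual).
#' @return integer vector of per-pair mismatch counts.
#' @export
hamming_distance <- function(a, b) {
  assert_dna(a, "a")
  assert_dna(b, "b")
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  if (any(nchar(a) != nchar(b))) {
    stop("hamming_distance requires equal-length sequences", call. = FALSE)
  }
  mapply(function(x, y) {
    sum(strsplit(x, "", fixed = TRUE)[[1]] != strsplit(y, "", fixed = TRUE)[[1]])
  }, a, b, USE.NAMES = FALSE)
}

#' Enumerate all canonical k-mers
#'
#' Every k-mer maps via [canonical_kmer()] to exactly one entry of the
#' returned list; e.g. the 4096 6-mers collapse to 2080 canonical 6-mers.
#'
#' @param k k-mer length (1 to 12).
#' @return character vector of canonical k-mers, sorted lexicographically.
#' @examples
#' enumerate_canonical(1) # "A" "C"
#' length(enumerate_canonical(6)) # 2080
#' @export
enumerate_canonical <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    stop("k must be a positive integer", call. = FALSE)
  }
  k <- as.integer(k)
  .check_table_k(k)
  code_to_kmer(canonical_codes(k), k)
}
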