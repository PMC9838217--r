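# Brute-force reference implementations, kept deliberately naive and
# independent of the package's vectorised code paths.

random_dna <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
}

oracle_revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

oracle_canonical <- function(s) {
  rc <- oracle_revcomp(s)
  if (rc < s) rc else s
}

# per-read set-of-canonical-windows counting, one read at a time
oracle_count <- function(reads, k) {
  reads <- reads[nchar(reads) >= k]
  hits <- new.env(parent = emptyenv())
  for (r in reads) {
    seen <- character(0)
    for (i in seq_len(nchar(r) - k + 1)) {
      win <- substr(r, i, i + k - 1)
      if (grepl("[^ACGT]", win)) next
      seen <- union(seen, oracle_canonical(win))
    }
    for (km in seen) {
      hits[[km]] <- (hits[[km]] %||% 0L) + 1L
    }
  }
  list(counts = hits, total = length(reads))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

oracle_hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# enumerate all (window, seed, orientation) triples per the matching rules
oracle_match_windows <- function(reads, seeds, max_mismatch = 1) {
  k <- nchar(seeds[1])
  refs <- list()
  for (s in seeds) {
    refs[[length(refs) + 1]] <- list(seq = s, emit = identity)
    rc <- oracle_revcomp(s)
    refs[[length(refs) + 1]] <- list(seq = rc, emit = oracle_revcomp)
  }
  out <- character(0)
  for (r in reads) {
    if (nchar(r) < k) next
    for (i in seq_len(nchar(r) - k + 1)) {
      win <- substr(r, i, i + k - 1)
      if (grepl("[^ACGT]", win)) next
      d <- vapply(refs, function(rf) oracle_hamming(win, rf$seq), numeric(1))
      best <- which.min(d)   # first minimum: earlier seed, then forward
      if (d[best] <= max_mismatch) {
        out <- c(out, refs[[best]]$emit(win))
      }
    }
  }
  out
}

oracle_pfm <- function(windows) {
  k <- nchar(windows[1])
  m <- matrix(0L, 4, k, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (w in windows) {
    for (j in seq_len(k)) {
      b <- substr(w, j, j)
      m[b, j] <- m[b, j] + 1L
    }
  }
  m
}

oracle_overlap <- function(sets) {
  kmers <- unique(unlist(sets))
  counts <- list()
  for (km in kmers) {
    inset <- names(sets)[vapply(sets, function(s) km %in% s, logical(1))]
    key <- paste(inset, collapse = "&")
    counts[[key]] <- (counts[[key]] %||% 0L) + 1L
  }
  counts
}
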