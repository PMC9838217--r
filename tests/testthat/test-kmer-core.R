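test_that("reverse complement handles bases, palindromes and random sequences", {
  expect_equal(reverse_complement("A"), "T")
  expect_equal(reverse_complement("ATATT"), "AATAT")
  # a palindromic duplex site is its own reverse complement
  expect_equal(reverse_complement("GATATTAATATC"), "GATATTAATATC")
  set.seed(11)
  seqs <- random_dna(50, 12)
  expect_equal(reverse_complement(seqs),
               vapply(seqs, oracle_revcomp, character(1), USE.NAMES = FALSE))
  # involution
  expect_equal(reverse_complement(reverse_complement(seqs)), seqs)
  expect_error(reverse_complement("ACGN"), "invalid")
  expect_error(reverse_complement(character(0)), "empty")
})

test_that("canonicalisation picks the lexicographically smaller strand", {
  expect_equal(canonical_kmer("TAATAT"), "ATATTA")
  expect_equal(canonical_kmer("ATATT"), "AATAT")
  expect_equal(canonical_kmer("GATATTAATATC"), "GATATTAATATC")
  expect_error(canonical_kmer("ACGU"), "invalid")
})

test_that("canonicalisation is idempotent and strand-invariant over all 6-mers", {
  # exhaustive: all 4096 six-mers
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid, rep(list(bases), 6))
  all_kmers <- do.call(paste0, grid)
  expect_length(all_kmers, 4096)
  canon <- canonical_kmer(all_kmers)
  expect_equal(canon, canonical_kmer(reverse_complement(all_kmers)))
  expect_equal(canonical_kmer(canon), canon)
  expect_setequal(unique(canon), enumerate_canonical(6))
})

test_that("canonical enumeration matches brute force for k = 1..6", {
  expect_equal(enumerate_canonical(1), c("A", "C"))
  expect_length(enumerate_canonical(2), 10)
  expect_length(enumerate_canonical(6), 2080)
  bases <- c("A", "C", "G", "T")
  for (k in 1:6) {
    grid <- do.call(expand.grid, rep(list(bases), k))
    brute <- sort(unique(vapply(do.call(paste0, grid), oracle_canonical,
                                character(1), USE.NAMES = FALSE)))
    expect_equal(enumerate_canonical(k), brute)
  }
  expect_error(enumerate_canonical(0), "positive")
})

test_that("composition counts total and longest-run A/T content", {
  comp <- kmer_composition(c("ATGATA", "GCGCGC", "ATTAAT"))
  expect_equal(comp$total_at, c(5L, 0L, 6L))
  expect_equal(comp$max_run_at, c(3L, 0L, 6L))
  # property: run never exceeds total; boundary cases pin each other
  set.seed(23)
  seqs <- random_dna(300, 6)
  comp <- kmer_composition(seqs)
  expect_true(all(comp$max_run_at <= comp$total_at))
  expect_true(all((comp$total_at == 0) == (comp$max_run_at == 0) |
                    comp$total_at > 0))
  expect_true(all(comp$max_run_at[comp$total_at == 6] == 6))
  # independent oracle via run-length encoding
  oracle_run <- vapply(strsplit(seqs, ""), function(b) {
    r <- rle(b %in% c("A", "T"))
    if (!any(r$values)) 0L else max(r$lengths[r$values])
  }, integer(1))
  expect_equal(comp$max_run_at, oracle_run)
})

test_that("hamming distance is symmetric, zero on identity, errors on length mismatch", {
  expect_equal(hamming_distance("ATATAT", "ATATAT"), 0L)
  expect_equal(hamming_distance("ATATAT", "ATCTAT"), 1L)
  expect_equal(hamming_distance("AAAAAA", "TTTTTT"), 6L)
  expect_equal(hamming_distance("ACGT", "TGCA"), hamming_distance("TGCA", "ACGT"))
  expect_error(hamming_distance("ACG", "ACGT"), "equal-length")
})
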