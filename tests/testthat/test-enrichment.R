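test_that("read-containment counting has presence/absence semantics", {
  tab <- count_containing_reads("GATATT", k = 6)
  expect_s3_class(tab, "kmer_count_table")
  expect_equal(tab$kmer[tab$containing_reads > 0], "AATATC")
  expect_equal(tab$fraction[tab$kmer == "AATATC"], 1)
  # three windows per read all canonicalise to ATATAT but count once per read
  tab2 <- count_containing_reads(c("ATATATAT", "ATATATAT"), k = 6)
  expect_equal(tab2$containing_reads[tab2$kmer == "ATATAT"], 2L)
  expect_equal(tab2$fraction[tab2$kmer == "ATATAT"], 1)
})

test_that("counting matches the brute-force oracle on random reads", {
  set.seed(42)
  reads <- random_dna(100, 20)
  tab <- count_containing_reads(reads, 6)
  orc <- oracle_count(reads, 6)
  expect_equal(attr(tab, "total_reads"), orc$total)
  for (i in which(tab$containing_reads > 0)) {
    expect_equal(tab$containing_reads[i],
                 orc$counts[[tab$kmer[i]]] %||% 0L)
  }
  expect_equal(sum(tab$containing_reads),
               sum(unlist(as.list(orc$counts))))
  # duplicating every read leaves all fractions unchanged
  tab3 <- count_containing_reads(rep(reads, 3), 6)
  expect_equal(tab3$fraction, tab$fraction)
  # reads with at least one valid window bound the containment sum below
  expect_gte(sum(tab$containing_reads), orc$total)
})

test_that("short reads are excluded with a warning; invalid windows skipped", {
  expect_warning(tab <- count_containing_reads(c("GATATT", "ACG"), 6),
                 "shorter than k")
  expect_equal(attr(tab, "total_reads"), 1L)
  # an N voids only the windows that touch it
  tab <- count_containing_reads("GATATTNATATATT", 6)
  orc <- oracle_count("GATATTNATATATT", 6)
  for (i in which(tab$containing_reads > 0)) {
    expect_equal(tab$containing_reads[i], orc$counts[[tab$kmer[i]]] %||% 0L)
  }
  expect_error(count_containing_reads(character(0), 6), "empty")
})

test_that("fold change is a plain fraction ratio with undefined flags", {
  set.seed(7)
  reads <- random_dna(60, 20)
  tab <- count_containing_reads(read_set(reads, "WT", 1, 6), 6)
  zero <- count_containing_reads(read_set(reads, "WT", 1, 0), 6)
  enr <- fold_change(tab, zero)
  def <- !is.na(enr$fold_change)
  expect_true(all(enr$fold_change[def] == 1))
  # undefined exactly where cycle 0 fraction is zero, never infinite
  expect_equal(is.na(enr$fold_change), zero$fraction == 0)
  expect_false(any(is.infinite(enr$fold_change)))
  # a doubled fraction gives fold change 2
  t2 <- count_containing_reads(read_set(c("GATATT"), "WT", 1, 6), 6)
  z2 <- count_containing_reads(read_set(c("GATATT", "GGGGGG"), "WT", 1, 0), 6)
  e2 <- fold_change(t2, z2)
  expect_equal(e2$fold_change[e2$kmer == "AATATC"], 2)
  expect_error(fold_change(tab, count_containing_reads(reads, 5)),
               "mismatched k")
})

test_that("group summaries aggregate per-replicate means and replicate spread", {
  set.seed(9)
  reads <- random_dna(50, 20)
  mk <- function(fc_mult, rep_i) {
    tab <- count_containing_reads(read_set(reads, "WT", rep_i, 6), 6)
    zero <- count_containing_reads(read_set(reads, "WT", rep_i, 0), 6)
    enr <- fold_change(tab, zero)
    enr$fold_change <- enr$fold_change * fc_mult
    enr
  }
  one <- summarise_groups(mk(1, 1), "total_at")
  expect_equal(nrow(one), 7L)              # groups 0..6
  expect_equal(one$group, 0:6)
  expect_true(all(one$mean_fc[one$n_kmers > 0] == 1))
  expect_true(all(one$sd_fc[one$n_kmers > 0] == 0))
  # replicate means 1, 2, 3 -> mean 2, sample sd 1
  three <- summarise_groups(list(mk(1, 1), mk(2, 2), mk(3, 3)), "total_at")
  expect_equal(three$mean_fc[three$n_kmers > 0],
               rep(2, sum(three$n_kmers > 0)))
  expect_equal(three$sd_fc[three$n_kmers > 0],
               rep(1, sum(three$n_kmers > 0)))
  expect_error(summarise_groups(list(mk(1, 1),
                                     fold_change(
                                       count_containing_reads(read_set(reads, "other", 1, 6), 6),
                                       count_containing_reads(read_set(reads, "other", 1, 0), 6)))),
               "one sample")
})

test_that("top-N ranking is descending with lexicographic ties", {
  reads <- c("AAAAAATTTTTT", "GGGGGGCCCCCC")
  tab <- count_containing_reads(read_set(reads, "s", 1, 6), 6)
  zero <- count_containing_reads(read_set(rep(reads, 2), "s", 1, 0), 6)
  enr <- fold_change(tab, zero)
  expect_equal(length(top_kmers(enr, 3)), 3L)
  # all defined fold changes tie at 1 here: order must be lexicographic
  expect_warning(all_top <- top_kmers(enr, 2080), "defined fold change")
  expect_equal(all_top, sort(all_top))
  # unique maximum comes first
  enr$fold_change[enr$kmer == "ATATAT"] <- 99
  expect_equal(top_kmers(enr, 1), "ATATAT")
})

test_that("Venn overlap counts match brute-force membership tabulation", {
  a <- enumerate_canonical(6)[1:100]
  expect_equal(overlap_sets(list(x = a, y = a, z = a))$count,
               c(0, 0, 0, 0, 0, 0, 100))
  b <- enumerate_canonical(6)[101:200]
  two <- overlap_sets(list(x = a, y = b))
  expect_equal(two$count[two$region == "x"], 100)
  expect_equal(two$count[two$region == "x&y"], 0)
  set.seed(31)
  pool <- enumerate_canonical(6)
  sets <- list(p = sample(pool, 120), q = sample(pool, 80),
               r = sample(pool, 150))
  res <- overlap_sets(sets)
  orc <- oracle_overlap(sets)
  for (i in seq_len(nrow(res))) {
    expect_equal(res$count[i], orc[[res$region[i]]] %||% 0L,
                 info = res$region[i])
  }
  # each set's exclusive regions sum back to its size
  for (nm in names(sets)) {
    expect_equal(sum(res$count[grepl(nm, res$region)]), length(sets[[nm]]))
  }
  expect_error(overlap_sets(list(x = "TTTTTT", y = a[1:3])), "non-canonical")
})
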