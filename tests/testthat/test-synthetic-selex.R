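# smaller library sizes than the study conditions keep these unit tests
# fast; the full-size behaviour is exercised by the acceptance suite

test_that("initial library is deterministic, uniform and metadata-tagged", {
  cfg <- selex_config(n_reads_per_cycle = 5000, rng_seed = 3)
  lib1 <- sample_initial_library(cfg, "WT", 1)
  lib2 <- sample_initial_library(cfg, "WT", 1)
  expect_identical(lib1$reads, lib2$reads)
  expect_false(identical(lib1$reads,
                         sample_initial_library(cfg, "WT", 2)$reads))
  expect_equal(length(lib1$reads), 5000L)
  expect_true(all(nchar(lib1$reads) == 20L))
  # per-base frequency 0.25 within 3 sigma of binomial at n = 100,000 bases
  bases <- table(strsplit(paste(lib1$reads, collapse = ""), "")[[1]])
  n_bases <- 5000 * 20
  tol <- 3 * sqrt(0.25 * 0.75 / n_bases)
  expect_true(all(abs(bases / n_bases - 0.25) < tol))
  # mean A/T count of a random 6-mer window is 3
  comp <- kmer_composition(substr(lib1$reads, 1, 6))
  expect_lt(abs(mean(comp$total_at) - 3),
            3 * sqrt(1.5 / 5000))   # binomial(6, .5) variance 1.5
})

test_that("affinity is strand-symmetric, non-negative and AT-graded", {
  model <- affinity_model()
  set.seed(13)
  seqs <- random_dna(40, 20)
  a <- affinity(seqs, model)
  expect_true(all(a > 0))
  expect_equal(a, affinity(reverse_complement(seqs), model))
  # all-G minimal, embedded all-A/T window dominates
  lows <- affinity(strrep("G", 20), model)
  high <- affinity(paste0(strrep("G", 7), "ATATTA", strrep("G", 7)), model)
  expect_lt(lows, high)
  expect_true(all(a > lows))
  # reduced-affinity scaling is exact
  expect_equal(affinity(seqs, affinity_model(affinity_scale = 0.1)), 0.1 * a)
  # constant mode (negative control) ignores sequence
  expect_equal(length(unique(affinity(seqs, affinity_model(beta = 0)))), 1L)
  expect_error(affinity("ACG", model), "shorter")
})

test_that("pwm mode evaluates both strands", {
  E <- matrix(-3, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  E["A", ] <- 0   # prefers AAAAAA; its complement TTTTTT scores via rc strand
  model <- affinity_model("pwm", energy = E)
  expect_equal(affinity("TTTTTTTTTT", model), affinity("AAAAAAAAAA", model))
  set.seed(5)
  seqs <- random_dna(20, 12)
  expect_equal(affinity(seqs, model),
               affinity(reverse_complement(seqs), model))
})

test_that("one AT-preferring cycle enriches all-A/T 6-mers over cycle 0", {
  cfg <- selex_config(n_reads_per_cycle = 5000, n_cycles = 1)
  model <- affinity_model()
  for (seed in 1:3) {
    lib0 <- sample_initial_library(cfg, "WT", 1, seed = seed)
    set.seed(seed + 500)
    lib1 <- run_cycle(lib0, model, cfg)
    t0 <- count_containing_reads(lib0, 6)
    t1 <- count_containing_reads(lib1, 6)
    anno <- kmer_composition(t0$kmer)
    all_at <- anno$total_at == 6
    expect_gt(mean(t1$fraction[all_at]), mean(t0$fraction[all_at]))
  }
})

test_that("constant-affinity selection leaves group fold changes near 1", {
  cfg <- selex_config(n_reads_per_cycle = 20000, n_cycles = 1)
  model <- affinity_model(beta = 0)
  lib0 <- sample_initial_library(cfg, "control", 1, seed = 99)
  set.seed(100)
  lib1 <- run_cycle(lib0, model, cfg)
  enr <- fold_change(count_containing_reads(lib1, 6),
                     count_containing_reads(lib0, 6))
  gs <- summarise_groups(enr, "total_at")
  expect_true(all(abs(gs$mean_fc[gs$n_kmers > 0] - 1) < 0.1))
})

test_that("simulation output is reproducible byte-for-byte with a manifest", {
  cfg <- selex_config(n_reads_per_cycle = 300, n_cycles = 3,
                      cycles_keep = c(0, 3), replicates = 2, rng_seed = 17)
  models <- list(WT = affinity_model())
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_selex(cfg, models, output_dir = d1, overwrite = TRUE)
  s2 <- simulate_selex(cfg, models, output_dir = d2, overwrite = TRUE)
  expect_identical(names(s1$read_sets), names(s2$read_sets))
  # 2 samples (WT + control) x 2 replicates x 2 kept cycles
  expect_length(s1$read_sets, 2 * 2 * 2)
  for (nm in names(s1$read_sets)) {
    expect_identical(s1$read_sets[[nm]]$reads, s2$read_sets[[nm]]$reads)
  }
  f1 <- list.files(d1, recursive = TRUE)
  expect_true("manifest.json" %in% f1)
  expect_identical(tools::md5sum(file.path(d1, f1)) |> unname(),
                   tools::md5sum(file.path(d2, f1)) |> unname())
  # refuses to clobber without the flag
  expect_error(simulate_selex(cfg, models, output_dir = d1), "overwrite")
})

test_that("selection with impossible stringency fails with advice", {
  cfg <- selex_config(n_reads_per_cycle = 50, n_cycles = 1,
                      half_saturation = 1e12, background_affinity = 0)
  lib <- sample_initial_library(cfg, "WT", 1, seed = 1)
  set.seed(2)
  expect_error(run_cycle(lib, affinity_model(), cfg),
               "retained no sequences")
})
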