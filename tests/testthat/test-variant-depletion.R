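annot <- protein_annotation("PROT", 1000, data.frame(
  name = c("zf_a", "zf_b", "whole"),
  start = c(101, 501, 1),
  end = c(200, 550, 1000)))

test_that("Vp is the positional missense fraction", {
  small <- protein_annotation("P", 100,
                              data.frame(name = "d", start = 1, end = 10))
  expect_equal(compute_vp(integer(0), small), 0)
  expect_equal(compute_vp(1:100, small), 1)
  expect_equal(compute_vp(seq_len(38), small), 0.38)
  expect_equal(compute_vp(c(5, 5, 5, 9), small), 0.02)  # duplicates collapse
  expect_error(compute_vp(101, small), "out of bounds: 101")
  expect_error(protein_annotation("P", 100,
                                  data.frame(name = "d", start = 0, end = 10)),
               "invalid domain")
})

test_that("a whole-protein pseudo-domain has Vd/Vp exactly 1", {
  set.seed(2)
  for (i in 1:5) {
    pos <- sample(1000, 150 + 10 * i)
    res <- compute_vdvp(pos, annot, "whole")
    expect_identical(res$VdVp, 1)
    rep <- depletion_report(pos, annot)
    expect_identical(rep$vdvp[rep$region == "PROT"], 1)
    expect_identical(rep$vdvp[rep$region == "whole"], 1)
  }
  expect_error(compute_vdvp(integer(0), annot, "whole"), "undefined")
  expect_error(compute_vdvp(5, annot, "nope"), "unknown domain")
})

test_that("empty domains score zero and within-domain variants raise VdVp", {
  pos <- c(300:340)   # nothing inside zf_a
  expect_equal(compute_vdvp(pos, annot, "zf_a")$Vd, 0)
  expect_equal(compute_vdvp(pos, annot, "zf_a")$VdVp, 0)
  # monotonicity: adding within-domain positions at fixed outside content
  # never decreases the domain ratio
  inside <- 101:200
  ratios <- vapply(seq(0, 100, by = 20), function(n_in) {
    compute_vdvp(c(pos, inside[seq_len(n_in)]), annot, "zf_a")$VdVp
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("uniform random placement gives domain VdVp unbiased around 1", {
  set.seed(404)
  ratios <- vapply(1:100, function(i) {
    pos <- which(stats::runif(1000) < 0.4)
    compute_vdvp(pos, annot, "zf_a")$VdVp
  }, numeric(1))
  # 3 sigma tolerance on the Monte-Carlo mean of a binomial-driven ratio:
  # sd(Vd) = sqrt(.4*.6/100), Vd ~ .4 => sd(ratio) ~ 0.1225
  expect_lt(abs(mean(ratios) - 1), 3 * 0.1225 / sqrt(100) + 0.01)
})

test_that("clinical-vs-population filtering is an exact positional set difference", {
  expect_equal(filter_candidates(c(4, 2, 9), integer(0)), c(2L, 4L, 9L))
  expect_equal(filter_candidates(c(4, 2), c(2, 4)), integer(0))
  expect_equal(filter_candidates(c(1, 2, 3), c(7, 8)), 1:3)
  # 56 clinical positions of which 45 coincide with population ones -> 11
  set.seed(77)
  clinical <- sample(900, 56)
  population <- c(sample(clinical, 45), setdiff(sample(900, 300), clinical))
  kept <- filter_candidates(clinical, population)
  expect_length(kept, 11L)
  expect_true(all(kept %in% clinical) && !any(kept %in% population))
})
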