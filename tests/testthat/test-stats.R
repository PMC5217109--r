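test_that("deletion-length bins are exhaustive with inclusive upper edges", {
  d <- bin_deletions(c(5, 10, 25, 50))
  expect_equal(d$count, c(1L, 1L, 1L, 1L))
  expect_equal(d$fraction, rep(0.25, 4))

  d <- bin_deletions(c(9, 19, 49))
  expect_equal(d$count, c(1L, 1L, 1L, 0L))

  expect_error(bin_deletions(c(3, 0, 5)), "intact")
  expect_error(bin_deletions(integer()), "no deletion")

  withr::with_seed(8, {
    lens <- sample(1:120, 300, replace = TRUE)
    d <- bin_deletions(lens)
    expect_equal(sum(d$fraction), 1)
    expect_equal(sum(d$count), 300L)
  })
})

test_that("Mann-Whitney exact p matches enumeration; U statistics are consistent", {
  res <- mwu_test(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_equal(res$p_two_tailed, 1 / 3, tolerance = 1e-12)
  expect_equal(res$method, "exact")

  # identical multisets: ties route to the approximation and give p = 1
  res <- mwu_test(c(5, 5, 5), c(5, 5, 5))
  expect_equal(res$p_two_tailed, 1)
  expect_equal(res$method, "normal_approx")

  withr::with_seed(55, {
    for (i in 1:100) {
      n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
      x <- runif(n1); y <- runif(n2)
      res <- mwu_test(x, y)
      expect_equal(res$method, "exact")
      expect_equal(res$p_two_tailed, oracle_mwu_exact(x, y), tolerance = 1e-12)
      # symmetry and U1 + U2 == n1 * n2
      expect_equal(res$p_two_tailed, mwu_test(y, x)$p_two_tailed,
                   tolerance = 1e-12)
      expect_equal(res$U + mwu_test(y, x)$U, n1 * n2)
    }
  })
})

test_that("exact and normal-approximation p-values agree for moderate samples", {
  withr::with_seed(66, {
    for (i in 1:100) {
      x <- rnorm(20); y <- rnorm(20, mean = runif(1, 0, 1))
      p_approx <- mwu_test(x, y)$p_two_tailed
      p_exact <- mwu_test(x, y, exact_max_n = 40L)$p_two_tailed
      expect_lt(abs(p_approx - p_exact), 0.02)
    }
  })
})

test_that("approximate p agrees with the standard tie-corrected implementation", {
  withr::with_seed(91, {
    for (i in 1:25) {
      x <- sample(1:30, 25, replace = TRUE)   # heavy ties
      y <- sample(1:40, 30, replace = TRUE)
      want <- suppressWarnings(
        stats::wilcox.test(x, y, correct = TRUE, exact = FALSE))$p.value
      expect_equal(mwu_test(x, y)$p_two_tailed, want, tolerance = 1e-9)
    }
  })
})

test_that("tidy and glance expose the test result as tibbles", {
  res <- mwu_test(c(1, 5, 9), c(2, 3, 11))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("U", "n1", "n2", "median1", "median2", "p.value",
                     "method"))
  expect_equal(glance(res)$nobs, 6L)
})

test_that("genotype contrasts emit one row per nuclease-mutant pair", {
  withr::with_seed(70, {
    events <- dplyr::tibble(
      genotype = rep(c("WT", "ku80"), each = 30),
      nuclease = rep(c("Cas9-CRU", "Cas9-PPO"), 30),
      event_class = "deletion",
      del_len = c(sample(3:12, 30, TRUE), sample(20:80, 30, TRUE)),
      ins_seq = "")
  })
  res <- compare_genotypes(events, "del_len")
  expect_equal(nrow(res), 2L)
  expect_setequal(res$nuclease, c("Cas9-CRU", "Cas9-PPO"))
  expect_true(all(res$group1 == "WT" & res$group2 == "ku80"))
  expect_true(all(res$significant))

  res_i <- suppressWarnings(compare_genotypes(events, "ins_len"))
  expect_equal(res_i$nuclease, "pooled")
  expect_true(is.na(res_i$p.value))   # no insertions at all
  expect_warning(compare_genotypes(events[c(1, 31), ], "del_len"),
                 "below minimum")
})

test_that("delins deletions are compared against plain deletions, NA when one-sided", {
  all_plain <- dplyr::tibble(genotype = "WT", nuclease = "Cas9-CRU",
                             event_class = "deletion",
                             del_len = c(5L, 8L, 12L), ins_seq = "")
  res <- suppressWarnings(deletion_with_without_insertion(all_plain))
  expect_true(is.na(res$p.value))

  withr::with_seed(13, {
    events <- dplyr::bind_rows(
      dplyr::tibble(genotype = "WT", nuclease = "Cas9-CRU",
                    event_class = "deletion",
                    del_len = sample(3:15, 50, TRUE), ins_seq = ""),
      dplyr::tibble(genotype = "ku80", nuclease = "Cas9-PPO",
                    event_class = "delins",
                    del_len = sample(3:15, 50, TRUE) * 3L, ins_seq = "ACGT"))
  })
  res <- deletion_with_without_insertion(events)
  expect_true(res$significant)
  expect_gt(res$median1, res$median2)
})

test_that("resistant band fraction is intensity over lane total", {
  expect_equal(resistant_fraction(30, c(30, 70)), 0.30)
  expect_equal(resistant_fraction(0, c(0, 100)), 0)
  expect_equal(resistant_fraction(50, c(50, 25, 25)), 0.50)
  expect_error(resistant_fraction(80, c(30, 40)), "exceeds")
  expect_error(resistant_fraction(0, c(0, 0)), "positive")
  expect_error(resistant_fraction(-1, c(10)), "non-negative")
})
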