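test_that("engrafted set logic matches the definition and a per-element oracle", {
  expect_setequal(engrafted_otus(c("A", "B", "C"), c("C", "D"), c("A", "C", "D")),
                  "A")
  # post == pre -> nothing new can engraft
  expect_length(engrafted_otus(c("A", "B"), c("A", "X"), c("A", "X")), 0)

  universe <- sprintf("otu%02d", 1:30)
  withr::with_seed(42, {
    for (i in 1:200) {
      donor <- sample(universe, rbinom(1, 30, 0.4))
      pre <- sample(universe, rbinom(1, 30, 0.4))
      post <- sample(universe, rbinom(1, 30, 0.4))
      got <- engrafted_otus(donor, pre, post)
      oracle <- universe[vapply(universe, function(o) {
        (o %in% donor) && (o %in% post) && !(o %in% pre)
      }, logical(1))]
      expect_setequal(got, oracle)
      expect_length(intersect(got, pre), 0)  # disjoint from baseline
    }
  })
})

test_that("engraftment percent honours all three denominators", {
  post <- c(A = 30L, C = 50L, D = 20L)
  expect_equal(engraftment_percent("A", c("A", "B"), post, "abundance"), 30)
  expect_equal(engraftment_percent(character(), c("A", "B"), post, "abundance"), 0)
  expect_equal(engraftment_percent(character(), c("A", "B"), post,
                                   "donor_richness"), 0)
  expect_equal(engraftment_percent("A", c("A", "B", "C"), post,
                                   "donor_richness"), 100 / 3)
  expect_equal(engraftment_percent("A", c("A", "B"), post, "post_richness"),
               100 / 3)
  expect_warning(
    res <- engraftment_percent(character(), character(), post, "donor_richness"),
    "empty donor")
  expect_true(is.na(res))
  expect_error(engraftment_percent("Z", c("A"), post), "subset")
})

test_that("timepoint averaging handles missing weeks with a flag", {
  avg <- average_engraftment(c(20, 8, NA, NA), c(11, NA, 4, NA))
  expect_equal(avg$percent_avg, c(15.5, 8, 4, NA))
  expect_equal(avg$single_timepoint, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(avg$n_timepoints, c(2, 1, 1, 0))
})

test_that("compute_engraftment works through table + metadata and flags exclusions", {
  # donor carries X and Y; subject has Y at baseline; post gains X
  m <- matrix(0L, 4, 4, dimnames = list(
    c("D01", "p1_baseline", "p1_week1", "p1_week10"),
    c("X", "Y", "Z", "W")))
  m["D01", ] <- c(50L, 50L, 0L, 0L)
  m["p1_baseline", ] <- c(0L, 30L, 70L, 0L)
  m["p1_week1", ] <- c(25L, 25L, 50L, 0L)
  m["p1_week10", ] <- c(10L, 40L, 50L, 0L)
  meta <- tibble::tibble(
    sample_id = rownames(m),
    subject_id = c("D01", "p1", "p1", "p1"),
    arm = c("donor", "FMT", "FMT", "FMT"),
    timepoint = c("donor", "baseline", "week1", "week10"),
    donor_ids = c(NA, "D01", "D01", "D01"))
  eng <- compute_engraftment(otu_table(m), meta)
  expect_equal(nrow(eng), 1)
  expect_equal(eng$percent_w1, 25)   # X carries 25 of 100 reads
  expect_equal(eng$percent_w10, 10)
  expect_equal(eng$percent_avg, 17.5)
  expect_equal(eng$n_engrafted_w1, 1)

  # drop the baseline sample -> subject excluded with a warning
  expect_warning(
    eng2 <- compute_engraftment(otu_table(m[-2, ]), meta[-2, ]),
    "no unique baseline")
  expect_equal(nrow(eng2), 0)
  expect_equal(attr(eng2, "exclusions")$reason, "no unique baseline sample")

  # only week1 present -> single-timepoint flag
  eng3 <- compute_engraftment(otu_table(m[-4, ]), meta[-4, ])
  expect_true(eng3$single_timepoint)
  expect_equal(eng3$percent_avg, 25)
})

test_that("arm comparison reduces to symmetric nulls and recovers ordering", {
  same <- tibble::tibble(
    subject_id = sprintf("p%d", 1:9),
    arm = rep(c("FMT", "R-FMT", "CM-FMT"), each = 3),
    percent_avg = rep(c(1, 5, 9), times = 3))
  res <- compare_engraftment_by_arm(same)
  expect_lt(res$omnibus$statistic, 1e-10)
  expect_true(all(res$pairwise$p.value > 0.99))

  sep <- tibble::tibble(
    subject_id = sprintf("p%d", 1:9),
    arm = rep(c("FMT", "R-FMT", "CM-FMT"), each = 3),
    percent_avg = c(21, 22, 23, 11, 12, 13, 1, 2, 3))
  res2 <- compare_engraftment_by_arm(sep)
  med <- setNames(res2$medians$median, res2$medians$arm)
  expect_true(med[["FMT"]] > med[["R-FMT"]] && med[["R-FMT"]] > med[["CM-FMT"]])
  # omnibus p against the exact permutation oracle at n = 9
  exact <- kruskal_wallis(sep$percent_avg, sep$arm, exact = TRUE)
  oracle <- kw_exact_oracle(sep$percent_avg, sep$arm)
  expect_equal(exact$p.value, oracle, tolerance = 1e-12)

  small <- dplyr::bind_rows(sep, tibble::tibble(
    subject_id = "p10", arm = "extra", percent_avg = 5))
  expect_warning(compare_engraftment_by_arm(small, arms = c(unique(sep$arm), "extra")),
                 "excluded: extra")
})

test_that("responder comparison is an exact Mann-Whitney at small n", {
  res <- tibble::tibble(
    subject_id = sprintf("p%d", 1:6),
    arm = "FMT",
    percent_avg = c(1, 2, 3, 10, 11, 12))
  flags <- tibble::tibble(subject_id = res$subject_id,
                          responder = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  out <- compare_engraftment_by_response(res, flags)
  expect_equal(out$p.value, mwu_exact_oracle(c(1, 2, 3), c(10, 11, 12)))
  expect_equal(out$p.value, 0.1)

  # identical distributions -> p == 1
  flags2 <- tibble::tibble(subject_id = res$subject_id,
                           responder = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  res2 <- dplyr::mutate(res, percent_avg = rep(c(4, 7, 9), 2))
  expect_equal(compare_engraftment_by_response(res2, flags2)$p.value, 1)

  # label shuffling under the null gives no systematic rejection
  withr::with_seed(5, {
    vals <- rnorm(12)
    ps <- replicate(50, {
      f <- tibble::tibble(subject_id = sprintf("p%d", 1:12),
                          responder = sample(rep(c(TRUE, FALSE), 6)))
      d <- tibble::tibble(subject_id = f$subject_id, arm = "FMT",
                          percent_avg = vals)
      compare_engraftment_by_response(d, f)$p.value
    })
    expect_lt(mean(ps < 0.05), 0.2)
    expect_gt(median(ps), 0.2)
  })

  expect_warning(
    out3 <- compare_engraftment_by_response(
      res, tibble::tibble(subject_id = res$subject_id, responder = TRUE)),
    "empty")
  expect_true(is.na(out3$p.value))
})
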