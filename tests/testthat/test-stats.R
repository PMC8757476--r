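test_that("summary-statistics ANOVA equals raw-data ANOVA on reconstructed data", {
  withr::with_seed(2, {
    for (rep in 1:5) {
      k <- sample(3:5, 1)
      n <- sample(4:12, k, replace = TRUE)
      mu <- rnorm(k, 0, 5); s <- runif(k, 0.5, 4)
      raw <- purrr::map2(seq_len(k), seq_len(k), function(i, j) {
        raw_from_summary(n[i], mu[i], s[i], seed = 100 + i + rep * 10)
      })
      g <- factor(rep(seq_len(k), times = n))
      x <- unlist(raw)
      ref <- summary(aov(x ~ g))[[1]]
      got <- anova_oneway_summary(
        tibble::tibble(n = n, mean = mu, sd = s))
      expect_equal(got$statistic, ref["g", "F value"], tolerance = 1e-10)
      expect_equal(got$p.value, ref["g", "Pr(>F)"], tolerance = 1e-10)
    }
  })
  # identical means -> F = 0, p = 1
  null <- anova_oneway_summary(tibble::tibble(n = c(5, 6), mean = c(2, 2),
                                              sd = c(1, 2)))
  expect_equal(null$statistic, 0)
  expect_equal(null$p.value, 1)
  expect_error(anova_oneway_summary(tibble::tibble(n = c(1, 5), mean = 0:1,
                                                   sd = c(1, 1))), "n >= 2")
})

test_that("summary t-tests equal stats::t.test on reconstructed raw data", {
  a <- raw_from_summary(9, 1.3, 2.1, seed = 4)
  b <- raw_from_summary(12, -0.4, 1.5, seed = 5)
  for (variant in c("pooled", "welch")) {
    ref <- stats::t.test(a, b, var.equal = variant == "pooled")
    got <- t_test_summary(list(n = 9, mean = 1.3, sd = 2.1),
                          list(n = 12, mean = -0.4, sd = 1.5),
                          variant = variant)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-10)
  }
  sym <- t_test_summary(list(n = 5, mean = 2, sd = 1),
                        list(n = 5, mean = 2, sd = 1))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p.value, 1)
  degen <- t_test_summary(list(n = 5, mean = 2, sd = 0),
                          list(n = 4, mean = 2, sd = 0))
  expect_true(degen$zero_variance)
  expect_equal(degen$p.value, 1)
})

test_that("Kruskal-Wallis H agrees with stats::kruskal.test incl. ties", {
  withr::with_seed(3, {
    for (rep in 1:10) {
      g <- factor(rep(1:3, times = sample(3:8, 3, replace = TRUE)))
      x <- round(rnorm(length(g)), 1)  # rounding induces ties
      ref <- stats::kruskal.test(x, g)
      got <- kruskal_wallis(x, g)
      expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
    }
  })
  ident <- kruskal_wallis(rep(c(1, 2), 3), rep(1:3, each = 2))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p.value, 1)
  expect_error(kruskal_wallis(1:3, c(1, 1, 1)), "2 groups")
})

test_that("exact permutation KW p equals the enumeration oracle", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(1:3, each = 3)
  got <- kruskal_wallis(x, g, exact = TRUE)
  expect_equal(got$p.value, kw_exact_oracle(x, g), tolerance = 1e-12)
  # chi-square approximation is within enumeration error at this n
  approx <- kruskal_wallis(x, g)
  expect_equal(approx$p.value, got$p.value, tolerance = 0.05)
  # two groups: agrees with Mann-Whitney normal approximation asymptotically
  withr::with_seed(14, {
    a <- rnorm(40); b <- rnorm(40, 0.4)
    kw <- kruskal_wallis(c(a, b), rep(1:2, each = 40))
    mw <- mann_whitney_u(a, b)
    expect_equal(kw$p.value, mw$p.value, tolerance = 0.02)
  })
})

test_that("Dunn posttest behaves on symmetric and separated groups", {
  g <- rep(c("a", "b", "c"), each = 4)
  x <- rep(c(1, 2, 3, 4), times = 3)
  res <- dunn_posttest(x, g)
  expect_true(all(abs(res$statistic) < 1e-12))
  expect_true(all(res$p.value > 0.999))

  x2 <- c(1:5, 11:15, 21:25)
  g2 <- rep(c("a", "b", "c"), each = 5)
  res2 <- dunn_posttest(x2, g2)
  z <- setNames(abs(res2$statistic), paste(res2$group1, res2$group2))
  expect_gt(z[["a c"]], z[["a b"]])
  expect_gt(z[["a c"]], z[["b c"]])

  # two of three groups identical in distribution -> their z is 0
  x3 <- c(1, 2, 3, 1, 2, 3, 11, 12, 13)
  res3 <- dunn_posttest(x3, rep(c("a", "b", "c"), each = 3))
  ab <- res3[res3$group1 == "a" & res3$group2 == "b", ]
  expect_equal(ab$statistic, 0)
  expect_equal(ab$p.value, 1)
  expect_error(dunn_posttest(1:4, rep(1:2, 2)), ">= 3 groups")

  bonf <- dunn_posttest(x2, g2, adjust = "bonferroni")
  expect_equal(bonf$p.value, pmin(1, res2$p.value * 3))
})

test_that("Mann-Whitney U is exact at small n and converges to the approximation", {
  got <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(got$p.value, 0.1)
  expect_equal(got$method, "exact enumeration")
  expect_equal(mann_whitney_u(c(2, 4, 9), c(2, 4, 9))$p.value, 1)

  withr::with_seed(6, {
    for (i in 1:10) {
      a <- sample(1:40, 6); b <- sample(1:40, 7)
      expect_equal(mann_whitney_u(a, b)$p.value, mwu_exact_oracle(a, b),
                   tolerance = 1e-12)
      # ties included
      a2 <- sample(1:6, 5, replace = TRUE); b2 <- sample(1:6, 5, replace = TRUE)
      expect_equal(mann_whitney_u(a2, b2)$p.value, mwu_exact_oracle(a2, b2),
                   tolerance = 1e-12)
    }
    # exact vs normal approximation at n = 8 per group
    a <- rnorm(8); b <- rnorm(8, 0.8)
    exact <- mann_whitney_u(a, b)$p.value
    rt <- rank(c(a, b))
    u <- sum(rt[1:8]) - 8 * 9 / 2
    sigma <- sqrt(8 * 8 * 17 / 12)
    zc <- (u - 32 - sign(u - 32) * 0.5) / sigma
    approx <- 2 * pnorm(-abs(zc))
    expect_lt(abs(exact - approx), 0.01)
  })
})

test_that("2x2 Fisher equals hypergeometric summation for all margins <= 6", {
  for (a in 0:6) for (b in 0:6) for (cc in 0:6) for (d in 0:6) {
    tab <- rbind(c(a, b), c(cc, d))
    if (any(rowSums(tab) > 6) || any(colSums(tab) > 6)) next
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    got <- fisher_exact(tab)$p.value
    expect_equal(got, fisher_2x2_oracle(tab), tolerance = 1e-12)
  }
  # cross-check against stats::fisher.test on a few tables
  withr::with_seed(9, {
    for (i in 1:20) {
      tab <- matrix(rpois(4, 4), 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      expect_equal(fisher_exact(tab)$p.value,
                   stats::fisher.test(tab)$p.value, tolerance = 1e-6)
    }
  })
})

test_that("Freeman-Halton enumeration matches oracles and handles edge cases", {
  # all 2x3 tables with total n <= 12 against an independent enumeration
  withr::with_seed(10, {
    count <- 0
    for (i in 1:400) {
      tab <- matrix(rpois(6, 1.2), 2, 3)
      if (sum(tab) > 12 || sum(tab) == 0) next
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      count <- count + 1
      got <- fisher_exact(tab)$p.value
      expect_equal(got, fisher_2xc_oracle(tab), tolerance = 1e-10)
      expect_equal(got, stats::fisher.test(tab)$p.value, tolerance = 1e-6)
    }
    expect_gt(count, 100)
  })
  # proportional rows -> exact independence -> p = 1
  expect_equal(fisher_exact(rbind(c(2, 4, 6), c(1, 2, 3)))$p.value, 1)
  # Monte-Carlo option approximates the enumerated p, deterministically
  tab <- rbind(c(2, 4, 4, 4), c(6, 5, 3, 7))
  mc1 <- fisher_exact(tab, simulate = TRUE, B = 4000, seed = 11)$p.value
  mc2 <- fisher_exact(tab, simulate = TRUE, B = 4000, seed = 11)$p.value
  expect_identical(mc1, mc2)
  expect_equal(mc1, fisher_exact(tab)$p.value, tolerance = 0.05)
  expect_error(fisher_exact(matrix(1:2)), "2 x 2")
  expect_error(fisher_exact(rbind(c(500, 400, 300), c(200, 600, 100)),
                            max_tables = 1000), "simulate")
})

test_that("Tukey HSD ranks an outlying group lowest and reduces to a pooled t", {
  withr::with_seed(12, {
    x <- c(rnorm(6, 0), rnorm(6, 0.3), rnorm(6, 5))
    g <- rep(c("a", "b", "c"), each = 6)
    res <- tukey_hsd(x, g)
    pc <- res$adj.p.value[res$group2 == "c" | res$group1 == "c"]
    pab <- res$adj.p.value[res$group1 == "a" & res$group2 == "b"]
    expect_true(all(pc < pab))
    ident <- tukey_hsd(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
    expect_true(all(ident$adj.p.value > 0.999))
    # two groups: Tukey-adjusted p equals the pooled two-sample t p
    x2 <- c(rnorm(7), rnorm(8, 1))
    g2 <- rep(c("a", "b"), c(7, 8))
    two <- tukey_hsd(x2, g2)
    ref <- stats::t.test(x2 ~ g2, var.equal = TRUE)$p.value
    expect_equal(two$adj.p.value, ref, tolerance = 1e-8)
  })
  expect_error(tukey_hsd(1:3, c("a", "a", "b")), "n >= 2")
})

test_that("baseline-adjusted ANCOVA matches a direct linear model", {
  withr::with_seed(13, {
    arm <- rep(c("a", "b", "c"), each = 8)
    base <- rnorm(24, 300, 50)
    change <- -0.2 * base + rnorm(24, 0, 30)
    got <- ancova_baseline(change, arm, base)
    ref <- stats::anova(stats::lm(change ~ factor(arm) + base))
    expect_equal(got$p.value, ref[1, "Pr(>F)"], tolerance = 1e-12)
  })
})
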