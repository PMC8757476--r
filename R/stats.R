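#' One-way ANOVA reconstructed from group summaries
#'
#' Classical fixed-effects one-way ANOVA computed from per-group
#' (n, mean, sd) triples, as printed in trial outcome tables:
#' between-group sum of squares \eqn{SSB = \sum n_i (\bar x_i - \bar x)^2},
#' within-group \eqn{SSW = \sum (n_i - 1) s_i^2}, with
#' \eqn{F = (SSB/(k-1)) / (SSW/(N-k))} referred to an F distribution.
#'
#' @param groups A data frame with columns `n`, `mean`, `sd` (one row per
#'   group; an optional `label` column is carried through).
#' @return A one-row tibble: `statistic` (F), `df1`, `df2`, `p.value`.
#' @export
#' @examples
#' anova_oneway_summary(tibble::tibble(
#'   n = c(8, 9, 7, 11),
#'   mean = c(-32.3, -85.3, -114, -93.4),
#'   sd = c(124.8, 94.6, 149.3, 97.1)))
anova_oneway_summary <- function(groups) {
  groups <- as_tibble(groups)
  stopifnot(all(c("n", "mean", "sd") %in% names(groups)))
  if (nrow(groups) < 2) abort("need at least 2 groups")
  if (any(groups$n < 2)) abort("every group needs n >= 2")
  if (any(groups$sd < 0)) abort("sd must be non-negative")
  n <- groups$n; m <- groups$mean; s <- groups$sd
  k <- length(n); N <- sum(n)
  grand <- sum(n * m) / N
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum((n - 1) * s^2)
  df1 <- k - 1; df2 <- N - k
  if (ssw == 0) {
    f <- if (ssb == 0) 0 else Inf
  } else {
    f <- (ssb / df1) / (ssw / df2)
  }
  p <- if (is.infinite(f)) 0 else pf(f, df1, df2, lower.tail = FALSE)
  tibble(statistic = f, df1 = df1, df2 = df2, p.value = p)
}

#' Two-sample t-test from group summaries
#'
#' @param a,b Lists or one-row data frames with `n`, `mean`, `sd`.
#' @param variant `"pooled"` (equal-variance, df = n1 + n2 - 2; default) or
#'   `"welch"`.
#' @return A one-row tibble: `statistic` (t), `df`, `p.value`,
#'   `zero_variance` flag.
#' @export
t_test_summary <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  a <- as.list(as_tibble(a)); b <- as.list(as_tibble(b))
  if (a$n < 2 || b$n < 2) abort("both groups need n >= 2")
  zv <- a$sd == 0 && b$sd == 0
  if (zv && a$mean == b$mean) {
    return(tibble(statistic = 0, df = a$n + b$n - 2, p.value = 1,
                  zero_variance = TRUE))
  }
  if (variant == "pooled") {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  t <- (a$mean - b$mean) / se
  p <- if (is.infinite(t)) 0 else 2 * pt(-abs(t), df)
  tibble(statistic = t, df = df, p.value = p, zero_variance = zv)
}

rank_tie_stats <- function(x) {
  r <- rank(x)
  t <- table(r)
  list(ranks = r, tie_term = sum(t^3 - t))
}

kw_statistic <- function(values, group) {
  rt <- rank_tie_stats(values)
  N <- length(values)
  rbar <- tapply(rt$ranks, group, mean)
  n <- tapply(rt$ranks, group, length)
  h <- 12 / (N * (N + 1)) * sum(n * (rbar - (N + 1) / 2)^2)
  corr <- 1 - rt$tie_term / (N^3 - N)
  if (corr > 0) h <- h / corr else h <- 0
  h
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-square reference distribution
#' (k - 1 df), or an exact permutation p-value over all assignments of the
#' pooled values to groups for small samples.
#'
#' @param values Numeric outcome values.
#' @param group Group labels, same length as `values`.
#' @param exact If `TRUE`, compute the exact permutation p (total n <= 10
#'   only; the null distribution is enumerated over all distinct
#'   assignments).
#' @return A one-row tibble: `statistic` (H), `df`, `p.value`, `method`.
#' @export
kruskal_wallis <- function(values, group, exact = FALSE) {
  group <- as.factor(group)
  if (length(values) != length(group)) abort("values and group lengths differ")
  n <- table(group)
  if (any(n == 0)) abort("empty group in kruskal_wallis")
  if (length(n) < 2 || length(values) < 3) abort("need >= 2 groups, total n >= 3")
  h <- kw_statistic(values, group)
  df <- length(n) - 1
  if (exact) {
    N <- length(values)
    if (N > 10) abort("exact permutation p only supported for total n <= 10")
    perms <- group_assignments(as.integer(n))
    hs <- vapply(perms, function(idx) {
      kw_statistic(values, idx)
    }, numeric(1))
    p <- mean(hs >= h - 1e-12)
    method <- "exact permutation"
  } else {
    p <- pchisq(h, df, lower.tail = FALSE)
    method <- "chi-square approximation"
  }
  tibble(statistic = h, df = df, p.value = p, method = method)
}

# all distinct assignments of N positions into groups of sizes n
group_assignments <- function(n) {
  N <- sum(n)
  assign_rec <- function(avail, sizes) {
    if (length(sizes) == 1) {
      return(list(list(avail)))
    }
    out <- list()
    picks <- combn(avail, sizes[1], simplify = FALSE)
    for (p in picks) {
      rest <- assign_rec(setdiff(avail, p), sizes[-1])
      out <- c(out, lapply(rest, function(r) c(list(p), r)))
    }
    out
  }
  sets <- assign_rec(seq_len(N), n)
  lapply(sets, function(s) {
    g <- integer(N)
    for (i in seq_along(s)) g[s[[i]]] <- i
    factor(g)
  })
}

#' Dunn's posttest after Kruskal-Wallis
#'
#' Pairwise z statistics on pooled mean ranks with the tie-corrected rank
#' variance \eqn{\sigma^2 = N(N+1)/12 - \sum(t^3 - t) / (12(N-1))}; two-sided
#' normal p-values, unadjusted by default.
#'
#' @inheritParams kruskal_wallis
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return A tibble with one row per group pair: `group1`, `group2`,
#'   `statistic` (z), `p.value`.
#' @export
dunn_posttest <- function(values, group, adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  group <- as.factor(group)
  if (nlevels(group) < 3) abort("Dunn's posttest needs >= 3 groups")
  rt <- rank_tie_stats(values)
  N <- length(values)
  rbar <- tapply(rt$ranks, group, mean)
  n <- tapply(rt$ranks, group, length)
  sigma2 <- N * (N + 1) / 12 - rt$tie_term / (12 * (N - 1))
  pairs <- combn(levels(group), 2, simplify = FALSE)
  res <- purrr::map_dfr(pairs, function(pr) {
    se <- sqrt(sigma2 * (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
    z <- if (se == 0) 0 else (rbar[[pr[1]]] - rbar[[pr[2]]]) / se
    tibble(group1 = pr[1], group2 = pr[2], statistic = z,
           p.value = 2 * pnorm(-abs(z)))
  })
  if (adjust == "bonferroni") {
    res$p.value <- pmin(1, res$p.value * nrow(res))
  }
  res
}

#' Mann-Whitney U test
#'
#' Exact two-sided p by full enumeration of group assignments when
#' min(n1, n2) <= 8 (ties handled by enumeration over the observed values);
#' otherwise a normal approximation with tie correction and continuity
#' correction. U counts pairs where `a` exceeds `b` (ties count 1/2).
#'
#' @param a,b Numeric vectors.
#' @return A one-row tibble: `statistic` (U), `p.value`, `method`.
#' @export
mann_whitney_u <- function(a, b) {
  a <- as.numeric(na.omit(a)); b <- as.numeric(na.omit(b))
  n1 <- length(a); n2 <- length(b)
  if (n1 < 1 || n2 < 1) abort("both groups must be non-empty")
  u_stat <- function(x, y) {
    sum(vapply(x, function(v) sum(v > y) + 0.5 * sum(v == y), numeric(1)))
  }
  u <- u_stat(a, b)
  N <- n1 + n2
  if (min(n1, n2) <= 8 && choose(N, n1) <= 2e5) {
    pooled <- c(a, b)
    sel <- combn(N, n1, simplify = FALSE)
    us <- vapply(sel, function(idx) u_stat(pooled[idx], pooled[-idx]),
                 numeric(1))
    p_lo <- mean(us <= u + 1e-12)
    p_hi <- mean(us >= u - 1e-12)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact enumeration"
  } else {
    rt <- rank_tie_stats(c(a, b))
    mu <- n1 * n2 / 2
    sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - rt$tie_term / (N * (N - 1))))
    z <- (u - mu - sign(u - mu) * 0.5) / sigma
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  tibble(statistic = u, p.value = p, method = method)
}

log_table_prob <- function(cells, lr, lc, ltot) {
  # multiple hypergeometric probability of a table given its margins
  lr + lc - ltot - sum(lfactorial(cells))
}

enumerate_rxc <- function(rs, cs) {
  # all non-negative integer tables with row sums rs and column sums cs,
  # built cell by cell in row-major order with feasibility pruning
  R <- length(rs); C <- length(cs)
  out <- list()
  cell_rec <- function(tab, i, j, rrem, crem) {
    if (i == R) {
      # last row forced by column remainders
      if (any(crem > rrem[R] + 1e-9)) {} # infeasible guard, handled below
      tab[R, ] <- crem
      if (all(crem >= 0) && sum(crem) == rrem[R]) out[[length(out) + 1]] <<- tab
      return(invisible())
    }
    if (j == C) {
      # last cell of a non-final row forced by the row remainder
      v <- rrem[i]
      if (v <= crem[C]) {
        tab[i, C] <- v
        rrem[i] <- 0; crem[C] <- crem[C] - v
        cell_rec(tab, i + 1, 1, rrem, crem)
      }
      return(invisible())
    }
    for (v in 0:min(rrem[i], crem[j])) {
      tab[i, j] <- v
      r2 <- rrem; r2[i] <- r2[i] - v
      c2 <- crem; c2[j] <- c2[j] - v
      cell_rec(tab, i, j + 1, r2, c2)
    }
  }
  cell_rec(matrix(0L, R, C), 1, 1, rs, cs)
  out
}

#' Fisher's exact test for R x C contingency tables
#'
#' For 2 x 2 tables, the standard two-sided hypergeometric test: the sum of
#' probabilities of all tables (with the observed margins) whose point
#' probability does not exceed the observed table's. For larger tables, the
#' Freeman-Halton generalisation by exhaustive enumeration over tables with
#' fixed margins, with the same probability-mass rule. When enumeration is
#' infeasible a seeded Monte-Carlo estimate over `stats::r2dtable` draws is
#' available.
#'
#' @param table A non-negative integer matrix (at least 2 x 2).
#' @param simulate Use Monte-Carlo estimation instead of enumeration.
#' @param B Number of Monte-Carlo tables (default 10000).
#' @param seed Seed for the Monte-Carlo draw (required when `simulate`).
#' @param max_tables Enumeration budget; beyond it an error suggests
#'   `simulate = TRUE`.
#' @return A one-row tibble: `p.value`, `method`.
#' @export
fisher_exact <- function(table, simulate = FALSE, B = 10000, seed = NULL,
                         max_tables = 2e6) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != trunc(tab))) {
    abort("contingency table must contain non-negative integers")
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) abort("table must be at least 2 x 2")
  rs <- rowSums(tab); cs <- colSums(tab)
  ltot <- lfactorial(sum(tab))
  lr <- sum(lfactorial(rs)); lc <- sum(lfactorial(cs))
  lp_obs <- log_table_prob(tab, lr, lc, ltot)
  fuzz <- 1e-7
  if (simulate) {
    if (is.null(seed)) abort("simulate = TRUE requires a seed")
    p <- withr::with_seed(as.integer(seed), {
      draws <- r2dtable(B, rs, cs)
      lps <- vapply(draws, log_table_prob, numeric(1), lr, lc, ltot)
      (1 + sum(lps <= lp_obs + fuzz)) / (B + 1)
    })
    return(tibble(p.value = p, method = "monte-carlo"))
  }
  if (nrow(tab) == 2 && ncol(tab) == 2) {
    # hypergeometric summation over the one free cell
    x <- 0:min(rs[1], cs[1])
    d <- dhyper(x, cs[1], cs[2], rs[1])
    d_obs <- dhyper(tab[1, 1], cs[1], cs[2], rs[1])
    p <- sum(d[d <= d_obs * (1 + fuzz)])
    return(tibble(p.value = min(1, p), method = "hypergeometric 2x2"))
  }
  free_r <- rs[-length(rs)]; free_c <- cs[-length(cs)]
  budget <- prod(outer(free_r, free_c, function(r, c) pmin(r, c) + 1))
  if (budget > max_tables) {
    abort("margins too large for enumeration; use simulate = TRUE with a seed")
  }
  tabs <- enumerate_rxc(rs, cs)
  lps <- vapply(tabs, log_table_prob, numeric(1), lr, lc, ltot)
  p <- sum(exp(lps[lps <= lp_obs + fuzz]))
  tibble(p.value = min(1, p), method = "freeman-halton enumeration")
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range adjusted pairwise p-values after a one-way fit
#' (wraps `stats::aov` + `stats::TukeyHSD`).
#'
#' @inheritParams kruskal_wallis
#' @return A tibble: `group1`, `group2`, `estimate` (difference in means),
#'   `conf.low`, `conf.high`, `adj.p.value`.
#' @export
tukey_hsd <- function(values, group) {
  group <- as.factor(group)
  if (nlevels(group) < 2) abort("need >= 2 groups")
  if (any(table(group) < 2)) abort("every group needs n >= 2")
  fit <- aov(values ~ group, data = data.frame(values = values, group = group))
  th <- TukeyHSD(fit)$group
  labs <- strsplit(rownames(th), "-", fixed = TRUE)
  tibble(group1 = vapply(labs, `[`, character(1), 1),
         group2 = vapply(labs, `[`, character(1), 2),
         estimate = th[, "diff"], conf.low = th[, "lwr"],
         conf.high = th[, "upr"], adj.p.value = th[, "p adj"])
}

#' Baseline-adjusted comparison of a change score (ANCOVA)
#'
#' Linear model `change ~ arm + baseline`; reports the arm term's F test.
#' Provided as a sensitivity option mirroring analyses adjusted for baseline
#' severity.
#'
#' @param change Numeric change scores.
#' @param arm Arm labels.
#' @param baseline Baseline scores.
#' @return A one-row tibble: `statistic` (F for the arm term), `df1`, `df2`,
#'   `p.value`.
#' @export
ancova_baseline <- function(change, arm, baseline) {
  d <- data.frame(change = change, arm = as.factor(arm), baseline = baseline)
  fit <- stats::lm(change ~ arm + baseline, data = d)
  an <- stats::anova(fit)
  tibble(statistic = an["arm", "F value"], df1 = an["arm", "Df"],
         df2 = an["Residuals", "Df"], p.value = an["arm", "Pr(>F)"])
}
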