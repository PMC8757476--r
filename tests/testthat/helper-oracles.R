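# Independent oracles and small fixtures built in code.

# random count table as a plain matrix
random_count_matrix <- function(n_samples, n_otus, seed, max_count = 20,
                                zero_prob = 0.6) {
  withr::with_seed(seed, {
    m <- matrix(rbinom(n_samples * n_otus, max_count, 0.3) *
                  (runif(n_samples * n_otus) > zero_prob),
                n_samples, n_otus,
                dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                                sprintf("otu%03d", seq_len(n_otus))))
    storage.mode(m) <- "integer"
    m
  })
}

# per-OTU brute-force filter predicate
filter_oracle_keep <- function(m, min_samples = 2, min_total_reads = 10) {
  keep <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    keep[j] <- sum(m[, j] > 0) >= min_samples && sum(m[, j]) >= min_total_reads
  }
  colnames(m)[keep]
}

# exact two-sided Mann-Whitney p by enumeration over group assignments
mwu_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a); N <- length(pooled)
  ustat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  uobs <- ustat(a, b)
  us <- apply(combn(N, n1), 2, function(idx) ustat(pooled[idx], pooled[-idx]))
  min(1, 2 * min(mean(us <= uobs + 1e-12), mean(us >= uobs - 1e-12)))
}

# exact Kruskal-Wallis permutation p by enumeration (statistic recomputed
# from scratch here, independent of the package internals)
kw_exact_oracle <- function(values, group) {
  group <- as.factor(group)
  n <- as.integer(table(group))
  N <- sum(n)
  hstat <- function(v, g) {
    r <- rank(v)
    rb <- tapply(r, g, mean)
    nn <- tapply(r, g, length)
    h <- 12 / (N * (N + 1)) * sum(nn * (rb - (N + 1) / 2)^2)
    tt <- table(r)
    corr <- 1 - sum(tt^3 - tt) / (N^3 - N)
    if (corr > 0) h / corr else 0
  }
  hobs <- hstat(values, group)
  # enumerate label assignments: choose positions for each group in turn
  count_ge <- 0; count_all <- 0
  rec <- function(avail, gi, labels) {
    if (gi == length(n)) {
      labels[avail] <- gi
      count_all <<- count_all + 1
      if (hstat(values, factor(labels)) >= hobs - 1e-12) {
        count_ge <<- count_ge + 1
      }
      return(invisible())
    }
    for (pick in combn(avail, n[gi], simplify = FALSE)) {
      l2 <- labels; l2[pick] <- gi
      rec(setdiff(avail, pick), gi + 1, l2)
    }
  }
  rec(seq_len(N), 1, integer(N))
  count_ge / count_all
}

# raw data with exactly a given mean and sd (for summary-stat oracles)
raw_from_summary <- function(n, mean, sd, seed) {
  withr::with_seed(seed, {
    z <- rnorm(n)
    z <- (z - mean(z)) / stats::sd(z)
    mean + sd * z
  })
}

# strict 2x2 two-sided Fisher by hypergeometric summation
fisher_2x2_oracle <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab)
  x <- 0:min(rs[1], cs[1])
  d <- dhyper(x, cs[1], sum(cs) - cs[1], rs[1])
  sum(d[d <= dhyper(tab[1, 1], cs[1], sum(cs) - cs[1], rs[1]) * (1 + 1e-7)])
}

# RxC Freeman-Halton by vectorised expand.grid enumeration over free cells
# (2 x C tables only; independent of the package's recursive enumeration)
fisher_2xc_oracle <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab)
  lf <- function(x) lfactorial(x)
  lconst <- sum(lf(rs)) + sum(lf(cs)) - lf(sum(tab))
  lp <- function(m) lconst - sum(lf(m))
  grid <- expand.grid(lapply(cs, function(cj) 0:min(rs[1], cj)))
  grid <- as.matrix(grid[rowSums(grid) == rs[1], , drop = FALSE])
  lps <- apply(grid, 1, function(r) lp(rbind(r, cs - r)))
  sum(exp(lps[lps <= lp(tab) + 1e-7]))
}

# toy six-OTU table exercising both filter rules
toy_filter_table <- function() {
  m <- matrix(0L, 4, 6,
              dimnames = list(paste0("s", 1:4), paste0("otu", 1:6)))
  m[, 1] <- c(12L, 0L, 0L, 0L)   # 1 sample, 12 reads -> drop (prevalence)
  m[, 2] <- c(3L, 3L, 3L, 0L)    # 3 samples, 9 reads -> drop (reads)
  m[, 3] <- c(5L, 5L, 0L, 0L)    # 2 samples, 10 reads -> keep (boundary)
  m[, 4] <- c(1L, 0L, 0L, 9L)    # 2 samples, 10 reads -> keep
  m[, 5] <- c(9L, 0L, 0L, 0L)    # 1 sample, 9 reads -> drop (both)
  m[, 6] <- c(20L, 1L, 1L, 1L)   # 4 samples, 23 reads -> keep
  m
}
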