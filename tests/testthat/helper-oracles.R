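# Independent brute-force oracles used to freeze expected values.  These are
# deliberately plain (double loops, full enumeration) and share no code with
# the implementation paths they check.

# all ways to split `values` into ordered groups of sizes `sizes`,
# returning the statistic of each split
oracle_enumerate <- function(values, sizes, stat) {
  out <- c()
  recurse <- function(idx, sz, acc) {
    if (length(sz) == 0) {
      out <<- c(out, stat(acc))
      return(invisible(NULL))
    }
    for (pick in utils::combn(idx, sz[1], simplify = FALSE))
      recurse(setdiff(idx, pick), sz[-1], c(acc, list(values[pick])))
  }
  recurse(seq_along(values), sizes, list())
  out
}

# plain pairwise-count JT statistic
oracle_jt <- function(groups) {
  J <- 0
  k <- length(groups)
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    for (a in groups[[i]]) for (b in groups[[j]])
      J <- J + (a < b) + 0.5 * (a == b)
  J
}

# plain mid-ecdf pseudorank contrast statistic (unstandardized)
oracle_hn_T <- function(groups, contrasts) {
  x <- unlist(groups)
  N <- length(x)
  k <- length(groups)
  psi <- numeric(N)
  for (m in seq_len(N)) {
    s <- 0
    for (i in seq_len(k)) {
      gi <- groups[[i]]
      s <- s + (sum(gi < x[m]) + 0.5 * sum(gi == x[m])) / length(gi)
    }
    psi[m] <- N * s / k + 0.5
  }
  idx <- rep(seq_len(k), lengths(groups))
  sum(contrasts * tapply(psi, idx, mean))
}

# plain integrated-squared-difference kernel statistic matching the
# implementation's bandwidth/grid conventions
oracle_ba_stat <- function(g1, g2, n_grid = 100) {
  x <- c(g1, g2)
  h <- stats::sd(x) * (4 / (3 * length(x)))^(1 / 5)
  grid <- seq(min(x) - 3 * h, max(x) + 3 * h, length.out = n_grid)
  f <- function(g) sapply(grid, function(y) mean(stats::dnorm((y - g) / h)) / h)
  sum((f(g1) - f(g2))^2) * (grid[2] - grid[1])
}

# tiny deterministic cohort for contract tests
small_cohort <- function(n = 120, seed = 42) {
  generate_cohort(default_config(n_total = n, seed = seed))$cohort
}

grade_rank <- function(level) match(level, evidence_levels())
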