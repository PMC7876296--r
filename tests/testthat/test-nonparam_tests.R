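test_that("correlation screen: identities, arithmetic oracle, codes", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 4, 6, 8, 10.1)
  scr <- correlation_screen(cbind(a = x, b = -x, c = y))
  expect_equal(scr$r["a", "a"], 1)
  expect_equal(scr$r["a", "b"], -1)
  # brute-force covariance-sum oracle
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(scr$r["a", "c"], r_oracle, tolerance = 1e-12)
  expect_equal(scr$codes["a", "c"], "***")
  expect_error(correlation_screen(cbind(a = x, k = rep(1, 5))), "constant")
  expect_error(correlation_screen(cbind(a = x[1:2], b = y[1:2])), "3 rows")
})

test_that("Kruskal-Wallis: degenerate, enumeration oracle, reference oracle", {
  expect_equal(kruskal_wallis(list(c(1, 1), c(1, 1), c(1, 1)))$statistic, 0)
  expect_equal(kruskal_wallis(list(c(1, 1), c(1, 1), c(1, 1)))$p_value, 1)

  g <- list(c(1, 2), c(3, 4), c(5, 6))
  kw <- kruskal_wallis(g)
  expect_equal(kw$statistic, 12 / 42 * 2 * ((1.5 - 3.5)^2 + 0 + (5.5 - 3.5)^2))
  # exact permutation p of H by full enumeration over 6!/(2!2!2!) = 90 splits
  null_H <- oracle_enumerate(unlist(g), c(2, 2, 2),
                             function(gl) kruskal_wallis(gl)$statistic)
  expect_length(null_H, 90)
  expect_equal(mean(null_H >= kw$statistic - 1e-9), 6 / 90)

  # agreement with the reference implementation on tied random data
  set.seed(2)
  x <- round(rnorm(60), 1)
  gl <- split(x, rep(1:3, each = 20))
  ref <- stats::kruskal.test(gl)
  ours <- kruskal_wallis(gl)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)

  # huge planted shift
  big <- kruskal_wallis(list(rnorm(30), rnorm(30) + 50, rnorm(30) + 100))
  expect_lt(big$p_value, 1e-6)
})

test_that("Jonckheere-Terpstra: exact enumeration and direction handling", {
  # two-group degenerate case: J = 4, one-sided exact p = 1/6
  jt <- jonckheere_terpstra(list(c(1, 2), c(3, 4)), "increasing")
  expect_equal(jt$statistic, 4)
  expect_equal(jt$p_value, 1 / 6)
  # independently via the plain-loop oracle
  null_J <- oracle_enumerate(c(1, 2, 3, 4), c(2, 2), oracle_jt)
  expect_equal(mean(null_J >= oracle_jt(list(c(1, 2), c(3, 4))) - 1e-9), 1 / 6)

  # exact path agrees with the oracle on a tied three-group instance
  g <- list(c(1, 2, 2), c(2, 3), c(3, 5))
  jt2 <- jonckheere_terpstra(g, "increasing", exact = TRUE)
  null_J2 <- oracle_enumerate(unlist(g), lengths(g), oracle_jt)
  expect_equal(jt2$statistic, oracle_jt(g))
  expect_equal(jt2$p_value, mean(null_J2 >= oracle_jt(g) - 1e-9))

  # decreasing alternative = increasing on reversed groups
  jt3 <- jonckheere_terpstra(list(c(5, 6), c(3, 4), c(1, 2)), "decreasing",
                             exact = TRUE)
  jt4 <- jonckheere_terpstra(list(c(1, 2), c(3, 4), c(5, 6)), "increasing",
                             exact = TRUE)
  expect_equal(jt3$p_value, jt4$p_value)

  # symmetrically interleaved groups: J at its null mean, p near 1/2
  jt5 <- jonckheere_terpstra(list(c(1, 6), c(2, 5), c(3, 4)), "increasing")
  expect_equal(jt5$statistic, 6)  # equals E[J] = (N^2 - sum n_i^2) / 4
  expect_gt(jt5$p_value, 0.3)
  expect_lt(jt5$p_value, 0.8)

  expect_error(jonckheere_terpstra(list(numeric(0), 1:3), "increasing"))
})

test_that("Jonckheere-Terpstra normal approximation tracks the exact p", {
  set.seed(7)
  for (rep in 1:8) {
    x <- sample(1:6, 12, replace = TRUE)  # ties included
    gl <- split(x, rep(1:3, each = 4))
    pe <- jonckheere_terpstra(gl, "increasing", exact = TRUE)$p_value
    pa <- jonckheere_terpstra(gl, "increasing", exact = FALSE)$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("pseudoranks reduce to midranks for equal group sizes", {
  set.seed(3)
  x <- round(rnorm(30), 1)
  gl <- split(x, rep(1:3, each = 10))
  expect_equal(max(abs(pseudoranks(gl) - rank(unlist(gl)))), 0)
  # unequal sizes: pseudoranks differ from plain midranks in general
  gl2 <- list(c(1, 2, 3, 4, 5, 6), c(2.5, 3.5), c(4.5, 5.5))
  expect_false(isTRUE(all.equal(pseudoranks(gl2), rank(unlist(gl2)))))
})

test_that("Hettmansperger-Norton: enumeration oracle and planted trend", {
  g <- list(c(3, 1, 4), c(2, 6), c(5, 7))
  cc <- 1:3 - 2
  hn <- hettmansperger_norton(g, alternative = "increasing", exact = TRUE)
  null_T <- oracle_enumerate(unlist(g), lengths(g),
                             function(gl) oracle_hn_T(gl, cc))
  expect_length(null_T, factorial(7) / (factorial(3) * 4))
  expect_equal(hn$p_value,
               mean(null_T >= oracle_hn_T(g, cc) - 1e-9))

  # planted increasing location trend with unequal sizes
  set.seed(11)
  gs <- list(rnorm(50), rnorm(30) + 0.8, rnorm(20) + 1.6)
  expect_lt(hettmansperger_norton(gs, alternative = "increasing",
                                  n_perm = 2000, seed = 2)$p_value, 0.05)
  # asymptotic path agrees with permutation on moderate samples
  pp <- hettmansperger_norton(gs, alternative = "increasing",
                              n_perm = 4000, seed = 3)$p_value
  pa <- hettmansperger_norton(gs, alternative = "increasing",
                              method = "asymptotic")$p_value
  expect_lt(abs(pp - pa), 0.02)
  expect_error(hettmansperger_norton(list(1, 1:3, 1:3)), "at least 2")
})

test_that("bootstrap median CI: degenerate, deterministic, contract", {
  ci <- bootstrap_median_ci(rep(3.5, 20), replicates = 200, seed = 1)
  expect_equal(c(ci$lower, ci$upper), c(3.5, 3.5))
  x <- rnorm(50)
  a <- bootstrap_median_ci(x, replicates = 500, seed = 7)
  b <- bootstrap_median_ci(x, replicates = 500, seed = 7)
  expect_identical(a, b)
  expect_lte(a$lower, a$upper)
  expect_error(bootstrap_median_ci(1:5), "n >= 8")
})

test_that("bootstrap median test: null, power, reproducibility", {
  set.seed(5)
  x <- rnorm(100)
  same <- bootstrap_median_test(x, x, replicates = 500, seed = 2)
  expect_false(same$significant)
  expect_gt(same$p_value, 0.5)
  shifted <- bootstrap_median_test(x, x + 10, replicates = 500, seed = 2)
  expect_true(shifted$significant)
  expect_lt(shifted$p_value, 0.01)
  r1 <- bootstrap_median_test(x, x + 0.2, replicates = 500, seed = 9)
  r2 <- bootstrap_median_test(x, x + 0.2, replicates = 500, seed = 9)
  expect_identical(r1, r2)
  expect_error(bootstrap_median_test(1:5, 1:20), "n >= 8")
})

test_that("density comparison: null identity, enumeration, determinism", {
  set.seed(8)
  x <- rnorm(12)
  same <- ba_density_test(x, x, n_perm = 100, seed = 1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_true(all(same$band_lower <= same$band_upper))
  # densities integrate to ~1 on the grid
  dx <- diff(same$grid[1:2])
  expect_lt(abs(sum(same$density_g) * dx - 1), 1e-3)

  # exact permutation p matches the plain-loop oracle for n1 = n2 = 4
  g1 <- c(0.2, 1.1, -0.4, 0.9); g2 <- c(2.5, 3.1, 1.9, 2.8)
  cmp <- ba_density_test(g1, g2, exact = TRUE)
  null_s <- oracle_enumerate(c(g1, g2), c(4, 4),
                             function(gl) oracle_ba_stat(gl[[1]], gl[[2]]))
  expect_equal(cmp$statistic, oracle_ba_stat(g1, g2), tolerance = 1e-12)
  expect_equal(cmp$p_value, mean(null_s >= cmp$statistic - 1e-12))

  set.seed(21); a <- rnorm(20); b <- rnorm(20)
  expect_identical(ba_density_test(a, b, n_perm = 150, exact = FALSE, seed = 4),
                   ba_density_test(a, b, n_perm = 150, exact = FALSE, seed = 4))
  expect_error(ba_density_test(rep(1, 10), rep(1, 10)), "bandwidth")
})

test_that("notch interval follows the printed formula", {
  x <- seq(40, 60, length.out = 100)
  nt <- notch_interval(x)
  expect_equal(nt$lower, nt$median - 1.58 * nt$iqr / sqrt(nt$n))
  expect_equal(nt$upper, nt$median + 1.58 * nt$iqr / sqrt(nt$n))
  # direct substitution check of the frozen example values
  expect_equal(50 - 1.58 * 20 / sqrt(100), 46.84)
  expect_equal(50 + 1.58 * 20 / sqrt(100), 53.16)
  # constant data: zero-width notch
  ntc <- notch_interval(rep(2, 10))
  expect_equal(ntc$lower, 2); expect_equal(ntc$upper, 2)
  # quartiles match a brute-force sorted-order oracle at n = 11 (type 7:
  # with n = 11 the quartiles fall exactly on order statistics 3.5 -> interp)
  set.seed(9)
  y <- rnorm(11)
  s <- sort(y)
  q1 <- s[3] + 0.5 * (s[4] - s[3])
  q3 <- s[8] + 0.5 * (s[9] - s[8])
  nty <- notch_interval(y)
  expect_equal(nty$q1, q1); expect_equal(nty$q3, q3)
  expect_error(notch_interval(1:4), "n >= 5")
})

test_that("proxy screen produces both tests per proxy and detects shifts", {
  co <- generate_cohort(default_config(n_total = 400, seed = 6))$cohort
  scr <- proxy_group_screen(co)
  expect_equal(nrow(scr), 16)
  expect_true(all(c("F", "anova_p", "H", "kw_p") %in% names(scr)))
  # SAP carries a strong planted group shift at this n
  expect_lt(scr$kw_p[scr$proxy == "SAP"], 0.01)
})

test_that("battery: structure, alphas, determinism, null and strong cases", {
  set.seed(12)
  x0 <- rep(seq(0, 1, length.out = 60), 3)  # identical groups
  g <- rep(c("NW", "OW", "OB"), each = 60)
  b0 <- run_battery(x0, g, boot_replicates = 300, ba_permutations = 100,
                    hn_permutations = 300, seed = 5)
  expect_length(b0$tests, 9)
  sig0 <- vapply(b0$tests, `[[`, logical(1), "significant")
  expect_equal(sum(sig0), 0)
  alphas <- vapply(b0$tests, `[[`, numeric(1), "alpha")
  expect_equal(alphas, c(0.05, 0.05, 0.05, 0.05, rep(0.05 / 3, 3), 0.05, 0.05))

  # strong planted separation -> 9/9
  x1 <- c(rnorm(60), rnorm(60) + 8, rnorm(60) + 16)
  b1 <- run_battery(x1, g, boot_replicates = 300, ba_permutations = 150,
                    hn_permutations = 300, seed = 5)
  expect_true(all(vapply(b1$tests, `[[`, logical(1), "significant")))
  expect_equal(b1$direction, "increasing")

  # decreasing trends are auto-detected
  b2 <- run_battery(-x1, g, boot_replicates = 200, ba_permutations = 100,
                    hn_permutations = 200, seed = 5)
  expect_equal(b2$direction, "decreasing")
  expect_true(b2$tests[[8]]$significant)

  # same seed, same battery
  b3 <- run_battery(x1, g, boot_replicates = 300, ba_permutations = 150,
                    hn_permutations = 300, seed = 5)
  expect_identical(lapply(b1$tests, `[[`, "p_value"),
                   lapply(b3$tests, `[[`, "p_value"))
})
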