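# ---- shared result container ----------------------------------------------

new_test_result <- function(test_name, statistic, p_value, alpha,
                            direction = NA_character_,
                            groups_compared = NA_character_) {
  p_value <- min(max(p_value, 0), 1)
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p_value = p_value, alpha = alpha,
                 significant = p_value <= alpha, direction = direction,
                 groups_compared = groups_compared),
            class = "carproc_test")
}

#' @export
print.carproc_test <- function(x, ...) {
  cat(sprintf("%s%s: statistic = %.4g, p = %.4g (alpha = %.3g) %s\n",
              x$test_name,
              if (is.na(x$groups_compared)) "" else
                paste0(" [", x$groups_compared, "]"),
              x$statistic, x$p_value, x$alpha,
              if (x$significant) "*" else ""))
  invisible(x)
}

# enumerate all distinct assignments of `values` into groups of the given
# sizes and apply `stat` to each grouping (exactness oracle backbone)
enumerate_assignments <- function(values, sizes, stat) {
  n <- length(values)
  res <- numeric(0)
  recurse <- function(idx_left, sizes_left, groups_acc) {
    if (length(sizes_left) == 1) {
      res[[length(res) + 1]] <<- stat(c(groups_acc, list(values[idx_left])))
      return(invisible(NULL))
    }
    picks <- utils::combn(idx_left, sizes_left[1], simplify = FALSE)
    for (pk in picks)
      recurse(setdiff(idx_left, pk), sizes_left[-1],
              c(groups_acc, list(values[pk])))
  }
  # fix first element of group 1? no: groups are distinguishable (ordered)
  recurse(seq_len(n), sizes, list())
  unlist(res)
}

n_arrangements <- function(sizes) {
  exp(lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1)))
}

# ---- correlation screen -----------------------------------------------------

#' Pearson correlation screen with significance codes
#'
#' Pairwise Pearson correlations of the supplied variables with two-sided
#' tests of zero correlation and the conventional star codes
#' (`***` for p <= 0.001, `**` for p <= 0.01, `*` for p <= 0.05).
#'
#' @param x numeric matrix or data.frame with at least 3 complete rows.
#' @return A list with matrices `r`, `p`, and character `codes`.
#' @export
correlation_screen <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("correlation screen needs at least 3 rows")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  r <- stats::cor(x)
  n <- nrow(x)
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  diag(p) <- NA
  codes <- matrix("", nrow(r), ncol(r), dimnames = dimnames(r))
  codes[!is.na(p) & p <= 0.05] <- "*"
  codes[!is.na(p) & p <= 0.01] <- "**"
  codes[!is.na(p) & p <= 0.001] <- "***"
  list(r = r, p = p, codes = codes)
}

# ---- per-proxy group screen -------------------------------------------------

#' ANOVA and Kruskal-Wallis screen of the proxies across BMI groups
#'
#' For each proxy, a one-way ANOVA F test and a tie-corrected
#' Kruskal-Wallis test of equality across the three BMI groups.
#'
#' @param cohort cohort data.frame with `group` and the proxy columns.
#' @param vars proxies to screen (default: all 16).
#' @return data.frame with one row per proxy: F statistic and p, KW H and p.
#' @export
proxy_group_screen <- function(cohort, vars = proxy_names()) {
  g <- cohort$group
  if (length(unique(g)) < 3 || any(table(g) < 2))
    stop("screen requires three groups with at least 2 observations each")
  out <- lapply(vars, function(v) {
    y <- cohort[[v]]
    an <- stats::oneway.test(y ~ g, var.equal = TRUE)
    kw <- kruskal_wallis(split(y, g))
    data.frame(proxy = v, F = unname(an$statistic),
               anova_p = unname(an$p.value), H = kw$statistic,
               kw_p = kw$p_value)
  })
  do.call(rbind, out)
}

# ---- Kruskal-Wallis ---------------------------------------------------------

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with the chi-square approximation on k - 1
#' degrees of freedom.  When all observations are identical the statistic
#' is undefined; it is reported as H = 0 with p = 1.
#'
#' @param groups list of numeric vectors (one per group).
#' @param alpha significance level attached to the result.
#' @return A `carproc_test` result.
#' @export
kruskal_wallis <- function(groups, alpha = 0.05) {
  if (any(lengths(groups) == 0)) stop("empty group")
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  H <- 12 / (N * (N + 1)) * sum(lengths(groups) * (rbar - (N + 1) / 2)^2)
  ties <- table(x)
  denom <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (denom <= 0) return(new_test_result("KW", 0, 1, alpha))
  H <- H / denom
  p <- stats::pchisq(H, df = length(groups) - 1, lower.tail = FALSE)
  new_test_result("KW", H, p, alpha)
}

# ---- Jonckheere-Terpstra ----------------------------------------------------

jt_statistic <- function(groups) {
  k <- length(groups)
  J <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    xi <- groups[[i]]; xj <- groups[[j]]
    cmp <- outer(xi, xj, `<`)
    tie <- outer(xi, xj, `==`)
    J <- J + sum(cmp) + 0.5 * sum(tie)
  }
  J
}

#' Jonckheere-Terpstra test for ordered alternatives
#'
#' Tests equality of group effects against a monotone trend over the given
#' group order (e.g. NW < OW < OB).  The statistic is the sum of pairwise
#' Mann-Whitney counts (ties counted 1/2).  The p-value is one-sided in
#' the requested direction: exact by complete enumeration of group
#' assignments when the total sample size is at most `exact_max` (default
#' 12), otherwise by the tie-corrected normal approximation with
#' continuity correction.  `"decreasing"` reverses the group order.
#'
#' @param groups list of numeric vectors in increasing hypothesized order.
#' @param alternative `"increasing"` or `"decreasing"`.
#' @param alpha significance level.
#' @param exact `TRUE`, `FALSE` or `"auto"` (exact when N <= `exact_max`).
#' @param exact_max sample-size cap for the exact path.
#' @return A `carproc_test` result (statistic J for the tested direction).
#' @export
jonckheere_terpstra <- function(groups,
                                alternative = c("increasing", "decreasing"),
                                alpha = 0.05, exact = "auto",
                                exact_max = 12) {
  alternative <- match.arg(alternative)
  if (any(lengths(groups) == 0)) stop("empty group")
  if (alternative == "decreasing") groups <- rev(groups)
  sizes <- lengths(groups)
  N <- sum(sizes)
  if (N < 4) stop("need at least 4 observations in total")
  J <- jt_statistic(groups)
  use_exact <- isTRUE(exact) || (identical(exact, "auto") && N <= exact_max)
  if (use_exact) {
    null_J <- enumerate_assignments(unlist(groups), sizes, jt_statistic)
    p <- mean(null_J >= J - 1e-9)
  } else {
    # tie-corrected moments of J under H0
    x <- unlist(groups)
    tj <- as.numeric(table(x))
    n <- as.numeric(sizes)
    EJ <- (N^2 - sum(n^2)) / 4
    v1 <- N * (N - 1) * (2 * N + 5) - sum(n * (n - 1) * (2 * n + 5)) -
      sum(tj * (tj - 1) * (2 * tj + 5))
    v2 <- sum(n * (n - 1) * (n - 2)) * sum(tj * (tj - 1) * (tj - 2))
    v3 <- sum(n * (n - 1)) * sum(tj * (tj - 1))
    VJ <- v1 / 72 + v2 / (36 * N * (N - 1) * (N - 2)) +
      v3 / (8 * N * (N - 1))
    z <- (J - EJ - 0.5) / sqrt(VJ)
    p <- stats::pnorm(z, lower.tail = FALSE)
  }
  new_test_result("JT", J, p, alpha, direction = alternative)
}

# ---- Hettmansperger-Norton --------------------------------------------------

#' Pseudoranks of pooled observations
#'
#' The pseudorank of observation x replaces the pooled empirical
#' distribution in the midrank by the unweighted mean of the per-group
#' mid-ECDFs: `psi(x) = N * (1/k) * sum_i Fhat_i(x) + 1/2`, removing the
#' influence of unequal group sizes.  With equal group sizes pseudoranks
#' reduce exactly to ordinary midranks.
#'
#' @param groups list of numeric vectors.
#' @return Numeric vector of pseudoranks for the pooled sample, in the
#'   order `unlist(groups)`.
#' @export
pseudoranks <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  Fbar <- rowMeans(vapply(groups, function(gx) {
    sgx <- sort(gx)
    leq <- findInterval(x, sgx)
    less <- findInterval(x, sgx, left.open = TRUE)
    (less + 0.5 * (leq - less)) / length(gx)
  }, numeric(N)))
  N * Fbar + 0.5
}

hn_statistic <- function(groups, contrasts) {
  psi <- pseudoranks(groups)
  idx <- rep(seq_along(groups), lengths(groups))
  means <- tapply(psi, idx, mean)
  Tstat <- sum(contrasts * means)
  # finite-population standardization under random group assignment
  s2 <- stats::var(psi)
  Vt <- s2 * sum(contrasts^2 / lengths(groups))
  if (Vt <= 0) return(c(T = Tstat, z = 0))
  c(T = Tstat, z = Tstat / sqrt(Vt))
}

#' Hettmansperger-Norton pseudorank trend test
#'
#' Tests equality of group effects against a monotone alternative using a
#' linear contrast of the per-group mean pseudoranks with centered trend
#' scores (default equally spaced 1, 2, 3).  The p-value is one-sided in
#' the requested direction, by label permutation (seeded; exact
#' enumeration when the number of distinct assignments is small) or by the
#' asymptotic normal approximation.
#'
#' @param groups list of numeric vectors in increasing hypothesized order,
#'   each of length >= 2.
#' @param trend_scores trend scores, one per group.
#' @param alternative `"increasing"` or `"decreasing"`.
#' @param alpha significance level.
#' @param n_perm Monte-Carlo permutations.
#' @param method `"permutation"` or `"asymptotic"`.
#' @param exact `TRUE`, `FALSE` or `"auto"` (enumerate when there are at
#'   most `exact_max` distinct assignments).
#' @param exact_max cap on enumerated assignments.
#' @param seed RNG seed for the Monte-Carlo path.
#' @return A `carproc_test` result (statistic = standardized contrast).
#' @export
hettmansperger_norton <- function(groups, trend_scores = seq_along(groups),
                                  alternative = c("increasing", "decreasing"),
                                  alpha = 0.05, n_perm = 10000,
                                  method = c("permutation", "asymptotic"),
                                  exact = "auto", exact_max = 20000,
                                  seed = 1L) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (any(lengths(groups) < 2)) stop("each group needs at least 2 observations")
  cc <- trend_scores - mean(trend_scores)
  if (alternative == "decreasing") cc <- -cc
  sizes <- lengths(groups)
  obs <- hn_statistic(groups, cc)
  if (method == "asymptotic") {
    p <- stats::pnorm(obs["z"], lower.tail = FALSE)
    return(new_test_result("HN", obs[["z"]], p, alpha,
                           direction = alternative))
  }
  stat_fun <- function(gl) hn_statistic(gl, cc)[["T"]]
  use_exact <- isTRUE(exact) ||
    (identical(exact, "auto") && n_arrangements(sizes) <= exact_max)
  if (use_exact) {
    null_T <- enumerate_assignments(unlist(groups), sizes, stat_fun)
    p <- mean(null_T >= obs[["T"]] - 1e-9)
  } else {
    x <- unlist(groups)
    set.seed(seed)
    null_T <- vapply(seq_len(n_perm), function(b) {
      xs <- sample(x)
      stat_fun(split(xs, rep(seq_along(sizes), sizes)))
    }, numeric(1))
    p <- (1 + sum(null_T >= obs[["T"]] - 1e-9)) / (n_perm + 1)
  }
  new_test_result("HN", obs[["z"]], p, alpha, direction = alternative)
}

# ---- bootstrap median inference --------------------------------------------

col_medians <- function(m) apply(m, 2, stats::median)

boot_medians <- function(x, replicates) {
  n <- length(x)
  col_medians(matrix(sample(x, n * replicates, replace = TRUE), n, replicates))
}

#' Non-parametric bootstrap confidence interval for the median
#'
#' Percentile interval of the resampled sample median.
#'
#' @param x numeric vector, n >= 8.
#' @param replicates bootstrap replicates (default 5000).
#' @param level confidence level.
#' @param seed RNG seed; the interval is deterministic given the seed.
#' @return A list of class `carproc_boot_ci`: `lower`, `upper`, `level`,
#'   `replicates`, `statistic = "median"`, `estimate`.
#' @export
bootstrap_median_ci <- function(x, replicates = 5000, level = 0.95,
                                seed = 1L) {
  if (length(x) < 8) stop("bootstrap median CI needs n >= 8")
  set.seed(seed)
  meds <- boot_medians(x, replicates)
  qs <- stats::quantile(meds, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  structure(list(lower = qs[1], upper = qs[2], level = level,
                 replicates = replicates, statistic = "median",
                 estimate = stats::median(x)),
            class = "carproc_boot_ci")
}

#' Non-parametric bootstrap median test
#'
#' Pairwise test of equality of two group medians: groups are resampled
#' independently, the percentile interval of the difference of medians is
#' formed at `level`, and the difference is significant when the interval
#' excludes zero.  The reported p-value is the smallest nominal level at
#' which the percentile interval excludes zero, which for the percentile
#' construction equals `2 * min(Pr(d* <= 0), Pr(d* >= 0))` over the
#' bootstrap distribution `d*` (the limit of a grid search over levels).
#'
#' @param g1,g2 numeric vectors, each n >= 8.
#' @param replicates bootstrap replicates.
#' @param level confidence level driving the significance call.
#' @param alpha significance level attached to the result
#'   (`1 - level` by default).
#' @param seed RNG seed.
#' @return A `carproc_test` result; the statistic is the observed median
#'   difference, with the bootstrap CI attached as attribute `"ci"`.
#' @export
bootstrap_median_test <- function(g1, g2, replicates = 5000, level = 0.95,
                                  alpha = 1 - level, seed = 1L) {
  if (length(g1) < 8 || length(g2) < 8)
    stop("bootstrap median test needs n >= 8 in both groups")
  set.seed(seed)
  d <- boot_medians(g1, replicates) - boot_medians(g2, replicates)
  p <- min(1, 2 * min(mean(d <= 0), mean(d >= 0)))
  qs <- stats::quantile(d, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  res <- new_test_result("Mt", stats::median(g1) - stats::median(g2),
                         p, alpha)
  # decision rule is CI exclusion of zero, consistent with the p above
  res$significant <- qs[1] > 0 || qs[2] < 0
  attr(res, "ci") <- qs
  res
}

# ---- Bowman-Azzalini density comparison ------------------------------------

#' Kernel density equality test with reference band
#'
#' Compares two group distributions through Gaussian kernel density
#' estimates with a common bandwidth (normal-optimal rule on the pooled
#' sample).  The statistic is the integrated squared difference of the two
#' estimates over a common grid; the p-value comes from permutation of the
#' group labels (exact enumeration when feasible and `exact` allows).  A
#' reference band for equality is centred on the pooled estimate with
#' pointwise half-width `z_0.975` times the standard error of the
#' difference of the two estimates under the null.
#'
#' @param g1,g2 numeric vectors, each n >= 4 (small groups are only useful
#'   for the exact enumeration path; reported analyses use n >= 10).
#' @param n_perm permutations for the Monte-Carlo path.
#' @param alpha significance level attached to the result.
#' @param n_grid evaluation grid size.
#' @param exact `TRUE`, `FALSE` or `"auto"` (enumerate when the number of
#'   distinct label arrangements is at most `exact_max`).
#' @param exact_max cap on enumerated arrangements.
#' @param seed RNG seed.
#' @return A list of class `carproc_density_cmp`: `grid`, `density_g`,
#'   `density_g2`, `pooled`, `band_lower`, `band_upper`, `bandwidth`,
#'   `statistic`, `p_value`, `significant`, `alpha`.
#' @export
ba_density_test <- function(g1, g2, n_perm = 500, alpha = 0.05,
                            n_grid = 100, exact = "auto", exact_max = 5000,
                            seed = 1L) {
  if (length(g1) < 4 || length(g2) < 4)
    stop("density comparison needs n >= 4 in both groups")
  x <- c(g1, g2)
  n1 <- length(g1); n2 <- length(g2); N <- n1 + n2
  sdp <- stats::sd(x)
  if (sdp == 0) stop("degenerate bandwidth: pooled sample has zero variance")
  h <- sdp * (4 / (3 * N))^(1 / 5)
  grid <- seq(min(x) - 3 * h, max(x) + 3 * h, length.out = n_grid)
  K <- stats::dnorm(outer(x, grid, `-`) / h) / h   # N x n_grid
  dx <- grid[2] - grid[1]
  ise <- function(idx1) {
    f1 <- colMeans(K[idx1, , drop = FALSE])
    f2 <- colMeans(K[-idx1, , drop = FALSE])
    sum((f1 - f2)^2) * dx
  }
  obs <- ise(seq_len(n1))
  n_arr <- choose(N, n1)
  use_exact <- isTRUE(exact) || (identical(exact, "auto") && n_arr <= exact_max)
  if (use_exact) {
    combs <- utils::combn(N, n1, simplify = FALSE)
    null_s <- vapply(combs, ise, numeric(1))
    p <- mean(null_s >= obs - 1e-12)
  } else {
    set.seed(seed)
    null_s <- vapply(seq_len(n_perm), function(b) ise(sample(N, n1)),
                     numeric(1))
    p <- (1 + sum(null_s >= obs - 1e-12)) / (n_perm + 1)
  }
  f1 <- colMeans(K[seq_len(n1), , drop = FALSE])
  f2 <- colMeans(K[-seq_len(n1), , drop = FALSE])
  fp <- colMeans(K)
  # Var(f1 - f2) under H0 ~ (1/n1 + 1/n2) * f(y) * R(K) / h,  R(K) = 1/(2 sqrt(pi))
  se <- sqrt((1 / n1 + 1 / n2) * fp / (2 * sqrt(pi) * h))
  z <- stats::qnorm(0.975)
  structure(list(grid = grid, density_g = f1, density_g2 = f2, pooled = fp,
                 band_lower = pmax(fp - z * se, 0), band_upper = fp + z * se,
                 bandwidth = h, statistic = obs, p_value = p,
                 significant = p <= alpha, alpha = alpha),
            class = "carproc_density_cmp")
}

# ---- notched box statistics -------------------------------------------------

#' Notch interval around the median
#'
#' `median +/- 1.58 * IQR / sqrt(n)`, an approximate 95% confidence
#' interval for the population median; quartiles use the
#' linear-interpolation rule (R quantile type 7).
#'
#' @param x numeric vector, n >= 5.
#' @return A list of class `carproc_notch`: `median`, `q1`, `q3`, `iqr`,
#'   `n`, `lower`, `upper`.
#' @examples
#' notch_interval(1:100)
#' @export
notch_interval <- function(x) {
  if (length(x) < 5) stop("notch interval needs n >= 5")
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- qs[3] - qs[1]
  half <- 1.58 * iqr / sqrt(length(x))
  structure(list(median = qs[2], q1 = qs[1], q3 = qs[3], iqr = iqr,
                 n = length(x), lower = qs[2] - half, upper = qs[2] + half),
            class = "carproc_notch")
}

# ---- the 9-test battery -----------------------------------------------------

#' Run the nine-test non-parametric battery on one indicator
#'
#' Applies, in order: one Kruskal-Wallis test across the three BMI groups;
#' three pairwise bootstrap median tests (NW-OW, NW-OB, OW-OB); three
#' pairwise kernel density equality tests on the same pairs at the
#' Bonferroni-corrected level 0.05/3; one Jonckheere-Terpstra and one
#' Hettmansperger-Norton test for the ordered alternative.  The trend
#' direction is either given or chosen automatically from the sign of the
#' observed rank trend across groups.
#'
#' @param x numeric indicator values.
#' @param group factor/character of BMI groups (levels NW, OW, OB).
#' @param direction `"auto"`, `"increasing"` or `"decreasing"` for the
#'   JT/HN ordered alternative.
#' @param alpha nominal level for KW, median, JT and HN tests.
#' @param ba_alpha level for each density test (Bonferroni 0.05/3).
#' @param boot_replicates bootstrap replicates for the median tests.
#' @param ba_permutations,hn_permutations Monte-Carlo permutation counts.
#' @param seed seed governing all resampling in the battery.
#' @return An object of class `carproc_battery`: a list of 9
#'   `carproc_test` results plus the direction used.
#' @export
run_battery <- function(x, group, direction = "auto", alpha = 0.05,
                        ba_alpha = 0.05 / 3, boot_replicates = 5000,
                        ba_permutations = 500, hn_permutations = 2000,
                        seed = 1L) {
  group <- factor(group, levels = c("NW", "OW", "OB"))
  if (any(is.na(group))) stop("group labels must be NW, OW or OB")
  gl <- split(x, group)
  if (any(lengths(gl) == 0)) stop("all three BMI groups must be present")
  if (identical(direction, "auto")) {
    rho <- stats::cor(rank(x), as.integer(group))
    direction <- if (rho >= 0) "increasing" else "decreasing"
  }
  pairs <- list(c("NW", "OW"), c("NW", "OB"), c("OW", "OB"))
  res <- list(kruskal_wallis(gl, alpha = alpha))
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    mt <- bootstrap_median_test(gl[[pr[1]]], gl[[pr[2]]],
                                replicates = boot_replicates,
                                level = 1 - alpha, alpha = alpha,
                                seed = seed + i)
    mt$groups_compared <- paste(pr, collapse = "-")
    res[[length(res) + 1]] <- mt
  }
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    ba <- ba_density_test(gl[[pr[1]]], gl[[pr[2]]], n_perm = ba_permutations,
                          alpha = ba_alpha, exact = FALSE, seed = seed + 10 + i)
    res[[length(res) + 1]] <-
      new_test_result("BA", ba$statistic, ba$p_value, ba_alpha,
                      groups_compared = paste(pr, collapse = "-"))
  }
  res[[length(res) + 1]] <-
    jonckheere_terpstra(gl, alternative = direction, alpha = alpha,
                        exact = "auto")
  res[[length(res) + 1]] <-
    hettmansperger_norton(gl, trend_scores = 1:3, alternative = direction,
                          alpha = alpha, n_perm = hn_permutations,
                          seed = seed + 20)
  structure(list(tests = res, direction = direction, alpha = alpha,
                 ba_alpha = ba_alpha), class = "carproc_battery")
}

#' @export
print.carproc_battery <- function(x, ...) {
  cat("9-test battery (direction:", x$direction, ")\n")
  for (t in x$tests) print(t)
  invisible(x)
}
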