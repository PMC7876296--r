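# shared fitted objects for the factor tests (n = 1200 keeps EFA stable
# while staying fast)
sim_fi <- generate_cohort(default_config(n_total = 1200, seed = 31))
adj_fi <- adjust(sim_fi$cohort, fit_adjustment(sim_fi$cohort),
                 vars = proxy_names())
efa_fi <- retain_factors(fit_efa(adj_fi, max_factors = 4))
lab_fi <- label_factors(efa_fi)
sc_fi <- factor_scores(efa_fi, adj_fi)

test_that("EFA on a pure one-factor model retains one strong factor", {
  set.seed(5)
  n <- 400; p <- 8
  f <- rnorm(n)
  x <- outer(f, rep(0.95, p)) + matrix(rnorm(n * p, sd = sqrt(1 - 0.95^2)),
                                       n, p)
  colnames(x) <- paste0("v", 1:p)
  m <- fit_efa(x, max_factors = 1)
  m <- retain_factors(m)
  expect_equal(m$q_retained, 1L)
  expect_true(all(abs(m$loadings[, 1]) >= 0.9))
})

test_that("default 4-factor cohort: retention, variance bookkeeping, labels", {
  expect_equal(efa_fi$q_retained, 4L)
  expect_true(all(efa_fi$pct_total_variance >= 10))
  expect_true(all(efa_fi$pct_total_communality >= 15))
  # loadings-to-variance identity
  expect_equal(unname(100 * colSums(efa_fi$loadings^2) / 16),
               unname(efa_fi$pct_total_variance), tolerance = 1e-6)
  expect_true(all(efa_fi$communalities >= 0 & efa_fi$communalities <= 1))
  expect_setequal(lab_fi$domain,
                  c("oscillatory", "amplitude", "pressure", "pulse"))
})

test_that("retention thresholds are enforced exactly", {
  fake <- structure(list(
    loadings = matrix(0.5, 16, 3,
                      dimnames = list(proxy_names(), paste0("F", 1:3))),
    pct_total_variance = c(F1 = 19, F2 = 9.9, F3 = 12),
    pct_total_communality = c(F1 = 32, F2 = 20, F3 = 14),
    q_retained = 3L), class = "carproc_efa")
  kept <- retain_factors(fake)
  expect_equal(names(kept$pct_total_variance), "F1")
  expect_equal(kept$q_retained, 1L)
  fake$pct_total_communality <- c(F1 = 10, F2 = 10, F3 = 10)
  expect_error(retain_factors(fake), "no factor")
})

test_that("factor labelling matches salient clusters to reference domains", {
  L <- matrix(0, 16, 2, dimnames = list(proxy_names(), c("F1", "F2")))
  L[c("SAP", "DAP", "SAP_Mean"), 1] <- c(0.8, 0.7, 0.75)
  L["HR", 2] <- 0.9; L["RR_Mean", 2] <- -0.9
  fake <- structure(list(loadings = L), class = "carproc_efa")
  lab <- label_factors(fake)
  expect_equal(lab$domain, c("pressure", "pulse"))
  expect_equal(lab$sign, c(1, 1))
  # flipped column gets sign -1 but the same domain
  L2 <- L; L2[, 1] <- -L2[, 1]
  lab2 <- label_factors(structure(list(loadings = L2),
                                  class = "carproc_efa"))
  expect_equal(lab2$domain[1], "pressure")
  expect_equal(lab2$sign[1], -1)
  # nothing salient -> unassigned
  L3 <- L; L3[] <- 0.2
  lab3 <- label_factors(structure(list(loadings = L3),
                                  class = "carproc_efa"))
  expect_true(all(lab3$domain == "unassigned"))
})

test_that("factor scores: centring, linearity, truth recovery", {
  expect_true(all(abs(colMeans(sc_fi)) < 1e-8))
  # sign-flipping a loadings column flips its scores
  flip <- efa_fi
  flip$loadings[, 2] <- -flip$loadings[, 2]
  sc_flip <- factor_scores(flip, adj_fi)
  expect_equal(sc_flip[, 2], -sc_fi[, 2])
  expect_error(factor_scores(efa_fi, adj_fi[, 1:5]), "proxies")
  # planted-truth recovery after domain matching and sign alignment
  planted <- c(oscillatory = "osc", amplitude = "amp", pressure = "press",
               pulse = "pul")
  for (i in seq_len(nrow(lab_fi))) {
    r <- lab_fi$sign[i] * cor(sc_fi[, lab_fi$factor[i]],
                              sim_fi$truth$factor_scores[, planted[[lab_fi$domain[i]]]])
    expect_gt(r, 0.8)
  }
})

test_that("indicators from scores: orientation, rank invariance, uniformity", {
  ind <- indicators_from_scores(sc_fi, lab_fi)
  expect_setequal(names(ind), c("OSC_ind", "AMP_ind", "PRESS_ind", "PUL_ind"))
  for (v in names(ind)) {
    expect_true(all(ind[[v]] > 0 & ind[[v]] < 100))
    expect_equal(mean(ind[[v]]), 50, tolerance = 1e-9)
    # KS distance to uniform small on tie-free percentiles
    ks <- suppressWarnings(stats::ks.test(ind[[v]] / 100, "punif"))
    expect_lt(unname(ks$statistic), 2 / sqrt(nrow(sc_fi)))
  }
  # PRESS-ind increases with adjusted SAP (reference orientation)
  expect_gt(cor(ind$PRESS_ind, adj_fi[, "SAP"]), 0)
  # pulse: increases with adjusted HR
  expect_gt(cor(ind$PUL_ind, adj_fi[, "HR"]), 0)
  # subject with the largest pressure score has the largest PRESS_ind
  press_f <- lab_fi$factor[lab_fi$domain == "pressure"]
  press_s <- lab_fi$sign[lab_fi$domain == "pressure"]
  expect_equal(which.max(ind$PRESS_ind), which.max(press_s * sc_fi[, press_f]))
  # monotone transform of a score column leaves its indicator unchanged
  sc2 <- sc_fi; sc2[, press_f] <- exp(sc2[, press_f] / 2)
  expect_equal(indicators_from_scores(sc2, lab_fi)$PRESS_ind, ind$PRESS_ind)
})

test_that("ANSI: ties, dominance, orientation and sign structure", {
  co <- small_cohort(n = 100, seed = 17)
  mod <- fit_adjustment(co)
  # identical adjusted components for everyone -> all ANSI at 50: use a
  # model with null covariate effects so constants stay tied after adjustment
  mod_null <- mod
  mod_null$coefficients[c("RR_Mean", "RR_TP", "dRR_LFnu"), ] <- 0
  co_tied <- co
  co_tied$RR_Mean <- 900; co_tied$RR_TP <- 2500; co_tied$dRR_LFnu <- 10
  expect_true(all(compute_ansi(co_tied, mod_null) == 50))
  expect_error(compute_ansi(co[, setdiff(names(co), "RR_TP")], mod), "RR_TP")
  # a subject pushed to the top of all three components gets the top ANSI
  co_dom <- co
  co_dom$RR_Mean[1] <- max(co$RR_Mean) * 3
  co_dom$RR_TP[1] <- max(co$RR_TP) * 10
  co_dom$dRR_LFnu[1] <- max(co$dRR_LFnu) + 50
  expect_equal(which.max(compute_ansi(co_dom, mod_null)), 1L)
  # invariance to an increasing affine transform of one component applied
  # to the scored and the fitting cohort alike
  ansi <- compute_ansi(co, mod)
  co3 <- co; co3$RR_Mean <- 5 + 2 * co$RR_Mean
  expect_equal(compute_ansi(co3, fit_adjustment(co3)), ansi,
               tolerance = 1e-12)
})

test_that("ANSI correlates with the domain indicators with the expected signs", {
  built <- build_indicators(sim_fi$cohort)
  ind <- built$indicators
  expect_lt(cor(ind$ANSI, ind$PUL_ind), 0)
  expect_gt(cor(ind$ANSI, ind$AMP_ind), 0)
  expect_true(all(vapply(ind, function(x) all(x > 0 & x < 100), logical(1))))
})

test_that("EFA input contracts", {
  expect_error(fit_efa(adj_fi[1:40, ]), "rows")
  dup <- cbind(adj_fi, adj_fi[, 1])
  expect_error(fit_efa(dup), "positive definite")
})
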