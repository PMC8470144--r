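test_that("d statistic matches hand arithmetic at s0 = 0", {
  # 4 metabolites with easy means/SEs, 3 vs 3 samples
  v <- cbind(m1 = c(1, 2, 3, 4, 5, 6),
             m2 = c(2, 2, 2, 2, 2, 2) + c(0, .1, -.1, 0, .1, -.1),
             m3 = c(0, 1, 2, 6, 7, 8),
             m4 = c(5, 6, 7, 5, 6, 7))
  pm <- make_pm(v, group = rep(c("control", "treated"), each = 3))
  st <- sam_statistics(pm, s0 = 0)
  # hand: d = (meanT - meanC) / sqrt((1/3 + 1/3) * pooled var)
  hand <- apply(v, 2, function(col) {
    mc <- mean(col[1:3]); mt <- mean(col[4:6])
    sp2 <- (2 * var(col[1:3]) + 2 * var(col[4:6])) / 4
    (mt - mc) / sqrt(sp2 * 2 / 3)
  })
  expect_equal(st$d, hand, tolerance = 1e-12)
  expect_equal(unname(st$d["m4"]), 0)   # equal group means -> d = 0
})

test_that("s0 shrinks d toward zero in the limit", {
  set.seed(50)
  pm <- make_pm(matrix(rnorm(12 * 15), 12, 15))
  d_small <- sam_statistics(pm, s0 = 0)$d
  d_huge <- sam_statistics(pm, s0 = 1e6)$d
  expect_lt(max(abs(d_huge)), 1e-4)
  expect_gt(max(abs(d_small)), 0.1)
})

test_that("with s0 = 0 the |d| ranking equals the |t| ranking", {
  set.seed(51)
  pm <- make_pm(matrix(rnorm(12 * 25), 12, 25))
  d <- sam_statistics(pm, s0 = 0)$d
  t <- t_test_all(pm)$t_statistic
  expect_equal(order(abs(d)), order(abs(t)))
  expect_equal(unname(d), t, tolerance = 1e-12)
})

test_that("balanced splits are enumerated: 462 for six vs six", {
  pm <- make_pm(matrix(rnorm(12 * 8, 0, 1), 12, 8))
  perm <- sam_permute(pm, s0 = 0, n_permutations = 1000, seed = 1)
  expect_equal(perm$n_permutations, 462)
  expect_equal(choose(12, 6) / 2, 462)
  # fixed seed determinism when sampling is forced
  p1 <- sam_permute(pm, s0 = 0, n_permutations = 100, seed = 9)
  p2 <- sam_permute(pm, s0 = 0, n_permutations = 100, seed = 9)
  expect_identical(p1$d_expected, p2$d_expected)
  expect_equal(nrow(p1$d_perm), 100)
})

test_that("permuting identical-valued samples leaves d unchanged", {
  # all samples identical: every d is 0 (given s0 > 0) under every
  # relabelling, and the all-constant matrix is rejected by the statistic
  v <- matrix(rep(c(1, 2, 3, 4), each = 12), 12, 4)
  pm <- make_pm(v)
  expect_error(sam_statistics(pm, s0 = 1), "constant")
  expect_warning(perm <- sam_permute(pm, s0 = 1, n_permutations = 20,
                                     seed = 2), "coarse")
  expect_true(all(perm$d_perm == 0))
  expect_true(all(perm$d_expected == 0))
})

test_that("called set shrinks monotonically in delta and q-values are sane", {
  sim <- simulate_panel(sim_config(n_metabolites = 120, frac_differential = 0.15,
                                   effect_fc_range = c(2.5, 3.5),
                                   missing_rate = 0, cellcount_cv = 0,
                                   seed = 61))
  pm <- preprocess_panel(sim$table)$log
  fit <- sam_fit(pm, seed = 61)
  tab <- fit$delta_table
  prev <- Inf
  for (g in seq(1, nrow(tab), by = 5)) {
    called_g <- sum(fit$d >= tab$cutup[g] | fit$d <= tab$cutlow[g])
    expect_lte(called_g, prev)
    prev <- called_g
  }
  expect_true(all(fit$q_value >= 0 & fit$q_value <= 1))
  # called metabolites have q at or below the fit's achieved FDR
  expect_true(all(fit$q_value[fit$called] <= fit$fdr_at_delta + 1e-12))
})

test_that("delta_for_fdr is monotone in the target and trivial at 1.0", {
  sim <- simulate_panel(sim_config(n_metabolites = 100, frac_differential = 0.2,
                                   effect_fc_range = c(2, 4),
                                   missing_rate = 0, seed = 62))
  fit <- sam_fit(preprocess_panel(sim$table)$log, seed = 62)
  expect_equal(delta_for_fdr(fit, 1.0)$delta, 0)
  d01 <- delta_for_fdr(fit, 0.01)$delta
  d10 <- delta_for_fdr(fit, 0.10)$delta
  expect_gte(d01, d10)
  expect_lte(delta_for_fdr(fit, 0.05)$fdr, 0.05)
})

test_that("huge delta calls nothing and delta 0 calls everything", {
  set.seed(63)
  pm <- make_pm(matrix(rnorm(12 * 30), 12, 30))
  big <- sam_fit(pm, delta = 1e6, seed = 63)
  expect_equal(sum(big$called), 0)
  expect_equal(big$fdr_at_delta, 0)  # empty call set reports FDR 0
  zero <- sam_fit(pm, delta = 0, seed = 63)
  expect_equal(sum(zero$called), 30)
})

test_that("planted effects are recovered with few false calls", {
  per_seed <- vapply(1:11, function(s) {
    sim <- simulate_panel(sim_config(n_metabolites = 200,
                                     frac_differential = 0.1,
                                     effect_fc_range = c(3, 3),
                                     baseline_log_sd = 0.2,
                                     missing_rate = 0, cellcount_cv = 0,
                                     seed = s))
    fit <- sam_fit(preprocess_panel(sim$table)$log, seed = s)
    sel <- names(fit$d)[fit$called]
    tr <- sim$truth$differential_ids
    c(hit = sum(sel %in% tr), false = sum(!sel %in% tr))
  }, numeric(2))
  expect_gte(median(per_seed["hit", ]), 15)
  expect_lte(median(per_seed["false", ]), 2)
})

test_that("null metabolites carry high q-values", {
  qmeds <- vapply(1:5, function(s) {
    sim <- simulate_panel(sim_config(n_metabolites = 150,
                                     frac_differential = 0, missing_rate = 0,
                                     cellcount_cv = 0, seed = 100 + s))
    fit <- sam_fit(preprocess_panel(sim$table)$log, seed = s)
    median(fit$q_value)
  }, numeric(1))
  expect_true(all(qmeds >= 0.5))
})
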