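test_that("abundance_table validates its inputs", {
  v <- matrix(1:12, 4, 3)
  expect_s3_class(make_table(v), "abundance_table")
  expect_error(abundance_table(v, c("a", "a", "a", "a")), "two groups")
  expect_error(abundance_table(v, c("a", "a", "b", "c")), "two groups")
  expect_error(abundance_table(-v, rep(c("control", "treated"), each = 2)),
               "non-negative")
  expect_error(abundance_table(v, rep(c("control", "treated"), each = 2),
                               control = "x"), "control label")
})

test_that("abundance CSV round-trips with empty fields as missing", {
  tab <- random_panel(m = 8, seed = 3)
  tab$values[2, 4] <- NA
  tab$values[7, 1] <- NA
  path <- tempfile(fileext = ".csv")
  write_abundance(tab, path)
  back <- read_abundance(path)
  expect_equal(back$values, tab$values)
  expect_equal(back$group, tab$group)
  expect_true(grepl(",,", readLines(path)[3]))  # row 2 has an empty field
})

test_that("filter_complete keeps exactly the all-present metabolites", {
  tab <- random_panel(m = 10, seed = 4)
  tab$values[5, 3] <- NA           # one missing cell anywhere removes it
  tab$values[c(1, 9), 7] <- NA
  out <- filter_complete(tab)
  expect_setequal(colnames(out$table$values),
                  setdiff(colnames(tab$values),
                          colnames(tab$values)[c(3, 7)]))
  expect_equal(out$retention_fraction, 8 / 10)

  # complete table is untouched
  full <- random_panel(m = 5, seed = 5)
  expect_equal(filter_complete(full)$table$values, full$values)
  expect_equal(filter_complete(full)$retention_pct, 100)

  # all-missing panel errors with a diagnostic
  gone <- random_panel(m = 3, seed = 6)
  gone$values[1, ] <- NA
  expect_error(filter_complete(gone), "nothing retained")
})

test_that("filter_complete is order-independent over samples", {
  tab <- random_panel(m = 20, seed = 7)
  set.seed(1)
  tab$values[cbind(sample(12, 8, TRUE), sample(20, 8, TRUE))] <- NA
  perm <- sample(nrow(tab$values))
  shuffled <- abundance_table(tab$values[perm, ], tab$group[perm])
  expect_setequal(colnames(filter_complete(tab)$table$values),
                  colnames(filter_complete(shuffled)$table$values))
})

test_that("normalize_to_control forces control means to one", {
  v <- matrix(c(2, 2, 4, 6), 4, 1,
              dimnames = list(NULL, "m1"))
  tab <- make_table(v, group = c("control", "control", "treated", "treated"))
  norm <- normalize_to_control(tab)
  expect_equal(unname(norm$values[, 1]), c(1, 1, 2, 3))
  # idempotent
  expect_equal(normalize_to_control(norm)$values, norm$values)
  # post-condition on a random table, every column
  tab2 <- random_panel(m = 15, seed = 8)
  norm2 <- normalize_to_control(tab2)
  ctrl_means <- colMeans(norm2$values[norm2$group == "control", ])
  expect_equal(unname(ctrl_means), rep(1, 15), tolerance = 1e-12)
})

test_that("normalize_to_control commutes with per-metabolite rescaling", {
  tab <- random_panel(m = 6, seed = 9)
  scaled <- tab
  f <- runif(6, 0.5, 4)
  scaled$values <- sweep(tab$values, 2L, f, "*")
  expect_equal(normalize_to_control(scaled)$values,
               normalize_to_control(tab)$values, tolerance = 1e-12)
})

test_that("pareto scaling centres and divides by sqrt(sd)", {
  # column (1,2,3,1,2,3): mean 2, sample sd sqrt(0.8), so each deviation is
  # divided by 0.8^(1/4) = 0.9457416
  v <- matrix(c(1, 2, 3, 1, 2, 3), 6, 1, dimnames = list(NULL, "m1"))
  tab <- make_table(v, group = rep(c("control", "treated"), each = 3))
  out <- pareto_scale(tab)
  expect_equal(unname(out$values[, 1]),
               c(-1, 0, 1, -1, 0, 1) / 0.8^0.25, tolerance = 1e-9)

  const <- make_table(matrix(5, 4, 1, dimnames = list(NULL, "m1")),
                      group = rep(c("control", "treated"), each = 2))
  expect_warning(res <- pareto_scale(const), "constant")
  expect_equal(unname(res$values[, 1]), rep(0, 4))

  # moments on a random column
  tab2 <- random_panel(m = 10, seed = 10)
  p <- pareto_scale(tab2)
  expect_equal(max(abs(colMeans(p$values))), 0, tolerance = 1e-12)
  expect_equal(apply(p$values, 2, var),
               apply(tab2$values, 2, sd), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("log transform rejects non-positive values", {
  tab <- random_panel(m = 3, seed = 11)
  tab$values[1, 1] <- 0
  expect_error(log_transform(tab), "strictly positive")
})

test_that("fold change is treated over control on the un-logged scale", {
  v <- cbind(m1 = c(1, 1, 2, 2), m2 = c(2, 2, 2, 2))
  tab <- make_table(v, group = c("control", "control", "treated", "treated"))
  fc <- fold_change(tab)
  expect_equal(unname(fc), c(2, 1))
})

test_that("planted fold changes are recovered within sampling error", {
  # metabolite planted at FC 3, n = 6/group, log-sd 0.1: estimates should
  # land in [2.5, 3.6] for the large majority of seeds
  est <- vapply(1:200, function(s) {
    sim <- simulate_panel(sim_config(n_metabolites = 5, n_per_group = 6,
                                     baseline_log_sd = 0.1,
                                     frac_differential = 1,
                                     effect_fc_range = c(3, 3),
                                     missing_rate = 0, cellcount_cv = 0,
                                     seed = s))
    id <- sim$truth$differential_ids[1]
    est <- fold_change(sim$table)[id]
    if (sim$truth$fc_by_id[id] < 1) 1 / est else est  # fold magnitude
  }, numeric(1))
  expect_gte(mean(est >= 2.5 & est <= 3.6), 0.95)
})

test_that("effect-free pipeline output is centred with no group structure", {
  sim <- simulate_panel(sim_config(n_metabolites = 100, frac_differential = 0,
                                   missing_rate = 0, seed = 12))
  panel <- preprocess_panel(sim$table)
  expect_equal(max(abs(colMeans(panel$pareto$values))), 0, tolerance = 1e-12)
  uni <- t_test_all(panel$log)
  expect_gt(min(uni$fdr_q), 0.05)  # nothing should be called
})
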