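test_that("percent_affected rounds to one decimal and validates", {
  expect_equal(percent_affected(0, 7), 0)
  expect_equal(percent_affected(7, 7), 100)
  expect_equal(percent_affected(1, 3), 33.3)
  expect_error(percent_affected(1, 0), "size")
  expect_error(percent_affected(5, 3), "hits")
})

test_that("library loads with synonym index and validates edges", {
  lib <- read_pathway_library(synthetic_library_path())
  expect_s3_class(lib, "pathway_library")
  expect_equal(length(lib$pathways), 12)
  p1 <- lib$pathways[[1]]
  expect_true(all(p1$edges %in% p1$compounds))
  # synonym lookup is case- and punctuation-insensitive
  first <- p1$synonyms[[1]]
  res <- map_metabolites(toupper(first$names[1]), lib)
  expect_equal(unname(res$matched), first$id)
  res2 <- map_metabolites(c("definitely-not-a-compound"), lib)
  expect_equal(res2$unmatched, "definitely-not-a-compound")
  expect_equal(map_metabolites(character(0), lib)$matched, character(0))
})

test_that("impact follows out-degree centrality with hand-checked values", {
  chain <- chain_pathway()
  # out-degrees: A = 1, B = 1, C = 0 -> importances (0.5, 0.5, 0)
  expect_equal(pathway_impact(chain, "A"), 0.5)
  expect_equal(pathway_impact(chain, c("A", "B")), 1.0)
  expect_equal(pathway_impact(chain, "C"), 0)
  expect_equal(pathway_impact(chain, c("A", "B", "C")), 1.0)
  expect_equal(pathway_impact(chain, character(0)), 0)
  expect_error(pathway_impact(chain, "Z"), "outside")
  # edgeless pathway: uniform importance
  orphan <- list(compounds = c("x", "y", "z", "w"),
                 edges = matrix(character(0), 0, 2))
  expect_equal(pathway_impact(orphan, c("x", "y")), 0.5)
})

test_that("KGML reader maps compounds and reaction direction", {
  kg <- read_kgml(system.file("extdata", "synthetic_chain.kgml",
                              package = "consensusmet"))
  expect_setequal(kg$compounds, c("C90901", "C90902", "C90903"))
  # irreversible 1->2 plus reversible 2<->3
  expect_equal(nrow(kg$edges), 3)
  expect_true(any(kg$edges[, 1] == "C90901" & kg$edges[, 2] == "C90902"))
  expect_true(any(kg$edges[, 1] == "C90903" & kg$edges[, 2] == "C90902"))
  expect_false(any(kg$edges[, 1] == "C90902" & kg$edges[, 2] == "C90901"))
})

test_that("single-member global test matches the squared-t permutation null", {
  set.seed(110)
  v <- matrix(rnorm(12 * 5), 12, 5)
  v[7:12, 3] <- v[7:12, 3] + 1.2
  colnames(v) <- paste0("C", 1:5)
  pm <- make_pm(v)
  gt <- global_test(pm, "C3", n_permutations = 4000, seed = 1)
  # oracle: permutation p of the squared t statistic for that column alone
  y <- rep(c(-1, 1), each = 6)
  x <- v[, 3]
  tstat <- function(yy) {
    a <- x[yy < 0]; b <- x[yy > 0]
    (mean(b) - mean(a))^2
  }
  obs <- tstat(y)
  set.seed(2)
  perm <- replicate(4000, tstat(sample(y)))
  p_oracle <- (1 + sum(perm >= obs)) / 4001
  expect_lt(abs(gt$p_value - p_oracle), 0.02)  # Monte-Carlo error bound
  expect_equal(gt$n_members_used, 1)
})

test_that("global test p is roughly uniform under the null", {
  ps <- vapply(1:40, function(s) {
    set.seed(4000 + s)
    v <- matrix(rnorm(12 * 6), 12, 6, dimnames = list(NULL, paste0("C", 1:6)))
    global_test(make_pm(v), paste0("C", 1:6), n_permutations = 199,
                seed = s)$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  # pathway with no measured member is excluded with reason
  v <- matrix(rnorm(12 * 2), 12, 2, dimnames = list(NULL, c("C1", "C2")))
  ex <- global_test(make_pm(v), c("Zz1", "Zz2"))
  expect_true(is.na(ex$p_value))
})

test_that("pathway analysis ranks a loaded pathway first and nests filters", {
  lib <- read_pathway_library(synthetic_library_path())
  # plant effects inside one pathway: 6 of SP10+SP09 compounds among noise
  target <- lib$pathways[["SP09"]]$compounds  # 10 compounds
  set.seed(111)
  all_ids <- unique(unlist(lapply(lib$pathways, function(p) p$compounds)))
  meas <- all_ids[1:120]
  meas <- union(meas, target)
  v <- matrix(rnorm(12 * length(meas)), 12,
              dimnames = list(NULL, meas))
  v[7:12, target[1:6]] <- v[7:12, target[1:6]] + 2
  pm <- make_pm(v)
  disc <- target[1:6]
  res <- pathway_analyze(pm, disc, lib, mode = "none", n_permutations = 300,
                         seed = 3)
  expect_equal(res$pathway[which.max(res$percent_affected)], "SP09")
  expect_equal(res$percent_affected[res$pathway == "SP09"],
               percent_affected(6, 10))
  # nested filter modes: full subset of fdr subset of none
  r_full <- pathway_analyze(pm, disc, lib, mode = "full",
                            n_permutations = 300, seed = 3)
  r_fdr <- pathway_analyze(pm, disc, lib, mode = "fdr",
                           n_permutations = 300, seed = 3)
  expect_true(all(r_full$pathway %in% r_fdr$pathway))
  expect_true(all(r_fdr$pathway %in% res$pathway))
  # empty discriminant set: all hits and impacts zero, full mode empty
  r0 <- pathway_analyze(pm, character(0), lib, mode = "none",
                        n_permutations = 100, seed = 3)
  expect_true(all(r0$hits == 0))
  expect_true(all(r0$impact == 0))
  r0full <- pathway_analyze(pm, character(0), lib, mode = "full",
                            n_permutations = 100, seed = 3)
  expect_equal(nrow(r0full), 0)
})

test_that("full-mode percent-affected gate is strictly greater than 20", {
  # one pathway with exactly 1 of 5 hit (20.0%) must not survive full mode
  lib <- list(pathways = list(P1 = list(id = "P1", name = "p1",
                                        super_pathway = "T",
                                        compounds = paste0("C", 1:5),
                                        edges = matrix(character(0), 0, 2))),
              compound_index = setNames(paste0("C", 1:5),
                                        tolower(paste0("c", 1:5))))
  class(lib) <- "pathway_library"
  set.seed(112)
  v <- matrix(rnorm(12 * 5), 12, 5, dimnames = list(NULL, paste0("C", 1:5)))
  v[7:12, 1] <- v[7:12, 1] + 4   # strong single-feature signal
  pm <- make_pm(v)
  res <- pathway_analyze(pm, "C1", lib, mode = "none", n_permutations = 400,
                         seed = 4)
  expect_equal(res$percent_affected, 20)
  full <- pathway_analyze(pm, "C1", lib, mode = "full", n_permutations = 400,
                          seed = 4)
  expect_equal(nrow(full), 0)
  # with 2 of 5 (40%) and high impact it survives when the FDR allows
  res2 <- pathway_analyze(pm, c("C1", "C2"), lib, mode = "full",
                          n_permutations = 400, seed = 4)
  if (res$fdr_q < 0.05) expect_equal(nrow(res2), 1)
})

test_that("super-pathway matrix aggregates and clusters sensibly", {
  lib <- read_pathway_library(synthetic_library_path())
  ids <- unlist(lapply(lib$pathways, function(p) p$compounds))
  set.seed(113)
  fc_a <- setNames(exp(rnorm(length(ids), 0, 0.1)), ids)
  fc_b <- fc_a            # identical condition
  fc_c <- setNames(exp(rnorm(length(ids), 1.5, 0.1)), ids)
  sp <- superpathway_matrix(list(a = fc_a, b = fc_b, c = fc_c), lib)
  expect_equal(sp$matrix[, "a"], sp$matrix[, "b"])
  expect_equal(dist(t(sp$matrix))[1], 0, ignore_attr = TRUE)
  hc <- hclust(dist(t(sp$matrix)), method = "ward.D2")
  merged_first <- sort(-hc$merge[1, ])
  expect_equal(merged_first, c(1, 2))  # identical columns merge first

  # single class, single metabolite: the cell equals |log2 FC|
  one <- list(pathways = list(P = list(id = "P", name = "p",
                                       super_pathway = "Solo",
                                       compounds = "C1",
                                       edges = matrix(character(0), 0, 2))),
              compound_index = c(c1 = "C1"))
  class(one) <- "pathway_library"
  m <- superpathway_matrix(list(only = c(C1 = 4)), one)
  expect_equal(unname(m$matrix["Solo", "only"]), 2)  # |log2 4| = 2
})
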