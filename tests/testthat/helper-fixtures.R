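# shared in-code fixtures

# processed matrix straight from a numeric matrix (bypasses the log/Pareto
# chain when a test wants full control of the values)
make_pm <- function(values, group = rep(c("control", "treated"),
                                        each = nrow(values) / 2),
                    control = "control") {
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("M%04d", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%d", seq_len(nrow(values)))
  consensusmet:::processed_matrix(values, group, control)
}

# small complete two-group abundance table with controllable values
make_table <- function(values, group = rep(c("control", "treated"),
                                           each = nrow(values) / 2)) {
  abundance_table(values, group)
}

# random complete panel on the natural scale
random_panel <- function(n_per_group = 6, m = 30, seed = 1) {
  set.seed(seed)
  vals <- matrix(exp(rnorm(2 * n_per_group * m, 5, 0.5)), 2 * n_per_group, m)
  make_table(vals)
}

# three-compound chain pathway A -> B -> C (hand-checkable topology)
chain_pathway <- function() {
  list(id = "CHAIN", name = "three-step chain", super_pathway = "Test",
       compounds = c("A", "B", "C"),
       edges = rbind(c("A", "B"), c("B", "C")))
}

synthetic_library_path <- function() {
  system.file("extdata", "synthetic_pathways.json", package = "consensusmet")
}

reference_table <- function(which) {
  read.delim(system.file("extdata",
                         sprintf("reference_stats_%s.tsv", which),
                         package = "consensusmet"))
}
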