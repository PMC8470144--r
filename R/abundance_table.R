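#' Two-group metabolite abundance table
#'
#' The basic container of the pipeline: a samples x metabolites matrix of
#' relative abundances (non-negative where measured, `NA` where the feature
#' was not detected in that sample), a group label per sample, and the name
#' of the control group. Zeros are treated as measured values, not as
#' missing: failure to detect and low concentration are different events in
#' LC-MS/MS panels, and only true missingness is filtered on.
#'
#' @param values numeric matrix, samples in rows, metabolites in columns.
#'   Row and column names are used as sample and metabolite identifiers;
#'   defaults (`S1...`, `M0001...`) are supplied when absent.
#' @param group character or factor of group labels, one per sample.
#'   Exactly two distinct labels with at least two samples each.
#' @param control the label in `group` naming the control/reference group.
#' @return an object of class `"abundance_table"`.
#' @export
abundance_table <- function(values, group, control = "control") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (samples x metabolites)")
  group <- as.character(group)
  if (length(group) != nrow(values))
    stop("`group` must have one label per sample (row)")
  labs <- unique(group)
  if (length(labs) != 2L)
    stop("expected exactly two groups, got: ", paste(labs, collapse = ", "))
  if (!control %in% labs)
    stop("control label '", control, "' not present in `group`")
  if (any(table(group) < 2L))
    stop("each group needs at least 2 samples")
  if (any(values < 0, na.rm = TRUE))
    stop("abundances must be non-negative where present")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("M%04d", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample identifiers")
  if (anyDuplicated(colnames(values)))
    stop("duplicate metabolite identifiers")
  structure(list(values = values, group = group, control = control),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  n_miss <- sum(is.na(x$values))
  cat("abundance_table:", nrow(x$values), "samples x", ncol(x$values),
      "metabolites\n")
  cat("  groups: ", paste(sprintf("%s (n=%d)", names(table(x$group)),
                                  table(x$group)), collapse = ", "),
      "; control = '", x$control, "'\n", sep = "")
  cat(sprintf("  missing entries: %d (%.1f%%)\n", n_miss,
              100 * n_miss / length(x$values)))
  invisible(x)
}

group_indices <- function(x) {
  list(control = which(x$group == x$control),
       treated = which(x$group != x$control))
}

#' Read an abundance table from CSV
#'
#' Expected layout: header row; first column sample identifier, second
#' column group label, remaining columns one metabolite each. Empty fields
#' and `NA` tokens are missing values.
#'
#' @param path CSV file path.
#' @param control control-group label (default `"control"`).
#' @return an [abundance_table()].
#' @export
read_abundance <- function(path, control = "control") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (ncol(df) < 3L) stop("need sample, group and at least one metabolite column")
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- as.character(df[[1L]])
  abundance_table(vals, df[[2L]], control = control)
}

#' Write an abundance table to CSV
#'
#' Inverse of [read_abundance()]; missing entries become empty fields.
#'
#' @param x an [abundance_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(x, path) {
  df <- data.frame(sample = rownames(x$values), group = x$group,
                   x$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
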