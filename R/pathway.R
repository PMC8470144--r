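#' Read a pathway library from JSON
#'
#' Schema: a list of pathway objects `{id, name, super_pathway,
#' compounds: [{id, names: [...]}, ...], edges: [[from, to], ...]}`. Edges
#' are directed compound pairs; every endpoint must be a member compound.
#' A compound synonym index (lower-cased, punctuation-normalised name ->
#' canonical ID) is built while loading.
#'
#' @param path JSON file.
#' @return object of class `"pathway_library"`: `pathways` (named list of
#'   pathway definitions) and `compound_index` (named character vector).
#' @export
read_pathway_library <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  pathways <- lapply(raw, function(p) {
    comps <- vapply(p$compounds, function(cc) cc$id, character(1))
    edges <- if (length(p$edges))
      do.call(rbind, lapply(p$edges, function(e) unlist(e))) else
      matrix(character(0), 0, 2)
    if (nrow(edges) && !all(edges %in% comps))
      stop("pathway ", p$id, ": edge endpoint outside member compounds")
    list(id = p$id, name = p$name,
         super_pathway = p$super_pathway %||% NA_character_,
         compounds = comps, edges = edges,
         synonyms = lapply(p$compounds, function(cc)
           list(id = cc$id, names = unlist(cc$names))))
  })
  ids <- vapply(pathways, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate pathway ids")
  names(pathways) <- ids
  index <- character(0)
  for (p in pathways) for (s in p$synonyms) {
    nm <- unique(c(s$id, s$names))
    index[.normalize_name(nm)] <- s$id
  }
  structure(list(pathways = pathways, compound_index = index),
            class = "pathway_library")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.normalize_name <- function(x) gsub("[^a-z0-9]+", "", tolower(x))

#' @export
print.pathway_library <- function(x, ...) {
  cat("pathway_library:", length(x$pathways), "pathways,",
      length(unique(x$compound_index)), "compounds\n")
  invisible(x)
}

#' Read a KGML (KEGG XML) pathway file
#'
#' Maps compound entries to their KEGG compound IDs and reaction
#' substrate -> product pairs to directed edges; intended for optionally
#' ingesting real KEGG pathways into the library schema.
#'
#' @param path KGML file.
#' @param super_pathway optional class label to attach.
#' @return a single pathway definition list compatible with the library
#'   (`id`, `name`, `compounds`, `edges`, `synonyms`).
#' @export
read_kgml <- function(path, super_pathway = NA_character_) {
  doc <- xml2::read_xml(path)
  root <- xml2::xml_attrs(doc)
  entries <- xml2::xml_find_all(doc, ".//entry[@type='compound']")
  entry_id <- xml2::xml_attr(entries, "id")
  cpd <- sub("^cpd:", "", vapply(strsplit(xml2::xml_attr(entries, "name"),
                                          " "), `[[`, character(1), 1L))
  names(cpd) <- entry_id
  edges <- matrix(character(0), 0, 2)
  for (rx in xml2::xml_find_all(doc, ".//reaction")) {
    subs <- sub("^cpd:", "", xml2::xml_attr(
      xml2::xml_find_all(rx, "./substrate"), "name"))
    prods <- sub("^cpd:", "", xml2::xml_attr(
      xml2::xml_find_all(rx, "./product"), "name"))
    rev <- identical(xml2::xml_attr(rx, "type"), "reversible")
    for (s in subs) for (p in prods) {
      edges <- rbind(edges, c(s, p))
      if (rev) edges <- rbind(edges, c(p, s))
    }
  }
  comps <- unique(cpd)
  edges <- edges[edges[, 1] %in% comps & edges[, 2] %in% comps, ,
                 drop = FALSE]
  list(id = unname(root["name"]), name = unname(root["title"]),
       super_pathway = super_pathway, compounds = comps,
       edges = unique(edges),
       synonyms = lapply(comps, function(id) list(id = id, names = id)))
}

#' Map metabolite names to canonical compound IDs
#'
#' Case-insensitive, punctuation-normalised exact matching against the
#' library's compound IDs and synonyms. Unmatched names are returned, never
#' silently dropped.
#'
#' @param names character vector of metabolite names.
#' @param library a [read_pathway_library()] object.
#' @return list: `matched` (named character vector, input name -> canonical
#'   ID) and `unmatched` (character vector).
#' @export
map_metabolites <- function(names, library) {
  stopifnot(inherits(library, "pathway_library"))
  if (!length(names)) return(list(matched = character(0),
                                  unmatched = character(0)))
  hit <- library$compound_index[.normalize_name(names)]
  ok <- !is.na(hit)
  list(matched = stats::setNames(unname(hit[ok]), names[ok]),
       unmatched = names[!ok])
}

#' Percent of a pathway's metabolites affected
#'
#' `100 * hits / size`, rounded to one decimal place; the score used to
#' screen out pathways whose statistical significance rests on a small
#' fraction of their members.
#'
#' @param hits number of differentiated member metabolites.
#' @param size pathway size (>= 1).
#' @return percentage in `[0, 100]`, 1 d.p.
#' @export
percent_affected <- function(hits, size) {
  if (any(size < 1)) stop("pathway size must be >= 1")
  if (any(hits < 0 | hits > size)) stop("need 0 <= hits <= size")
  round(100 * hits / size, 1)
}

#' Permutation Global Test for pathway association
#'
#' Goeman-style score statistic `Q = (y - ybar)' X X' (y - ybar) / m` on the
#' pathway's `m` measured member columns (y the class code), with the null
#' distribution obtained by permuting group labels:
#' `p = (1 + #permuted >= observed) / (1 + B)`. Chosen over the asymptotic
#' approximation because group sizes of ~6 are far from asymptotia.
#'
#' @param x a `"processed_matrix"`.
#' @param compounds compound/metabolite IDs of the pathway; only those
#'   present as columns of `x` are used.
#' @param n_permutations B (default 2000).
#' @param seed RNG seed.
#' @return list: `p_value`, `statistic`, `n_members_used`; or `NULL`-like
#'   excluded record (`p_value = NA`) when no member is measured.
#' @export
global_test <- function(x, compounds, n_permutations = 2000, seed = 1) {
  stopifnot(inherits(x, "processed_matrix"))
  member <- intersect(compounds, colnames(x$values))
  if (!length(member))
    return(list(p_value = NA_real_, statistic = NA_real_, n_members_used = 0L,
                excluded = "no measured members"))
  X <- x$values[, member, drop = FALSE]
  y <- ifelse(x$group == x$control, -1, 1)
  qstat <- function(yc) {
    r <- yc - mean(yc)
    sum(drop(crossprod(X, r))^2) / length(member)
  }
  obs <- qstat(y)
  set.seed(seed)
  perm <- vapply(seq_len(n_permutations), function(i) qstat(sample(y)),
                 numeric(1))
  list(p_value = (1 + sum(perm >= obs)) / (1 + n_permutations),
       statistic = obs, n_members_used = length(member))
}

#' Topology impact of a hit set on a pathway
#'
#' Node importance is out-degree in the pathway's directed compound graph,
#' normalised to sum to 1 across the pathway's compounds; the impact is the
#' total importance carried by the hit compounds. An edgeless pathway falls
#' back to uniform importance `1/size`.
#'
#' @param pathway a pathway definition from a [read_pathway_library()].
#' @param hits character vector of hit compound IDs (must be members).
#' @return impact in `[0, 1]`.
#' @export
pathway_impact <- function(pathway, hits) {
  comps <- pathway$compounds
  if (!all(hits %in% comps))
    stop("hit compounds outside the pathway: ",
         paste(setdiff(hits, comps), collapse = ", "))
  outdeg <- stats::setNames(numeric(length(comps)), comps)
  if (nrow(pathway$edges)) {
    tab <- table(pathway$edges[, 1L])
    outdeg[names(tab)] <- as.numeric(tab)
  }
  tot <- sum(outdeg)
  importance <- if (tot == 0) rep(1 / length(comps), length(comps)) else
    outdeg / tot
  names(importance) <- comps
  sum(importance[hits])
}

#' Pathway analysis of a discriminant metabolite set
#'
#' Per pathway: hits = discriminant set intersected with the pathway's
#' compounds; percent affected with the library size as denominator;
#' permutation Global Test p on the measured members; out-degree impact;
#' BH FDR across all tested pathways. Three reporting modes: `"none"`
#' (everything), `"fdr"` (FDR < `fdr_max`), `"full"` (FDR < `fdr_max` AND
#' impact > `impact_min` AND percent affected > `pct_min`). Pathways with
#' no measured member are excluded from testing and listed separately.
#'
#' @param x a `"processed_matrix"` whose columns are canonical compound IDs
#'   (map names first with [map_metabolites()]).
#' @param discriminant character vector of discriminant compound IDs.
#' @param library a [read_pathway_library()].
#' @param mode filter mode, see above.
#' @param fdr_max,impact_min,pct_min filter thresholds (strict comparisons).
#' @param size_from `"library"` (denominator = all library compounds of the
#'   pathway, the default) or `"measured"` (only measured members).
#' @param n_permutations,seed Global Test settings.
#' @return object of class `"pathway_result"`: data.frame with `pathway`,
#'   `name`, `super_pathway`, `hits`, `size`, `percent_affected`,
#'   `differentiated` ("hits/size"), `p_value`, `fdr_q`, `impact`; the
#'   unfiltered table is kept in `attr(, "unfiltered")`, excluded pathways
#'   in `attr(, "excluded")`.
#' @export
pathway_analyze <- function(x, discriminant, library,
                            mode = c("none", "fdr", "full"), fdr_max = 0.05,
                            impact_min = 0.25, pct_min = 20,
                            size_from = c("library", "measured"),
                            n_permutations = 2000, seed = 1) {
  stopifnot(inherits(library, "pathway_library"))
  mode <- match.arg(mode)
  size_from <- match.arg(size_from)
  if (!length(library$pathways)) stop("empty pathway library")
  measured <- colnames(x$values)
  rows <- list(); excluded <- character(0)
  for (p in library$pathways) {
    members_measured <- intersect(p$compounds, measured)
    if (!length(members_measured)) { excluded <- c(excluded, p$id); next }
    hits <- intersect(discriminant, p$compounds)
    size <- if (size_from == "library") length(p$compounds) else
      length(members_measured)
    gt <- global_test(x, p$compounds, n_permutations = n_permutations,
                      seed = seed)
    rows[[p$id]] <- data.frame(
      pathway = p$id, name = p$name, super_pathway = p$super_pathway,
      hits = length(hits), size = size,
      percent_affected = percent_affected(length(hits), size),
      differentiated = sprintf("%d/%d", length(hits), size),
      p_value = gt$p_value,
      impact = pathway_impact(p, hits),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    stop("no pathway has measured members in the matrix")
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$fdr_q <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$fdr_q, -res$percent_affected), ]
  keep <- switch(mode,
                 none = rep(TRUE, nrow(res)),
                 fdr = res$fdr_q < fdr_max,
                 full = res$fdr_q < fdr_max & res$impact > impact_min &
                   res$percent_affected > pct_min)
  out <- res[keep, , drop = FALSE]
  attr(out, "unfiltered") <- res
  attr(out, "excluded") <- excluded
  class(out) <- c("pathway_result", "data.frame")
  out
}

#' Super-pathway aggregation matrix for heatmaps
#'
#' Aggregates per-metabolite log2 fold changes into super-pathway classes
#' (default statistic: mean absolute log2 fold change over the class's
#' measured member metabolites) for each condition, and orders rows and
#' columns by Ward-linkage hierarchical clustering on Euclidean distance.
#'
#' @param fc_by_condition named list: condition -> named fold-change vector
#'   (un-logged scale) keyed by canonical compound ID.
#' @param library a [read_pathway_library()] with `super_pathway` labels.
#' @param aggregate function applied to the class's `|log2 FC|` values
#'   (default `mean`).
#' @return list: `matrix` (super-pathway x condition), `row_order`,
#'   `col_order` (from [stats::hclust()], `ward.D2`), `dropped` (classes
#'   with no measured members).
#' @export
superpathway_matrix <- function(fc_by_condition, library, aggregate = mean) {
  stopifnot(inherits(library, "pathway_library"), length(fc_by_condition) > 0)
  class_of <- list()
  for (p in library$pathways) {
    if (is.na(p$super_pathway)) next
    class_of[[p$super_pathway]] <- unique(c(class_of[[p$super_pathway]],
                                            p$compounds))
  }
  if (!length(class_of)) stop("library carries no super_pathway labels")
  conds <- names(fc_by_condition)
  mat <- matrix(NA_real_, length(class_of), length(conds),
                dimnames = list(names(class_of), conds))
  for (k in names(class_of)) for (cd in conds) {
    fc <- fc_by_condition[[cd]]
    members <- intersect(class_of[[k]], names(fc))
    if (length(members))
      mat[k, cd] <- aggregate(abs(log2(fc[members])))
  }
  dropped <- rownames(mat)[rowSums(!is.na(mat)) == 0]
  mat <- mat[rowSums(!is.na(mat)) > 0, , drop = FALSE]
  row_order <- seq_len(nrow(mat)); col_order <- seq_len(ncol(mat))
  if (nrow(mat) > 2)
    row_order <- stats::hclust(stats::dist(mat), method = "ward.D2")$order
  if (ncol(mat) > 2)
    col_order <- stats::hclust(stats::dist(t(mat)), method = "ward.D2")$order
  list(matrix = mat, row_order = row_order, col_order = col_order,
       dropped = dropped)
}
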