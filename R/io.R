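#' File formats
#'
#' Per-subject connectivity matrices travel as plain delimited text (n rows x
#' n columns, no header, as exported by common tractography tools), cohort
#' metadata as CSV, parcellation labels as TSV, and run configuration as
#' JSON.
#'
#' @name io
NULL

#' Read / write a streamline-count matrix as delimited text
#'
#' @param path file path.
#' @param m matrix to write.
#' @return `read_count_matrix` returns a numeric matrix.
#' @export
read_count_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  validate_count_matrix(m)
  m
}

#' @rdname read_count_matrix
#' @export
write_count_matrix <- function(m, path) {
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Synthetic parcellation label table
#'
#' A label table for an n-region parcellation with alternating left/right
#' hemisphere assignment (the convention of paired atlas orderings). These
#' labels are synthetic placeholders, not a real anatomical atlas.
#'
#' @param n_nodes number of regions.
#' @return data.frame: index, name, hemisphere.
#' @export
make_parcellation <- function(n_nodes = 90) {
  hemi <- ifelse(seq_len(n_nodes) %% 2 == 1, "L", "R")
  data.frame(index = seq_len(n_nodes),
             name = sprintf("region_%03d_%s", seq_len(n_nodes), hemi),
             hemisphere = hemi, stringsAsFactors = FALSE)
}

#' Read / write a parcellation label TSV
#'
#' @param labels data.frame with columns index, name, hemisphere.
#' @param path file path.
#' @export
write_parcellation <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write a synthetic cohort to disk
#'
#' One delimited matrix file per subject, a metadata CSV, a parcellation
#' TSV, and the generating spec (seeds included) as JSON.
#'
#' @param cohort a `tbi_cohort` from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tbi_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mat_dir <- file.path(dir, "matrices")
  dir.create(mat_dir, showWarnings = FALSE)
  for (id in names(cohort$matrices))
    write_count_matrix(cohort$matrices[[id]],
                       file.path(mat_dir, paste0(id, ".txt")))
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  write_parcellation(make_parcellation(cohort$spec$n_nodes),
                     file.path(dir, "parcellation.tsv"))
  cfg <- unclass(cohort$spec)
  cfg$target_region <- cohort$target_region
  jsonlite::write_json(cfg, file.path(dir, "cohort_spec.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort from disk
#'
#' Counterpart of [write_cohort()]; also accepts any directory holding a
#' `matrices/` folder of per-subject delimited matrices named
#' `<subject_id>.txt` and a `metadata.csv`.
#'
#' @param dir cohort directory.
#' @return list with `matrices` (named list) and `metadata` (data.frame).
#' @export
read_cohort <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "metadata.csv"),
                          stringsAsFactors = FALSE)
  mats <- lapply(meta$subject_id, function(id)
    read_count_matrix(file.path(dir, "matrices", paste0(id, ".txt"))))
  names(mats) <- meta$subject_id
  list(matrices = mats, metadata = meta)
}

#' Export a weighted network as GraphML
#'
#' Thin wrapper around igraph's GraphML writer (igraph must be installed).
#'
#' @param net a `weighted_network`.
#' @param path output file.
#' @export
export_graphml <- function(net, path) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("GraphML export requires the igraph package")
  g <- igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Printed hub-region group summaries bundled with the package
#'
#' Per-group means and standard deviations of the three network measures
#' (raw-count strength, efficiency, clustering coefficient) in the twelve
#' hub regions of the emulated study, together with the group sizes
#' (22 controls, 12 mTBI, 10 msTBI). These printed summary statistics are
#' sufficient for one-way ANOVA, so group comparisons can be recomputed from
#' them exactly even though the underlying subject data are confidential.
#'
#' @return data.frame: region, measure, group, mean, sd, n.
#' @export
hub_region_summaries <- function() {
  path <- system.file("extdata", "hub_region_measures.csv",
                      package = "tbiconn", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Printed demographic group summaries bundled with the package
#'
#' Group means/SDs of age at assessment and time since injury (years) of the
#' emulated study.
#'
#' @return data.frame: variable, group, mean, sd, n.
#' @export
demographic_summaries <- function() {
  path <- system.file("extdata", "group_demographics.csv",
                      package = "tbiconn", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
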