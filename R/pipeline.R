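#' Severity-analysis pipeline
#'
#' End-to-end orchestration: simulate (or load) a cohort of streamline-count
#' matrices, build weighted networks, compute the measure table, identify
#' per-group betweenness hubs, run the dose-response group statistics with
#' FDR control in three families (global measures; hub regions; all regions
#' per measure), and correlate regional measures with cognitive change
#' scores. Re-running with the same configuration and seed reproduces every
#' output.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' All tunable parameters of a run; defaults reproduce the analysis choices
#' of the emulated study (streamline threshold 10, top-10% hub rule, FDR at
#' 0.05, inverse weight-length mapping).
#'
#' @param simulation a [cohort_spec()] used when no `input_dir` is given.
#' @param input_dir optional directory of an existing cohort (see
#'   [read_cohort()]); when supplied, no simulation is run.
#' @param threshold streamline-count noise threshold.
#' @param hub_fraction top fraction of ranked betweenness classified as hubs.
#' @param fdr_alpha FDR level for every analysis family.
#' @param map weight-to-length mapping for path-based measures.
#' @param regional_efficiency `"local"` or `"nodal"` per-node efficiency in
#'   the measure table (see [network_measures()]).
#' @param seed integer seed; overrides `simulation$seed` so one value
#'   controls the whole run.
#' @param out_dir optional output directory; when given, every table is
#'   written there.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = cohort_spec(),
                            input_dir = NULL,
                            threshold = 10,
                            hub_fraction = 0.10,
                            fdr_alpha = 0.05,
                            map = c("inverse", "neglog"),
                            regional_efficiency = c("local", "nodal"),
                            seed = 1L,
                            out_dir = NULL) {
  stopifnot(threshold >= 0, hub_fraction > 0, hub_fraction < 1,
            fdr_alpha > 0, fdr_alpha < 1)
  simulation$seed <- as.integer(seed)
  structure(list(simulation = validate_cohort_spec(simulation),
                 input_dir = input_dir, threshold = threshold,
                 hub_fraction = hub_fraction, fdr_alpha = fdr_alpha,
                 map = match.arg(map),
                 regional_efficiency = match.arg(regional_efficiency),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

# one ANOVA + LSD row per (measure, node) cell of a measure table
.compare_cell <- function(values, groups) {
  split_vals <- split(values, groups)
  a <- anova_oneway(split_vals)
  ph <- lsd_posthoc(split_vals)
  list(anova = a, posthoc = ph)
}

#' Group comparisons over an analysis family with FDR control
#'
#' Runs one-way ANOVA (and LSD post-hoc tests) for every requested
#' measure/region cell and applies Benjamini-Hochberg FDR across the family.
#'
#' @param measures measure table from [measure_table()].
#' @param metadata cohort metadata with `subject_id` and `group`.
#' @param scope `"global"` or `"node"`.
#' @param family_measures measure names to test.
#' @param regions for node scope, the node labels to test (default: all).
#' @param fdr_alpha FDR level.
#' @return data.frame: measure, node, F, df_between, df_within, p, q,
#'   significant, and LSD pairwise p-values (one column per group pair).
#' @export
compare_groups <- function(measures, metadata, scope = c("global", "node"),
                           family_measures, regions = NULL,
                           fdr_alpha = 0.05) {
  scope <- match.arg(scope)
  tab <- measures[measures$scope == scope &
                    measures$measure %in% family_measures, ]
  if (scope == "node" && !is.null(regions))
    tab <- tab[tab$node %in% regions, ]
  if (nrow(tab) == 0) stop("no measure rows match the requested family")
  grp <- metadata$group[match(tab$subject_id, metadata$subject_id)]
  if (anyNA(grp)) stop("subjects in the measure table missing from metadata")
  key <- if (scope == "global") tab$measure else
    paste(tab$measure, tab$node, sep = "\r")
  cells <- split(seq_len(nrow(tab)), key)
  constant <- vapply(cells, function(idx) stats::sd(tab$value[idx]) == 0,
                     logical(1))
  if (any(constant)) {
    skipped <- sub("\r", " @ ", names(cells)[constant])
    warning("skipping constant measure cell(s): ",
            paste(skipped, collapse = ", "))
    cells <- cells[!constant]
  }
  if (!length(cells)) stop("every cell in the family is constant")
  rows <- lapply(cells, function(idx) {
    cmp <- .compare_cell(tab$value[idx], grp[idx])
    ph <- cmp$posthoc
    pp <- stats::setNames(ph$p, paste0("p_", ph$group1, "_vs_", ph$group2))
    c(list(measure = tab$measure[idx[1]],
           node = if (scope == "global") NA_character_ else tab$node[idx[1]],
           F = cmp$anova$F, df_between = cmp$anova$df_between,
           df_within = cmp$anova$df_within, p = cmp$anova$p),
      as.list(pp))
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  fdr <- bh_fdr(out$p, alpha = fdr_alpha)
  out$q <- fdr$q
  out$significant <- fdr$significant
  out
}

#' Correlate regional network measures with cognitive change scores
#'
#' Pearson correlations between each (region, measure) pair and the RPM
#' change score, pooled over every subject with a non-missing change score
#' and separately within each group. Subjects without cognition scores are
#' dropped within this analysis only (listwise deletion). FDR is applied
#' across the pooled family. Groups with fewer than 3 scored subjects and
#' constant measures are skipped with a warning.
#'
#' @param measures measure table (node scope rows are used).
#' @param metadata cohort metadata with `subject_id`, `group`, `rpm_change`.
#' @param regions node labels to correlate.
#' @param family_measures measure names to correlate.
#' @param fdr_alpha FDR level for the pooled family.
#' @return data.frame: node, measure, group (`"all"` or a group name), n, r,
#'   p, q (pooled rows only), significant.
#' @export
correlate_cognition <- function(measures, metadata, regions,
                                family_measures = c("strength_raw",
                                                    "efficiency",
                                                    "clustering"),
                                fdr_alpha = 0.05) {
  stopifnot("rpm_change" %in% names(metadata))
  tab <- measures[measures$scope == "node" & measures$node %in% regions &
                    measures$measure %in% family_measures, ]
  if (nrow(tab) == 0) stop("no node-scope rows match the requested regions")
  meta_idx <- match(tab$subject_id, metadata$subject_id)
  tab$group <- metadata$group[meta_idx]
  tab$rpm_change <- metadata$rpm_change[meta_idx]
  tab <- tab[!is.na(tab$rpm_change), ]
  cells <- split(seq_len(nrow(tab)),
                 paste(tab$node, tab$measure, sep = "\r"))
  rows <- list()
  for (idx in cells) {
    node <- tab$node[idx[1]]; ms <- tab$measure[idx[1]]
    subsets <- c(list(all = idx),
                 split(idx, tab$group[idx]))
    for (gname in names(subsets)) {
      sidx <- subsets[[gname]]
      if (length(sidx) < 3) {
        warning("skipping ", gname, " for ", node, "/", ms,
                ": fewer than 3 scored subjects")
        next
      }
      if (stats::sd(tab$value[sidx]) == 0) {
        warning("skipping ", gname, " for ", node, "/", ms,
                ": measure is constant")
        next
      }
      ct <- pearson_correlation(tab$value[sidx], tab$rpm_change[sidx])
      rows[[length(rows) + 1]] <-
        data.frame(node = node, measure = ms, group = gname, n = ct$n,
                   r = ct$r, p = ct$p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- NA_real_
  out$significant <- NA
  pooled <- out$group == "all"
  if (any(pooled)) {
    fdr <- bh_fdr(out$p[pooled], alpha = fdr_alpha)
    out$q[pooled] <- fdr$q
    out$significant[pooled] <- fdr$significant
  }
  out
}

#' Run the full severity-analysis pipeline
#'
#' Simulate or load the cohort, build every subject's weighted network,
#' compute the measure table, rank per-group betweenness and classify hubs,
#' run the three FDR-controlled comparison families, and correlate hub-region
#' measures with cognitive change scores.
#'
#' @param config a [pipeline_config()].
#' @return an `analysis_report` list: `config`, `metadata`, `measures`,
#'   `hub_ranking`, `hub_sets`, `hub_overlap`, `stats_global`,
#'   `stats_hub_regions`, `stats_local`, `correlations`, `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$input_dir)) {
    cohort <- generate_cohort(config$simulation)
    matrices <- cohort$matrices
    metadata <- cohort$metadata
  } else {
    loaded <- read_cohort(config$input_dir)
    matrices <- loaded$matrices
    metadata <- loaded$metadata
    if (!"rpm_change" %in% names(metadata))
      metadata$rpm_change <- change_score(metadata$rpm_pre, metadata$rpm_post)
    cohort <- NULL
  }
  labels <- make_parcellation(nrow(matrices[[1]]))$name
  networks <- lapply(names(matrices), function(id)
    build_network(matrices[[id]], min_streamlines = config$threshold,
                  labels = labels))
  names(networks) <- names(matrices)

  measures <- measure_table(networks,
                            regional_efficiency = config$regional_efficiency,
                            map = config$map)

  bet <- measures[measures$scope == "node" & measures$measure == "betweenness", ]
  groups <- sort(unique(metadata$group))
  rankings <- lapply(groups, function(g) {
    subj <- metadata$subject_id[metadata$group == g]
    b <- bet[bet$subject_id %in% subj, ]
    bm <- do.call(rbind, lapply(split(b$value, b$subject_id), rbind))
    colnames(bm) <- b$node[b$subject_id == subj[1]]
    hub_ranking(bm, group = g, fraction = config$hub_fraction)
  })
  names(rankings) <- groups
  ranking_tab <- do.call(rbind, rankings)
  rownames(ranking_tab) <- NULL
  hub_sets <- lapply(rankings, function(r) r$node[r$is_hub])
  overlap <- hub_overlap(hub_sets)

  stats_global <- compare_groups(
    measures, metadata, scope = "global",
    family_measures = c("strength_raw", "global_efficiency", "clustering"),
    fdr_alpha = config$fdr_alpha)
  stats_hub <- compare_groups(
    measures, metadata, scope = "node",
    family_measures = c("strength_raw", "efficiency", "clustering"),
    regions = overlap$union, fdr_alpha = config$fdr_alpha)
  local_measures <- c("strength_raw", "efficiency", "clustering")
  stats_local <- do.call(rbind, lapply(local_measures, function(ms)
    compare_groups(measures, metadata, scope = "node",
                   family_measures = ms, fdr_alpha = config$fdr_alpha)))
  rownames(stats_local) <- NULL

  correlations <- NULL
  if (any(!is.na(metadata$rpm_change)))
    correlations <- correlate_cognition(measures, metadata,
                                        regions = overlap$union,
                                        fdr_alpha = config$fdr_alpha)

  report <- structure(list(
    config = config, metadata = metadata, measures = measures,
    hub_ranking = ranking_tab, hub_sets = hub_sets, hub_overlap = overlap,
    stats_global = stats_global, stats_hub_regions = stats_hub,
    stats_local = stats_local, correlations = correlations,
    provenance = list(seed = config$seed,
                      package_version = as.character(
                        utils::packageVersion("tbiconn")))),
    class = "analysis_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Severity-analysis report:", nrow(x$metadata), "subjects\n")
  cat("  hub sets:", paste(sprintf("%s (%d)", names(x$hub_sets),
                                   lengths(x$hub_sets)), collapse = ", "), "\n")
  cat("  shared hubs:", length(x$hub_overlap$shared),
      "| union:", x$hub_overlap$union_size, "\n")
  sig <- x$stats_global[x$stats_global$significant, "measure"]
  cat("  global measures significant after FDR:",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Write an analysis report to disk
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if missing).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(report$measures, file.path(dir, "measures.csv"),
                   row.names = FALSE)
  utils::write.csv(report$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  wt(report$hub_ranking, "hub_ranking.tsv")
  wt(report$stats_global, "stats_global.tsv")
  wt(report$stats_hub_regions, "stats_hub_regions.tsv")
  wt(report$stats_local, "stats_local.tsv")
  if (!is.null(report$correlations)) wt(report$correlations, "correlations.tsv")
  jsonlite::write_json(report$hub_overlap, file.path(dir, "hub_overlap.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  cfg <- report$config
  cfg$simulation <- unclass(cfg$simulation)
  jsonlite::write_json(c(unclass(cfg), report$provenance),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
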