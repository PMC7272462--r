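#' Synthetic connectome cohort generator
#'
#' The study cohorts this package analyzes are confidential, so the pipeline
#' is exercised on synthetic streamline-count cohorts that carry the
#' statistical structure the analysis assumes: a shared connected template
#' with a high-weight core (so betweenness hubs exist and are stable), a
#' multiplicative severity-graded attenuation of every edge (control > mild >
#' moderate-severe expected strength, the dose-response structure), optional
#' extra attenuation targeted at chosen hub nodes in chosen groups, and
#' cognitive change scores coupled to a hub region's nodal efficiency in
#' controls only.
#'
#' @name synthetic-cohort
NULL

#' Specification of a synthetic cohort
#'
#' Holds every parameter of the generator. Defaults describe the study
#' conditions being emulated: a 90-region parcellation, group sizes
#' 22 controls / 12 mild TBI / 10 moderate-severe TBI, and a graded edge
#' attenuation (1, 0.9, 0.75) producing the qualitative dose-response.
#'
#' @param n_nodes number of parcellation regions.
#' @param group_sizes named integer vector (control, mTBI, msTBI), each >= 2.
#' @param edge_density fraction of node pairs connected in the template,
#'   in (0, 1].
#' @param mean_count expected streamline count of a present template edge.
#' @param attenuation per-group multiplicative factor on every edge weight,
#'   in (0, 1], non-increasing from control to msTBI; control is 1.
#' @param hub_nodes integer indices (or labels) of nodes whose edges receive
#'   extra attenuation (empty by default).
#' @param extra_hub_attenuation factor in (0, 1] applied to edges incident to
#'   `hub_nodes` in the groups listed in `hub_attenuation_groups`.
#' @param hub_attenuation_groups groups receiving the targeted hub
#'   attenuation (default `"msTBI"`).
#' @param dispersion overdispersion of the count noise: subject counts are
#'   negative-binomial with variance `mu + dispersion * mu^2`; 0 gives
#'   deterministic rounded means.
#' @param subject_sigma SD of the per-subject log-normal global scaling
#'   factor (between-subject variability in overall tract yield).
#' @param cognition_slope,cognition_noise_sd control-group coupling between
#'   standardized target-region nodal efficiency and the cognitive change
#'   score: `change = slope * z(eff) + N(0, noise_sd)`. Defaults (1, 1) give
#'   a population correlation of `1/sqrt(2)`, about 0.71.
#' @param cognition_group_shift mean change score of TBI subjects (decoupled
#'   from efficiency); negative values emulate post-injury decline.
#' @param n_control_cognition number of controls carrying cognitive scores
#'   (the remaining controls have missing scores).
#' @param core_frac,core_boost fraction of nodes forming the high-weight
#'   core, and the count multiplier of core-core edges (core-periphery edges
#'   get `sqrt(core_boost)`); this produces stable betweenness hubs.
#' @param seed integer seed; every random draw of the generator derives from
#'   it.
#' @return a validated `cohort_spec` object (a list).
#' @export
cohort_spec <- function(n_nodes = 90,
                        group_sizes = c(control = 22, mTBI = 12, msTBI = 10),
                        edge_density = 0.3,
                        mean_count = 500,
                        attenuation = c(control = 1, mTBI = 0.9, msTBI = 0.75),
                        hub_nodes = integer(0),
                        extra_hub_attenuation = 0.5,
                        hub_attenuation_groups = "msTBI",
                        dispersion = 0.02,
                        subject_sigma = 0.12,
                        cognition_slope = 1,
                        cognition_noise_sd = 1,
                        cognition_group_shift = -2,
                        n_control_cognition = 8,
                        core_frac = 0.15,
                        core_boost = 3,
                        seed = 1L) {
  spec <- list(n_nodes = as.integer(n_nodes), group_sizes = group_sizes,
               edge_density = edge_density, mean_count = mean_count,
               attenuation = attenuation, hub_nodes = hub_nodes,
               extra_hub_attenuation = extra_hub_attenuation,
               hub_attenuation_groups = hub_attenuation_groups,
               dispersion = dispersion, subject_sigma = subject_sigma,
               cognition_slope = cognition_slope,
               cognition_noise_sd = cognition_noise_sd,
               cognition_group_shift = cognition_group_shift,
               n_control_cognition = as.integer(n_control_cognition),
               core_frac = core_frac, core_boost = core_boost,
               seed = as.integer(seed))
  validate_cohort_spec(spec)
}

#' @rdname cohort_spec
#' @param spec a `cohort_spec` list to validate.
#' @export
validate_cohort_spec <- function(spec) {
  stopifnot(spec$n_nodes >= 3)
  gs <- spec$group_sizes
  if (length(gs) != 3 || !all(c("control", "mTBI", "msTBI") %in% names(gs)))
    stop("group_sizes must name control, mTBI and msTBI")
  if (any(gs < 2)) stop("all group sizes must be >= 2")
  at <- spec$attenuation[c("control", "mTBI", "msTBI")]
  if (anyNA(at) || any(at <= 0 | at > 1))
    stop("attenuation factors must lie in (0, 1] for each group")
  if (any(diff(unname(at)) > 1e-12))
    stop("attenuation must be non-increasing from control to msTBI")
  if (abs(at[["control"]] - 1) > 1e-12)
    stop("control attenuation is fixed at 1")
  if (spec$edge_density <= 0 || spec$edge_density > 1)
    stop("edge_density must lie in (0, 1]")
  if (spec$dispersion < 0) stop("dispersion must be >= 0")
  if (spec$extra_hub_attenuation <= 0 || spec$extra_hub_attenuation > 1)
    stop("extra_hub_attenuation must lie in (0, 1]")
  if (spec$n_control_cognition < 0 ||
      spec$n_control_cognition > gs[["control"]])
    stop("n_control_cognition must be between 0 and the number of controls")
  structure(spec, class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec:", x$n_nodes, "nodes;",
      paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
            collapse = ", "), "\n")
  cat("  attenuation:", paste(sprintf("%s=%.2f", names(x$attenuation),
                                      x$attenuation), collapse = ", "), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# connectivity check on the nonzero adjacency (breadth-first search)
.is_connected <- function(m) {
  n <- nrow(m)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    u <- queue[1L]
    queue <- queue[-1L]
    nb <- which(m[u, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Generate a template streamline-count matrix
#'
#' Random connected template shared by all subjects of a cohort: each node
#' pair is connected independently with probability `edge_density`, present
#' edges carry overdispersed counts around `mean_count`, and edges within a
#' randomly chosen core of `ceiling(core_frac * n)` nodes are boosted by
#' `core_boost` (core-periphery edges by `sqrt(core_boost)`), giving the
#' template a stable set of high-betweenness nodes. Disconnected draws are
#' re-sampled up to `max_tries` times before failing.
#'
#' @inheritParams cohort_spec
#' @param max_tries resampling attempts before giving up on connectivity.
#' @param template_size negative-binomial size of template counts (controls
#'   the heterogeneity of edge weights across the template).
#' @return symmetric integer matrix with zero diagonal; attribute
#'   `"core_nodes"` records the boosted core.
#' @export
generate_template <- function(n_nodes = 90, edge_density = 0.3,
                              mean_count = 500, seed = 1L,
                              core_frac = 0.15, core_boost = 3,
                              max_tries = 25, template_size = 10) {
  stopifnot(n_nodes >= 3, edge_density > 0, edge_density <= 1, mean_count > 0)
  if (edge_density * choose(n_nodes, 2) < n_nodes - 1)
    stop("edge_density ", edge_density, " is too low to connect ", n_nodes,
         " nodes")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  core <- sort(sample.int(n_nodes, ceiling(core_frac * n_nodes)))
  boost <- matrix(1, n_nodes, n_nodes)
  boost[core, ] <- sqrt(core_boost)
  boost[, core] <- sqrt(core_boost)
  boost[core, core] <- core_boost
  ut <- upper.tri(boost)
  for (try in seq_len(max_tries)) {
    m <- matrix(0, n_nodes, n_nodes)
    present <- stats::runif(sum(ut)) < edge_density
    mu <- mean_count * boost[ut]
    counts <- pmax(1, stats::rnbinom(sum(ut), mu = mu, size = template_size))
    m[ut] <- present * counts
    m <- m + t(m)
    if (.is_connected(m)) {
      attr(m, "core_nodes") <- core
      return(m)
    }
  }
  stop("could not draw a connected template in ", max_tries,
       " attempts; increase edge_density")
}

#' Generate one subject's streamline-count matrix from a template
#'
#' Each present template edge gets expected count `template * group_attenuation
#' * subject_scale`, further multiplied by `extra_hub_attenuation` when either
#' endpoint lies in `hub_nodes`. With `dispersion > 0` counts are drawn from a
#' negative-binomial law with variance `mu + dispersion * mu^2`; with
#' `dispersion = 0` counts are the rounded means. Symmetry and the zero
#' diagonal are preserved.
#'
#' @param template template matrix from [generate_template()].
#' @param group_attenuation multiplicative factor in (0, 1].
#' @param hub_nodes node indices receiving extra attenuation.
#' @param extra_hub_attenuation factor in (0, 1].
#' @param dispersion overdispersion parameter (>= 0).
#' @param seed integer seed.
#' @param subject_scale subject-level global scaling factor (> 0).
#' @return symmetric integer matrix with zero diagonal.
#' @export
generate_subject_matrix <- function(template, group_attenuation = 1,
                                    hub_nodes = integer(0),
                                    extra_hub_attenuation = 1,
                                    dispersion = 0, seed = 1L,
                                    subject_scale = 1) {
  stopifnot(group_attenuation > 0, group_attenuation <= 1,
            extra_hub_attenuation > 0, extra_hub_attenuation <= 1,
            dispersion >= 0, subject_scale > 0)
  n <- nrow(template)
  mu <- template * group_attenuation * subject_scale
  if (length(hub_nodes)) {
    hub <- matrix(FALSE, n, n)
    hub[hub_nodes, ] <- TRUE
    hub[, hub_nodes] <- TRUE
    mu[hub] <- mu[hub] * extra_hub_attenuation
  }
  ut <- upper.tri(mu)
  present <- template[ut] > 0
  m <- matrix(0, n, n)
  vals <- numeric(sum(ut))
  if (dispersion == 0) {
    vals[present] <- round(mu[ut][present])
  } else {
    set.seed(as.integer(seed) %% .Machine$integer.max)
    vals[present] <- stats::rnbinom(sum(present), mu = mu[ut][present],
                                    size = 1 / dispersion)
  }
  m[ut] <- vals
  m + t(m)
}

#' Generate cognitive scores for one subject
#'
#' Controls: change score (post minus pre) = `cognition_slope *
#' target_efficiency + N(0, cognition_noise_sd)`. TBI subjects: the coupling
#' slope is forced to zero and the change score is `cognition_group_shift +
#' N(0, cognition_noise_sd)` regardless of efficiency, emulating the loss of
#' the efficiency-cognition association after injury.
#'
#' @param group `"control"`, `"mTBI"` or `"msTBI"`.
#' @param target_efficiency (standardized) nodal efficiency of the target
#'   region for this subject.
#' @param spec a `cohort_spec`.
#' @param seed integer seed.
#' @return named numeric vector `c(rpm_pre, rpm_post)`.
#' @export
generate_cognition <- function(group, target_efficiency, spec, seed = 1L) {
  stopifnot(is.finite(target_efficiency))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  pre <- round(stats::rnorm(1, mean = 45, sd = 5), 1)
  noise <- if (spec$cognition_noise_sd > 0)
    stats::rnorm(1, 0, spec$cognition_noise_sd) else 0
  change <- if (group == "control")
    spec$cognition_slope * target_efficiency + noise
  else
    spec$cognition_group_shift + noise
  c(rpm_pre = pre, rpm_post = pre + change)
}

# nodal efficiency of a single node from a raw count matrix, after standard
# network construction; used by the generator to couple cognition.
.target_efficiency <- function(m, target, min_streamlines = 10) {
  net <- build_network(m, min_streamlines = min_streamlines)
  unname(nodal_efficiency(net, nodes = target))
}

#' Generate a full synthetic cohort
#'
#' Draws the template, per-subject matrices, demographics (GCS within each
#' group's legal range, age and time since injury around the emulated study's
#' group summaries), and cognitive scores. The cognition target region is the
#' template node with the highest betweenness centrality (a template hub);
#' its per-subject nodal efficiency drives the control change scores.
#'
#' @param spec a `cohort_spec`.
#' @return a `tbi_cohort`: list with `spec`, `template`, `target_region`,
#'   `matrices` (named list of count matrices), and `metadata` (data.frame:
#'   subject_id, group, gcs, age, time_since_injury, rpm_pre, rpm_post,
#'   rpm_change).
#' @export
generate_cohort <- function(spec) {
  spec <- validate_cohort_spec(spec)
  set.seed(spec$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, sum(spec$group_sizes) * 3 + 1)
  template <- generate_template(spec$n_nodes, spec$edge_density,
                                spec$mean_count, seed = seeds[1],
                                core_frac = spec$core_frac,
                                core_boost = spec$core_boost)
  tpl_net <- build_network(template)
  target <- which.max(betweenness_centrality(tpl_net))

  groups <- rep(names(spec$group_sizes), spec$group_sizes)
  n_total <- length(groups)
  ids <- sprintf("sub-%03d", seq_len(n_total))
  set.seed(seeds[length(seeds)])
  scored_controls <- sort(sample(which(groups == "control"),
                                 spec$n_control_cognition))
  age_par <- list(control = c(27.1, 4.3), mTBI = c(34.9, 7.0),
                  msTBI = c(28.3, 3.8))
  tsi_par <- list(mTBI = c(3.67, 1.79), msTBI = c(2.53, 1.60))

  matrices <- vector("list", n_total)
  names(matrices) <- ids
  meta <- data.frame(subject_id = ids, group = groups,
                     gcs = NA_integer_, age = NA_real_,
                     time_since_injury = NA_real_,
                     rpm_pre = NA_real_, rpm_post = NA_real_,
                     stringsAsFactors = FALSE)
  eff <- rep(NA_real_, n_total)
  for (i in seq_len(n_total)) {
    g <- groups[i]
    set.seed(seeds[n_total + i])
    scale_i <- exp(stats::rnorm(1, 0, spec$subject_sigma))
    ap <- age_par[[g]]
    meta$age[i] <- round(min(45, max(18, stats::rnorm(1, ap[1], ap[2]))), 1)
    if (g != "control") {
      meta$gcs[i] <- if (g == "mTBI") sample(14:15, 1) else sample(3:13, 1)
      tp <- tsi_par[[g]]
      meta$time_since_injury[i] <-
        round(max(1, stats::rnorm(1, tp[1], tp[2])), 2)
    }
    hub_nodes_i <- if (g %in% spec$hub_attenuation_groups) spec$hub_nodes
                   else integer(0)
    matrices[[i]] <- generate_subject_matrix(
      template, group_attenuation = spec$attenuation[[g]],
      hub_nodes = hub_nodes_i,
      extra_hub_attenuation = spec$extra_hub_attenuation,
      dispersion = spec$dispersion, seed = seeds[i],
      subject_scale = scale_i)
    scored <- (g != "control") || (i %in% scored_controls)
    if (scored && g == "control")
      eff[i] <- .target_efficiency(matrices[[i]], target)
  }
  # standardize control target efficiencies, then draw cognition
  ctrl <- which(!is.na(eff))
  z <- rep(NA_real_, n_total)
  if (length(ctrl) >= 2) {
    z[ctrl] <- (eff[ctrl] - mean(eff[ctrl])) / stats::sd(eff[ctrl])
  } else if (length(ctrl) == 1) {
    z[ctrl] <- 0
  }
  for (i in seq_len(n_total)) {
    g <- groups[i]
    scored <- (g != "control") || (i %in% scored_controls)
    if (!scored) next
    zi <- if (g == "control") z[i] else 0
    rpm <- generate_cognition(g, zi, spec, seed = seeds[2 * n_total + i])
    meta$rpm_pre[i] <- rpm[["rpm_pre"]]
    meta$rpm_post[i] <- rpm[["rpm_post"]]
  }
  meta$rpm_change <- change_score(meta$rpm_pre, meta$rpm_post)
  structure(list(spec = spec, template = template,
                 target_region = unname(target),
                 target_efficiency = eff,
                 matrices = matrices, metadata = meta),
            class = "tbi_cohort")
}

#' @export
print.tbi_cohort <- function(x, ...) {
  cat("Synthetic TBI cohort:", length(x$matrices), "subjects (",
      paste(sprintf("%s=%d", names(x$spec$group_sizes), x$spec$group_sizes),
            collapse = ", "), ")\n")
  cat("  nodes:", x$spec$n_nodes, " cognition target region:",
      x$target_region, "\n")
  invisible(x)
}

#' Generate a cohort with targeted disruption of the template hub
#'
#' Two-pass construction of the focal-disconnection scenario: the cohort is
#' first drawn without any targeted attenuation to locate the template's
#' highest-betweenness node (the cognition target region), then regenerated
#' from the same seed with that node's edges attenuated by `factor` in the
#' requested groups. Because both passes share the seed, the template and
#' every untargeted subject matrix are identical across passes. This emulates
#' disconnection of a hub region on top of the diffuse severity-graded
#' attenuation.
#'
#' @param spec a [cohort_spec()]; its `hub_nodes` are ignored and replaced by
#'   the template's top-betweenness node.
#' @param groups groups receiving the targeted attenuation.
#' @param factor extra attenuation factor in (0, 1].
#' @return a `tbi_cohort` whose `target_region` is the disrupted node.
#' @export
generate_disrupted_cohort <- function(spec, groups = "msTBI",
                                      factor = spec$extra_hub_attenuation) {
  base <- spec
  base$hub_nodes <- integer(0)
  pilot <- generate_cohort(validate_cohort_spec(base))
  spec$hub_nodes <- pilot$target_region
  spec$hub_attenuation_groups <- groups
  spec$extra_hub_attenuation <- factor
  generate_cohort(validate_cohort_spec(spec))
}

#' Per-subject target-region efficiency and cognition recovery analysis
#'
#' For every scored subject of a synthetic cohort, rebuilds the weighted
#' network and computes the nodal efficiency of the cohort's cognition
#' target region, then correlates it with the RPM change score pooled over
#' all scored subjects and within each group (mirroring the all-subject and
#' per-group correlation analyses).
#'
#' @param cohort a `tbi_cohort`.
#' @param min_streamlines noise threshold used when rebuilding networks.
#' @return list with `data` (data.frame: subject_id, group, efficiency,
#'   rpm_change) and `correlations` (data.frame: group incl. `"all"`, n, r,
#'   p; groups with fewer than 3 scored subjects are omitted).
#' @export
target_efficiency_correlations <- function(cohort, min_streamlines = 10) {
  stopifnot(inherits(cohort, "tbi_cohort"))
  meta <- cohort$metadata
  scored <- which(!is.na(meta$rpm_change))
  eff <- vapply(scored, function(i)
    .target_efficiency(cohort$matrices[[i]], cohort$target_region,
                       min_streamlines), numeric(1))
  dat <- data.frame(subject_id = meta$subject_id[scored],
                    group = meta$group[scored], efficiency = eff,
                    rpm_change = meta$rpm_change[scored],
                    stringsAsFactors = FALSE)
  subsets <- c(list(all = seq_len(nrow(dat))),
               split(seq_len(nrow(dat)), dat$group))
  rows <- list()
  for (g in names(subsets)) {
    idx <- subsets[[g]]
    if (length(idx) < 3) next
    ct <- pearson_correlation(dat$efficiency[idx], dat$rpm_change[idx])
    rows[[length(rows) + 1]] <- data.frame(group = g, n = ct$n, r = ct$r,
                                           p = ct$p, stringsAsFactors = FALSE)
  }
  list(data = dat, correlations = do.call(rbind, rows))
}
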