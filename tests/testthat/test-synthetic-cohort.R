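test_that("templates are symmetric, integer, zero-diagonal and connected", {
  m <- generate_template(n_nodes = 4, edge_density = 1, mean_count = 100,
                         seed = 1)
  expect_equal(diag(m), rep(0, 4))
  expect_true(all(m[upper.tri(m)] > 0))  # density 1 forces a complete graph
  expect_equal(m, t(m))
  expect_true(all(m == round(m)))
  # determinism under a fixed seed
  m2 <- generate_template(n_nodes = 4, edge_density = 1, mean_count = 100,
                          seed = 1)
  expect_identical(m, m2)
  expect_false(identical(
    m, generate_template(4, 1, 100, seed = 2)))
  expect_error(generate_template(n_nodes = 90, edge_density = 0.001,
                                 mean_count = 100, seed = 1), "too low")
})

test_that("template edge presence follows the Bernoulli sampling law", {
  m <- generate_template(n_nodes = 90, edge_density = 0.3, mean_count = 500,
                         seed = 7)
  n_edges <- sum(m[upper.tri(m)] > 0)
  expected <- 0.3 * choose(90, 2)            # 1201.5
  sd3 <- 3 * sqrt(choose(90, 2) * 0.3 * 0.7) # binomial oracle
  expect_true(abs(n_edges - expected) <= sd3)
})

test_that("subject matrices implement multiplicative attenuation with noise", {
  tpl <- generate_template(n_nodes = 15, edge_density = 0.6, mean_count = 200,
                           seed = 3)
  attr(tpl, "core_nodes") <- NULL
  # identity case
  expect_equal(generate_subject_matrix(tpl, 1, dispersion = 0, seed = 1), tpl)
  # deterministic halving
  half <- generate_subject_matrix(tpl, 0.5, dispersion = 0, seed = 1)
  expect_equal(half, round(tpl * 0.5) + 0)  # rounding applied entrywise
  # severity ordering is forced at zero dispersion
  ms <- vapply(c(1, 0.9, 0.75), function(a)
    mean(rowSums(generate_subject_matrix(tpl, a, dispersion = 0))), 1)
  expect_true(ms[1] > ms[2] && ms[2] > ms[3])
  # hub-targeted extra attenuation hits only incident edges
  hub <- generate_subject_matrix(tpl, 1, hub_nodes = 3,
                                 extra_hub_attenuation = 0.5, dispersion = 0)
  expect_equal(hub[3, ], round(tpl[3, ] * 0.5) + 0)
  others <- setdiff(seq_len(15), 3)
  expect_equal(hub[others, others], tpl[others, others])
  # noisy draws stay symmetric, nonnegative, integer, zero-diagonal
  noisy <- generate_subject_matrix(tpl, 0.9, dispersion = 0.05, seed = 9)
  expect_equal(noisy, t(noisy))
  expect_true(all(noisy >= 0) && all(noisy == round(noisy)))
  expect_equal(diag(noisy), rep(0, 15))
  # noise preserves the template support
  expect_true(all(noisy[tpl == 0] == 0))
})

test_that("cognition model couples controls and shifts TBI groups", {
  sp <- cohort_spec(cognition_noise_sd = 0, cognition_slope = 2,
                    cognition_group_shift = -2)
  ctl <- generate_cognition("control", target_efficiency = 1.5, sp, seed = 1)
  expect_equal(unname(ctl["rpm_post"] - ctl["rpm_pre"]), 2 * 1.5)
  tbi <- generate_cognition("msTBI", target_efficiency = 99, sp, seed = 1)
  expect_equal(unname(tbi["rpm_post"] - tbi["rpm_pre"]), -2)
})

test_that("sample correlation sits inside the Fisher-z band of the target", {
  # slope and noise chosen for population r = 0.7:
  # sd(noise) = slope * sqrt(1 - r^2) / r
  slope <- 1
  noise <- slope * sqrt(1 - 0.7^2) / 0.7
  sp <- cohort_spec(cognition_slope = slope, cognition_noise_sd = noise)
  set.seed(61)
  z <- rnorm(50)
  change <- vapply(seq_along(z), function(i) {
    rpm <- generate_cognition("control", z[i], sp, seed = 7000 + i)
    unname(rpm["rpm_post"] - rpm["rpm_pre"])
  }, 1)
  r <- cor(z, change)
  band <- atanh(0.7) + c(-1, 1) * 1.96 / sqrt(50 - 3)
  expect_true(atanh(r) > band[1] && atanh(r) < band[2])
})

test_that("cohorts have the specified composition and legal metadata", {
  coh <- generate_cohort(cohort_spec(seed = 71))
  meta <- coh$metadata
  expect_equal(nrow(meta), 44)
  expect_equal(as.integer(table(meta$group)[c("control", "mTBI", "msTBI")]),
               c(22L, 12L, 10L))
  # GCS consistent with the severity rule
  expect_true(all(is.na(meta$gcs[meta$group == "control"])))
  expect_true(all(meta$gcs[meta$group == "mTBI"] %in% 14:15))
  expect_true(all(meta$gcs[meta$group == "msTBI"] %in% 3:13))
  expect_equal(classify_severity(meta$gcs[meta$group != "control"]),
               meta$group[meta$group != "control"])
  # cognition scored for all TBI and exactly n_control_cognition controls
  expect_equal(sum(!is.na(meta$rpm_change[meta$group == "control"])), 8)
  expect_true(all(!is.na(meta$rpm_change[meta$group != "control"])))
  expect_equal(meta$rpm_change, meta$rpm_post - meta$rpm_pre)
  # every matrix satisfies the count-matrix invariants
  for (m in coh$matrices) {
    expect_equal(m, t(m))
    expect_true(all(m >= 0) && all(m == round(m)))
    expect_equal(sum(diag(m)), 0)
  }
  # byte-identical regeneration under the same seed
  coh2 <- generate_cohort(cohort_spec(seed = 71))
  expect_identical(coh$metadata, coh2$metadata)
  expect_identical(coh$matrices, coh2$matrices)
  expect_identical(coh$target_region, coh2$target_region)
})

test_that("targeted disruption changes only the targeted group's matrices", {
  sp <- cohort_spec(seed = 81, group_sizes = c(control = 4, mTBI = 3,
                                               msTBI = 3),
                    n_nodes = 30, n_control_cognition = 3)
  dis <- generate_disrupted_cohort(sp, groups = "msTBI", factor = 0.5)
  base <- generate_cohort(cohort_spec(seed = 81,
                                      group_sizes = c(control = 4, mTBI = 3,
                                                      msTBI = 3),
                                      n_nodes = 30, n_control_cognition = 3))
  ctrl_ids <- base$metadata$subject_id[base$metadata$group != "msTBI"]
  for (id in ctrl_ids)
    expect_identical(dis$matrices[[id]], base$matrices[[id]])
  ms_ids <- base$metadata$subject_id[base$metadata$group == "msTBI"]
  t <- dis$target_region
  for (id in ms_ids)
    expect_true(sum(dis$matrices[[id]][t, ]) < sum(base$matrices[[id]][t, ]))
})

test_that("cohorts round-trip through the on-disk layout", {
  sp <- cohort_spec(seed = 91, n_nodes = 20,
                    group_sizes = c(control = 3, mTBI = 2, msTBI = 2),
                    n_control_cognition = 2)
  coh <- generate_cohort(sp)
  dir <- tempfile("cohort")
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  expect_true(file.exists(file.path(dir, "parcellation.tsv")))
  expect_true(file.exists(file.path(dir, "cohort_spec.json")))
  back <- read_cohort(dir)
  expect_equal(length(back$matrices), 7)
  for (id in names(coh$matrices))
    expect_equal(back$matrices[[id]], unname(coh$matrices[[id]]),
                 ignore_attr = TRUE)
  expect_equal(back$metadata$group, coh$metadata$group)
  expect_equal(back$metadata$rpm_change, coh$metadata$rpm_change,
               tolerance = 1e-9)
})
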