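test_that("constant data give a flat, converged profile", {
  prof <- convergence_profile(const_quadruple(), n_points = 10)
  expect_equal(prof$profile$cumulative_delta_h, rep(-7.63, 10))
  expect_equal(prof$drift, 0)
  expect_true(prof$converged)
  expect_error(convergence_profile(const_quadruple(), n_points = 1), "at least 2")
})

test_that("profile at fraction 1 reproduces the full estimate bit for bit", {
  spec <- small_synth_spec(seed = 61, N = 1024)
  g <- gen_quadruple(spec)
  est <- delta_h(g$quadruple)
  prof <- convergence_profile(g$quadruple, n_points = 7)
  expect_identical(prof$final_value,
                   prof$profile$cumulative_delta_h[7])
  expect_equal(prof$final_value, est$delta_h, tolerance = 1e-12)
})

test_that("a slow ramp in the complex energy is flagged as unconverged", {
  n <- 10000
  ramp <- energy_trace(seq(0, 2, length.out = n), trajectory_id = "c1",
                       dt = 0.1)
  mk <- function(tr, role) trajectory_ensemble(list(tr), role)
  quad <- suppressWarnings(build_quadruple(
    mk(ramp, "complex"),
    mk(const_trace(0, n), "solvent"),
    mk(const_trace(0, n), "receptor"),
    mk(const_trace(0, n), "ligand")))
  prof <- convergence_profile(quad, n_points = 20, window = 0.2, tol = 0.5)
  # closed form: full mean of the ramp is 1; the last-20% window mean is
  # the ramp's average over [0.8, 1], i.e. 2 * 0.9 = 1.8; drift = 0.8
  expect_equal(prof$final_value, 1, tolerance = 1e-3)
  expect_equal(prof$drift, 0.8, tolerance = 1e-2)
  expect_false(prof$converged)
})

test_that("stationary data converge at the default tolerance", {
  ok <- vapply(1:20, function(s) {
    g <- gen_quadruple(small_synth_spec(seed = 100 + s, N = 4096, sigma = 3))
    convergence_profile(g$quadruple)$converged
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("single-linkage grouping of trajectory means: hand-checked case", {
  mk <- function(vals) {
    tr <- lapply(seq_along(vals), function(i)
      const_trace(vals[i], n = 8, id = sprintf("t%02d", i)))
    trajectory_ensemble(tr, "complex")
  }
  rep1 <- trajectory_heterogeneity(mk(c(0.0, 0.1, 5.0, 5.1)),
                                   link_threshold = 1.0)
  expect_length(rep1$groups, 2)
  expect_setequal(rep1$groups$group1, c("t01", "t02"))
  expect_setequal(rep1$groups$group2, c("t03", "t04"))
  expect_equal(rep1$gap, 4.9)
  expect_true(rep1$flagged)
  # all equal -> one group, gap 0, not flagged
  rep2 <- trajectory_heterogeneity(mk(rep(2, 4)), link_threshold = 1.0)
  expect_length(rep2$groups, 1)
  expect_equal(rep2$gap, 0)
  expect_false(rep2$flagged)
  expect_error(trajectory_heterogeneity(mk(0), link_threshold = 1), "at least 2")
})

test_that("grouping agrees with hclust single linkage on random means", {
  for (s in 1:5) {
    set.seed(700 + s)
    means <- rnorm(12, sd = 3)
    tr <- lapply(seq_along(means), function(i)
      const_trace(means[i], n = 8, id = sprintf("t%02d", i)))
    ens <- trajectory_ensemble(tr, "complex")
    thr <- 1.0
    rep <- trajectory_heterogeneity(ens, link_threshold = thr)
    hc <- stats::hclust(stats::dist(means), method = "single")
    ref <- stats::cutree(hc, h = thr)
    # same partition (labels may differ)
    got <- integer(length(means))
    for (g in seq_along(rep$groups))
      got[match(rep$groups[[g]], sprintf("t%02d", seq_along(means)))] <- g
    expect_equal(length(unique(ref)), length(rep$groups))
    expect_true(all(tapply(got, ref, function(v) length(unique(v)) == 1)))
  }
})

test_that("grouping is invariant to relabeling and global mean shifts", {
  set.seed(77)
  means <- c(rnorm(5, 0, 0.1), rnorm(5, 6, 0.1))
  mk <- function(vals, ids) {
    tr <- lapply(seq_along(vals), function(i)
      const_trace(vals[i], n = 8, id = ids[i]))
    trajectory_ensemble(tr, "complex")
  }
  ids <- sprintf("t%02d", 1:10)
  a <- trajectory_heterogeneity(mk(means, ids), link_threshold = 1)
  b <- trajectory_heterogeneity(mk(means + 100, ids), link_threshold = 1)
  expect_equal(lengths(a$groups), lengths(b$groups))
  expect_equal(a$gap, b$gap)
  # permuted ids: same partition as sets
  perm <- sample(10)
  c_ <- trajectory_heterogeneity(mk(means[perm], ids[perm]),
                                 link_threshold = 1)
  expect_setequal(lapply(unname(a$groups), sort), lapply(unname(c_$groups), sort))
})

test_that("externally supplied group labels are respected", {
  tr <- lapply(1:4, function(i) const_trace(i, n = 8, id = paste0("t", i)))
  ens <- trajectory_ensemble(tr, "complex")
  rep <- trajectory_heterogeneity(
    ens, groups = c(t1 = "A", t2 = "A", t3 = "B", t4 = "B"))
  expect_length(rep$groups, 2)
  expect_setequal(rep$groups$group1, c("t1", "t2"))
  expect_true(rep$flagged)
})

test_that("conditional dH on the full ensembles is the identity", {
  g <- gen_quadruple(small_synth_spec(seed = 81, N = 512))
  est <- delta_h(g$quadruple)
  full <- lapply(g$quadruple, function(e) names(e$traces))
  cond <- conditional_delta_h(g$quadruple, full)
  expect_equal(cond$delta_h, est$delta_h)
  expect_error(conditional_delta_h(g$quadruple, list(complex = character(0))),
               "empty")
  expect_error(conditional_delta_h(g$quadruple, list(complex = "nope")),
               "unknown trajectory")
})

test_that("one trajectory per role still yields a finite SEM from within-trajectory blocking", {
  g <- gen_quadruple(small_synth_spec(seed = 82, N = 512))
  one <- lapply(g$quadruple, function(e) names(e$traces)[1])
  est <- conditional_delta_h(g$quadruple, one)
  expect_true(is.finite(est$delta_h))
  expect_gt(est$uncertainty$combined_sem, 0)
  expect_equal(attr(est, "subset_sizes"),
               c(complex = 1L, solvent = 1L, receptor = 1L, ligand = 1L))
})

test_that("group-size-weighted conditional estimates recombine to the full estimate", {
  g <- gen_quadruple(small_synth_spec(seed = 83, N = 512))
  ids <- names(g$quadruple$complex$traces)
  part <- list(ids[1:7], ids[8:20])
  dhs <- vapply(part, function(p)
    conditional_delta_h(g$quadruple, list(complex = p))$delta_h, numeric(1))
  full <- delta_h(g$quadruple)$delta_h
  expect_equal(sum(dhs * lengths(part)) / length(ids), full,
               tolerance = 1e-12)
})

test_that("a two-state mixture recovers each state's enthalpy conditionally", {
  offs <- data.frame(offset = c(-2.5, 2.5), weight = c(0.5, 0.5))
  spec <- small_synth_spec(seed = 84, N = 2048, complex_offsets = offs)
  g <- gen_quadruple(spec)
  st <- g$state_assignments$complex
  for (s in 1:2) {
    ids <- names(st)[st == s]
    if (length(ids) < 2) next
    est <- conditional_delta_h(g$quadruple, list(complex = ids))
    truth <- g$true_state_delta_h$complex[s]
    expect_lt(abs(est$delta_h - truth), 3 * est$uncertainty$combined_sem +
                1e-12)
  }
})
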