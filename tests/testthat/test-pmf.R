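test_that("window schedule planning counts windows and total time", {
  plan <- plan_schedule(window_schedule())
  expect_equal(plan$n_windows, 41L)
  expect_equal(plan$total_time, 2460)
  expect_equal(signif(plan$total_time / 1000, 2), 2.5)  # ns, 2 s.f.
  # degenerate single-window schedule
  p1 <- plan_schedule(window_schedule(start = 10, stop = 10))
  expect_equal(p1$n_windows, 1L)
  expect_equal(p1$total_time, 60)
  expect_equal(plan_schedule(window_schedule(10, 5, 0.5))$n_windows, 11L)
  expect_error(plan_schedule(window_schedule(10, 5, 0.4)), "multiple")
})

test_that("zero mean forces integrate to the pure Jacobian term", {
  plan <- plan_schedule(window_schedule())
  win <- restraint_windows(plan$distances, rep(0, plan$n_windows))
  prof <- integrate_pmf(win, temperature = 298.15)
  kBT <- 8.314462618 * 298.15 / 4184
  expect_equal(prof$F, -2 * kBT * log(prof$R / prof$R[1]), tolerance = 1e-12)
  # with the Jacobian disabled the profile is identically zero
  prof0 <- integrate_pmf(win, jacobian = FALSE)
  expect_equal(prof0$F, rep(0, plan$n_windows))
  # reference value is a pure additive shift
  prof5 <- integrate_pmf(win, reference_value = 5)
  expect_equal(prof5$F, prof$F + 5, tolerance = 1e-12)
})

test_that("harmonic-well forces are recovered against a fine-grid quadrature oracle", {
  c0 <- 0.8; R0 <- 8.5
  force_fn <- function(R) -c0 * (R - R0)          # -dV/dR
  sched <- window_schedule()
  reps <- synth_window_forces("harmonic", sched, noise_sd = 0,
                              params = list(k = c0, center = R0))
  prof <- integrate_pmf(reps[[1]], jacobian = FALSE)
  # oracle: 100x refined trapezoid of the same force field
  oracle <- -oracle_fine_quadrature(force_fn, prof$R, refine = 100)
  expect_equal(prof$F, oracle, tolerance = 1e-6)
  # and both match the analytic potential (relative to the reference window)
  V <- function(R) 0.5 * c0 * (R - R0)^2
  expect_equal(prof$F, V(prof$R) - V(prof$R[1]), tolerance = 1e-9)
})

test_that("trapezoid integration converges at second order", {
  # smooth Gaussian-well force field; halve the step, error should drop ~4x
  params <- list(depth = 2.394, center = 8.5, width = 2)
  V <- function(R) -params$depth * exp(-(R - params$center)^2 / (2 * params$width^2))
  err_at_step <- function(step) {
    sched <- window_schedule(21.5, 1.5, step)
    win <- synth_window_forces("gaussian", sched, params = params)[[1]]
    prof <- integrate_pmf(win, jacobian = FALSE)
    max(abs(prof$F - (V(prof$R) - V(prof$R[1]))))
  }
  e1 <- err_at_step(0.5)
  e2 <- err_at_step(0.25)
  expect_gt(e1 / e2, 3)   # ~4 for a second-order rule
  expect_lt(e1 / e2, 5)
})

test_that("integration is additive over subintervals", {
  params <- list(depth = 2, center = 8.5, width = 2)
  win <- synth_window_forces("gaussian", window_schedule(), params = params)[[1]]
  full <- integrate_pmf(win, jacobian = FALSE)
  upper <- integrate_pmf(win[win$R_o >= 10, ], jacobian = FALSE)
  lower <- integrate_pmf(win[win$R_o <= 10, ], jacobian = FALSE)
  # chain the lower segment onto the upper one at the shared grid point
  chained <- lower$F + upper$F[upper$R == 10]
  expect_equal(chained, full$F[full$R <= 10], tolerance = 1e-10)
})

test_that("replicate aggregation uses the Student-t interval", {
  plan <- plan_schedule(window_schedule())
  mk <- function(shift) {
    win <- restraint_windows(plan$distances, rep(0, plan$n_windows))
    prof <- integrate_pmf(win, reference_value = shift)
    prof
  }
  # identical replicates: zero width
  agg <- aggregate_replicates(list(mk(0), mk(0), mk(0)))
  expect_equal(max(agg$ci_half_width), 0)
  # two replicates at 1 and 3: mean 2, half-width qt(.975, 1) * sd / sqrt(2)
  agg2 <- aggregate_replicates(list(mk(1), mk(3)))
  expect_equal(agg2$F[1], 2)
  expect_equal(agg2$ci_half_width[1], 12.7062047 * sqrt(2) / sqrt(2),
               tolerance = 1e-6)
  # single replicate: mean passes through, CI flagged undefined
  agg1 <- aggregate_replicates(list(mk(4)))
  expect_equal(agg1$F[1], 4)
  expect_true(all(is.na(agg1$ci_half_width)))
  expect_false(attr(agg1, "ci_defined"))
  # mismatched grids are rejected
  short <- integrate_pmf(restraint_windows(c(21.5, 21, 20.5), c(0, 0, 0)))
  expect_error(aggregate_replicates(list(mk(0), short)), "grid")
})

test_that("binding-energy extraction finds well depth, location and width", {
  # constructed profile: plateau at 0 for R >= 17.5, minimum -2.394 at 8.5 A
  R <- seq(21.5, 1.5, by = -0.5)
  F_ <- -2.394 * exp(-(R - 8.5)^2 / (2 * 1.5^2))
  prof <- structure(data.frame(R = R, F = F_),
                    class = c("pmf_profile", "data.frame"))
  res <- extract_binding_energy(prof)
  expect_equal(res$dG, -2.394, tolerance = 1e-3)
  expect_equal(res$R_min, 8.5)
  expect_false(res$no_well)
  expect_gt(res$well_width, 0)
  # additive shifts leave the extraction unchanged
  prof_up <- prof; prof_up$F <- prof$F + 7
  res_up <- extract_binding_energy(prof_up)
  expect_equal(res_up$dG, res$dG, tolerance = 1e-12)
  expect_equal(res_up$well_width, res$well_width)
  # flat profile: no well
  flat <- prof; flat$F <- rep(0, length(R))
  res_flat <- extract_binding_energy(flat)
  expect_equal(res_flat$dG, 0)
  expect_true(res_flat$no_well)
  # monotone decrease toward contact: minimum at the smallest distance,
  # well reported to the range edge
  mono <- prof; mono$F <- (R - 21.5) / 5
  res_mono <- extract_binding_energy(mono)
  expect_equal(res_mono$R_min, 1.5)
  # plateau mean is -0.4; F drops below it from R = 19.0 down to the edge
  expect_equal(res_mono$well_width, 19.0 - 1.5)
  # empty plateau region is a configuration error
  expect_error(extract_binding_energy(prof, plateau_min = 50), "plateau")
})

test_that("synthetic window generator is deterministic and honest about noise", {
  sched <- window_schedule()
  flat <- synth_window_forces("flat", sched, noise_sd = 0)[[1]]
  expect_equal(flat$mean_force, rep(0, 41))
  a <- synth_window_forces("gaussian", sched, noise_sd = 0.05,
                           n_replicates = 3, seed = 99)
  b <- synth_window_forces("gaussian", sched, noise_sd = 0.05,
                           n_replicates = 3, seed = 99)
  expect_identical(a, b)
  expect_error(synth_window_forces("flat", sched, noise_sd = -1), "noise_sd")
})

test_that("noisy synthetic wells are recovered within the replicate CI", {
  # Monte-Carlo coverage: with 7 replicates of noise sd 0.05 the aggregated
  # well depth should bracket the true depth in >= 90% of trials
  params <- list(depth = 2.394, center = 8.5, width = 2)
  sched <- window_schedule()
  true_prof <- integrate_pmf(synth_window_forces("gaussian", sched,
                                                 params = params)[[1]])
  true_dG <- extract_binding_energy(true_prof)$dG
  hits <- 0
  n_trials <- 100
  for (t in seq_len(n_trials)) {
    reps <- synth_window_forces("gaussian", sched, noise_sd = 0.05,
                                n_replicates = 7, seed = 1000 + t,
                                params = params)
    profs <- lapply(reps, integrate_pmf)
    agg <- aggregate_replicates(profs)
    res <- extract_binding_energy(agg)
    i_min <- which.min(agg$F)
    hw <- agg$ci_half_width[i_min]
    if (abs(res$dG - true_dG) <= hw) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("window tables round-trip through delimited text byte-identically", {
  win <- synth_window_forces("gaussian", window_schedule(), noise_sd = 0.02,
                             n_replicates = 2, seed = 5)
  tab <- do.call(rbind, win)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_restraint_windows(tab, f1)
  back <- read_restraint_windows(f1)
  write_restraint_windows(back, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # missing columns are reported with the required header
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(R_o = 1:3), bad, row.names = FALSE)
  expect_error(read_restraint_windows(bad), "mean_force")
})
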