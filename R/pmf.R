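#' Restrained-window schedule
#'
#' Describes the series of harmonic-restraint windows along the
#' centroid-centroid distance. Defaults reproduce the standard protocol:
#' windows from 21.5 A down to 1.5 A at 0.5 A intervals, each with 10 ps of
#' equilibration and 50 ps of production.
#'
#' @param start Largest target distance in Angstrom.
#' @param stop Smallest target distance in Angstrom.
#' @param step Spacing between windows in Angstrom.
#' @param equilibration_time Per-window equilibration time in ps.
#' @param production_time Per-window production time in ps.
#' @return An object of class `window_schedule`.
#' @export
window_schedule <- function(start = 21.5, stop = 1.5, step = 0.5,
                            equilibration_time = 10, production_time = 50) {
  if (!(start >= stop) || stop <= 0 || step <= 0)
    stop("window_schedule: require start >= stop > 0 and step > 0", call. = FALSE)
  if (equilibration_time < 0 || production_time < 0)
    stop("window_schedule: times must be non-negative", call. = FALSE)
  structure(list(start = start, stop = stop, step = step,
                 equilibration_time = equilibration_time,
                 production_time = production_time),
            class = "window_schedule")
}

#' Expand a window schedule into its target distances
#'
#' @param schedule A [window_schedule()].
#' @return A list with `distances` (Angstrom, decreasing from start to stop
#'   inclusive), `n_windows`, and `total_time` in ps
#'   (n_windows x (equilibration + production)).
#' @export
#' @examples
#' plan_schedule(window_schedule())$total_time  # 2460 ps ~ 2.5 ns
plan_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "window_schedule"))
  span <- schedule$start - schedule$stop
  k <- span / schedule$step
  if (abs(k - round(k)) > 1e-6)
    stop("plan_schedule: (start - stop) is not an integer multiple of step",
         call. = FALSE)
  k <- as.integer(round(k))
  distances <- schedule$start - schedule$step * (0:k)
  list(distances = distances,
       n_windows = k + 1L,
       total_time = (k + 1) * (schedule$equilibration_time + schedule$production_time))
}

.window_cols <- c("replicate", "R_o", "K_r", "mean_force", "n_samples")

#' Construct a table of restrained-window records
#'
#' One row per window: replicate label, target distance `R_o` (A), harmonic
#' force constant `K_r` (kcal mol^-1 A^-2, default 100), time-averaged
#' restraint force `mean_force` = <K_r (R(t) - R_o)> (kcal mol^-1 A^-1) and
#' the number of samples averaged.
#'
#' @param R_o Target distances in Angstrom.
#' @param mean_force Mean restraint forces, one per window.
#' @param K_r Harmonic force constant(s).
#' @param replicate Replicate label(s).
#' @param n_samples Sample count(s) per window.
#' @return A data.frame with columns replicate, R_o, K_r, mean_force,
#'   n_samples.
#' @export
restraint_windows <- function(R_o, mean_force, K_r = 100, replicate = 1L,
                              n_samples = 1L) {
  if (any(K_r <= 0))
    stop("restraint_windows: force constant must be positive", call. = FALSE)
  if (any(R_o <= 0))
    stop("restraint_windows: target distances must be positive", call. = FALSE)
  data.frame(replicate = replicate, R_o = R_o, K_r = K_r,
             mean_force = mean_force, n_samples = n_samples)
}

.check_windows <- function(windows) {
  if (!all(.window_cols %in% names(windows)))
    stop("window table must have columns: ",
         paste(.window_cols, collapse = ", "), call. = FALSE)
  if (nrow(windows) < 2)
    stop("integrate_pmf: need at least 2 windows", call. = FALSE)
  if (anyDuplicated(windows$R_o))
    stop("integrate_pmf: duplicated window distances", call. = FALSE)
  if (is.unsorted(rev(windows$R_o), strictly = TRUE))
    stop("integrate_pmf: windows must be sorted by decreasing R_o", call. = FALSE)
  invisible(windows)
}

#' Integrate a free-energy profile from mean restraint forces
#'
#' Reconstructs the potential of mean force along the centroid-centroid
#' distance R from per-window mean restraint forces:
#' F(R') = -integral from R_o' to R' of <f> dR''  - 2 k_B T ln(R'/R_o')
#' + F(R_o'), where R_o' is the outermost (largest) window, taken as the
#' reference. The quadrature is the composite trapezoid rule on the window
#' grid; the logarithmic term is the Jacobian correction for the growth of
#' configuration space with R and can be switched off.
#'
#' @param windows A window table (see [restraint_windows()]) sorted by
#'   decreasing `R_o` with unique distances.
#' @param temperature Temperature in K.
#' @param reference_value F at the reference (outermost) distance, kcal/mol.
#' @param jacobian Include the -2 k_B T ln(R/R_o') term (default TRUE).
#' @return An object of class `pmf_profile`: a data.frame with columns `R`
#'   (Angstrom, decreasing) and `F` (kcal/mol), with attributes
#'   `reference_distance` and `reference_value`.
#' @export
integrate_pmf <- function(windows, temperature = 298.15, reference_value = 0,
                          jacobian = TRUE) {
  .check_windows(windows)
  R <- windows$R_o
  f <- windows$mean_force
  quad <- -as.numeric(pracma::cumtrapz(R, f))
  kBT <- physical_constants()$gas * temperature /
    physical_constants()$joules_per_kcal
  jac <- if (jacobian) -2 * kBT * log(R / R[1]) else 0
  prof <- data.frame(R = R, F = quad + jac + reference_value)
  attr(prof, "reference_distance") <- R[1]
  attr(prof, "reference_value") <- reference_value
  attr(prof, "temperature") <- temperature
  class(prof) <- c("pmf_profile", "data.frame")
  prof
}

#' Average replicate profiles with confidence intervals
#'
#' Per-distance mean over replicate profiles with a two-sided Student-t
#' confidence interval across replicates.
#'
#' @param profiles A list of `pmf_profile` objects sharing one distance grid.
#' @param level Confidence level (default 0.95).
#' @return A `pmf_profile` data.frame with columns `R`, `F` (mean),
#'   `ci_half_width`, and `n` (replicates). With a single replicate the CI is
#'   `NA` and attribute `ci_defined` is FALSE.
#' @export
aggregate_replicates <- function(profiles, level = 0.95) {
  stopifnot(is.list(profiles), length(profiles) >= 1)
  R <- profiles[[1]]$R
  for (p in profiles) {
    if (length(p$R) != length(R) || any(abs(p$R - R) > 1e-9))
      stop("aggregate_replicates: profiles are on different distance grids",
           call. = FALSE)
  }
  n <- length(profiles)
  Fm <- sapply(profiles, function(p) p$F)
  if (is.null(dim(Fm))) Fm <- matrix(Fm, nrow = 1)
  mean_F <- rowMeans(Fm)
  if (n >= 2) {
    sd_F <- apply(Fm, 1, stats::sd)
    hw <- stats::qt((1 + level) / 2, df = n - 1) * sd_F / sqrt(n)
    ci_defined <- TRUE
  } else {
    hw <- rep(NA_real_, length(R))
    ci_defined <- FALSE
  }
  out <- data.frame(R = R, F = mean_F, ci_half_width = hw, n = n)
  attr(out, "level") <- level
  attr(out, "ci_defined") <- ci_defined
  class(out) <- c("pmf_profile", "data.frame")
  out
}

#' Extract the binding free energy from a PMF profile
#'
#' The well depth is measured relative to the unbound plateau:
#' Delta G = F(global minimum) - mean(F) over all points with
#' R >= `plateau_min`. The well width is the contiguous span of distances
#' around the minimum where F stays below the plateau mean.
#'
#' @param profile A `pmf_profile`.
#' @param plateau_min Smallest distance counted as plateau (default 17.5 A).
#' @return A list: `dG` (kcal/mol), `R_min` (location of the minimum, A),
#'   `well_width` (A), `plateau_mean`, and `no_well` (TRUE when dG >= 0).
#' @export
extract_binding_energy <- function(profile, plateau_min = 17.5) {
  stopifnot(inherits(profile, "pmf_profile"))
  plateau <- profile$F[profile$R >= plateau_min]
  if (length(plateau) == 0)
    stop("extract_binding_energy: no profile points in the plateau region (R >= ",
         plateau_min, " A)", call. = FALSE)
  pm <- mean(plateau)
  i_min <- which.min(profile$F)
  dG <- profile$F[i_min] - pm
  below <- profile$F < pm
  # contiguous run of below-plateau points containing the minimum
  if (below[i_min]) {
    lo <- i_min
    while (lo > 1 && below[lo - 1]) lo <- lo - 1
    hi <- i_min
    while (hi < length(below) && below[hi + 1]) hi <- hi + 1
    well_width <- abs(profile$R[lo] - profile$R[hi])
  } else {
    well_width <- 0
  }
  list(dG = dG, R_min = profile$R[i_min], well_width = well_width,
       plateau_mean = pm, no_well = dG >= 0)
}

# analytic potentials for the synthetic generator; each returns -dV/dR
.synth_force <- function(potential, params) {
  switch(potential,
    flat = function(R) rep(0, length(R)),
    harmonic = {
      c0 <- if (!is.null(params$k)) params$k else 1
      R0 <- if (!is.null(params$center)) params$center else 8.5
      function(R) -c0 * (R - R0)           # V = 1/2 c (R - R0)^2
    },
    gaussian = {
      depth <- if (!is.null(params$depth)) params$depth else 2.394
      R0 <- if (!is.null(params$center)) params$center else 8.5
      width <- if (!is.null(params$width)) params$width else 2
      # V = -depth exp(-(R-R0)^2 / (2 width^2))
      function(R) -depth * (R - R0) / width^2 * exp(-(R - R0)^2 / (2 * width^2))
    },
    stop("synth_window_forces: unknown potential '", potential, "'",
         call. = FALSE)
  )
}

#' Generate synthetic restrained-window mean forces
#'
#' Emulates the restrained-window protocol for a known analytic potential:
#' per window, the mean restraint force is -dV/dR at the window distance plus
#' Gaussian noise. This stands in for a molecular-dynamics engine so the
#' integration and aggregation machinery can be exercised against known
#' ground truth.
#'
#' @param potential `"harmonic"` (V = 1/2 k (R - center)^2), `"gaussian"`
#'   (well of given `depth` and `width` at `center`) or `"flat"`.
#' @param schedule A [window_schedule()].
#' @param noise_sd Gaussian noise standard deviation, kcal mol^-1 A^-1.
#' @param n_replicates Number of replicate window series.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param params Named list of potential parameters (`k`, `center`, `depth`,
#'   `width`).
#' @param K_r Force constant recorded in the window table.
#' @return A list of `n_replicates` window tables (see
#'   [restraint_windows()]).
#' @export
synth_window_forces <- function(potential = c("harmonic", "gaussian", "flat"),
                                schedule = window_schedule(), noise_sd = 0,
                                n_replicates = 1, seed = 1,
                                params = list(), K_r = 100) {
  potential <- match.arg(potential)
  if (noise_sd < 0)
    stop("synth_window_forces: noise_sd must be non-negative", call. = FALSE)
  plan <- plan_schedule(schedule)
  force_fn <- .synth_force(potential, params)
  base <- force_fn(plan$distances)
  set.seed(seed)
  lapply(seq_len(n_replicates), function(rep) {
    noise <- if (noise_sd > 0) stats::rnorm(plan$n_windows, 0, noise_sd) else 0
    restraint_windows(R_o = plan$distances, mean_force = base + noise,
                      K_r = K_r, replicate = rep,
                      n_samples = schedule$production_time)
  })
}

#' Read and write restrained-window tables
#'
#' Window tables are stored as comma-separated text with a header row and
#' columns `replicate, R_o, K_r, mean_force, n_samples` ('.' decimal mark).
#'
#' @param path File path.
#' @param windows A window table.
#' @return `read_restraint_windows` returns the validated data.frame;
#'   `write_restraint_windows` returns `path` invisibly.
#' @export
read_restraint_windows <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.window_cols, names(df))
  if (length(missing))
    stop("window file ", path, " is missing required columns: ",
         paste(missing, collapse = ", "),
         " (required header: ", paste(.window_cols, collapse = ","), ")",
         call. = FALSE)
  df[, .window_cols]
}

#' @rdname read_restraint_windows
#' @export
write_restraint_windows <- function(windows, path) {
  if (!all(.window_cols %in% names(windows)))
    stop("write_restraint_windows: malformed window table", call. = FALSE)
  utils::write.csv(windows[, .window_cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a PMF profile as comma-separated text
#'
#' @param profile A `pmf_profile`.
#' @param path File path.
#' @export
write_pmf_profile <- function(profile, path) {
  stopifnot(inherits(profile, "pmf_profile"))
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
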