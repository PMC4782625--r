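#' Coarse-grained fondaparinux model
#'
#' Fondaparinux is represented by its net charge (-10 elementary units at
#' physiological pH) and a rod geometry. The charge layout is either a single
#' lumped point charge at the approach position (default) or ten -1 charges
#' spaced evenly along the rod axis tangent to the polymer surface.
#'
#' @param net_charge Net charge in elementary units (default -10).
#' @param rod A [rod_geometry()].
#' @param charge_layout `"lumped"` or `"distributed"`.
#' @return An object of class `fondaparinux_model`.
#' @export
fondaparinux_model <- function(net_charge = -10, rod = rod_geometry(),
                               charge_layout = c("lumped", "distributed")) {
  charge_layout <- match.arg(charge_layout)
  stopifnot(inherits(rod, "rod_geometry"))
  structure(list(net_charge = net_charge, rod = rod,
                 charge_layout = charge_layout),
            class = "fondaparinux_model")
}

# charge_set for a fondaparinux approaching radially above `seed_pos` (a point
# on the sphere surface) at distance `a`; for the distributed layout the rod
# lies tangent to the sphere through the approach point.
.fondaparinux_charges <- function(fx, seed_pos, a) {
  u <- seed_pos / sqrt(sum(seed_pos^2))
  center <- seed_pos + a * u
  if (fx$charge_layout == "lumped") {
    return(charge_set(matrix(center, ncol = 3), fx$net_charge,
                      label = "fondaparinux"))
  }
  # tangent direction: any unit vector orthogonal to u (deterministic choice)
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- ref - sum(ref * u) * u
  t1 <- t1 / sqrt(sum(t1^2))
  n_q <- 10
  s <- seq(-fx$rod$l, fx$rod$l, length.out = n_q)
  pos <- t(vapply(s, function(si) center + si * t1, numeric(3)))
  charge_set(pos, rep(fx$net_charge / n_q, n_q), label = "fondaparinux")
}

#' Identify binding sites on a scaffold
#'
#' A binding site is three or more binding groups lying close enough together
#' that one fondaparinux molecule can come within the approach distance of
#' all of them. This is realized as greedy disjoint clustering: groups are
#' visited in placement order; a not-yet-assigned group seeds a candidate
#' consisting of itself plus every not-yet-assigned group within
#' `capture_radius` (Euclidean); candidates with at least three members
#' become sites and their members are consumed.
#'
#' @param scaffold A [place_groups()] scaffold.
#' @param capture_radius Capture radius in Angstrom around the seed group;
#'   defaults to the fondaparinux rod length 2l = 30 A (a rod contacting all
#'   members bounds their spread by its length).
#' @return A list of sites, each a list with `seed` (index), `members`
#'   (indices, including the seed), `location` (seed position) and
#'   `capture_radius`. Empty list when fewer than 3 groups exist or no
#'   cluster is large enough.
#' @export
find_binding_sites <- function(scaffold, capture_radius = 30) {
  stopifnot(inherits(scaffold, "polymer_scaffold"))
  n <- nrow(scaffold$positions)
  if (n < 3) return(list())
  d <- as.matrix(stats::dist(scaffold$positions))
  assigned <- rep(FALSE, n)
  sites <- list()
  for (i in seq_len(n)) {
    if (assigned[i]) next
    members <- which(!assigned & d[i, ] <= capture_radius)
    members <- sort(unique(c(i, members)))
    if (length(members) >= 3) {
      assigned[members] <- TRUE
      sites[[length(sites) + 1]] <- list(
        seed = i, members = members,
        location = scaffold$positions[i, ],
        capture_radius = capture_radius)
    }
  }
  sites
}

#' Sequential fondaparinux binding with charge bookkeeping
#'
#' Processes binding sites in seed order. For each binding event a
#' fondaparinux molecule approaches radially above the seed group to the
#' minimal approach distance `a`; the screened interaction energy Delta U
#' between the incoming fondaparinux and the current polymer charge state
#' (remaining free groups plus previously lumped sites) is computed, along
#' with the event's association rate constant.
#'
#' Under the refined criterion (`variant = "refined"`, a = 8.5 A) every site
#' binds; the bound fondaparinux and the site's member groups are replaced by
#' a single lumped charge (net fondaparinux charge plus the sum of the member
#' effective charges) at the seed location, so unneutralized fondaparinux
#' charge remains part of the system (system neutralization). Under the
#' simplified criterion (`variant = "simplified"`, a = 6 A) a site binds only
#' if its member effective charges sum to at least `neutralization_threshold`
#' (almost complete neutralization of the -10 fondaparinux); the neutralized
#' complex is then removed and leaves no residual charge.
#'
#' @param scaffold A [place_groups()] scaffold.
#' @param sites Sites from [find_binding_sites()].
#' @param fondaparinux A [fondaparinux_model()].
#' @param variant `"refined"` or `"simplified"`.
#' @param cond A [solution_conditions()].
#' @param a Minimal approach distance in Angstrom; defaults to 8.5 (refined)
#'   or 6 (simplified).
#' @param neutralization_threshold Minimum summed member effective charge for
#'   a simplified-criterion site to bind (default +9).
#' @return An object of class `complex_state`: `scaffold`, `variant`, `a`,
#'   `events` (data.frame with site, seed, n_members, site_charge, dU, ka),
#'   `bound_count`, `free_indices`, `lumped` (data.frame seed, x, y, z,
#'   charge), `total_charge`.
#' @export
bind_sequential <- function(scaffold, sites, fondaparinux = fondaparinux_model(),
                            variant = c("refined", "simplified"),
                            cond = solution_conditions(), a = NULL,
                            neutralization_threshold = 9) {
  variant <- match.arg(variant)
  stopifnot(inherits(scaffold, "polymer_scaffold"),
            inherits(fondaparinux, "fondaparinux_model"),
            inherits(cond, "solution_conditions"))
  if (is.null(a)) a <- if (variant == "refined") 8.5 else 6
  if (a <= 0)
    stop("bind_sequential: approach distance must be positive", call. = FALSE)

  q_eff <- scaffold$group$effective_charge
  n <- nrow(scaffold$positions)
  free <- rep(TRUE, n)
  lumped <- data.frame(seed = integer(0), x = numeric(0), y = numeric(0),
                       z = numeric(0), charge = numeric(0))
  events <- data.frame(site = integer(0), seed = integer(0),
                       n_members = integer(0), site_charge = numeric(0),
                       dU = numeric(0), ka = numeric(0))

  # basal rate from sphere (r_H) and rod hydrodynamics
  D_A <- diffusion_constant(scaffold$r_H, cond)
  D_B <- diffusion_constant(fondaparinux$rod$hydrodynamic_radius, cond)
  ka0 <- basal_rate(D_A, D_B, interaction_radius(fondaparinux$rod))

  for (s_idx in seq_along(sites)) {
    site <- sites[[s_idx]]
    member_charge <- length(site$members) * q_eff
    if (variant == "simplified" && member_charge < neutralization_threshold)
      next
    # current polymer charge state
    idx <- which(free)
    pos <- scaffold$positions[idx, , drop = FALSE]
    q <- rep(q_eff, length(idx))
    if (nrow(lumped)) {
      pos <- rbind(pos, as.matrix(lumped[, c("x", "y", "z")]))
      q <- c(q, lumped$charge)
    }
    polymer_cs <- charge_set(pos, q, label = "polymer")
    fx_cs <- .fondaparinux_charges(fondaparinux, site$location, a)
    dU <- interaction_energy(fx_cs, polymer_cs, cond, a)
    ka <- association_rate(ka0, dU, cond, a)
    site_charge <- fondaparinux$net_charge + member_charge
    events <- rbind(events, data.frame(
      site = s_idx, seed = site$seed, n_members = length(site$members),
      site_charge = site_charge, dU = dU, ka = ka))
    free[site$members] <- FALSE
    if (variant == "refined") {
      lumped <- rbind(lumped, data.frame(
        seed = site$seed, x = site$location[1], y = site$location[2],
        z = site$location[3], charge = site_charge))
    }
  }

  total_charge <- sum(free) * q_eff + sum(lumped$charge)
  structure(list(scaffold = scaffold, variant = variant, a = a,
                 ka0 = ka0, events = events, bound_count = nrow(events),
                 free_indices = which(free), lumped = lumped,
                 total_charge = total_charge),
            class = "complex_state")
}

#' Per-polymer association rate constant
#'
#' The association rate constant reported for a polymer is that of its first
#' binding event, computed through the Schreiber relation on top of the
#' sphere-rod Smoluchowski basal rate. A polymer with no binding event
#' returns exactly 1 (the no-binding sentinel, which keeps geometric means
#' over mixed ensembles well defined).
#'
#' @param state A [bind_sequential()] complex state.
#' @param cond A [solution_conditions()].
#' @param rod A [rod_geometry()]; defaults to the rod used at binding time.
#' @param sphere A [sphere_geometry()]; defaults to the scaffold sphere.
#' @param a Minimal approach distance; defaults to the state's value.
#' @return k_a in M^-1 s^-1, or exactly 1 when nothing bound.
#' @export
polymer_ka <- function(state, cond = solution_conditions(), rod = NULL,
                       sphere = NULL, a = NULL) {
  stopifnot(inherits(state, "complex_state"))
  if (state$bound_count == 0) return(1)
  if (is.null(a)) a <- state$a
  ka0 <- if (is.null(rod) && is.null(sphere)) {
    state$ka0
  } else {
    r_sph <- if (is.null(sphere)) state$scaffold$r_H else sphere$r_H
    rd <- if (is.null(rod)) stop("polymer_ka: supply rod with sphere", call. = FALSE) else rod
    basal_rate(diffusion_constant(r_sph, cond),
               diffusion_constant(rd$hydrodynamic_radius, cond),
               interaction_radius(rd))
  }
  association_rate(ka0, state$events$dU[1], cond, a)
}
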