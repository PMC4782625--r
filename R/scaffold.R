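# deterministic per-replicate seed derived from a master seed; kept < 2^31-1.
# Products stay below 2^53 so double arithmetic is exact.
.derive_seed <- function(master, index) {
  m <- 2147483647
  s <- (as.numeric(master) %% m)
  s <- (s * 48271 + 12345) %% m
  s <- (s + as.numeric(index) * 2654435) %% m
  s <- (s * 16807 + 1) %% m
  as.integer(s)
}

# necessary spherical-cap packing bound: n caps of angular radius theta/2,
# theta = central angle subtending a chord of r_min
.packing_feasible <- function(n, r_H, r_min) {
  if (n <= 1) return(TRUE)
  x <- r_min / (2 * r_H)
  if (x > 1) return(FALSE)           # r_min exceeds the sphere diameter
  theta <- 2 * asin(x)
  n * (1 - cos(theta / 2)) / 2 <= 1
}

# n points uniform on a sphere of radius r (rows of an n x 3 matrix)
.runif_sphere <- function(n, r) {
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  r * m / sqrt(rowSums(m^2))
}

#' Place binding groups randomly on a spherical scaffold
#'
#' Samples `n` points uniformly on the surface of a sphere of radius `r_H`,
#' conditional on every pairwise Euclidean distance being at least `r_min`
#' (rejection sampling). `r_min` stands in for inter-group electrostatic
#' repulsion and sterics; the default 9.16 A exceeds the radii of the R4-1
#' and R6-1 groups.
#'
#' @param n Number of binding groups (>= 1).
#' @param r_H Sphere radius in Angstrom.
#' @param r_min Minimum pairwise distance in Angstrom.
#' @param seed Integer seed for reproducible placement; `NULL` uses the
#'   current RNG state.
#' @param group A [binding_group()] attached to the scaffold.
#' @param max_attempts Rejection attempts per group before restarting.
#' @param max_restarts Full restarts before giving up.
#' @return An object of class `polymer_scaffold`: `positions` (n x 3 matrix,
#'   Angstrom), `r_H`, `r_min`, `group`.
#' @export
place_groups <- function(n, r_H, r_min = 9.16, seed = NULL,
                         group = binding_group("R4-1"),
                         max_attempts = 1e4, max_restarts = 100) {
  if (n < 1) stop("place_groups: need n >= 1", call. = FALSE)
  if (r_H <= 0 || r_min < 0)
    stop("place_groups: invalid geometry", call. = FALSE)
  if (!.packing_feasible(n, r_H, r_min))
    stop(sprintf(
      "place_groups: infeasible packing (area bound violated) for n = %d, r_H = %g A, r_min = %g A",
      n, r_H, r_min), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  for (restart in seq_len(max_restarts)) {
    pos <- matrix(NA_real_, nrow = n, ncol = 3)
    pos[1, ] <- .runif_sphere(1, r_H)
    k <- 1
    failed <- FALSE
    while (k < n) {
      placed <- FALSE
      for (attempt in seq_len(max_attempts)) {
        cand <- .runif_sphere(1, r_H)
        d2 <- rowSums((pos[seq_len(k), , drop = FALSE] -
                         matrix(cand, nrow = k, ncol = 3, byrow = TRUE))^2)
        if (all(d2 >= r_min^2)) {
          k <- k + 1
          pos[k, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) { failed <- TRUE; break }
    }
    if (!failed) {
      return(structure(list(positions = pos, r_H = r_H, r_min = r_min,
                            group = group),
                       class = "polymer_scaffold"))
    }
  }
  stop(sprintf(
    "place_groups: attempt budget exhausted for n = %d, r_H = %g A, r_min = %g A",
    n, r_H, r_min), call. = FALSE)
}

#' @export
print.polymer_scaffold <- function(x, ...) {
  cat(sprintf("polymer_scaffold: %d x %s on r_H = %g A (r_min = %g A)\n",
              nrow(x$positions), x$group$name, x$r_H, x$r_min))
  invisible(x)
}

#' Serialize a scaffold (or complex state) as structured text
#'
#' One record per group or lumped site with columns
#' `index, x, y, z, charge, role` (role is `"group"` or `"site"`),
#' comma-separated with a header row.
#'
#' @param x A `polymer_scaffold` or `complex_state`.
#' @param path Output file path.
#' @export
write_scaffold <- function(x, path) {
  if (inherits(x, "polymer_scaffold")) {
    df <- data.frame(index = seq_len(nrow(x$positions)),
                     x = x$positions[, 1], y = x$positions[, 2],
                     z = x$positions[, 3],
                     charge = x$group$effective_charge, role = "group")
  } else if (inherits(x, "complex_state")) {
    sc <- x$scaffold
    free <- x$free_indices
    df_free <- if (length(free)) {
      data.frame(index = free, x = sc$positions[free, 1],
                 y = sc$positions[free, 2], z = sc$positions[free, 3],
                 charge = sc$group$effective_charge, role = "group")
    } else NULL
    df_site <- if (nrow(x$lumped)) {
      data.frame(index = x$lumped$seed, x = x$lumped$x, y = x$lumped$y,
                 z = x$lumped$z, charge = x$lumped$charge, role = "site")
    } else NULL
    df <- rbind(df_free, df_site)
  } else {
    stop("write_scaffold: unsupported object", call. = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a serialized scaffold record table
#'
#' @param path File path written by [write_scaffold()].
#' @return A data.frame with columns index, x, y, z, charge, role.
#' @export
read_scaffold <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("index", "x", "y", "z", "charge", "role")
  if (!all(need %in% names(df)))
    stop("read_scaffold: missing columns in ", path, call. = FALSE)
  df[, need]
}
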