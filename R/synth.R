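# Synthetic ensembles with the statistical structure the analyses assume:
# Boltzmann samples on a tabulated 1D potential, linearly tilted water-number
# distributions (with an optional dewetted basin), harmonic umbrella windows
# on a known PMF, rigid 3-site water boxes with planted hydrogen bonds, and
# 2D density grids with planted dry patches. Everything is deterministic
# under a fixed seed and records that seed in its output.

#' Tabulated 1D potential / potential of mean force
#'
#' @param z Grid in nm, strictly increasing.
#' @param value Potential values in kcal/mol, finite.
#' @return A `potential_spec` with linear interpolation between grid points;
#'   outside the grid the potential is infinite (hard walls).
#' @export
potential_spec <- function(z, value) {
  if (length(z) != length(value) || length(z) < 2) {
    abort("`z` and `value` must be equal-length vectors (>= 2 points).")
  }
  if (any(diff(z) <= 0)) abort("`z` must be strictly increasing.")
  if (!all(is.finite(value))) abort("Potential values must be finite on the grid.")
  structure(list(z = as.numeric(z), value = as.numeric(value)),
            class = "potential_spec")
}

#' Evaluate a tabulated potential
#' @param potential A [potential_spec()].
#' @param z Positions (nm); outside the tabulated range the value is `Inf`.
#' @return Potential values in kcal/mol.
#' @export
potential_energy <- function(potential, z) {
  u <- approx(potential$z, potential$value, xout = z, rule = 1)$y
  u[is.na(u)] <- Inf
  u
}

#' Benchmark double-well potential of mean force
#'
#' A smooth analytic double-well along a surface-separation coordinate:
#' wells of about -3 kcal/mol at z = 1.0 nm and -1 kcal/mol at z = 2.0 nm,
#' a ~2 kcal/mol barrier between them, a repulsive wall at small z, and a
#' flat bulk plateau at 0 beyond ~2.6 nm. Tabulated on a fine grid so it can
#' serve as a ground truth for umbrella sampling and PMF reconstruction.
#'
#' @param z_min,z_max,dz Tabulation grid (nm).
#' @return A [potential_spec()].
#' @export
double_well_potential <- function(z_min = 0.55, z_max = 3.6, dz = 0.002) {
  z <- seq(z_min, z_max, by = dz)
  w <- -3 * exp(-(z - 1.0)^2 / (2 * 0.12^2)) +
        2 * exp(-(z - 1.5)^2 / (2 * 0.15^2)) -
        1 * exp(-(z - 2.0)^2 / (2 * 0.12^2)) +
        8 * exp(-(z - z_min) / 0.05)
  potential_spec(z, w)
}

# adaptive random-walk Metropolis on a vector of chains sharing a potential
# function; returns matrix (n_steps x n_chains). energy_fn must be vectorized.
.metropolis <- function(energy_fn, x0, n, beta, step, n_burn = 2000L,
                        thin = 1L) {
  nc <- length(x0)
  x <- x0
  e <- energy_fn(x)
  if (any(!is.finite(e))) abort("Initial states have non-finite energy.")
  step <- rep_len(step, nc)
  acc <- numeric(nc)
  # burn-in with step adaptation toward ~45% acceptance
  for (t in seq_len(n_burn)) {
    xp <- x + runif(nc, -1, 1) * step
    ep <- energy_fn(xp)
    ok <- log(runif(nc)) < -beta * (ep - e)
    ok[!is.finite(ep) & ep > 0] <- FALSE
    x[ok] <- xp[ok]; e[ok] <- ep[ok]
    acc <- acc + ok
    if (t %% 100L == 0L) {
      rate <- acc / 100
      step <- step * exp(rate - 0.45)
      acc <- numeric(nc)
    }
  }
  out <- matrix(NA_real_, n, nc)
  for (t in seq_len(n * thin)) {
    xp <- x + runif(nc, -1, 1) * step
    ep <- energy_fn(xp)
    ok <- log(runif(nc)) < -beta * (ep - e)
    ok[!is.finite(ep) & ep > 0] <- FALSE
    x[ok] <- xp[ok]; e[ok] <- ep[ok]
    if (t %% thin == 0L) out[t %/% thin, ] <- x
  }
  out
}

#' Sample a 1D Boltzmann distribution
#'
#' Random-walk Metropolis on a tabulated potential, with the proposal step
#' tuned during burn-in toward a 30-60% acceptance rate. Samples are
#' distributed proportional to exp(-beta U(z)).
#'
#' @param potential A [potential_spec()].
#' @param n Number of samples.
#' @param seed Integer seed; the same seed yields an identical stream.
#' @param beta Inverse thermal energy in mol/kcal (default 1/RT at 298.15 K).
#' @param n_burn Burn-in steps (discarded).
#' @param thin Decorrelation stride: one sample is recorded every `thin`
#'   accepted-or-rejected steps (default 10, near-independent draws).
#' @return Tibble with columns `sample` (index) and `z` (nm); attribute
#'   `seed` records the seed.
#' @export
sample_boltzmann_1d <- function(potential, n, seed,
                                beta = 1 / thermal_energy(), n_burn = 2000L,
                                thin = 10L) {
  stopifnot(n >= 1, beta > 0)
  if (!all(is.finite(potential$value))) abort("Potential must be finite on its grid.")
  set.seed(seed)
  x0 <- potential$z[which.min(potential$value)]
  zr <- diff(range(potential$z))
  s <- .metropolis(function(z) potential_energy(potential, z),
                   x0, n, beta, step = zr / 10, n_burn = n_burn, thin = thin)
  structure(tibble::tibble(sample = seq_len(n), z = s[, 1]), seed = seed)
}

#' Water-number fluctuation model
#'
#' A discrete model of the unbiased water-number distribution P0(N) in a probe
#' volume: a Gaussian basin at `mean_N0` with variance `var_N`, optionally
#' mixed with a second (dewetted) basin at a lower mean, offset by a free
#' energy `basin2_offset_kT` (in kT) that plays the role of the barrier to
#' dewetting at zero bias.
#'
#' @param mean_N0 Mean water count at zero bias (> 0).
#' @param var_N Variance at zero bias (> 0).
#' @param basin2_mean,basin2_var,basin2_offset_kT Optional dewetted basin.
#' @return A `number_fluctuation_model`.
#' @export
number_fluctuation_model <- function(mean_N0, var_N, basin2_mean = NULL,
                                     basin2_var = NULL, basin2_offset_kT = NULL) {
  stopifnot(mean_N0 > 0, var_N > 0)
  two <- !is.null(basin2_mean)
  if (two) stopifnot(basin2_var > 0)
  structure(list(mean_N0 = mean_N0, var_N = var_N,
                 basin2_mean = basin2_mean, basin2_var = basin2_var,
                 basin2_offset_kT = basin2_offset_kT, two_basin = two),
            class = "number_fluctuation_model")
}

#' Exact tilted water-number distribution
#'
#' The discrete distribution P(N) proportional to P0(N) exp(-beta_phi * N)
#' under the linear bias Hamiltonian H = H0 + phi * N, computed exactly on
#' the integer grid. This is the closed-form reweighting oracle for the
#' sampled generators and the sparse-sampling estimator.
#'
#' @param model A [number_fluctuation_model()].
#' @param beta_phi Dimensionless bias strength (>= 0).
#' @return Tibble with columns `N` and `p` (normalized probability).
#' @export
tilted_number_pmf <- function(model, beta_phi = 0) {
  stopifnot(beta_phi >= 0)
  hi <- ceiling(model$mean_N0 + 8 * sqrt(model$var_N))
  N <- 0:hi
  logp0 <- -(N - model$mean_N0)^2 / (2 * model$var_N)
  if (model$two_basin) {
    logp2 <- -(N - model$basin2_mean)^2 / (2 * model$basin2_var) -
      model$basin2_offset_kT
    logp0 <- pmax(logp0, logp2) + log1p(exp(-abs(logp0 - logp2)))
  }
  lw <- logp0 - beta_phi * N
  lw <- lw - max(lw)
  p <- exp(lw); p <- p / sum(p)
  tibble::tibble(N = N, p = p)
}

#' Sample biased water numbers
#'
#' Draws integer water counts from the exactly computed tilted distribution
#' [tilted_number_pmf()]. For the single-Gaussian model far from the N = 0
#' boundary the sample mean is approximately `mean_N0 - beta_phi * var_N`
#' (Gaussian tilting identity).
#'
#' @param model A [number_fluctuation_model()].
#' @param beta_phi Dimensionless bias (>= 0).
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return Tibble with columns `sample` and `N`; attribute `seed`.
#' @export
sample_biased_number <- function(model, beta_phi, n, seed) {
  stopifnot(n >= 1, beta_phi >= 0)
  pmf <- tilted_number_pmf(model, beta_phi)
  set.seed(seed)
  structure(tibble::tibble(sample = seq_len(n),
                           N = sample(pmf$N, n, replace = TRUE, prob = pmf$p)),
            seed = seed)
}

#' Generate a set of biased water-number series
#'
#' Convenience wrapper producing the long table consumed by
#' [normalized_response()] and [sparse_sampling_free_energy()]: one series of
#' `n` samples for each value of `beta_phi`.
#'
#' @param model A [number_fluctuation_model()].
#' @param beta_phi Vector of dimensionless bias values (must include 0 for the
#'   downstream estimators).
#' @param n Samples per bias value.
#' @param seed Integer seed.
#' @param beta Inverse thermal energy mol/kcal (used to record `phi` in
#'   kcal/mol alongside `beta_phi`).
#' @return Tibble with columns `phi`, `beta_phi`, `sample`, `N`.
#' @export
generate_biased_series <- function(model, beta_phi, n, seed,
                                   beta = 1 / thermal_energy()) {
  purrr::map2_dfr(beta_phi, seed + seq_along(beta_phi) - 1L, function(bp, sd) {
    s <- sample_biased_number(model, bp, n, sd)
    tibble::tibble(phi = bp / beta, beta_phi = bp, sample = s$sample, N = s$N)
  })
}

#' Generate harmonic umbrella-window samples on a known PMF
#'
#' Window i is sampled proportional to exp(-beta [W(z) + k/2 (z - c_i)^2])
#' by adaptive Metropolis, all windows advanced in parallel.
#'
#' @param potential A [potential_spec()] holding the ground-truth W(z)
#'   (kcal/mol).
#' @param centers Sorted window centers, nm.
#' @param k Force constant in kcal/mol/nm^2 (use [kj_to_kcal()] for kJ input).
#' @param n_per_window Samples recorded per window (>= 1).
#' @param seed Integer seed.
#' @param beta Inverse thermal energy, mol/kcal.
#' @param n_burn Burn-in steps per window.
#' @param thin Decorrelation stride between recorded samples (default 10,
#'   giving effectively independent draws).
#' @return Tibble with columns `window`, `center`, `k`, `sample`, `z`;
#'   attribute `seed`. A warning is recorded if adjacent windows are spaced
#'   more than 4 thermal widths apart (WHAM will be ill-posed).
#' @export
generate_umbrella_windows <- function(potential, centers, k, n_per_window,
                                      seed, beta = 1 / thermal_energy(),
                                      n_burn = 2000L, thin = 10L) {
  if (n_per_window < 1) abort("`n_per_window` must be >= 1.")
  if (is.unsorted(centers, strictly = TRUE)) abort("`centers` must be sorted, strictly increasing.")
  stopifnot(k > 0, beta > 0)
  sd_w <- 1 / sqrt(beta * k)
  if (length(centers) > 1 && max(diff(centers)) > 4 * sd_w) {
    warn("Adjacent umbrella windows are > 4 thermal widths apart; WHAM may be ill-posed.")
  }
  set.seed(seed)
  efun <- function(z) {
    # z is a vector with one entry per window
    potential_energy(potential, z) + 0.5 * k * (z - centers)^2
  }
  # start each chain at its center, clamped to the tabulated range
  x0 <- pmin(pmax(centers, min(potential$z)), max(potential$z))
  s <- .metropolis(efun, x0, n_per_window, beta, step = 2.4 * sd_w,
                   n_burn = n_burn, thin = thin)
  out <- tidyr::expand_grid(sample = seq_len(n_per_window),
                            window = seq_along(centers)) |>
    dplyr::mutate(center = centers[.data$window], k = k,
                  z = s[cbind(.data$sample, .data$window)]) |>
    dplyr::arrange(.data$window, .data$sample) |>
    dplyr::select("window", "center", "k", "sample", "z")
  structure(out, seed = seed)
}

# random rotation matrix (uniform over SO(3)) from a unit quaternion
.random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# rigid 3-site water in its local frame: O at origin, H's in the xz plane
.water_template <- function() {
  d_oh <- 0.09572; half <- 104.52 / 2 * pi / 180
  rbind(O = c(0, 0, 0),
        H1 = d_oh * c(sin(half), 0, cos(half)),
        H2 = d_oh * c(-sin(half), 0, cos(half)))
}

#' Generate a rigid 3-site water box with planted hydrogen bonds
#'
#' Waters use the standard rigid 3-site geometry (O-H 0.09572 nm, H-O-H
#' 104.52 deg). Planted donor-acceptor pairs realize their requested
#' donor-acceptor distance and D-H-A angle exactly; pairs are laid out on a
#' coarse grid so planted geometries are not confounded by periodic images.
#' Remaining waters get random positions and orientations.
#'
#' @param n_waters Total number of waters (>= 2 * number of planted pairs).
#' @param box Length-3 periodic box, nm.
#' @param planted_pairs Tibble/data frame with columns `distance` (donor
#'   O to acceptor O, nm) and `angle` (D-H-A, degrees); NULL for none.
#' @param seed Integer seed.
#' @return Tibble with one row per water: `molecule`, `ox,oy,oz`,
#'   `h1x,h1y,h1z`, `h2x,h2y,h2z` (nm) and `planted_role`
#'   ("donor", "acceptor" or NA); attribute `seed`.
#' @export
generate_water_box <- function(n_waters, box, planted_pairs = NULL, seed = 1) {
  stopifnot(n_waters >= 0, length(box) == 3, all(box > 0))
  set.seed(seed)
  np <- if (is.null(planted_pairs)) 0L else nrow(planted_pairs)
  if (2L * np > n_waters) abort("Not enough waters to host the planted pairs.")
  tmpl <- .water_template()
  rows <- list()
  if (np > 0) {
    # lay planted pairs on a coarse grid of exclusive slots so their
    # geometry is never confounded by periodic images
    margin <- max(planted_pairs$distance) + 0.25
    nslot <- pmax(1L, floor(box / (2 * margin)))
    if (any(box < 2 * margin)) abort("Planting infeasible: box too small for the requested pairs.")
    slots <- tidyr::expand_grid(gx = seq_len(nslot[1]), gy = seq_len(nslot[2]),
                                gz = seq_len(nslot[3]))
    if (nrow(slots) < np) abort("Planting infeasible: box too small for the requested pairs.")
    for (p in seq_len(np)) {
      d <- planted_pairs$distance[p]
      th <- planted_pairs$angle[p] * pi / 180
      # donor O at origin, its H1 along +x; acceptor O in the xy plane such
      # that |D-A| = d and the D-H-A angle is th
      d_oh <- 0.09572
      wdir <- c(-cos(th), sin(th), 0)       # unit vector from H toward A
      h <- c(d_oh, 0, 0)
      # |h + t*wdir| = d  ->  t^2 + 2 t (h.wdir) + |h|^2 - d^2 = 0
      b <- sum(h * wdir); cc <- d_oh^2 - d^2
      t <- -b + sqrt(b^2 - cc)
      acc_o <- h + t * wdir
      # donor water: O at origin with H1 = h; rotate template so its H1 lands on h
      don <- .orient_water(tmpl, h_target = h)
      # acceptor water: random orientation about its O
      R2 <- .random_rotation()
      accw <- sweep(tmpl %*% t(R2), 2, acc_o, "+")
      # place the pair rigidly at its grid slot with a random rotation
      Rp <- .random_rotation()
      origin <- c(slots$gx[p], slots$gy[p], slots$gz[p]) * 2 * margin - margin
      don_g <- sweep(don %*% t(Rp), 2, origin, "+")
      acc_g <- sweep(accw %*% t(Rp), 2, origin, "+")
      rows[[length(rows) + 1L]] <- .water_row(don_g, "donor")
      rows[[length(rows) + 1L]] <- .water_row(acc_g, "acceptor")
    }
  }
  n_rand <- n_waters - 2L * np
  for (i in seq_len(n_rand)) {
    R <- .random_rotation()
    o <- runif(3) * box
    w <- sweep(tmpl %*% t(R), 2, o, "+")
    rows[[length(rows) + 1L]] <- .water_row(w, NA_character_)
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else .water_row(NULL, character())
  out <- dplyr::mutate(out, molecule = dplyr::row_number(), .before = 1)
  structure(out, seed = seed, box = box)
}

# rotate the rigid template so its first O-H bond points along h_target
.orient_water <- function(tmpl, h_target) {
  u <- tmpl["H1", ] / sqrt(sum(tmpl["H1", ]^2))
  v <- h_target / sqrt(sum(h_target^2))
  w <- .cross3(u, v); s <- sqrt(sum(w^2)); c <- sum(u * v)
  R <- if (s < 1e-12) diag(3) * sign(c) else {
    K <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0), 3, 3, byrow = TRUE)
    diag(3) + K + K %*% K * ((1 - c) / s^2)
  }
  tmpl %*% t(R)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

.water_row <- function(w, role) {
  if (is.null(w)) {
    return(tibble::tibble(ox = numeric(), oy = numeric(), oz = numeric(),
                          h1x = numeric(), h1y = numeric(), h1z = numeric(),
                          h2x = numeric(), h2y = numeric(), h2z = numeric(),
                          planted_role = character()))
  }
  tibble::tibble(ox = w[1, 1], oy = w[1, 2], oz = w[1, 3],
                 h1x = w[2, 1], h1y = w[2, 2], h1z = w[2, 3],
                 h2x = w[3, 1], h2y = w[3, 2], h2z = w[3, 3],
                 planted_role = role)
}

#' Generate a 2D density grid with planted dry patches
#'
#' @param shape Length-2 integer: cells along x and y.
#' @param cell_size Cell edge, nm.
#' @param bulk_density Background density, molecules/nm^3.
#' @param dry_patches Tibble/data frame with columns `cx`, `cy` (centers, nm)
#'   and `radius` (nm); cells whose centers fall inside a patch get density 0.
#' @return A `density_map_2d` tibble (`x`, `y`, `density`) with attributes
#'   `cell_size`, `threshold` (default 5 molecules/nm^3) and `shape`.
#' @export
generate_density_grid <- function(shape, cell_size, bulk_density,
                                  dry_patches = NULL) {
  stopifnot(length(shape) == 2, all(shape >= 1), cell_size > 0, bulk_density >= 0)
  lx <- shape[1] * cell_size; ly <- shape[2] * cell_size
  if (!is.null(dry_patches) && any(dry_patches$radius >= min(lx, ly) / 2)) {
    abort("Patch radius must be below half the smaller grid dimension.")
  }
  g <- tidyr::expand_grid(ix = seq_len(shape[1]) - 1L, iy = seq_len(shape[2]) - 1L) |>
    dplyr::mutate(x = (.data$ix + 0.5) * cell_size,
                  y = (.data$iy + 0.5) * cell_size,
                  density = bulk_density)
  if (!is.null(dry_patches)) {
    for (p in seq_len(nrow(dry_patches))) {
      inside <- (g$x - dry_patches$cx[p])^2 + (g$y - dry_patches$cy[p])^2 <=
        dry_patches$radius[p]^2
      g$density[inside] <- 0
    }
  }
  new_density_map(dplyr::select(g, "x", "y", "density"),
                  cell_size = cell_size, shape = as.integer(shape))
}
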