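# Coarse-grained water number over a union-of-spheres probe volume, linear
# bias energetics with analytic forces, and the sparse-sampling free energy
# of dewetting.
#
# The per-sphere smoothed indicator is the exact 3D convolution of the sharp
# sphere indicator with a truncated, shifted, renormalized Gaussian kernel
# phi(s) = A [exp(-s^2/2 sigma^2) - exp(-r_c^2/2 sigma^2)] for s <= r_c.
# For a water at distance d from the sphere center the angular integral is
# carried out analytically, leaving erf/exp antiderivatives in s.

#' Coarse-graining parameters for the smoothed indicator
#'
#' @param sigma Gaussian width, nm (default 0.01). `sigma = 0` selects the
#'   sharp (Heaviside) indicator, i.e. an exact count.
#' @param r_c Kernel truncation length, nm (default 0.02); must be >= sigma.
#' @return A `coarse_grain_params` list.
#' @export
coarse_grain_params <- function(sigma = 0.01, r_c = 0.02) {
  if (sigma < 0 || r_c <= 0) abort("Require sigma >= 0 and r_c > 0.")
  if (sigma > 0 && r_c < sigma) abort("Require r_c >= sigma.")
  structure(list(sigma = sigma, r_c = r_c), class = "coarse_grain_params")
}

#' Union-of-spheres probe volume
#'
#' @param centers Matrix or data frame of sphere centers (n x 3), nm.
#' @param R_v Sphere radius, nm (default 0.6).
#' @return A `probe_volume` list.
#' @export
probe_volume <- function(centers, R_v = 0.6) {
  centers <- as.matrix(centers)
  if (nrow(centers) < 1 || ncol(centers) != 3) abort("`centers` must be n x 3 with n >= 1.")
  if (R_v <= 0) abort("`R_v` must be positive.")
  storage.mode(centers) <- "double"
  structure(list(centers = centers, R_v = R_v), class = "probe_volume")
}

# Gaussian moment antiderivatives over [a, b]:
#   G1 = int s   exp(-s^2/2s2) ds,  G2 = int s^2 ..., G3 = int s^3 ...
.g0 <- function(a, b, sg) sg * sqrt(pi / 2) * (erf_(b / (sg * sqrt(2))) - erf_(a / (sg * sqrt(2))))
.g1 <- function(a, b, sg) sg^2 * (exp(-a^2 / (2 * sg^2)) - exp(-b^2 / (2 * sg^2)))
.g2 <- function(a, b, sg) sg^2 * (a * exp(-a^2 / (2 * sg^2)) - b * exp(-b^2 / (2 * sg^2))) + sg^2 * .g0(a, b, sg)
.g3 <- function(a, b, sg) sg^2 * ((a^2 + 2 * sg^2) * exp(-a^2 / (2 * sg^2)) -
                                    (b^2 + 2 * sg^2) * exp(-b^2 / (2 * sg^2)))
erf_ <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# kernel normalization A: int_0^rc 4 pi s^2 phi(s) ds = 1
.kernel_A <- function(sigma, r_c) {
  E <- exp(-r_c^2 / (2 * sigma^2))
  1 / (4 * pi * (.g2(0, r_c, sigma) - E * r_c^3 / 3))
}

# smoothed indicator of one sphere of radius R at center distance d, and its
# radial derivative; vectorized over d. Returns list(h, dh).
.smooth_sphere <- function(d, R, sigma, r_c, deriv = FALSE) {
  h <- ifelse(d <= R - r_c, 1, 0)
  dh <- numeric(length(d))
  shell <- d > R - r_c & d < R + r_c
  if (any(shell)) {
    ds <- d[shell]
    A <- .kernel_A(sigma, r_c)
    E <- exp(-r_c^2 / (2 * sigma^2))
    s1 <- abs(R - ds)
    g1 <- .g1(s1, r_c, sigma); g2 <- .g2(s1, r_c, sigma); g3 <- .g3(s1, r_c, sigma)
    inner <- ifelse(ds < R, 4 * pi * A * (.g2(0, s1, sigma) - E * s1^3 / 3), 0)
    part <- 2 * pi * A * (
      g2 + (R^2 - ds^2) / (2 * ds) * g1 - g3 / (2 * ds) -
        E * ((r_c^3 - s1^3) / 3 +
               (R^2 - ds^2) / (2 * ds) * (r_c^2 - s1^2) / 2 -
               (r_c^4 - s1^4) / (8 * ds)))
    h[shell] <- pmin(pmax(inner + part, 0), 1)
    if (deriv) {
      dh[shell] <- 2 * pi * A * (
        -(R^2 + ds^2) / (2 * ds^2) * g1 + g3 / (2 * ds^2) -
          E * (-(R^2 + ds^2) / (2 * ds^2) * (r_c^2 - s1^2) / 2 +
                 (r_c^4 - s1^4) / (8 * ds^2)))
    }
  }
  list(h = h, dh = dh)
}

# minimum-image displacement matrix of points (n x 3) relative to one center
.min_image <- function(delta, box) {
  if (is.null(box)) return(delta)
  sweep_box <- matrix(box, nrow(delta), 3, byrow = TRUE)
  delta - sweep_box * round(delta / sweep_box)
}

.as_positions <- function(positions) {
  if (is.data.frame(positions)) {
    cols <- intersect(c("x", "y", "z"), names(positions))
    if (length(cols) == 3) positions <- positions[, c("x", "y", "z")]
    else positions <- positions[, intersect(c("ox", "oy", "oz"), names(positions))]
  }
  m <- as.matrix(positions)
  if (length(m) == 0) m <- matrix(numeric(), 0, 3)
  if (ncol(m) != 3) abort("Positions must be n x 3 (columns x, y, z).")
  storage.mode(m) <- "double"
  m
}

# per-water smoothed union indicator h in [0,1]; optionally also the gradient
# of h with respect to each water position (n x 3)
.union_indicator <- function(positions, volume, params, box, grad = FALSE) {
  pos <- .as_positions(positions)
  n <- nrow(pos); K <- nrow(volume$centers)
  if (n == 0) {
    return(list(h = numeric(0), grad = matrix(numeric(), 0, 3)))
  }
  H <- matrix(0, n, K)
  dH <- if (grad) matrix(0, n, K) else NULL
  U <- if (grad) vector("list", K) else NULL
  for (k in seq_len(K)) {
    delta <- .min_image(sweep(pos, 2, volume$centers[k, ], "-"), box)
    d <- sqrt(rowSums(delta^2))
    if (params$sigma == 0) {
      H[, k] <- as.numeric(d <= volume$R_v)
    } else {
      sk <- .smooth_sphere(d, volume$R_v, params$sigma, params$r_c, deriv = grad)
      H[, k] <- sk$h
      if (grad) {
        dH[, k] <- sk$dh
        U[[k]] <- delta / pmax(d, 1e-300)
      }
    }
  }
  M <- 1 - H
  P <- apply(M, 1, prod)
  h <- 1 - P
  g <- NULL
  if (grad) {
    g <- matrix(0, n, 3)
    for (k in seq_len(K)) {
      pk <- ifelse(M[, k] > 1e-12, P / M[, k],
                   apply(M[, -k, drop = FALSE], 1, prod))
      g <- g + (pk * dH[, k]) * U[[k]]
    }
  }
  list(h = h, grad = g)
}

#' Coarse-grained water number in a probe volume
#'
#' N_v-tilde = sum_i h_i where h_i in [0,1] is the smoothed union-of-spheres
#' indicator for water i (union handled as 1 - prod_k (1 - h_k), exact when
#' kernel shells do not overlap and smooth everywhere). With `sigma = 0` the
#' sharp indicator is used and the result is the exact integer count.
#'
#' @param positions Water oxygen positions: n x 3 matrix or a data frame with
#'   columns `x,y,z` (or `ox,oy,oz`), nm.
#' @param volume A [probe_volume()].
#' @param params A [coarse_grain_params()].
#' @param box Optional length-3 periodic box (nm) for minimum-image distances.
#' @return The coarse-grained number, a real in `[0, n_waters]`, continuous
#'   and differentiable in the positions.
#' @export
coarse_grained_number <- function(positions, volume,
                                  params = coarse_grain_params(), box = NULL) {
  sum(.union_indicator(positions, volume, params, box)$h)
}

#' Linear bias energy and per-water forces
#'
#' Under the biased Hamiltonian H = H0 + phi * N_v-tilde, returns the bias
#' energy U = phi * N_v-tilde and the force on each water,
#' F_i = -phi * dN_v-tilde/dr_i (analytic gradient of the smoothed
#' indicator).
#'
#' @inheritParams coarse_grained_number
#' @param phi Bias strength, kcal/mol per molecule.
#' @return List with `energy` (kcal/mol), `n_tilde`, and `force`
#'   (n x 3 matrix, kcal/mol/nm).
#' @export
bias_energy_force <- function(positions, phi, volume,
                              params = coarse_grain_params(), box = NULL) {
  if (params$sigma == 0) abort("Forces require a smoothed indicator (sigma > 0).")
  u <- .union_indicator(positions, volume, params, box, grad = TRUE)
  list(energy = phi * sum(u$h), n_tilde = sum(u$h), force = -phi * u$grad)
}

#' Normalized water-number response to the linear bias
#'
#' The mean water number at each bias, normalized by the unbiased mean, with
#' block-averaged standard errors. The ratio is 1 at beta*phi = 0 by
#' construction (its SEM is reported as 0 there).
#'
#' @param data Long tibble with columns `N` and `beta_phi` (or `phi`, with
#'   `beta` supplied).
#' @param beta Inverse thermal energy, mol/kcal (used only if `beta_phi` is
#'   absent).
#' @param n_blocks Blocks for [block_sem()].
#' @param discard Initial samples discarded per series (equilibration).
#' @return Tibble `(beta_phi, mean_N, response, sem)` sorted by `beta_phi`.
#' @export
normalized_response <- function(data, beta = 1 / thermal_energy(),
                                n_blocks = 5, discard = 0) {
  data <- .with_beta_phi(data, beta)
  tab <- data |>
    dplyr::group_by(.data$beta_phi) |>
    dplyr::summarise(
      mean_N = mean(utils::tail(.data$N, dplyr::n() - discard)),
      sem_N = block_sem(utils::tail(.data$N, dplyr::n() - discard), n_blocks),
      .groups = "drop") |>
    dplyr::arrange(.data$beta_phi)
  if (!any(tab$beta_phi == 0)) abort("A beta_phi = 0 (unbiased) series is required.")
  m0 <- tab$mean_N[tab$beta_phi == 0]
  s0 <- tab$sem_N[tab$beta_phi == 0]
  tab |>
    dplyr::mutate(
      response = .data$mean_N / m0,
      sem = ifelse(.data$beta_phi == 0, 0,
                   abs(.data$response) *
                     sqrt((.data$sem_N / .data$mean_N)^2 + (s0 / m0)^2))) |>
    dplyr::select("beta_phi", "mean_N", "response", "sem")
}

.with_beta_phi <- function(data, beta) {
  if (!"beta_phi" %in% names(data)) {
    if (!"phi" %in% names(data)) abort("Need a `beta_phi` or `phi` column.")
    data$beta_phi <- data$phi * beta
  }
  if (!"N" %in% names(data)) abort("Need an `N` column of water-number samples.")
  data
}

#' Sparse-sampling free energy of dewetting
#'
#' At each bias phi the free energy at the mean coarse-grained number is
#' assembled from three terms: the biased distribution evaluated at its mean
#' under a Gaussian approximation, -1/beta * ln P = 1/(2 beta) ln(2 pi var),
#' minus the bias work phi * <N>, plus the thermodynamic integral of <N> over
#' phi (trapezoid on the sampled grid, no extrapolation). The profile is
#' shifted so F = 0 at phi = 0.
#'
#' @param data Long tibble with columns `N` and `beta_phi` (or `phi` with
#'   `beta`); must contain beta_phi = 0 and at least 3 bias values, and will
#'   be processed in ascending bias order.
#' @param beta Inverse thermal energy, mol/kcal.
#' @param ref_beta_phi Bias defining the dewetted reference state for the
#'   dewetting free energy (default 7).
#' @param discard Initial samples discarded per series.
#' @return A `free_energy_profile`: table `(beta_phi, mean_N, var_N, F_kT)`
#'   plus `beta`, `ref_beta_phi`, and `F_dewet` (kT; `NA` if the reference
#'   bias is not covered).
#' @export
sparse_sampling_free_energy <- function(data, beta = 1 / thermal_energy(),
                                        ref_beta_phi = 7, discard = 0) {
  data <- .with_beta_phi(data, beta)
  tab <- data |>
    dplyr::group_by(.data$beta_phi) |>
    dplyr::summarise(mean_N = mean(utils::tail(.data$N, dplyr::n() - discard)),
                     var_N = var(utils::tail(.data$N, dplyr::n() - discard)),
                     .groups = "drop") |>
    dplyr::arrange(.data$beta_phi)
  if (nrow(tab) < 3) abort("Need >= 3 bias values (including 0).")
  if (!any(tab$beta_phi == 0)) abort("A beta_phi = 0 (unbiased) series is required.")
  if (any(tab$beta_phi < 0)) abort("Bias values must be >= 0.")
  if (any(!is.finite(tab$var_N)) || any(tab$var_N <= 0)) {
    abort("Zero or undefined variance in a bias window; Gaussian approximation degenerate.")
  }
  # cumulative trapezoid of <N> d(beta phi), in kT
  bp <- tab$beta_phi; mN <- tab$mean_N
  integral <- c(0, cumsum(diff(bp) * (utils::head(mN, -1) + utils::tail(mN, -1)) / 2))
  F_kT <- 0.5 * log(2 * pi * tab$var_N) - bp * mN + integral
  F_kT <- F_kT - F_kT[bp == 0]
  tab$F_kT <- F_kT
  F_dewet <- {
    i <- .match_beta_phi(bp, ref_beta_phi)
    if (is.na(i)) NA_real_ else F_kT[i]
  }
  structure(list(table = tab, beta = beta, ref_beta_phi = ref_beta_phi,
                 F_dewet = F_dewet),
            class = "free_energy_profile")
}

.match_beta_phi <- function(grid, target, tol = 1e-6) {
  i <- which(abs(grid - target) <= tol * max(1, abs(target)))
  if (length(i) == 0) NA_integer_ else i[1]
}

#' Dewetting free energy from a sparse-sampling profile
#'
#' The free-energy cost of emptying the probe volume down to the waters
#' remaining at the reference bias (beta*phi = 7 by default):
#' F_dewet = F(<N> at beta*phi = ref) - F(<N> at phi = 0), in kT. The
#' reference bias must have been sampled; interpolation is refused.
#'
#' @param profile A `free_energy_profile` from [sparse_sampling_free_energy()].
#' @param ref_beta_phi Reference bias (default: the profile's).
#' @return Dewetting free energy in kT.
#' @export
dewetting_free_energy <- function(profile, ref_beta_phi = NULL) {
  stopifnot(inherits(profile, "free_energy_profile"))
  ref <- ref_beta_phi %||% profile$ref_beta_phi
  i <- .match_beta_phi(profile$table$beta_phi, ref)
  if (is.na(i)) {
    abort(paste0("beta_phi = ", ref, " was not sampled (max sampled: ",
                 max(profile$table$beta_phi),
                 "); interpolation refused."))
  }
  profile$table$F_kT[i] - profile$table$F_kT[profile$table$beta_phi == 0]
}

#' Compressibility slope of the normalized response
#'
#' Least-squares slope of <N>/<N0> versus beta*phi over the low-bias linear
#' regime; its magnitude tracks the compressibility of the first hydration
#' shell (steeper = more compressible = more hydrophobic).
#'
#' @param response Output of [normalized_response()].
#' @param max_beta_phi Upper end of the fit range (default includes all).
#' @return One-row tibble `(slope, se, n_points)`.
#' @export
compressibility_slope <- function(response, max_beta_phi = Inf) {
  sub <- dplyr::filter(response, .data$beta_phi <= max_beta_phi)
  if (nrow(sub) < 2) abort("Need >= 2 points within the fit range.")
  fit <- lm(response ~ beta_phi, data = sub)
  tibble::tibble(slope = coef(fit)[[2]],
                 se = summary(fit)$coefficients[2, 2],
                 n_points = nrow(sub))
}

#' Build a probe volume encapsulating hydrophilic head groups
#'
#' Spheres of radius `R_v` centered on each head atom plus filler spheres on
#' the segments and triangles spanned by the heads at spacing <= `R_v`, so
#' the union is gap-free and approximately triangular for three heads
#' (covering roughly two hydration shells around each group).
#'
#' @param head_positions n x 3 matrix or data frame (`x,y,z`), nm.
#' @param R_v Sphere radius, nm (default 0.6).
#' @return A [probe_volume()].
#' @export
build_triangular_probe <- function(head_positions, R_v = 0.6) {
  pos <- .as_positions(head_positions)
  if (nrow(pos) < 1) abort("At least one head position is required.")
  pts <- list(pos)
  n <- nrow(pos)
  if (n >= 2) {
    for (pair in utils::combn(n, 2, simplify = FALSE)) {
      a <- pos[pair[1], ]; b <- pos[pair[2], ]
      len <- sqrt(sum((b - a)^2))
      m <- ceiling(len / R_v)
      if (m > 1) {
        t <- seq_len(m - 1) / m
        pts[[length(pts) + 1L]] <- outer(1 - t, a) + outer(t, b)
      }
    }
  }
  if (n >= 3) {
    for (tri in utils::combn(n, 3, simplify = FALSE)) {
      a <- pos[tri[1], ]; b <- pos[tri[2], ]; c <- pos[tri[3], ]
      m <- ceiling(max(dist(pos[tri, ])) / R_v)
      bc <- tidyr::expand_grid(i = 0:m, j = 0:m) |> dplyr::filter(.data$i + .data$j <= m)
      w <- cbind(bc$i, bc$j, m - bc$i - bc$j) / m
      pts[[length(pts) + 1L]] <- w %*% rbind(a, b, c)
    }
  }
  all_pts <- do.call(rbind, pts)
  keep <- !duplicated(round(all_pts, 6))
  probe_volume(all_pts[keep, , drop = FALSE], R_v = R_v)
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat("<free_energy_profile> ", nrow(x$table), " bias points, beta_phi in [",
      min(x$table$beta_phi), ", ", max(x$table$beta_phi), "]\n", sep = "")
  if (is.finite(x$F_dewet)) {
    cat("  F_dewet (beta_phi = ", x$ref_beta_phi, "): ",
        signif(x$F_dewet, 4), " kT\n", sep = "")
  }
  print(x$table, n = 5)
  invisible(x)
}
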