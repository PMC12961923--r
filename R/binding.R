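# Potential of mean force from umbrella windows via the weighted histogram
# analysis method (WHAM), bootstrap errors, and the binding free energy from
# Boltzmann-weighted integrals over bound and unbound regions.

.check_windows <- function(windows) {
  need <- c("window", "center", "k", "z")
  if (!all(need %in% names(windows))) {
    abort(paste0("Umbrella data needs columns: ", paste(need, collapse = ", "), "."))
  }
  if (any(windows$k <= 0)) abort("Force constants must be positive.")
  windows
}

# histogram counts per window on shared bins; checks pairwise overlap chain
.wham_setup <- function(windows, n_bins, discard) {
  w <- .check_windows(windows) |>
    dplyr::group_by(.data$window) |>
    dplyr::filter(dplyr::row_number() > discard) |>
    dplyr::ungroup()
  if (nrow(w) == 0) abort("No samples left after equilibration discard.")
  ids <- sort(unique(w$window))
  rng <- range(w$z)
  edges <- seq(rng[1], rng[2] + 1e-12, length.out = n_bins + 1)
  mids <- (utils::head(edges, -1) + utils::tail(edges, -1)) / 2
  counts <- vapply(ids, function(i) {
    zi <- w$z[w$window == i]
    tabulate(findInterval(zi, edges, rightmost.closed = TRUE), nbins = n_bins)
  }, numeric(n_bins))
  meta <- w |> dplyr::distinct(.data$window, .data$center, .data$k) |>
    dplyr::arrange(.data$window)
  # connectivity: adjacent (by center) windows must share sampled range
  ord <- order(meta$center)
  for (a in seq_len(length(ord) - 1)) {
    i <- ord[a]; j <- ord[a + 1]
    ri <- range(w$z[w$window == meta$window[i]])
    rj <- range(w$z[w$window == meta$window[j]])
    if (ri[2] < rj[1] || rj[2] < ri[1]) {
      abort(paste0("Windows at centers ", meta$center[i], " and ", meta$center[j],
                   " nm do not overlap in sampled range; WHAM is ill-posed."))
    }
  }
  list(counts = counts, mids = mids, edges = edges, meta = meta,
       N = colSums(counts))
}

# bin-averaged bias factors: logc[b, i] = log (1/dz) int_bin exp(-beta u_i) dz
# (5-point Gauss-Legendre per bin; plain bin-center evaluation biases the
# PMF noticeably when beta k dz^2 is not small)
.wham_logc <- function(edges, meta, beta) {
  gl_x <- c(-0.9061798459, -0.5384693101, 0, 0.5384693101, 0.9061798459)
  gl_w <- c(0.2369268851, 0.4786286705, 0.5688888889, 0.4786286705, 0.2369268851)
  lo <- utils::head(edges, -1); hi <- utils::tail(edges, -1)
  half <- (hi - lo) / 2; mid <- (hi + lo) / 2
  K <- nrow(meta); nb <- length(mid)
  out <- matrix(-Inf, nb, K)
  for (i in seq_len(K)) {
    acc <- matrix(0, nb, length(gl_x))
    for (q in seq_along(gl_x)) {
      z <- mid + half * gl_x[q]
      acc[, q] <- log(gl_w[q] / 2) - beta * 0.5 * meta$k[i] * (z - meta$center[i])^2
    }
    mx <- apply(acc, 1, max)
    out[, i] <- mx + log(rowSums(exp(acc - mx)))
  }
  out
}

# core WHAM solver on precomputed histograms and bin-averaged log bias
# factors. The self-consistent (Picard) iteration converges slowly for long
# window chains, so the equivalent convex maximum-likelihood objective
#   A(f) = -sum_i N_i f_i + sum_b M_b log sum_i N_i exp(f_i + logc_ib)
# (whose stationary point is exactly the WHAM fixed point) is minimized by
# BFGS first; Picard iterations then polish to the requested tolerance.
.wham_solve <- function(counts, logc, N, beta, tol, max_iter, f0 = NULL) {
  K <- ncol(logc)
  nb <- rowSums(counts)
  f <- f0 %||% numeric(K)   # f_i = beta * window free energy
  if (K > 1) {
    lN <- log(N)
    den_terms <- function(f) {
      lw <- sweep(logc, 2, f + lN, "+")
      mx <- do.call(pmax, as.data.frame(lw))
      list(lw = lw, logden = mx + log(rowSums(exp(lw - mx))))
    }
    # fix f_1 = 0; optimize the remaining K-1 components
    objfn <- function(f2) {
      d <- den_terms(c(0, f2))
      -sum(N * c(0, f2)) + sum(nb * d$logden)
    }
    grfn <- function(f2) {
      d <- den_terms(c(0, f2))
      w <- exp(sweep(d$lw, 1, d$logden, "-"))  # n_bins x K, rows: N_i e^{f_i+logc}/den
      (-N + colSums(nb * w))[-1]
    }
    o <- stats::optim(f[-1] - f[1], objfn, grfn, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))
    f <- c(0, o$par)
  }
  for (it in seq_len(max_iter)) {
    # log denominator per bin: log sum_i N_i exp(f_i + logc_ib)
    lw <- sweep(logc, 2, f + log(N), "+")
    mx <- apply(lw, 1, max)
    logden <- mx + log(rowSums(exp(lw - mx)))
    logp <- ifelse(nb > 0, log(nb) - logden, -Inf)
    # f_i = -log sum_b exp(logc_ib + logp_b)
    lt <- logc + logp
    mt <- apply(lt, 2, max)
    fnew <- -(mt + log(colSums(exp(sweep(lt, 2, mt, "-")))))
    fnew <- fnew - fnew[1]
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < tol) {
      return(list(logp = logp, f = f, iterations = it, residual = delta))
    }
  }
  abort(paste0("WHAM did not converge in ", max_iter,
               " iterations (residual ", signif(delta, 3), ")."))
}

#' WHAM potential of mean force from umbrella windows
#'
#' Solves the standard WHAM equations self-consistently: the unbiased density
#' from histogram counts and window free energies, and the window free
#' energies from the density, iterated until the largest change in any window
#' free energy is below `tol` (in kT). The PMF is W = -kT ln(density), shifted
#' so its mean over the detected (or supplied) bulk plateau is zero.
#'
#' @param windows Long tibble with columns `window`, `center` (nm), `k`
#'   (kcal/mol/nm^2; use [kj_to_kcal()] for kJ input) and `z` (nm), e.g. from
#'   [generate_umbrella_windows()].
#' @param temperature Kelvin; sets RT (0.592 kcal/mol at the default 298.15 K).
#' @param n_bins Number of histogram bins over the sampled range; default one
#'   bin per 1/16 window spacing (with stiff springs the histogram
#'   discretization bias scales as the squared bin width, so bins must be
#'   well below the window width).
#' @param tol Convergence tolerance on window free energies, kT.
#' @param max_iter Iteration cap; non-convergence is an error reporting the
#'   residual.
#' @param discard Initial samples discarded per window (equilibration).
#' @param plateau_range Optional `c(z3, z4)` bulk region; if NULL it is
#'   detected as the longest trailing stretch (>= `plateau_min_length` nm)
#'   of the lightly smoothed profile whose total variation stays below
#'   0.3 kcal/mol with no material trend between its halves. If no such
#'   stretch exists the trailing 25% of the range is used with a warning.
#' @param plateau_min_length Minimum plateau length, nm (default 0.5).
#' @return A `pmf_profile`: table `(z, W, err)` (kcal/mol; `err` filled by
#'   [bootstrap_pmf()]), `plateau_range`, `RT`, iteration diagnostics.
#' @export
wham <- function(windows, temperature = 298.15, n_bins = NULL, tol = 1e-8,
                 max_iter = 100000, discard = 0, plateau_range = NULL,
                 plateau_min_length = 0.5) {
  RT <- thermal_energy(temperature)
  beta <- 1 / RT
  meta0 <- .check_windows(windows) |> dplyr::distinct(.data$window, .data$center)
  spacing <- if (nrow(meta0) > 1) min(diff(sort(meta0$center))) else NA_real_
  n_bins <- n_bins %||% {
    if (is.na(spacing)) 50L else
      max(20L, ceiling(diff(range(windows$z)) / (spacing / 16)))
  }
  st <- .wham_setup(windows, n_bins, discard)
  logc <- .wham_logc(st$edges, st$meta, beta)
  sol <- .wham_solve(st$counts, logc, st$N, beta, tol, max_iter)
  W <- -RT * sol$logp
  # keep only well-constrained bins: beyond the outermost windows the counts
  # collapse and the estimate is dominated by truncation noise
  tot <- rowSums(st$counts)
  keep <- is.finite(W) & tot >= 0.01 * max(tot)
  tab <- tibble::tibble(z = st$mids[keep], W = W[keep], err = NA_real_)
  pr <- plateau_range %||% .detect_plateau(tab, plateau_min_length)
  in_pl <- tab$z >= pr[1] & tab$z <= pr[2]
  tab$W <- tab$W - mean(tab$W[in_pl])
  structure(list(table = tab, plateau_range = pr, RT = RT,
                 temperature = temperature, n_bins = n_bins,
                 f = sol$f, iterations = sol$iterations,
                 setup = list(edges = st$edges, meta = st$meta, discard = discard)),
            class = "pmf_profile")
}

# longest trailing interval (>= min_len) that is genuinely flat: total W
# variation below `flat_tol` and no material trend (first- vs second-half
# means agree within flat_tol/3; per-bin noise makes p-value tests on the
# slope unreliable here)
.detect_plateau <- function(tab, min_len, flat_tol = 0.3) {
  n <- nrow(tab)
  # scan a lightly smoothed profile (~0.05 nm rolling mean) so per-bin noise
  # does not mask a genuine plateau
  bw <- if (n > 1) stats::median(diff(tab$z)) else 1
  half <- max(0L, min(round(0.025 / bw), (n - 1) %/% 2))
  if (half > 0) {
    ker <- rep(1 / (2 * half + 1), 2 * half + 1)
    sm <- as.numeric(stats::filter(tab$W, ker, sides = 2))
    ok <- which(!is.na(sm))
    sm[seq_len(ok[1] - 1)] <- sm[ok[1]]
    sm[seq(ok[length(ok)] + 1, length.out = n - ok[length(ok)])] <- sm[ok[length(ok)]]
    tab$W <- sm
  }
  for (start in seq_len(n - 2)) {
    seg <- tab[start:n, ]
    if (diff(range(seg$z)) < min_len) break
    if (diff(range(seg$W)) > flat_tol) next
    half <- nrow(seg) %/% 2
    if (abs(mean(seg$W[seq_len(half)]) -
            mean(seg$W[(half + 1):nrow(seg)])) > flat_tol / 2) next
    return(range(seg$z))
  }
  warn("No flat trailing plateau detected; using the trailing 25% of the range.")
  c(stats::quantile(tab$z, 0.75)[[1]], max(tab$z))
}

#' Bootstrap standard errors for a WHAM PMF
#'
#' Resamples each window's (post-discard) samples with replacement, reruns
#' WHAM on the same bins, and reports the per-bin standard deviation of the
#' plateau-shifted PMF across trials.
#'
#' @param windows As in [wham()].
#' @param pmf The `pmf_profile` whose binning/plateau should be reused.
#' @param n_boot Number of bootstrap trials (>= 2; the conventional choice
#'   is 100).
#' @param seed Integer seed (deterministic trials).
#' @return The `pmf_profile` with its `err` column filled (kcal/mol).
#' @export
bootstrap_pmf <- function(windows, pmf, n_boot = 100, seed = 1) {
  stopifnot(inherits(pmf, "pmf_profile"), n_boot >= 2)
  beta <- 1 / pmf$RT
  discard <- pmf$setup$discard
  w <- .check_windows(windows) |>
    dplyr::group_by(.data$window) |>
    dplyr::filter(dplyr::row_number() > discard) |>
    dplyr::ungroup()
  ids <- sort(unique(w$window))
  edges <- pmf$setup$edges
  n_bins <- length(edges) - 1
  meta <- pmf$setup$meta
  zs <- lapply(ids, function(i) w$z[w$window == i])
  set.seed(seed)
  f_warm <- pmf$f
  logc <- .wham_logc(edges, meta, beta)
  trials <- matrix(NA_real_, n_bins, n_boot)
  for (b in seq_len(n_boot)) {
    counts <- vapply(zs, function(z) {
      zb <- sample(z, length(z), replace = TRUE)
      tabulate(findInterval(zb, edges, rightmost.closed = TRUE), nbins = n_bins)
    }, numeric(n_bins))
    sol <- .wham_solve(counts, logc, colSums(counts), beta, tol = 1e-7,
                       max_iter = 100000, f0 = f_warm)
    f_warm <- sol$f
    Wb <- -pmf$RT * sol$logp
    mids <- (utils::head(edges, -1) + utils::tail(edges, -1)) / 2
    in_pl <- mids >= pmf$plateau_range[1] & mids <= pmf$plateau_range[2] & is.finite(Wb)
    trials[, b] <- Wb - mean(Wb[in_pl])
  }
  mids <- (utils::head(edges, -1) + utils::tail(edges, -1)) / 2
  err_all <- apply(trials, 1, function(r) sd(r[is.finite(r)]))
  pmf$table$err <- err_all[match(pmf$table$z, mids)]
  pmf$n_boot <- n_boot
  pmf
}

#' Identify the bound region of a PMF
#'
#' Locates the global minimum lying below the bulk plateau by more than one
#' noise floor, then returns the contiguous interval around it where
#' W <= W_min + `kT_window` (thermal fluctuations up to 1 kT, 0.592 kcal/mol
#' at 298.15 K). Returns NULL when no such minimum exists (purely repulsive
#' surface). If two minima tie, the widest interval is used, broken toward
#' smaller z, and the tie is flagged.
#'
#' @param pmf A `pmf_profile`.
#' @param kT_window Half-depth of the thermal window, kcal/mol (default
#'   `pmf$RT`, i.e. 1 kT).
#' @param noise_floor Minimum depth below the plateau to count as a bound
#'   minimum; defaults to the median bootstrap error, or the plateau residual
#'   standard deviation when errors are absent.
#' @return `c(z1, z2)` with attribute `tied` (logical), or NULL.
#' @export
identify_bound_region <- function(pmf, kT_window = NULL, noise_floor = NULL) {
  stopifnot(inherits(pmf, "pmf_profile"))
  kT_window <- kT_window %||% pmf$RT
  tab <- pmf$table
  in_pl <- tab$z >= pmf$plateau_range[1] & tab$z <= pmf$plateau_range[2]
  noise <- noise_floor %||% {
    if (all(is.na(tab$err))) sd(tab$W[in_pl]) else stats::median(tab$err, na.rm = TRUE)
  }
  cand <- tab$z < pmf$plateau_range[1]
  if (!any(cand)) return(NULL)
  wmin <- min(tab$W[cand])
  if (wmin >= 0 - noise) return(NULL)   # no minimum below the plateau
  lev <- wmin + kT_window
  below <- tab$W <= lev & cand
  # contiguous runs of below-level bins; candidate intervals containing a min
  r <- rle(below)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  runs <- tibble::tibble(start = starts[r$values], end = ends[r$values])
  runs <- runs |>
    dplyr::mutate(width = tab$z[.data$end] - tab$z[.data$start],
                  depth = purrr::map2_dbl(.data$start, .data$end,
                                          ~ min(tab$W[.x:.y]))) |>
    dplyr::filter(.data$depth <= wmin + noise)
  tied <- nrow(runs) > 1
  best <- runs |>
    dplyr::arrange(dplyr::desc(.data$width), .data$start) |>
    dplyr::slice(1)
  structure(c(tab$z[best$start], tab$z[best$end]), tied = tied)
}

#' Binding free energy from a PMF
#'
#' Delta G_bind = -RT ln[ int_bound exp(-W/RT) dz / int_unbound exp(-W/RT) dz ]
#' with trapezoidal quadrature on the PMF grid (endpoints included by linear
#' interpolation). More negative means more favorable binding. With the PMF
#' plateau shifted to zero, the denominator is effectively the width of the
#' unbound reference region.
#'
#' @param pmf A `pmf_profile`.
#' @param bound `c(z1, z2)` from [identify_bound_region()], or NULL for an
#'   unbound (purely repulsive) surface.
#' @param unbound `c(z3, z4)`; defaults to the plateau range. The PMF must be
#'   flat there (|mean W| below its noise), otherwise the call is rejected.
#' @return A `binding_result`: list with `dG` (kcal/mol; `NA` with
#'   `has_minimum = FALSE` when no bound region exists), `bound_range`,
#'   `unbound_range`, `has_minimum`, `RT`.
#' @export
binding_free_energy <- function(pmf, bound = NULL, unbound = NULL) {
  stopifnot(inherits(pmf, "pmf_profile"))
  unbound <- unbound %||% pmf$plateau_range
  tab <- pmf$table
  in_un <- tab$z >= unbound[1] & tab$z <= unbound[2]
  noise <- if (all(is.na(tab$err))) max(sd(tab$W[in_un]), 1e-3) else
    stats::median(tab$err[in_un], na.rm = TRUE)
  if (abs(mean(tab$W[in_un])) > max(noise, 1e-6)) {
    abort(paste0("Unbound range is not a zero plateau (mean W = ",
                 signif(mean(tab$W[in_un]), 3), " kcal/mol > noise ",
                 signif(noise, 3), "); shift or re-detect the plateau."))
  }
  if (is.null(bound)) {
    return(structure(list(dG = NA_real_, bound_range = NULL,
                          unbound_range = unbound, has_minimum = FALSE,
                          RT = pmf$RT),
                     class = "binding_result"))
  }
  num <- .boltzmann_integral(tab, bound, pmf$RT)
  den <- .boltzmann_integral(tab, unbound, pmf$RT)
  structure(list(dG = -pmf$RT * log(num / den), bound_range = bound,
                 unbound_range = unbound, has_minimum = TRUE, RT = pmf$RT),
            class = "binding_result")
}

# trapezoid of exp(-W/RT) over [a, b], with interpolated endpoints
.boltzmann_integral <- function(tab, range, RT) {
  a <- range[1]; b <- range[2]
  if (b <= a) abort("Integration range must have positive width.")
  zin <- tab$z[tab$z > a & tab$z < b]
  z <- c(a, zin, b)
  W <- approx(tab$z, tab$W, xout = z, rule = 2)$y
  f <- exp(-W / RT)
  sum(diff(z) * (utils::head(f, -1) + utils::tail(f, -1)) / 2)
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat("<pmf_profile> ", nrow(x$table), " bins, z in [",
      signif(min(x$table$z), 4), ", ", signif(max(x$table$z), 4),
      "] nm, RT = ", signif(x$RT, 4), " kcal/mol\n",
      "  plateau: [", signif(x$plateau_range[1], 4), ", ",
      signif(x$plateau_range[2], 4), "] nm; converged in ",
      x$iterations, " iterations\n", sep = "")
  invisible(x)
}

#' @export
print.binding_result <- function(x, ...) {
  if (x$has_minimum) {
    cat("<binding_result> dG = ", signif(x$dG, 4), " kcal/mol, bound [",
        signif(x$bound_range[1], 4), ", ", signif(x$bound_range[2], 4),
        "] nm, unbound [", signif(x$unbound_range[1], 4), ", ",
        signif(x$unbound_range[2], 4), "] nm\n", sep = "")
  } else {
    cat("<binding_result> no PMF minimum below the plateau; binding not favorable\n")
  }
  invisible(x)
}
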