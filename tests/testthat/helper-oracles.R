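# Independent oracles used across the suite. None of these share code with
# the package implementations they check.

# Smoothed sphere indicator by direct numerical convolution: the sharp
# indicator of a sphere of radius R integrated against the truncated,
# shifted, renormalized Gaussian kernel, reduced to 1D quadrature in the
# kernel radius via the analytic solid-angle fraction.
quad_smooth_indicator <- function(d, R = 0.6, sigma = 0.01, r_c = 0.02) {
  E <- exp(-r_c^2 / (2 * sigma^2))
  A <- 1 / (4 * pi * stats::integrate(function(s) s^2 * (exp(-s^2 / (2 * sigma^2)) - E),
                                      0, r_c, rel.tol = 1e-13)$value)
  vapply(d, function(dd) {
    if (dd <= R - r_c) return(1)
    if (dd >= R + r_c) return(0)
    frac <- function(s) {
      mu <- (R^2 - dd^2 - s^2) / (2 * dd * s)
      pmin(pmax((1 + mu) / 2, 0), 1)
    }
    stats::integrate(function(s) 4 * pi * s^2 * A * (exp(-s^2 / (2 * sigma^2)) - E) * frac(s),
                     0, r_c, rel.tol = 1e-12)$value
  }, numeric(1))
}

# Exhaustive all-triples hydrogen-bond detector with its own minimum-image
# arithmetic: every (donor, hydrogen, acceptor) combination is tested.
oracle_hbonds <- function(donors, hydrogens, acceptors, box, d_max = 0.35,
                          angle_min = 150) {
  mi <- function(dd, L) dd - L * round(dd / L)
  nd <- nrow(donors); na <- nrow(acceptors)
  # donor-acceptor distances for all pairs
  d2 <- matrix(0, nd, na)
  for (dim in c("x", "y", "z")) {
    dd <- outer(acceptors[[dim]], rep(1, nd))  # na x nd, then transpose below
    dd <- t(dd) - donors[[dim]]
    dd <- -dd  # acceptor - donor
    if (!is.null(box)) dd <- mi(dd, box[match(dim, c("x", "y", "z"))])
    d2 <- d2 + dd^2
  }
  dda <- sqrt(d2)
  out <- list()
  for (hi in seq_len(nrow(hydrogens))) {
    di <- match(hydrogens$donor_id[hi], donors$id)
    hd <- numeric(3); ha <- matrix(0, na, 3)
    for (j in 1:3) {
      dim <- c("x", "y", "z")[j]
      v <- donors[[dim]][di] - hydrogens[[dim]][hi]
      if (!is.null(box)) v <- mi(v, box[j])
      hd[j] <- v
      w <- acceptors[[dim]] - hydrogens[[dim]][hi]
      if (!is.null(box)) w <- mi(w, box[j])
      ha[, j] <- w
    }
    cosang <- (ha %*% hd) / (sqrt(sum(hd^2)) * sqrt(rowSums(ha^2)))
    ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    hit <- which(dda[di, ] <= d_max & ang >= angle_min &
                   acceptors$id != donors$id[di])
    for (ai in hit) {
      out[[length(out) + 1L]] <- data.frame(donor = donors$id[di], hydrogen = hi,
                                            acceptor = acceptors$id[ai])
    }
  }
  if (length(out) == 0) {
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$donor, res$hydrogen, res$acceptor), , drop = FALSE]
}

# Independent multistate-reweighting (MBAR-style) PMF estimator working on
# the raw samples, not histograms: window free energies from the convex
# self-consistency objective, then per-bin log-sums of unbiased weights.
mbar_pmf <- function(win, edges, beta) {
  meta <- unique(as.data.frame(win[, c("window", "center", "k")]))
  meta <- meta[order(meta$window), ]
  K <- nrow(meta); z <- win$z
  Ni <- as.numeric(table(factor(win$window, levels = meta$window)))
  negbU <- sapply(seq_len(K),
                  function(i) -beta * 0.5 * meta$k[i] * (z - meta$center[i])^2)
  logden_of <- function(f) {
    lw <- sweep(negbU, 2, f + log(Ni), "+")
    mx <- do.call(pmax, as.data.frame(lw))
    mx + log(rowSums(exp(lw - mx)))
  }
  objfn <- function(f2) { f <- c(0, f2); sum(logden_of(f)) - sum(Ni * f) }
  grfn <- function(f2) {
    f <- c(0, f2); ld <- logden_of(f)
    W <- exp(sweep(negbU, 2, f + log(Ni), "+") - ld)
    (colSums(W) - Ni)[-1]
  }
  o <- stats::optim(numeric(K - 1), objfn, grfn, method = "BFGS",
                    control = list(maxit = 1000, reltol = 1e-15))
  ld <- logden_of(c(0, o$par))
  b <- findInterval(z, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1
  lp <- vapply(seq_len(nb), function(j) {
    s <- -ld[b == j]
    if (!length(s)) return(-Inf)
    m <- max(s); m + log(sum(exp(s - m)))
  }, numeric(1))
  -lp / beta
}

# random wide-format water box (positions only; orientations irrelevant for
# oxygen-based pair tests)
random_water_box <- function(n, box, seed) {
  set.seed(seed)
  w <- generate_water_box(n, box, seed = seed)
  w
}

# Shift a tabulated true PMF by the same plateau rule as a pmf_profile and
# return per-bin errors of the estimate.
pmf_errors <- function(pmf, potential) {
  wtrue <- potential_energy(potential, pmf$table$z)
  inpl <- pmf$table$z >= pmf$plateau_range[1] & pmf$table$z <= pmf$plateau_range[2]
  wtrue <- wtrue - mean(wtrue[inpl])
  pmf$table$W - wtrue
}

# pmf_profile built directly from a tabulated curve (for closed-form tests
# of the bound-region and binding-integral operations)
profile_from_curve <- function(z, W, plateau_range, RT = thermal_energy()) {
  structure(list(table = tibble::tibble(z = z, W = W, err = NA_real_),
                 plateau_range = plateau_range, RT = RT,
                 temperature = 298.15, iterations = 0L, f = 0,
                 setup = list()),
            class = "pmf_profile")
}
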