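test_that("smoothed indicator matches the numerical convolution oracle", {
  pv <- probe_volume(matrix(0, 1, 3), R_v = 0.6)
  cg <- coarse_grain_params()
  d <- seq(0.578, 0.622, by = 0.0017)
  mine <- vapply(d, function(dd)
    coarse_grained_number(matrix(c(dd, 0, 0), 1, 3), pv, cg), numeric(1))
  expect_equal(mine, quad_smooth_indicator(d), tolerance = 1e-10)
  # frozen oracle value for a water exactly at the sphere radius
  expect_equal(coarse_grained_number(matrix(c(0.6, 0, 0), 1, 3), pv, cg),
               0.4952289, tolerance = 1e-6)
  # deep interior saturates; empty volume counts zero
  expect_equal(coarse_grained_number(matrix(0, 1, 3), pv, cg), 1)
  expect_equal(coarse_grained_number(matrix(numeric(), 0, 3), pv, cg), 0)
})

test_that("coarse-grained number is bounded, additive, and sharp in the sigma -> 0 limit", {
  pv <- probe_volume(rbind(c(0, 0, 0), c(0.4, 0.2, 0), c(-0.3, 0.3, 0.2)), R_v = 0.6)
  sharp <- coarse_grain_params(sigma = 0)
  near <- coarse_grain_params(sigma = 1e-4, r_c = 2e-4)
  cg <- coarse_grain_params()
  set.seed(17)
  for (rep in 1:100) {
    pos <- matrix(runif(45, -1.2, 1.2), 15, 3)
    n_exact <- coarse_grained_number(pos, pv, sharp)
    expect_equal(n_exact, round(n_exact))
    # the smoothed count converges to the sharp count except for waters
    # inside the vanishing kernel layer around a sphere surface
    dmin <- apply(pos, 1, function(p)
      min(abs(sqrt(colSums((t(pv$centers) - p)^2)) - 0.6)))
    if (all(dmin > 5e-4)) {
      expect_equal(coarse_grained_number(pos, pv, near), n_exact,
                   tolerance = 1e-9)
    }
    h <- hydropattern:::.union_indicator(pos, pv, cg, box = NULL)$h
    expect_true(all(h >= 0 & h <= 1))
    expect_equal(sum(h), coarse_grained_number(pos, pv, cg))
  }
})

test_that("bias forces agree with central differences on boundary configurations", {
  cg <- coarse_grain_params()
  pv <- probe_volume(rbind(c(0, 0, 0), c(0.55, 0, 0)), R_v = 0.6)
  set.seed(31)
  u <- matrix(rnorm(60), 20, 3); u <- u / sqrt(rowSums(u^2))
  pos <- u * (0.6 + runif(20, -0.019, 0.019))
  phi <- 1.5
  bf <- bias_energy_force(pos, phi, pv, cg)
  expect_equal(bf$energy, phi * bf$n_tilde)
  h <- 1e-5
  num <- matrix(0, 20, 3)
  for (i in 1:20) for (kdim in 1:3) {
    pp <- pos; pp[i, kdim] <- pp[i, kdim] + h
    pm <- pos; pm[i, kdim] <- pm[i, kdim] - h
    num[i, kdim] <- -(bias_energy_force(pp, phi, pv, cg)$energy -
                        bias_energy_force(pm, phi, pv, cg)$energy) / (2 * h)
  }
  nrm <- sqrt(rowSums(num^2))
  abserr <- sqrt(rowSums((bf$force - num)^2))
  # appreciable forces: relative agreement; vanishing forces near the kernel
  # truncation edge: absolute agreement
  expect_lt(max((abserr / nrm)[nrm > 1]), 1e-5)
  expect_lt(max(abserr[nrm <= 1]), 1e-4)
  # zero bias and plateau interior give exactly zero force
  expect_equal(bias_energy_force(pos, 0, pv, cg)$force, matrix(0, 20, 3))
  deep <- bias_energy_force(matrix(c(0.1, 0, 0), 1, 3), phi, pv, cg)
  expect_equal(deep$force, matrix(0, 1, 3))
})

test_that("normalized response is 1 at zero bias and linear with slope -var/mean for a Gaussian model", {
  m <- number_fluctuation_model(100, 25)
  ser <- generate_biased_series(m, seq(0, 1.6, by = 0.2), n = 20000, seed = 12)
  resp <- normalized_response(ser)
  expect_equal(resp$response[resp$beta_phi == 0], 1)
  expect_equal(resp$sem[resp$beta_phi == 0], 0)
  cs <- compressibility_slope(resp, max_beta_phi = 1.6)
  expect_equal(cs$slope, -25 / 100, tolerance = 0.02)
  # constant response has zero slope
  flat <- tibble::tibble(beta_phi = 0:3, response = 1, sem = 0)
  expect_equal(suppressWarnings(compressibility_slope(flat))$slope, 0,
               tolerance = 1e-12)
  expect_error(compressibility_slope(flat[1, ]), ">= 2")
  expect_error(normalized_response(dplyr::filter(ser, beta_phi > 0)), "beta_phi = 0")
})

test_that("two-basin response drops sigmoidally at the planted transition", {
  m <- number_fluctuation_model(80, 20, basin2_mean = 6, basin2_var = 5,
                                basin2_offset_kT = 40)
  bp <- seq(0, 2, by = 0.25)
  ser <- generate_biased_series(m, bp, n = 10000, seed = 13)
  resp <- normalized_response(ser)
  # exact reweighting oracle per bias value
  exact <- vapply(bp, function(b) {
    p <- tilted_number_pmf(m, b); sum(p$N * p$p)
  }, numeric(1))
  expect_equal(resp$response, exact / exact[1], tolerance = 0.02)
  # transition: response falls below half only after the planted crossover
  expect_gt(resp$response[resp$beta_phi == 0.25], 0.9)
  expect_lt(resp$response[resp$beta_phi == 2], 0.2)
})

test_that("sparse sampling recovers the exact Gaussian free-energy parabola", {
  m <- number_fluctuation_model(100, 25)
  bp <- seq(0, 2.8, by = 0.2)
  ser <- generate_biased_series(m, bp, n = 20000, seed = 14)
  prof <- sparse_sampling_free_energy(ser)
  tab <- tidy(prof)
  expect_equal(tab$F_kT[tab$beta_phi == 0], 0)
  exact <- (tab$mean_N - 100)^2 / (2 * 25)
  expect_lt(max(abs(tab$F_kT - exact)), 0.1)
  # reproducibility: independent seeds agree within the combined SEM
  prof2 <- sparse_sampling_free_energy(generate_biased_series(m, bp, 20000, seed = 99))
  sem_F <- bp * 5 / sqrt(20000) * sqrt(2)   # bias-work term dominates
  expect_true(all(abs(tidy(prof2)$F_kT - tab$F_kT) <= 3 * sem_F + 1e-9))
  # preconditions
  expect_error(sparse_sampling_free_energy(dplyr::filter(ser, beta_phi == 0)), ">= 3")
  degen <- tibble::tibble(beta_phi = rep(c(0, 1, 2), each = 4), N = rep(5, 12))
  expect_error(sparse_sampling_free_energy(degen), "variance")
})

test_that("dewetting free energy matches the exact tilted-Gaussian difference and refuses interpolation", {
  m <- number_fluctuation_model(40, 4)
  bp <- seq(0, 7, by = 0.25)
  ser <- generate_biased_series(m, bp, n = 30000, seed = 15)
  prof <- sparse_sampling_free_energy(ser, ref_beta_phi = 7)
  fd <- dewetting_free_energy(prof)
  # exact model: beta F(N) = (N - 40)^2 / 8 evaluated at the exact tilted mean
  p7 <- tilted_number_pmf(m, 7)
  exact <- (sum(p7$N * p7$p) - 40)^2 / 8
  expect_equal(fd, exact, tolerance = 0.02 * exact)
  expect_equal(prof$F_dewet, fd)
  # a profile truncated below the reference bias refuses to interpolate
  trunc <- sparse_sampling_free_energy(dplyr::filter(ser, beta_phi <= 5))
  expect_error(dewetting_free_energy(trunc), "not sampled")
  # a deeper basin (smaller variance) removes fewer waters at the reference
  # bias and costs less by the exact tilted-Gaussian free-energy difference
  m2 <- number_fluctuation_model(40, 2)
  ser2 <- generate_biased_series(m2, bp, n = 30000, seed = 16)
  fd2 <- dewetting_free_energy(sparse_sampling_free_energy(ser2))
  expect_lt(fd2, fd)
})

test_that("halving the bias grid spacing changes the dewetting free energy by under 2%", {
  m <- number_fluctuation_model(40, 4)
  coarse <- generate_biased_series(m, seq(0, 7, by = 0.5), n = 30000, seed = 18)
  fine <- generate_biased_series(m, seq(0, 7, by = 0.25), n = 30000, seed = 19)
  f1 <- dewetting_free_energy(sparse_sampling_free_energy(coarse))
  f2 <- dewetting_free_energy(sparse_sampling_free_energy(fine))
  expect_lt(abs(f2 - f1) / f2, 0.02)
})

test_that("triangular probe volumes are gap-free unions covering all heads", {
  one <- build_triangular_probe(matrix(c(1, 2, 3), 1, 3))
  expect_equal(nrow(one$centers), 1)
  tri <- matrix(c(0, 0, 0, 1, 0, 0, 0.5, sqrt(3) / 2, 0), 3, 3, byrow = TRUE)
  pv <- build_triangular_probe(tri, R_v = 0.6)
  cc <- pv$centers
  expect_gte(nrow(cc), 3)
  # every sphere overlaps a neighbor: center distances <= 2 R_v pairwise-connected
  dm <- as.matrix(dist(cc))
  diag(dm) <- Inf
  expect_true(all(apply(dm, 1, min) <= 2 * 0.6))
  # head positions themselves are sphere centers
  expect_true(all(apply(tri, 1, function(p)
    any(colSums(abs(t(cc) - p)) < 1e-9))))
  expect_error(build_triangular_probe(matrix(numeric(), 0, 3)), "head")
})
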