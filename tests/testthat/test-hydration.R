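test_that("hydrogen-bond detection matches the exhaustive all-triples oracle exactly", {
  box <- c(2.5, 2.5, 2.5)
  crit <- hbond_criterion()
  for (seed in 1:10) {
    wb <- generate_water_box(150, box, seed = seed)
    donors <- tibble::tibble(id = wb$molecule, x = wb$ox, y = wb$oy, z = wb$oz)
    hyd <- dplyr::bind_rows(
      tibble::tibble(donor_id = wb$molecule, x = wb$h1x, y = wb$h1y, z = wb$h1z),
      tibble::tibble(donor_id = wb$molecule, x = wb$h2x, y = wb$h2y, z = wb$h2z))
    got_cell <- find_hbonds(donors, hyd, donors, box, crit, method = "cell")
    got_brute <- find_hbonds(donors, hyd, donors, box, crit, method = "brute")
    ora <- oracle_hbonds(donors, hyd, donors, box)
    key <- function(d) paste(d$donor, d$hydrogen, d$acceptor)
    expect_setequal(key(got_cell), key(ora))
    expect_setequal(key(got_brute), key(ora))
  }
  # a clear-cut geometric pair is detected; hydrogens need a parent donor
  donors <- tibble::tibble(id = 1, x = 0, y = 0, z = 0)
  acc <- tibble::tibble(id = 2, x = 0.29, y = 0, z = 0)
  hyd <- tibble::tibble(donor_id = 1, x = 0.0957, y = 0.004, z = 0)  # ~175 deg
  expect_equal(nrow(find_hbonds(donors, hyd, acc, NULL)), 1)
  bad_h <- tibble::tibble(donor_id = 9, x = 0, y = 0, z = 0)
  expect_error(find_hbonds(donors, bad_h, acc, NULL), "parent donor")
})

test_that("block SEM follows its definition and catches degenerate input", {
  expect_equal(block_sem(rep(3.7, 100), 5), 0)
  set.seed(51)
  x <- rnorm(10000)
  s <- block_sem(x, 5)
  expect_gt(s, 0.5 / sqrt(10000))
  expect_lt(s, 2 / sqrt(10000))
  # definition check against direct arithmetic
  y <- c(1, 1, 2, 2, 3, 3)
  expect_equal(block_sem(y, 3), sd(c(1, 2, 3)) / sqrt(3))
  expect_error(block_sem(1:3, 4), "shorter")
  expect_error(block_sem(1:10, 1), "n_blocks")
})

test_that("surface-water hydrogen bonds per group average correctly over frames", {
  counts <- tibble::tibble(frame = 1:10, n_bonds = rep(c(2, 4), 5))
  out <- avg_hbonds_per_group(counts, n_groups = 1)
  expect_equal(out$mean, 3)
  # planted-bond construction: k bonds among n groups gives k/n
  out2 <- avg_hbonds_per_group(tibble::tibble(frame = 1:10, n_bonds = 12),
                               n_groups = 4)
  expect_equal(out2$mean, 3)
  expect_equal(out2$sem, 0)
  # a single frame cannot be blocked: SEM flagged undefined
  expect_warning(one <- avg_hbonds_per_group(counts[1, ], n_groups = 1),
                 "SEM")
  expect_true(is.na(one$sem))
  expect_equal(one$mean, 2)
})

test_that("RDF is 1 for an ideal gas and matches the single-pair closed form", {
  set.seed(52)
  box <- c(3, 3, 3)
  wt <- tibble::tibble(x = runif(3000) * 3, y = runif(3000) * 3, z = runif(3000) * 3)
  rf <- tibble::tibble(x = runif(40) * 3, y = runif(40) * 3, z = runif(40) * 3)
  g <- rdf(rf, wt, box, r_max = 1.4, dr = 0.05)
  far <- g$r > 0.3
  sem <- sd(g$g[far]) / sqrt(sum(far))
  expect_equal(mean(g$g[far]), 1, tolerance = 3 * max(sem, 0.01))

  # one reference, one water at exactly 0.5 nm: single occupied bin whose
  # height is V / shell volume
  rf1 <- tibble::tibble(x = 1, y = 1, z = 1)
  wt1 <- tibble::tibble(x = 1.5, y = 1, z = 1)
  g1 <- rdf(rf1, wt1, box, r_max = 1.0, dr = 0.01)
  hit <- which(g1$g > 0)
  expect_length(hit, 1)
  expect_equal(g1$r[hit], 0.505, tolerance = 0.011)
  shell <- 4 / 3 * pi * (0.51^3 - 0.50^3)
  expect_equal(g1$g[hit], prod(box) / shell, tolerance = 1e-6)
  expect_equal(g1$g[hit], 1 / (4 * pi * 0.505^2 * 0.01 * (1 / prod(box))),
               tolerance = 0.01)  # spec's r^2 dr approximation of the shell
  expect_error(rdf(rf1, wt1, box, r_max = 0.5, dr = 0.6), "dr")
  expect_error(rdf(rf1, wt1, box, r_max = 2), "half")
})

test_that("angular distributions are normalized, flat for isotropic water, and peaked for aligned water", {
  wb <- generate_water_box(4000, c(6, 6, 6), seed = 53)
  ref <- tibble::tibble(x = 3, y = 3, z = 3)
  shells <- shell_spec(first = c(0, 1), second = c(1, 2), bulk = c(2, 2.9))
  ad <- angular_distribution(ref, wb, shells, box = c(6, 6, 6), n_bins = 20)
  for (sh in unique(ad$shell)) {
    d <- ad[ad$shell == sh, ]
    expect_equal(sum(d$density) * (2 / 20), 1, tolerance = 1e-9)
    expect_equal(mean(d$density), 0.5, tolerance = 1e-9)
    # isotropy: histogram consistent with uniform cos(theta) at the 1% level
    counts <- round(d$density * d$n_waters[1] * 2 * (2 / 20))
    ct <- suppressWarnings(stats::chisq.test(counts, p = rep(1 / 20, 20)))
    expect_gt(ct$p.value, 0.01)
  }
  # all O-H vectors constructed to point at the reference: mass at cos = 1
  n <- 50
  set.seed(54)
  o <- matrix(runif(3 * n, 2.2, 3.8), n, 3)
  to_ref <- t(apply(o, 1, function(p) (c(3, 3, 3) - p) / sqrt(sum((c(3, 3, 3) - p)^2))))
  h <- o + 0.0957 * to_ref
  aligned <- tibble::tibble(ox = o[, 1], oy = o[, 2], oz = o[, 3],
                            h1x = h[, 1], h1y = h[, 2], h1z = h[, 3],
                            h2x = h[, 1], h2y = h[, 2], h2z = h[, 3])
  ad2 <- angular_distribution(ref, aligned,
                              shell_spec(first = c(0, 1.5), second = c(1.5, 2),
                                         bulk = c(2, 2.9)),
                              box = c(6, 6, 6), n_bins = 20) |>
    suppressWarnings()
  first <- ad2[ad2$shell == "first", ]
  expect_equal(sum(first$density[first$cos_theta > 0.9]) * (2 / 20), 1,
               tolerance = 1e-9)
  # empty shells are flagged
  w <- testthat::capture_warnings(
    angular_distribution(ref, wb[1, ],
                         shell_spec(first = c(0, 0.01), second = c(0.02, 0.03),
                                    bulk = c(0.04, 0.05)), box = c(6, 6, 6)))
  expect_true(any(grepl("no waters", w)))
})

test_that("local hydrogen-bond density localizes planted donors and conserves counts", {
  box <- c(5, 5, 5)
  ref <- tibble::tibble(x = 2.5, y = 2.5, z = 2.5)
  # planted donor-acceptor pair with the donor oxygen at r = 0.5 from the ref
  tmpl <- generate_water_box(2, box, tibble::tibble(distance = 0.29, angle = 175),
                             seed = 55)
  shift <- c(2.5 + 0.5, 2.5, 2.5) - as.numeric(tmpl[1, c("ox", "oy", "oz")])
  for (cc in list(c("ox", "h1x", "h2x"), c("oy", "h1y", "h2y"), c("oz", "h1z", "h2z"))) {
    i <- match(cc, names(tmpl))
    tmpl[, i] <- tmpl[, i] + shift[match(cc[1], c("ox", "oy", "oz"))]
  }
  ld <- local_hbond_density(ref, tmpl, box, shell_thickness = 0.35, r_max = 1.4)
  expect_equal(sum(ld$count > 0), 1)
  expect_gt(ld$count[ld$r > 0.35 & ld$r < 0.7], 0)  # shell containing r = 0.5
  # no bonds anywhere: all shells zero
  lone <- generate_water_box(3, box, seed = 56)
  lone$ox <- c(0.5, 2.0, 4.0)  # spread out, no pairs within 0.35
  ld0 <- local_hbond_density(ref, lone, box)
  expect_true(all(ld0$bond_density == 0))
  # partition identity: counts times shell volumes equals bonds within r_max
  wb <- generate_water_box(120, c(2.5, 2.5, 2.5),
                           tibble::tibble(distance = rep(0.29, 3), angle = rep(170, 3)),
                           seed = 57)
  ldw <- local_hbond_density(tibble::tibble(x = 1.2, y = 1.2, z = 1.2), wb,
                             c(2.5, 2.5, 2.5), shell_thickness = 0.35, r_max = 1.05)
  hb <- water_hbonds(wb, c(2.5, 2.5, 2.5))
  don_o <- as.matrix(wb[match(hb$donor, wb$molecule), c("ox", "oy", "oz")])
  dd <- sqrt(rowSums(hydropattern:::.mi_vec(don_o,
    matrix(1.2, nrow(don_o), 3), c(2.5, 2.5, 2.5))^2))
  expect_equal(sum(ldw$count), sum(dd <= 1.05))
})

test_that("2D density maps average planted densities and handle degenerate slabs", {
  set.seed(58)
  frames <- dplyr::bind_rows(lapply(1:6, function(f)
    tibble::tibble(frame = f, x = runif(2000) * 3, y = runif(2000) * 3,
                   z = runif(2000) * 0.9)))
  # planted uniform density: 2000 / (3*3*0.9) = 82.3; slab sees the same value
  m <- density_map_2d(frames, box = c(3, 3, 5), slab = c(0, 0.6), cell_size = 0.5)
  rho <- 2000 / (3 * 3 * 0.9)
  sem <- sd(m$density) / sqrt(nrow(m))
  expect_equal(mean(m$density), rho, tolerance = 3 * max(sem, 1))
  # empty slab: all zeros
  m0 <- density_map_2d(frames, box = c(3, 3, 5), slab = c(4, 4.5), cell_size = 0.5)
  expect_true(all(m0$density == 0))
  # non-dividing cell size: grid auto-adjusted with a warning
  expect_warning(density_map_2d(frames, c(3, 3, 5), c(0, 0.6), cell_size = 0.7),
                 "adjusted")
})

test_that("dewetted area is monotone in threshold and finds connected footprints", {
  g <- generate_density_grid(c(60, 60), 0.05, 33,
                             tibble::tibble(cx = c(1, 2.4), cy = c(1, 2.4),
                                            radius = c(0.5, 0.25)))
  expect_equal(dewetted_area(g), pi * (0.5^2 + 0.25^2), tolerance = 0.06)
  # connected mode keeps only the larger disc
  expect_equal(dewetted_area(g, connected = TRUE), pi * 0.25, tolerance = 0.05)
  thresholds <- c(0, 2, 5, 20, 40)
  areas <- vapply(thresholds, function(th) dewetted_area(g, threshold = th),
                  numeric(1))
  expect_true(all(diff(areas) >= 0))
  expect_equal(areas[1], 0)                      # nothing below zero density
  expect_equal(areas[5], 3 * 3)                  # all cells below 40
})

test_that("pearson_r matches hand evaluation and is affine-invariant", {
  expect_equal(pearson_r(1:10, -(1:10)), -1)
  expect_equal(pearson_r(1:10, 1:10 + 5), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(2, 1, 3)), 0.5)  # product-moment by hand
  set.seed(59)
  x <- rnorm(30); y <- rnorm(30)
  r <- pearson_r(x, y)
  expect_equal(pearson_r(2 * x + 1, y), r)
  expect_equal(pearson_r(-3 * x, y), -r)
  expect_error(pearson_r(1:2, 1:2), "length")
  expect_error(pearson_r(rep(1, 5), 1:5), "variance")
})
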