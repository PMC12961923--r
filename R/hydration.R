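# Interfacial water structure analytics: geometric hydrogen-bond detection,
# block-averaged errors, radial distribution functions, water orientation
# distributions per hydration shell, local hydrogen-bond densities,
# 2D interfacial density maps, dewetted areas, and correlation.

#' Geometric hydrogen-bond criterion
#'
#' A donor-hydrogen-acceptor triple is a hydrogen bond when the
#' donor-acceptor distance is <= `d_max` and the D-H-A angle is >=
#' `angle_min` (near-linear).
#'
#' @param d_max Donor-acceptor distance cutoff, nm (default 0.35).
#' @param angle_min D-H-A angle threshold, degrees (default 150).
#' @return An `hbond_criterion` list.
#' @export
hbond_criterion <- function(d_max = 0.35, angle_min = 150) {
  if (d_max <= 0) abort("`d_max` must be positive.")
  if (angle_min <= 0 || angle_min > 180) abort("`angle_min` must be in (0, 180].")
  structure(list(d_max = d_max, angle_min = angle_min), class = "hbond_criterion")
}

#' Named hydration shells around a reference atom
#'
#' @param first,second,bulk Radial intervals `c(lo, hi)` in nm. Defaults:
#'   first shell r < 0.4, second 0.4-0.7, bulk 1.2-1.5.
#' @return A `shell_spec` tibble (`shell`, `lo`, `hi`).
#' @export
shell_spec <- function(first = c(0, 0.4), second = c(0.4, 0.7),
                       bulk = c(1.2, 1.5)) {
  s <- tibble::tibble(shell = factor(c("first", "second", "bulk"),
                                     levels = c("first", "second", "bulk")),
                      lo = c(first[1], second[1], bulk[1]),
                      hi = c(first[2], second[2], bulk[2]))
  if (any(s$hi <= s$lo) || is.unsorted(s$lo)) {
    abort("Shells must be increasing, non-overlapping intervals.")
  }
  structure(s, class = c("shell_spec", class(s)))
}

# minimum-image displacement between two coordinate matrices' rows (a - b)
.mi_vec <- function(a, b, box) {
  d <- a - b
  if (!is.null(box)) {
    bb <- matrix(box, nrow(d), 3, byrow = TRUE)
    d <- d - bb * round(d / bb)
  }
  d
}

# minimum-image distance matrix between rows of a (n x 3) and b (m x 3)
.mi_dist <- function(a, b, box) {
  n <- nrow(a); m <- nrow(b)
  out <- matrix(0, n, m)
  for (dim in 1:3) {
    dd <- outer(a[, dim], b[, dim], "-")
    if (!is.null(box)) dd <- dd - box[dim] * round(dd / box[dim])
    out <- out + dd^2
  }
  sqrt(out)
}

#' Detect hydrogen bonds by the geometric criterion
#'
#' Each hydrogen belongs to one donor; a (donor, hydrogen, acceptor) triple
#' is reported iff d(D, A) <= `d_max` and the D-H-A angle >= `angle_min`,
#' using minimum-image distances. Acceptors sharing an id with the donor are
#' skipped (no self-bonds). The cell-list and brute-force paths return the
#' identical set.
#'
#' @param donors Tibble with columns `id`, `x`, `y`, `z` (nm).
#' @param hydrogens Tibble with columns `donor_id`, `x`, `y`, `z`; every
#'   `donor_id` must appear in `donors$id`.
#' @param acceptors Tibble with columns `id`, `x`, `y`, `z`.
#' @param box Length-3 periodic box, nm (NULL for open boundaries).
#' @param criterion An [hbond_criterion()].
#' @param method `"cell"` (spatial cell list) or `"brute"` (all pairs).
#' @return Tibble `(donor, hydrogen, acceptor, distance, angle)`; `hydrogen`
#'   is the row index into `hydrogens`.
#' @export
find_hbonds <- function(donors, hydrogens, acceptors, box = NULL,
                        criterion = hbond_criterion(),
                        method = c("cell", "brute")) {
  method <- match.arg(method)
  if (!all(hydrogens$donor_id %in% donors$id)) {
    abort("Every hydrogen must reference a parent donor id.")
  }
  D <- as.matrix(donors[, c("x", "y", "z")])
  A <- as.matrix(acceptors[, c("x", "y", "z")])
  H <- as.matrix(hydrogens[, c("x", "y", "z")])
  pairs <- if (method == "brute") {
    dm <- .mi_dist(D, A, box)
    which(dm <= criterion$d_max, arr.ind = TRUE)
  } else {
    .cell_pairs(D, A, box, criterion$d_max)
  }
  if (nrow(pairs) == 0) return(.empty_hbonds())
  pairs <- pairs[donors$id[pairs[, 1]] != acceptors$id[pairs[, 2]], , drop = FALSE]
  if (nrow(pairs) == 0) return(.empty_hbonds())
  out <- list()
  hyd_by_donor <- split(seq_len(nrow(hydrogens)),
                        match(hydrogens$donor_id, donors$id))
  for (r in seq_len(nrow(pairs))) {
    di <- pairs[r, 1]; ai <- pairs[r, 2]
    dvec <- .mi_vec(A[ai, , drop = FALSE], D[di, , drop = FALSE], box)
    dist_da <- sqrt(sum(dvec^2))
    if (dist_da > criterion$d_max) next
    for (hi in hyd_by_donor[[as.character(di)]] %||% integer()) {
      hd <- .mi_vec(D[di, , drop = FALSE], H[hi, , drop = FALSE], box)
      ha <- .mi_vec(A[ai, , drop = FALSE], H[hi, , drop = FALSE], box)
      cosang <- sum(hd * ha) / (sqrt(sum(hd^2)) * sqrt(sum(ha^2)))
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      if (ang >= criterion$angle_min) {
        out[[length(out) + 1L]] <- tibble::tibble(
          donor = donors$id[di], hydrogen = hi, acceptor = acceptors$id[ai],
          distance = dist_da, angle = ang)
      }
    }
  }
  if (length(out) == 0) return(.empty_hbonds())
  dplyr::arrange(dplyr::bind_rows(out), .data$donor, .data$hydrogen, .data$acceptor)
}

.empty_hbonds <- function() {
  tibble::tibble(donor = integer(), hydrogen = integer(), acceptor = integer(),
                 distance = numeric(), angle = numeric())
}

# candidate donor/acceptor pairs within cutoff via a cell list; periodic
# when `box` is given, bounding-box grid otherwise. Cells are >= cutoff wide
# so only the 27 neighboring cells need scanning.
.cell_pairs <- function(D, A, box, cutoff) {
  wrap <- !is.null(box)
  if (wrap) {
    lo <- c(0, 0, 0)
    span <- box
  } else {
    lo <- pmin(apply(D, 2, min), apply(A, 2, min)) - 1e-9
    span <- pmax(apply(D, 2, max), apply(A, 2, max)) - lo + 2e-9
  }
  ncell <- pmax(1L, as.integer(floor(span / cutoff)))
  cell_of <- function(X) {
    ii <- matrix(0L, nrow(X), 3)
    for (dim in 1:3) {
      xx <- X[, dim] - lo[dim]
      if (wrap) xx <- xx %% span[dim]
      v <- floor(xx / (span[dim] / ncell[dim]))
      ii[, dim] <- pmin(as.integer(v), ncell[dim] - 1L)
    }
    ii
  }
  cd <- cell_of(D); ca <- cell_of(A)
  key <- function(ii) ii[, 1] + ncell[1] * (ii[, 2] + ncell[2] * ii[, 3])
  amap <- split(seq_len(nrow(A)), key(ca))
  offs <- as.matrix(tidyr::expand_grid(ox = -1:1, oy = -1:1, oz = -1:1))
  res <- list()
  for (di in seq_len(nrow(D))) {
    neigh <- sweep(offs, 2, cd[di, ], "+")
    if (wrap) {
      neigh <- sweep(neigh, 2, ncell, function(a, b) ((a %% b) + b) %% b)
    } else {
      ok <- neigh[, 1] >= 0 & neigh[, 2] >= 0 & neigh[, 3] >= 0 &
        neigh[, 1] < ncell[1] & neigh[, 2] < ncell[2] & neigh[, 3] < ncell[3]
      neigh <- neigh[ok, , drop = FALSE]
    }
    cand <- unique(unlist(amap[as.character(unique(key(neigh)))], use.names = FALSE))
    if (length(cand) == 0) next
    dv <- .mi_vec(A[cand, , drop = FALSE],
                  D[rep(di, length(cand)), , drop = FALSE], box)
    dd <- sqrt(rowSums(dv^2))
    hit <- cand[dd <= cutoff]
    if (length(hit)) res[[length(res) + 1L]] <- cbind(di, hit)
  }
  if (length(res) == 0) matrix(integer(), 0, 2) else do.call(rbind, res)
}

#' Water-water hydrogen bonds from a water-box tibble
#'
#' Convenience wrapper around [find_hbonds()] for the wide water format of
#' [generate_water_box()] (each oxygen is both a donor with two hydrogens and
#' an acceptor).
#'
#' @param waters Tibble with `molecule`, `ox,oy,oz`, `h1x..h2z`.
#' @inheritParams find_hbonds
#' @return As [find_hbonds()]; `hydrogen` is 1 or 2 within the donor
#'   molecule, reported as `(donor - 1) * 2 + h`.
#' @export
water_hbonds <- function(waters, box = NULL, criterion = hbond_criterion(),
                         method = c("cell", "brute")) {
  donors <- tibble::tibble(id = waters$molecule, x = waters$ox, y = waters$oy,
                           z = waters$oz)
  hyd <- dplyr::bind_rows(
    tibble::tibble(donor_id = waters$molecule, x = waters$h1x, y = waters$h1y,
                   z = waters$h1z),
    tibble::tibble(donor_id = waters$molecule, x = waters$h2x, y = waters$h2y,
                   z = waters$h2z)) |>
    dplyr::arrange(.data$donor_id)
  find_hbonds(donors, hyd, donors, box, criterion, method)
}

#' Block-averaged standard error of the mean
#'
#' Splits the series into `n_blocks` contiguous equal blocks (any remainder
#' truncated) and returns sd(block means)/sqrt(n_blocks).
#'
#' @param series Numeric vector, length >= `n_blocks`.
#' @param n_blocks Number of blocks (>= 2; default 5).
#' @return The SEM estimate.
#' @export
block_sem <- function(series, n_blocks = 5) {
  if (n_blocks < 2) abort("`n_blocks` must be >= 2.")
  if (length(series) < n_blocks) abort("Series shorter than `n_blocks`.")
  len <- floor(length(series) / n_blocks)
  m <- matrix(series[seq_len(len * n_blocks)], nrow = len)
  sd(colMeans(m)) / sqrt(n_blocks)
}

#' Average surface-water hydrogen bonds per hydrophilic group
#'
#' Per-frame total of surface-water hydrogen bonds divided by the number of
#' hydrophilic groups, averaged over frames with a block-averaged SEM. For
#' hydroxyl heads supply triples from both donor and acceptor roles.
#'
#' @param frames Tibble with a `frame` column and list-columns `donors`,
#'   `hydrogens`, `acceptors` (each a tibble as in [find_hbonds()]), or a
#'   precomputed tibble `(frame, n_bonds)`.
#' @param n_groups Number of hydrophilic groups.
#' @param box,criterion,method Passed to [find_hbonds()].
#' @param n_blocks Blocks for the SEM; if fewer frames than blocks, the SEM
#'   is `NA` and flagged with a warning.
#' @return One-row tibble `(mean, sem, n_frames, n_groups)`.
#' @export
avg_hbonds_per_group <- function(frames, n_groups, box = NULL,
                                 criterion = hbond_criterion(),
                                 method = "cell", n_blocks = 5) {
  stopifnot(n_groups >= 1, nrow(frames) >= 1)
  counts <- if ("n_bonds" %in% names(frames)) {
    frames$n_bonds
  } else {
    purrr::pmap_dbl(frames[c("donors", "hydrogens", "acceptors")],
                    function(donors, hydrogens, acceptors) {
                      nrow(find_hbonds(donors, hydrogens, acceptors, box,
                                       criterion, method))
                    })
  }
  per_group <- counts / n_groups
  sem <- if (length(per_group) >= n_blocks) block_sem(per_group, n_blocks) else {
    warn("Fewer frames than blocks; SEM undefined.")
    NA_real_
  }
  tibble::tibble(mean = mean(per_group), sem = sem,
                 n_frames = length(per_group), n_groups = n_groups)
}

#' Radial distribution function
#'
#' Standard shell-normalized pair distribution between reference atoms and
#' water oxygens under the periodic minimum image; g(r) tends to 1 at large r
#' for homogeneous systems.
#'
#' @param reference Tibble with `x,y,z` (and optional `frame`).
#' @param waters Tibble with `x,y,z` or `ox,oy,oz` (and optional `frame`).
#' @param box Length-3 periodic box, nm.
#' @param r_max Maximum distance, nm; must be <= half the smallest box edge.
#' @param dr Bin width, nm; must be < r_max.
#' @return Tibble `(r, g)` with bin centers.
#' @export
rdf <- function(reference, waters, box, r_max = NULL, dr = 0.002) {
  r_max <- r_max %||% (min(box) / 2)
  if (r_max > min(box) / 2 + 1e-9) abort("`r_max` must be <= half the smallest box edge.")
  if (dr <= 0 || dr >= r_max) abort("Require 0 < dr < r_max.")
  ref <- .split_frames(reference); wat <- .split_frames(waters)
  if (length(ref) != length(wat)) abort("`reference` and `waters` must have matching frames.")
  edges <- seq(0, r_max, by = dr)
  if (abs(edges[length(edges)] - r_max) > 1e-12) edges <- c(edges, r_max)
  counts <- numeric(length(edges) - 1)
  n_pairs_norm <- 0
  V <- prod(box)
  for (f in seq_along(ref)) {
    R <- .as_positions(ref[[f]]); W <- .as_positions(wat[[f]])
    dm <- .mi_dist(R, W, box)
    d <- dm[dm <= r_max & dm > 1e-12]
    counts <- counts + tabulate(findInterval(d, edges, rightmost.closed = TRUE),
                                nbins = length(edges) - 1)
    n_pairs_norm <- n_pairs_norm + nrow(R) * nrow(W) / V
  }
  shell_vol <- 4 / 3 * pi * diff(edges^3)
  tibble::tibble(r = (utils::head(edges, -1) + utils::tail(edges, -1)) / 2,
                 g = counts / (shell_vol * n_pairs_norm))
}

.split_frames <- function(df) {
  if ("frame" %in% names(df)) split(df, df$frame) else list(df)
}

#' Water orientation distribution per hydration shell
#'
#' For each water whose oxygen falls in a shell around its nearest reference
#' atom, the angle theta between each O-H bond vector (`mode = "oh"`) or the
#' molecular dipole bisector (`mode = "dipole"`) and the vector from the
#' water oxygen to that reference atom is histogrammed on cos(theta) in
#' [-1, 1], normalized so the integral over cos(theta) is 1.
#'
#' @param reference Tibble with `x,y,z`.
#' @param waters Wide water tibble (`ox..h2z`) as from [generate_water_box()].
#' @param shells A [shell_spec()].
#' @param box Periodic box (nm) or NULL.
#' @param n_bins Histogram bins on cos(theta).
#' @param mode Orientation vector convention.
#' @return Tibble `(shell, cos_theta, density, n_waters)`; shells with no
#'   waters are returned empty with `n_waters = 0` and flagged by a warning.
#' @export
angular_distribution <- function(reference, waters, shells = shell_spec(),
                                 box = NULL, n_bins = 40,
                                 mode = c("oh", "dipole")) {
  mode <- match.arg(mode)
  R <- .as_positions(reference)
  O <- as.matrix(waters[, c("ox", "oy", "oz")])
  dm <- .mi_dist(O, R, box)
  nearest <- apply(dm, 1, which.min)
  r_near <- dm[cbind(seq_len(nrow(O)), nearest)]
  edges <- seq(-1, 1, length.out = n_bins + 1)
  out <- purrr::pmap_dfr(shells, function(shell, lo, hi) {
    sel <- which(r_near > lo & r_near <= hi)
    if (length(sel) == 0) {
      warn(paste0("Shell '", shell, "' contains no waters."))
      return(tibble::tibble(shell = shell, cos_theta = numeric(),
                            density = numeric(), n_waters = integer()))
    }
    refvec <- .mi_vec(R[nearest[sel], , drop = FALSE], O[sel, , drop = FALSE], box)
    refvec <- refvec / sqrt(rowSums(refvec^2))
    cosv <- if (mode == "oh") {
      b1 <- as.matrix(waters[sel, c("h1x", "h1y", "h1z")]) - O[sel, , drop = FALSE]
      b2 <- as.matrix(waters[sel, c("h2x", "h2y", "h2z")]) - O[sel, , drop = FALSE]
      c(rowSums(b1 * refvec) / sqrt(rowSums(b1^2)),
        rowSums(b2 * refvec) / sqrt(rowSums(b2^2)))
    } else {
      dp <- (as.matrix(waters[sel, c("h1x", "h1y", "h1z")]) +
               as.matrix(waters[sel, c("h2x", "h2y", "h2z")])) / 2 -
        O[sel, , drop = FALSE]
      rowSums(dp * refvec) / sqrt(rowSums(dp^2))
    }
    h <- tabulate(findInterval(cosv, edges, rightmost.closed = TRUE),
                  nbins = n_bins)
    dens <- h / (sum(h) * diff(edges))
    tibble::tibble(shell = shell,
                   cos_theta = (utils::head(edges, -1) + utils::tail(edges, -1)) / 2,
                   density = dens, n_waters = length(sel))
  })
  out
}

#' Local water-water hydrogen-bond density around reference atoms
#'
#' Counts water-water hydrogen bonds whose donor oxygen lies in concentric
#' shells of the given thickness around each reference atom, divides by the
#' shell volume, and averages over reference atoms (and frames when a `frame`
#' column is present).
#'
#' @param reference Tibble with `x,y,z`.
#' @param waters Wide water tibble; may carry a `frame` column.
#' @param box Periodic box, nm.
#' @param shell_thickness Shell thickness, nm (default 0.35; reported r is
#'   the shell center).
#' @param r_max Outermost shell edge, nm.
#' @param criterion An [hbond_criterion()].
#' @return Tibble `(r, bond_density, count)` with density in bonds/nm^3.
#' @export
local_hbond_density <- function(reference, waters, box,
                                shell_thickness = 0.35, r_max = 1.4,
                                criterion = hbond_criterion()) {
  if (shell_thickness <= 0) abort("`shell_thickness` must be positive.")
  R <- .as_positions(reference)
  frames <- .split_frames(waters)
  edges <- seq(0, r_max + 1e-12, by = shell_thickness)
  nshell <- length(edges) - 1
  counts <- numeric(nshell)
  for (w in frames) {
    hb <- water_hbonds(w, box, criterion)
    if (nrow(hb) == 0) next
    don_o <- as.matrix(w[match(hb$donor, w$molecule), c("ox", "oy", "oz")])
    dm <- .mi_dist(don_o, R, box)
    for (j in seq_len(ncol(dm))) {
      counts <- counts + tabulate(
        findInterval(dm[dm[, j] <= r_max, j], edges, rightmost.closed = TRUE),
        nbins = nshell)
    }
  }
  vol <- 4 / 3 * pi * diff(edges^3)
  denom <- nrow(R) * length(frames)
  tibble::tibble(r = (utils::head(edges, -1) + utils::tail(edges, -1)) / 2,
                 bond_density = counts / denom / vol,
                 count = counts / denom)
}

# --- 2D density maps and dewetted area ------------------------------------

new_density_map <- function(tab, cell_size, shape, threshold = 5,
                            slab = NULL) {
  structure(tab, class = c("density_map_2d", class(tab)),
            cell_size = cell_size, shape = shape, threshold = threshold,
            slab = slab)
}

#' 2D interfacial water density map
#'
#' Time-averaged water-oxygen count per lateral cell within a z slab,
#' expressed as molecules/nm^3 (cell area x slab thickness). The interface
#' slab is conventionally ~0.6 nm thick (roughly two hydration layers).
#'
#' @param waters Tibble with `x,y,z` or `ox,oy,oz`, optional `frame` column.
#' @param box Periodic box, nm (x and y set the lateral extent).
#' @param slab `c(z_lo, z_hi)` interval, nm.
#' @param cell_size Lateral cell edge, nm. If it does not divide the box
#'   edge, the grid is auto-adjusted to the nearest dividing value with a
#'   warning (no partial trailing cells).
#' @param threshold Low-density threshold stored on the map (default 5
#'   molecules/nm^3).
#' @return A `density_map_2d` tibble `(x, y, density)`.
#' @export
density_map_2d <- function(waters, box, slab, cell_size = 0.1, threshold = 5) {
  stopifnot(length(slab) == 2, slab[2] > slab[1])
  nx <- round(box[1] / cell_size); ny <- round(box[2] / cell_size)
  cs_x <- box[1] / nx; cs_y <- box[2] / ny
  if (abs(cs_x - cell_size) > 1e-9 || abs(cs_y - cell_size) > 1e-9) {
    warn(sprintf("cell_size %.4g does not divide the box; grid adjusted to %d x %d cells (%.4g x %.4g nm).",
                 cell_size, nx, ny, cs_x, cs_y))
  }
  frames <- .split_frames(waters)
  acc <- matrix(0, nx, ny)
  for (w in frames) {
    P <- .as_positions(w)
    sel <- P[, 3] >= slab[1] & P[, 3] < slab[2]
    if (!any(sel)) next
    ix <- pmin(floor((P[sel, 1] %% box[1]) / cs_x), nx - 1) + 1
    iy <- pmin(floor((P[sel, 2] %% box[2]) / cs_y), ny - 1) + 1
    for (q in seq_along(ix)) acc[ix[q], iy[q]] <- acc[ix[q], iy[q]] + 1
  }
  vol <- cs_x * cs_y * (slab[2] - slab[1])
  g <- tidyr::expand_grid(ix = seq_len(nx), iy = seq_len(ny)) |>
    dplyr::mutate(x = (.data$ix - 0.5) * cs_x, y = (.data$iy - 0.5) * cs_y,
                  density = acc[cbind(.data$ix, .data$iy)] / (length(frames) * vol)) |>
    dplyr::select("x", "y", "density")
  new_density_map(g, cell_size = cs_x, shape = c(nx, ny),
                  threshold = threshold, slab = slab)
}

#' Dewetted interfacial area
#'
#' Area of cells whose density is below the threshold (default 5
#' molecules/nm^3), optionally restricted to the largest 4-connected
#' low-density component (the contiguous solute footprint).
#'
#' @param map A `density_map_2d`.
#' @param threshold Density cutoff, molecules/nm^3; defaults to the map's.
#' @param connected If TRUE, only the largest 4-connected dry component
#'   counts.
#' @return Dewetted area in nm^2.
#' @export
dewetted_area <- function(map, threshold = NULL, connected = FALSE) {
  threshold <- threshold %||% attr(map, "threshold")
  shape <- attr(map, "shape"); cs <- attr(map, "cell_size")
  dry <- matrix(map$density < threshold, shape[1], shape[2], byrow = TRUE)
  # map rows are expand_grid(ix, iy): iy varies fastest -> byrow = TRUE over iy
  if (!connected) return(sum(dry) * cs^2)
  if (!any(dry)) return(0)
  lab <- .label_components(dry)
  sizes <- tabulate(lab[lab > 0])
  max(sizes) * cs^2
}

# 4-connectivity flood labelling (non-periodic)
.label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (mask[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i, j))
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        if (p[1] < 1 || p[2] < 1 || p[1] > nrow(mask) || p[2] > ncol(mask)) next
        if (!mask[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
        lab[p[1], p[2]] <- cur
        stack <- c(stack, list(p + c(1, 0)), list(p - c(1, 0)),
                   list(p + c(0, 1)), list(p - c(0, 1)))
      }
    }
  }
  lab
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper around `stats::cor` for correlating, e.g., dewetted
#' area against binding free energy across surfaces.
#'
#' @param x,y Equal-length numeric vectors (n >= 3) with nonzero variance.
#' @return Correlation coefficient in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("`x` and `y` must be equal-length vectors of length >= 3.")
  }
  if (var(x) == 0 || var(y) == 0) abort("Series must have nonzero variance.")
  stats::cor(x, y, method = "pearson")
}
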