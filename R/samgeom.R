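# Idealized patterned self-assembled monolayer (SAM) geometry.
#
# Strands are all-trans alkanethiols represented by their heavy atoms placed
# on the chain axis at the all-trans axial rise (the lateral zig-zag offset is
# omitted in this idealization); a terminal functional group is appended, the
# strand is twisted about its axis and tilted from the surface normal, and the
# result is replicated on a rectangular lattice with hydrophilic strands on an
# SX sublattice (X methyl strands between hydrophilic strands).

.head_groups <- c("methyl", "hydroxyl", "guanidinium", "ammonium")

# axial rises (nm) for collinear placement: bond length * cos(35.264°),
# half the tetrahedral supplement
.rise <- function(bond) bond * cos((180 - 109.471) / 2 * pi / 180)

#' Specify an alkanethiol strand
#'
#' @param chain_length Number of backbone carbons (default 10).
#' @param head_group One of `"methyl"`, `"hydroxyl"`, `"guanidinium"`,
#'   `"ammonium"`. For `"methyl"` the terminal backbone carbon is the head.
#' @param tilt_deg Tilt angle from the surface normal, degrees; must satisfy
#'   `0 <= tilt_deg < 90` (a 90° strand would lie in the surface plane).
#' @param twist_deg Twist angle about the chain axis, degrees.
#' @return A `strand_spec` list.
#' @export
#' @examples
#' strand_spec(10, "guanidinium", tilt_deg = 30, twist_deg = 53)
strand_spec <- function(chain_length = 10, head_group = "methyl",
                        tilt_deg = 30, twist_deg = 53) {
  if (!is.numeric(chain_length) || chain_length < 1) {
    abort("`chain_length` must be a positive integer.")
  }
  if (!is.character(head_group) || length(head_group) != 1 ||
      !head_group %in% .head_groups) {
    abort(paste0("Unknown `head_group`: ", format(head_group)[1],
                 ". Must be one of: ", paste(.head_groups, collapse = ", "), "."))
  }
  if (!is.numeric(tilt_deg) || tilt_deg < 0 || tilt_deg >= 90) {
    abort("`tilt_deg` must satisfy 0 <= tilt < 90 degrees.")
  }
  structure(list(chain_length = as.integer(chain_length),
                 head_group = head_group,
                 tilt_deg = tilt_deg, twist_deg = twist_deg),
            class = "strand_spec")
}

#' Specify the rectangular SAM lattice
#'
#' @param ax,ay Lattice constants in nm along x and y (defaults 0.5 and 0.432).
#' @param nx,ny Strand counts per axis.
#' @param box Periodic box lengths, length-3 numeric, nm. Default
#'   `c(nx * ax, ny * ay, 14)`.
#' @return A `lattice_spec` list.
#' @export
lattice_spec <- function(nx, ny, ax = 0.5, ay = 0.432, box = NULL) {
  stopifnot(ax > 0, ay > 0, nx >= 1, ny >= 1)
  box <- box %||% c(nx * ax, ny * ay, 14)
  if (length(box) != 3 || any(box <= 0)) abort("`box` must be 3 positive lengths (nm).")
  if (nx * ax > box[1] + 1e-9 || ny * ay > box[2] + 1e-9) {
    abort("Lattice does not fit in box: need nx*ax <= box_x and ny*ay <= box_y.")
  }
  structure(list(ax = ax, ay = ay, nx = as.integer(nx), ny = as.integer(ny),
                 box = as.numeric(box)),
            class = "lattice_spec")
}

#' Specify the SX hydrophilic pattern
#'
#' An SX pattern has X methyl strands between hydrophilic strands, i.e. a
#' hydrophilic strand every (X+1) lattice sites along the patterned axes.
#'
#' @param spacing_index X in SX, a non-negative integer. S0 places hydrophilic
#'   strands on adjacent sites (~0.5 nm apart on the default lattice), S1
#'   every other site, etc.
#' @param hydrophilic_head Head group for the patterned strands (non-methyl).
#' @param layout `"sublattice2d"` (hydrophilic sites every (X+1) positions in
#'   both x and y) or `"stripes"` (every (X+1) columns along x, all rows).
#' @return A `pattern_spec` list. Use `hydrophilic_head = "methyl"` (or
#'   `spacing_index = NULL`... see `all_methyl_pattern()`) for a homogeneous
#'   surface.
#' @export
pattern_spec <- function(spacing_index = 1, hydrophilic_head = "hydroxyl",
                         layout = c("sublattice2d", "stripes")) {
  layout <- match.arg(layout)
  if (!is.numeric(spacing_index) || spacing_index < 0) {
    abort("`spacing_index` must be a non-negative integer.")
  }
  if (!hydrophilic_head %in% .head_groups) {
    abort(paste0("Unknown `hydrophilic_head`: ", hydrophilic_head))
  }
  structure(list(spacing_index = as.integer(spacing_index),
                 hydrophilic_head = hydrophilic_head, layout = layout),
            class = "pattern_spec")
}

#' @rdname pattern_spec
#' @export
all_methyl_pattern <- function() {
  structure(list(spacing_index = NA_integer_, hydrophilic_head = "methyl",
                 layout = "sublattice2d"),
            class = "pattern_spec")
}

# head-group atom templates appended above the terminal backbone carbon.
# z offsets are axial rises from the terminal carbon; reference marks the
# hydrophilic reference atom (O of hydroxyl, N of ammonium, terminal N of
# guanidinium).
.head_atoms <- function(head_group, z_top) {
  switch(head_group,
    methyl = tibble::tibble(name = character(), element = character(),
                            x = numeric(), y = numeric(), z = numeric(),
                            reference = logical()),
    hydroxyl = tibble::tibble(name = "OH", element = "O", x = 0, y = 0,
                              z = z_top + .rise(0.143), reference = TRUE),
    ammonium = tibble::tibble(name = "NZ", element = "N", x = 0, y = 0,
                              z = z_top + .rise(0.147), reference = TRUE),
    guanidinium = {
      cz <- z_top + .rise(0.147)
      # planar sp2 guanidinium: terminal N on axis, two NH2 nitrogens at
      # +/-120 degrees in the xz plane, C-N 0.133 nm
      s <- 0.133 * sin(120 * pi / 180)
      c <- 0.133 * cos(120 * pi / 180)
      tibble::tibble(
        name = c("CZ", "NH1", "NH2", "NT"),
        element = c("C", "N", "N", "N"),
        x = c(0, s, -s, 0), y = 0,
        z = c(cz, cz + c, cz + c, cz + 0.133),
        reference = c(FALSE, FALSE, FALSE, TRUE))
    })
}

#' Build one SAM strand
#'
#' Places a sulfur at the origin and an all-trans alkanethiol chain along +z
#' (backbone atoms on the chain axis at the all-trans axial rise), appends the
#' head group, then rotates by `twist_deg` about the chain axis and tilts by
#' `tilt_deg` from the surface normal (rotation about y).
#'
#' @param spec A [strand_spec()].
#' @return Tibble of atoms with columns `name`, `element`, `x`, `y`, `z`
#'   (nm) and `reference` (hydrophilic head reference atom flag).
#' @export
#' @examples
#' str <- build_strand(strand_spec(10, "methyl", tilt_deg = 0, twist_deg = 0))
#' all(abs(str$x) < 1e-12)  # collinear with z when untilted
build_strand <- function(spec) {
  if (!inherits(spec, "strand_spec")) spec <- do.call(strand_spec, spec)
  n <- spec$chain_length
  z_c <- .rise(0.182) + (seq_len(n) - 1) * .rise(0.154)  # S-C then C-C rises
  atoms <- dplyr::bind_rows(
    tibble::tibble(name = "S", element = "S", x = 0, y = 0, z = 0,
                   reference = FALSE),
    tibble::tibble(name = paste0("C", seq_len(n)), element = "C",
                   x = 0, y = 0, z = z_c, reference = FALSE),
    .head_atoms(spec$head_group, z_c[n]))
  xyz <- rbind(atoms$x, atoms$y, atoms$z)
  tw <- spec$twist_deg * pi / 180
  ti <- spec$tilt_deg * pi / 180
  Rz <- matrix(c(cos(tw), sin(tw), 0, -sin(tw), cos(tw), 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cos(ti), 0, -sin(ti), 0, 1, 0, sin(ti), 0, cos(ti)), 3, 3)
  xyz <- Ry %*% (Rz %*% xyz)
  atoms$x <- xyz[1, ]; atoms$y <- xyz[2, ]; atoms$z <- xyz[3, ]
  atoms
}

#' Assemble a patterned SAM slab
#'
#' Replicates a strand on the rectangular lattice, substituting hydrophilic
#' strands on the SX sublattice of the pattern. The sulfur plane sits at z = 0
#' and the surface normal is +z; x and y coordinates are wrapped into the box.
#'
#' @param lattice A [lattice_spec()].
#' @param pattern A [pattern_spec()] (or [all_methyl_pattern()]).
#' @param strand A [strand_spec()] describing the background (methyl) strand;
#'   hydrophilic strands reuse its chain length, tilt and twist.
#' @return A `sam_system`: list with `atoms` (tibble: `strand`, `site_i`,
#'   `site_j`, `name`, `element`, `residue`, `x`, `y`, `z`), `box` (nm) and
#'   `head_indices` (row indices of hydrophilic head reference atoms;
#'   empty for an all-methyl surface).
#' @export
assemble_sam <- function(lattice, pattern = all_methyl_pattern(),
                         strand = strand_spec()) {
  stopifnot(inherits(lattice, "lattice_spec"), inherits(pattern, "pattern_spec"))
  if (!inherits(strand, "strand_spec")) strand <- do.call(strand_spec, strand)
  step <- if (is.na(pattern$spacing_index)) NA_integer_ else pattern$spacing_index + 1L
  if (!is.na(step) && pattern$hydrophilic_head != "methyl" && step > lattice$nx) {
    abort(paste0("Pattern period ", step, " exceeds nx = ", lattice$nx,
                 "; sublattice does not fit."))
  }
  if (!is.na(step) && pattern$hydrophilic_head != "methyl" &&
      (lattice$nx %% step != 0 ||
       (pattern$layout == "sublattice2d" && lattice$ny %% step != 0))) {
    warn(paste0("Pattern period ", step, " does not divide the lattice (",
                lattice$nx, " x ", lattice$ny,
                "); head spacings are irregular across the periodic boundary."))
  }
  base <- build_strand(strand)
  hydro <- if (!is.na(step) && pattern$hydrophilic_head != "methyl") {
    build_strand(strand_spec(strand$chain_length, pattern$hydrophilic_head,
                             strand$tilt_deg, strand$twist_deg))
  } else NULL

  sites <- tidyr::expand_grid(i = seq_len(lattice$nx) - 1L,
                              j = seq_len(lattice$ny) - 1L)
  is_hydro <- if (is.null(hydro)) rep(FALSE, nrow(sites)) else switch(
    pattern$layout,
    sublattice2d = sites$i %% step == 0L & sites$j %% step == 0L,
    stripes = sites$i %% step == 0L)

  atoms <- purrr::pmap_dfr(
    list(sites$i, sites$j, is_hydro, seq_len(nrow(sites))),
    function(i, j, h, id) {
      a <- if (h) hydro else base
      dplyr::mutate(a,
        strand = id, site_i = i, site_j = j,
        residue = if (h) toupper(substr(pattern$hydrophilic_head, 1, 3)) else "MET",
        x = .data$x + i * lattice$ax,
        y = .data$y + j * lattice$ay)
    })
  # wrap into the box laterally; z is kept (sulfur plane at 0)
  atoms$x <- atoms$x %% lattice$box[1]
  atoms$y <- atoms$y %% lattice$box[2]
  atoms <- dplyr::select(atoms, "strand", "site_i", "site_j", "name",
                         "element", "residue", "x", "y", "z", "reference")
  structure(list(atoms = atoms, box = lattice$box,
                 head_indices = which(atoms$reference),
                 lattice = lattice, pattern = pattern),
            class = "sam_system")
}

#' Nearest-neighbor spacing of hydrophilic head groups
#'
#' @param system A `sam_system` from [assemble_sam()].
#' @param axis `"x"` (heads within a lattice row, the patterned-axis spacing),
#'   `"y"`, or `"any"` (minimum 3D center-to-center distance over all pairs).
#' @return Nearest-neighbor head spacing in nm. For an SX pattern along x this
#'   equals `(X + 1) * ax`.
#' @export
head_spacing <- function(system, axis = c("x", "y", "any")) {
  axis <- match.arg(axis)
  heads <- system$atoms[system$head_indices, ]
  if (nrow(heads) < 2) abort("Fewer than two hydrophilic heads; no spacing defined.")
  if (axis == "any") {
    d <- as.matrix(stats::dist(heads[, c("x", "y", "z")]))
    return(min(d[upper.tri(d)]))
  }
  key <- if (axis == "x") "site_j" else "site_i"
  along <- if (axis == "x") "x" else "y"
  L <- if (axis == "x") system$box[1] else system$box[2]
  sp <- heads |>
    dplyr::group_by(.data[[key]]) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(d = {
      s <- sort(.data[[along]])
      # periodic nearest-neighbor gap along the axis
      min(c(diff(s), L - (max(s) - min(s))))
    }, .groups = "drop")
  if (nrow(sp) == 0) abort("No lattice row/column holds two or more heads.")
  min(sp$d)
}

#' Write a SAM system to a structure file
#'
#' GRO files are written directly (fixed-width, nm); PDB files are written via
#' the bio3d package (coordinates in angstrom).
#'
#' @param system A `sam_system`.
#' @param path Output file path.
#' @param format `"gro"` or `"pdb"`; default inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_structure <- function(system, path, format = NULL) {
  format <- tolower(format %||% tools::file_ext(path))
  if (!format %in% c("gro", "pdb")) abort("`format` must be 'gro' or 'pdb'.")
  a <- system$atoms
  if (format == "gro") {
    lines <- c(
      "idealized patterned SAM slab",
      sprintf("%5d", nrow(a)),
      sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
              a$strand %% 100000L, substr(a$residue, 1, 5),
              substr(a$name, 1, 5), seq_len(nrow(a)) %% 100000L,
              a$x, a$y, a$z),
      sprintf("%10.5f%10.5f%10.5f", system$box[1], system$box[2], system$box[3]))
    con <- file(path, "w"); on.exit(close(con))
    writeLines(lines, con)
  } else {
    xyz <- as.numeric(t(cbind(a$x, a$y, a$z))) * 10  # nm -> angstrom
    bio3d::write.pdb(file = path, xyz = xyz,
                     resno = a$strand, resid = a$residue,
                     eleno = seq_len(nrow(a)), elety = a$name,
                     chain = "A")
  }
  invisible(path)
}

#' Read a GRO structure file
#'
#' @param path GRO file path.
#' @return List with `atoms` tibble (`residue_number`, `residue`, `name`,
#'   `x`, `y`, `z` in nm) and `box` (length-3, nm).
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[2]))
  rec <- lines[3:(2 + n)]
  atoms <- tibble::tibble(
    residue_number = as.integer(substr(rec, 1, 5)),
    residue = trimws(substr(rec, 6, 10)),
    name = trimws(substr(rec, 11, 15)),
    x = as.numeric(substr(rec, 21, 28)),
    y = as.numeric(substr(rec, 29, 36)),
    z = as.numeric(substr(rec, 37, 44)))
  box <- as.numeric(strsplit(trimws(lines[3 + n]), "\\s+")[[1]])[1:3]
  list(atoms = atoms, box = box)
}

#' @export
print.sam_system <- function(x, ...) {
  p <- x$pattern
  lab <- if (is.na(p$spacing_index) || p$hydrophilic_head == "methyl") {
    "all-methyl"
  } else {
    paste0("S", p$spacing_index, " ", p$hydrophilic_head, " (", p$layout, ")")
  }
  cat("<sam_system> ", lab, ": ",
      x$lattice$nx, "x", x$lattice$ny, " strands, ",
      nrow(x$atoms), " atoms, ", length(x$head_indices),
      " hydrophilic heads, box ",
      paste(signif(x$box, 4), collapse = " x "), " nm\n", sep = "")
  invisible(x)
}
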