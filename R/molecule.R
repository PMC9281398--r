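#' Covalent radii used for bond inference and clash detection
#'
#' Single-bond covalent radii in Angstrom for the elements that occur in
#' small organic molecules and peptides.
#' @keywords internal
COVALENT_RADII <- c(
  H = 0.31, He = 0.28, Li = 1.28, Be = 0.96, B = 0.84, C = 0.76,
  N = 0.71, O = 0.66, F = 0.57, Ne = 0.58, Na = 1.66, Mg = 1.41,
  Al = 1.21, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Ar = 1.06,
  K = 2.03, Ca = 1.76, Br = 1.20, I = 1.39
)

covalent_radius <- function(element) {
  r <- COVALENT_RADII[element]
  if (anyNA(r)) {
    abort(paste0("no covalent radius for element(s): ",
                 paste(unique(element[is.na(r)]), collapse = ", ")))
  }
  unname(r)
}

#' Define a flexible molecule as a rigid skeleton plus rotatable dihedrals
#'
#' A molecule is represented by its reference Cartesian geometry and an
#' ordered list of searchable dihedral angles.  Bond lengths, bond angles and
#' any dihedrals declared fixed are frozen at their reference values; only the
#' free dihedrals span the search space (dimensionality `D`).
#'
#' Atom indices are 0-based at every interface of this package; angles are in
#' degrees throughout.
#'
#' @param atoms Tibble/data frame with columns `element`, `x`, `y`, `z`
#'   (Angstrom): the reference geometry.
#' @param dihedrals Tibble with columns `a`, `b`, `c`, `d` (0-based atom
#'   indices) and optionally `low`, `high` (degrees, default 0/360) and
#'   `periodic` (default `TRUE`).  Symmetry-reduced dihedrals use a reduced
#'   range (e.g. `[0, 180]`) and are treated as periodic with span equal to
#'   the range length.
#' @param fixed Optional tibble with columns `a`, `b`, `c`, `d`, `value`:
#'   dihedrals clamped to `value` degrees during sampling.
#' @param name Text label.
#' @param bonds Optional two-column matrix of 0-based atom indices overriding
#'   the inferred bond graph.  By default bonds are inferred from the
#'   reference geometry with a covalent-radius criterion (factor 1.2).
#' @return An object of class `molecule_spec` with element `D`, the number of
#'   free dihedrals.
#' @export
molecule_spec <- function(atoms, dihedrals, fixed = NULL, name = "molecule",
                          bonds = NULL) {
  atoms <- as_tibble(atoms)
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  n <- nrow(atoms)
  dihedrals <- as_tibble(dihedrals)
  if (is.null(dihedrals[["low"]])) dihedrals$low <- 0
  if (is.null(dihedrals[["high"]])) dihedrals$high <- 360
  if (is.null(dihedrals[["periodic"]])) dihedrals$periodic <- TRUE

  idx <- as.matrix(dihedrals[, c("a", "b", "c", "d")])
  if (any(idx < 0) || any(idx >= n)) abort("dihedral atom index out of bounds")
  if (any(apply(idx, 1, function(r) length(unique(r)) != 4L))) {
    abort("the four atoms of a dihedral must be distinct")
  }
  with(dihedrals, stopifnot(all(low >= 0), all(low < high), all(high <= 360)))
  if (nrow(dihedrals) < 1) abort("at least one free dihedral is required (D >= 1)")

  if (!is.null(fixed)) {
    fixed <- as_tibble(fixed)
    fidx <- as.matrix(fixed[, c("a", "b", "c", "d")])
    if (any(fidx < 0) || any(fidx >= n)) abort("fixed dihedral index out of bounds")
  }

  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (is.null(bonds)) {
    bonds <- infer_bonds(atoms$element, coords)
  } else {
    bonds <- matrix(as.integer(bonds), ncol = 2) + 1L
  }

  spec <- structure(
    list(atoms = atoms, coords = coords, dihedrals = dihedrals,
         fixed = fixed, name = name, bonds = bonds,
         D = nrow(dihedrals)),
    class = "molecule_spec"
  )
  # Precompute, for every rotatable bond, the atom set rigidly attached to
  # the d-side; errors out if the bond lies in a ring.
  all_quads <- rbind(idx, if (!is.null(fixed)) as.matrix(fixed[, c("a","b","c","d")]))
  spec$rot_side <- lapply(seq_len(nrow(all_quads)), function(i) {
    q <- all_quads[i, ] + 1L
    rotating_side(spec$bonds, n, q[2], q[3], q[1])
  })
  spec$ranges <- tibble(low = dihedrals$low, high = dihedrals$high,
                        periodic = dihedrals$periodic)
  spec
}

#' @export
print.molecule_spec <- function(x, ...) {
  cat("<molecule_spec> ", x$name, ": ", nrow(x$atoms), " atoms, D = ", x$D,
      " free dihedral(s)", if (!is.null(x$fixed)) paste0(", ", nrow(x$fixed), " fixed"),
      "\n", sep = "")
  invisible(x)
}

# Bond graph from a covalent-radius distance criterion (factor 1.2).
infer_bonds <- function(elements, coords, factor = 1.2) {
  n <- nrow(coords)
  r <- covalent_radius(elements)
  d <- as.matrix(stats::dist(coords))
  thr <- factor * outer(r, r, "+")
  hit <- which(d < thr & upper.tri(d), arr.ind = TRUE)
  matrix(as.integer(hit), ncol = 2, dimnames = NULL)
}

# Atoms rigidly attached to atom `cc` when bond bb-cc is cut (1-based).
# `aa` is the a-side anchor; if it remains connected to cc the bond is in a
# ring and torsion driving is unsupported.
rotating_side <- function(bonds, n, bb, cc, aa) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(bonds))) {
    p <- bonds[i, 1]; q <- bonds[i, 2]
    adj[[p]] <- c(adj[[p]], q)
    adj[[q]] <- c(adj[[q]], p)
  }
  seen <- logical(n)
  seen[cc] <- TRUE
  frontier <- cc
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (!seen[w] && !(v == cc && w == bb) && !(v == bb && w == cc)) {
          # never cross the bb-cc bond
          if (!(v == cc && w == bb)) {
            seen[w] <- TRUE
            nxt <- c(nxt, w)
          }
        }
      }
    }
    frontier <- nxt
  }
  if (seen[bb] || seen[aa]) {
    abort("rotatable bond lies in a ring: unsupported topology")
  }
  setdiff(which(seen), cc)
}

#' Measure a single dihedral angle from Cartesian coordinates
#'
#' Standard four-point torsion: the angle between the half-plane containing
#' atom `a` and the half-plane containing atom `d`, about the `b`-`c` bond.
#' Returned in `[0, 360)` degrees; the trans arrangement measures 180.
#'
#' @param coords Numeric n-by-3 matrix (Angstrom).
#' @param quad Four 0-based atom indices `(a, b, c, d)`.
#' @return Dihedral angle in degrees, in `[0, 360)`.
#' @export
measure_dihedral <- function(coords, quad) {
  q <- as.integer(quad) + 1L
  p <- coords[q, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  u2 <- b2 / sqrt(sum(b2^2))
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, u2)
  theta <- atan2(sum(m1 * n2), sum(n1 * n2)) / DEG2RAD
  theta %% 360
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Measure all free dihedrals of a molecule
#'
#' @param spec A [molecule_spec()].
#' @param coords Coordinate matrix; defaults to the reference geometry.
#' @return Numeric vector of length `D`, each wrapped into its declared range.
#' @export
measure_dihedrals <- function(spec, coords = spec$coords) {
  idx <- as.matrix(spec$dihedrals[, c("a", "b", "c", "d")])
  raw <- vapply(seq_len(nrow(idx)), function(i) measure_dihedral(coords, idx[i, ]),
                numeric(1))
  wrap_angles(raw, spec$ranges)
}

#' Realize a conformation from a dihedral vector
#'
#' Rotates the rigid subtree on the `d`-side of each rotatable bond so that
#' every free dihedral takes the requested value and every fixed dihedral its
#' declared value, while all bond lengths and bond angles stay at their
#' reference values.
#'
#' @param spec A [molecule_spec()].
#' @param angles Degree vector of length `D`, inside the declared ranges.
#' @return A `conformation`: list with `angles`, `coords`, `energy`,
#'   `scaled_energy`, `valid`.
#' @export
apply_dihedrals <- function(spec, angles) {
  if (length(angles) != spec$D) abort("angles length must equal D")
  lo <- spec$ranges$low; hi <- spec$ranges$high
  if (any(angles < lo - 1e-9) || any(angles > hi + 1e-9)) {
    abort("requested dihedral outside its declared range")
  }
  coords <- spec$coords
  nfree <- spec$D
  quads <- as.matrix(spec$dihedrals[, c("a", "b", "c", "d")])
  targets <- angles
  if (!is.null(spec$fixed)) {
    quads <- rbind(quads, as.matrix(spec$fixed[, c("a", "b", "c", "d")]))
    targets <- c(targets, spec$fixed$value)
  }
  for (i in seq_len(nrow(quads))) {
    q <- quads[i, ] + 1L
    cur <- measure_dihedral(coords, quads[i, ])
    delta <- (targets[i] - cur) %% 360
    if (delta > 180) delta <- delta - 360
    if (abs(delta) < 1e-12) next
    axis_origin <- coords[q[3], ]
    u <- coords[q[3], ] - coords[q[2], ]
    u <- u / sqrt(sum(u^2))
    side <- spec$rot_side[[i]]
    # right-handed rotation about b->c by -delta increases the measured
    # dihedral by +delta (see measure_dihedral's sign convention)
    coords[side, ] <- rotate_about(coords[side, , drop = FALSE],
                                   axis_origin, u, -delta * DEG2RAD)
  }
  conformation(angles = angles, coords = coords)
}

rotate_about <- function(pts, origin, u, phi) {
  v <- sweep(pts, 2, origin)
  cosp <- cos(phi); sinp <- sin(phi)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  R <- diag(3) * cosp + sinp * K + (1 - cosp) * tcrossprod(u)
  sweep(v %*% t(R), 2, origin, "+")
}

#' Construct a conformation record
#'
#' @param angles Degree vector of free-dihedral values.
#' @param coords Optional n-by-3 coordinate matrix.
#' @param energy Raw backend energy in eV, or `NA`.
#' @param scaled_energy Scaled energy, or `NA`.
#' @param valid Logical validity flag; invalid conformations carry no energy.
#' @export
conformation <- function(angles, coords = NULL, energy = NA_real_,
                         scaled_energy = NA_real_, valid = TRUE) {
  if (!valid) energy <- NA_real_
  structure(list(angles = as.numeric(angles), coords = coords,
                 energy = energy, scaled_energy = scaled_energy,
                 valid = valid),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat("<conformation> D =", length(x$angles),
      if (!is.na(x$energy)) paste0(" E = ", signif(x$energy, 8), " eV"),
      if (!x$valid) " (invalid)", "\n")
  invisible(x)
}

#' Flag steric clashes
#'
#' A conformation clashes when any non-bonded atom pair is closer than
#' `scale` times the sum of the two covalent radii.  Directly bonded pairs
#' are exempt.  Clashing structures are treated as invalid and excluded from
#' the data pool, standing in for failed single-point calculations.
#'
#' @param conf A `conformation` with coordinates.
#' @param spec The owning [molecule_spec()] (supplies elements and bonds).
#' @param scale Clash threshold as a fraction of the covalent-radius sum;
#'   default 0.7.
#' @return `TRUE` if a clash is present.
#' @export
detect_clash <- function(conf, spec, scale = 0.7) {
  coords <- conf$coords
  if (is.null(coords)) abort("conformation has no coordinates")
  r <- covalent_radius(spec$atoms$element)
  d <- as.matrix(stats::dist(coords))
  thr <- scale * outer(r, r, "+")
  bonded <- matrix(FALSE, nrow(coords), nrow(coords))
  bonded[spec$bonds] <- TRUE
  bonded[spec$bonds[, 2:1, drop = FALSE]] <- TRUE
  close <- d < thr & upper.tri(d) & !bonded
  any(close)
}

#' Mean and maximum dihedral-space distance between two angle vectors
#'
#' Per-dimension differences are circular for periodic dimensions
#' (`min(|delta|, span - |delta|)` with span = range length) and absolute
#' otherwise.  Two structures are conventionally considered similar when the
#' mean is below 15 degrees; a target is reached when the maximum is below
#' 15 degrees.
#'
#' @param a,b Degree vectors of equal length.
#' @param ranges Tibble with columns `low`, `high`, `periodic`; defaults to
#'   full 360-degree periodic dimensions.
#' @return Named numeric vector `c(mean = , max = )` in degrees.
#' @export
dihedral_distance <- function(a, b, ranges = NULL) {
  if (length(a) != length(b)) abort("angle vectors differ in length")
  ranges <- as_ranges(ranges, length(a))
  d <- angle_diff(a, b, ranges)
  c(mean = mean(d), max = max(d))
}

#' Synthetic linear-chain molecule fixture
#'
#' Builds an acyclic n-atom chain (synthetic, alkane-like) with uniform bond
#' length 1.54 A and tetrahedral bond angles, all backbone dihedrals at 180
#' degrees, and declares the `n - 3` backbone torsions as free dihedrals.
#' Used as a self-contained geometry fixture in examples and tests.
#'
#' @param n Number of atoms (>= 4).
#' @param element Element symbol for every atom.
#' @return A [molecule_spec()].
#' @export
chain_molecule <- function(n = 8, element = "C") {
  stopifnot(n >= 4)
  r <- 1.54; ang <- 109.47
  coords <- matrix(0, n, 3)
  coords[2, ] <- c(r, 0, 0)
  coords[3, ] <- coords[2, ] + c(-r * cos(ang * DEG2RAD), r * sin(ang * DEG2RAD), 0)
  for (k in 4:n) {
    coords[k, ] <- place_atom(coords[k - 1, ], coords[k - 2, ], coords[k - 3, ],
                              r, ang, 180)
  }
  dih <- tibble(a = 0:(n - 4), b = 1:(n - 3), c = 2:(n - 2), d = 3:(n - 1),
                low = 0, high = 360, periodic = TRUE)
  molecule_spec(
    atoms = tibble(element = rep(element, n),
                   x = coords[, 1], y = coords[, 2], z = coords[, 3]),
    dihedrals = dih, name = paste0("chain", n)
  )
}

# NeRF-style placement: new atom at distance r from p1, angle ang (deg) with
# p2-p1, dihedral tau (deg) about p2-p1 relative to p3.
place_atom <- function(p1, p2, p3, r, ang, tau) {
  bc <- p1 - p2; bc <- bc / sqrt(sum(bc^2))
  ab <- p2 - p3
  n <- cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  a <- ang * DEG2RAD; t <- tau * DEG2RAD
  d2 <- c(-r * cos(a), r * sin(a) * cos(t), r * sin(a) * sin(t))
  p1 + d2[1] * bc + d2[2] * m + d2[3] * n
}
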