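#' Default energy parameters for atomistic graph construction
#'
#' Returns the full parameter set used to detect and weight covalent and
#' non-covalent interactions. All energies are kJ/mol, all distances
#' Angstrom. Every entry can be overridden by passing a named list of
#' replacements, so tests can pin constants and users can recalibrate
#' individual potentials without touching code.
#'
#' The four non-covalent potentials follow the standard functional
#' families used for energy-weighted protein graphs:
#' \itemize{
#'   \item hydrogen bonds: a 12-10 potential in the donor--acceptor
#'     distance modulated by the squared cosine of the D-H...A angle;
#'   \item hydrophobic contacts: a 12-6 Lennard-Jones well between apolar
#'     carbon/sulfur atoms;
#'   \item electrostatics: screened Coulomb between formally charged
#'     side-chain atoms with a distance-dependent dielectric;
#'   \item ring stacking: a 12-6 well in the ring-centroid distance for
#'     near-parallel aromatic rings.
#' }
#' Attractive (negative) energies are mapped to positive edge weights by
#' absolute value, since the Laplacian machinery requires nonnegative
#' weights.
#'
#' @param overrides named list; entries replace the corresponding default
#'   (top-level names only, e.g. `list(hbond = list(...))` replaces the
#'   whole hydrogen-bond block).
#' @return A list of class `bp_energy_params`.
#' @export
default_energy_parameters <- function(overrides = list()) {
  params <- list(
    # mean single/double bond enthalpies, kJ/mol, keyed "EL1-EL2" with
    # elements in alphabetical order; "=" marks bond order 2
    covalent_energies = c(
      "C-C" = 346, "C=C" = 602, "C-N" = 305, "C=N" = 615,
      "C-O" = 358, "C=O" = 749, "C-S" = 272, "C-H" = 411,
      "H-N" = 386, "H-O" = 459, "H-S" = 363, "N-N" = 167,
      "N=N" = 418, "N-O" = 201, "O-O" = 145, "O=O" = 498,
      "S-S" = 266, "H-H" = 436, "N-S" = 249, "O-S" = 265,
      "O-P" = 335, "O=P" = 544, "C-P" = 264, "N-P" = 290
    ),
    covalent_default_energy = 300,  # fallback for untabulated pairs
    # covalent radii for distance-based bond detection in non-template
    # groups (ligands, modified residues)
    covalent_radii = c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
                       P = 1.07, F = 0.57, CL = 1.02, BR = 1.2, I = 1.39,
                       SE = 1.2, FE = 1.32, ZN = 1.22, MG = 1.41, CA = 1.76,
                       MN = 1.39, "NA" = 1.66, K = 2.03, CU = 1.32, NI = 1.24),
    covalent_tolerance = 0.4,       # Angstrom added to radii sum
    hbond = list(
      D0 = 33.5,        # well depth, kJ/mol (8 kcal/mol)
      R0 = 2.75,        # equilibrium donor-acceptor distance
      max_DA = 3.5,     # detection: donor-acceptor distance ceiling
      min_angle = 120,  # detection: D-H...A angle floor, degrees
      angular_power = 2
    ),
    hydrophobic = list(
      epsilon = 0.65,   # well depth, kJ/mol (~ CH2-CH2 pair)
      sigma = 3.8,      # distance of minimum energy
      max_dist = 4.5    # detection ceiling between apolar atoms
    ),
    electrostatic = list(
      coulomb_k = 1389.35,       # kJ/mol * Angstrom for unit charges
      dielectric_slope = 4,      # eps_r = slope * r (distance screening)
      max_dist = 4.0             # salt-bridge detection ceiling
    ),
    pi_stacking = list(
      E0 = 8.0,          # well depth, kJ/mol
      d0 = 3.8,          # centroid-centroid equilibrium distance
      max_dist = 6.0,    # detection ceiling
      max_angle = 30     # max angle between ring normals, degrees
    ),
    # formal charges carried by side-chain atoms (salt-bridge definition)
    formal_charges = c(
      "LYS:NZ" = 1, "ARG:NH1" = 0.5, "ARG:NH2" = 0.5,
      "ASP:OD1" = -0.5, "ASP:OD2" = -0.5,
      "GLU:OE1" = -0.5, "GLU:OE2" = -0.5,
      "HIS:ND1" = 0.5, "HIS:NE2" = 0.5
    ),
    # aromatic ring definitions for stacking detection
    aromatic_rings = list(
      PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
      TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
      HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
      TRP = list(c("CG", "CD1", "CD2", "NE1", "CE2"),
                 c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"))
    ),
    hydrogen_attach_max = 1.5  # H bonded to nearest heavy atom under this
  )
  stopifnot(is.list(overrides))
  for (nm in names(overrides)) params[[nm]] <- overrides[[nm]]
  structure(params, class = "bp_energy_params")
}

# Look up the standard bond energy for an element pair and bond order.
covalent_energy <- function(params, el1, el2, order = 1) {
  pair <- paste(sort(c(toupper(el1), toupper(el2))),
                collapse = if (order >= 2) "=" else "-")
  e <- params$covalent_energies[pair]
  ifelse(is.na(e), params$covalent_default_energy, e)
}

#' Evaluate the hydrogen-bond potential
#'
#' 12-10 well in the donor--acceptor distance with an angular modulation
#' `cos(theta)^angular_power` for the D-H...A angle (theta = 180 deg is
#' ideal). Returns the (negative) energy in kJ/mol.
#'
#' @param r_DA donor-acceptor distance, Angstrom
#' @param theta D-H...A angle, degrees
#' @param p hydrogen-bond parameter block from [default_energy_parameters()]
#' @return numeric energy (negative = attractive)
#' @export
hbond_energy <- function(r_DA, theta, p) {
  rr <- p$R0 / r_DA
  ang <- cos(pi - theta * pi / 180)^p$angular_power
  -p$D0 * (5 * rr^12 - 6 * rr^10) * ang
}

# 12-6 Lennard-Jones well for apolar contacts.
hydrophobic_energy <- function(r, p) {
  rr <- p$sigma / r
  p$epsilon * (rr^12 - 2 * rr^6)
}

# Screened Coulomb with distance-dependent dielectric eps_r = slope * r.
electrostatic_energy <- function(r, q1, q2, p) {
  p$coulomb_k * q1 * q2 / (p$dielectric_slope * r * r)
}

# 12-6 well in the ring-centroid distance.
pi_stacking_energy <- function(d, p) {
  dd <- p$d0 / d
  p$E0 * (dd^12 - 2 * dd^6)
}

#' Read energy-parameter overrides from a key-value text file
#'
#' The file holds one `path.to.entry: value` pair per line (a minimal
#' YAML-like subset); blank lines and `#` comments are ignored. Values
#' are numeric. Nested entries use dots, e.g.
#' \preformatted{
#' hbond.D0: 30
#' hydrophobic.max_dist: 5.0
#' covalent_default_energy: 250
#' }
#'
#' @param path file to read
#' @param base parameter set to override
#' @return a `bp_energy_params` with the overrides applied
#' @export
read_energy_parameters <- function(path, base = default_energy_parameters()) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    keys <- strsplit(trimws(kv[1]), ".", fixed = TRUE)[[1]]
    val <- suppressWarnings(as.numeric(trimws(kv[2])))
    if (is.na(val)) stop("non-numeric value in config line: ", ln)
    base[[keys]] <- val
  }
  base
}
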