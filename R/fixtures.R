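# Idealized residue geometry used by make_mini_pdb. Coordinates are
# offsets from the residue origin (backbone N); standard bond lengths,
# laid out so detection criteria fire deterministically.
MINI_RES_OFFSETS <- list(
  common = list(N = c(0, 0, 0), H = c(0, -1.01, 0), CA = c(1.47, 0, 0),
                HA = c(1.47, 1.09, 0), C = c(2.99, 0, 0), O = c(2.99, 1.23, 0)),
  GLY = list(HA2 = c(1.47, 0, -1.09)),
  ALA = list(CB = c(1.47, 0, 1.53), HB1 = c(1.47, -1.09, 1.53),
             HB2 = c(2.24, 0.77, 1.53), HB3 = c(0.70, 0.77, 1.53)),
  SER = list(CB = c(1.47, 0, 1.53), HB2 = c(2.24, 0.77, 1.53),
             HB3 = c(0.70, 0.77, 1.53), OG = c(1.47, 0, 2.96),
             HG = c(1.47, 0, 3.92)),
  CYS = list(CB = c(1.47, 0, 1.53), HB2 = c(2.24, 0.77, 1.53),
             HB3 = c(0.70, 0.77, 1.53), SG = c(1.47, 0, 3.34),
             HG = c(2.81, 0, 3.34))
)
MINI_PITCH <- 4.32  # residue-to-residue x spacing, gives C-N(+1) = 1.33

#' Generate a tiny idealized peptide PDB with planted interactions
#'
#' Builds a short extended peptide (ALA/GLY/SER/CYS repertoire) with
#' hydrogens at template geometry, plus an optional two-atom
#' pseudo-ligand positioned so its oxygen accepts a hydrogen bond from
#' one backbone amide at ideal geometry (donor-acceptor 2.91 Angstrom,
#' collinear). Adjacent ALA/CYS side chains sit 4.32 Angstrom apart,
#' planting hydrophobic contacts. The returned truth table lists every
#' intended interaction so graph construction can be checked against
#' generator bookkeeping rather than against itself.
#'
#' @param n_res number of residues (>= 2)
#' @param sequence residue names drawn from ALA/GLY/SER/CYS; default is
#'   a fixed ALA-rich pattern of length `n_res`
#' @param ligand add the hydrogen-bond-accepting pseudo-ligand (LIG)
#' @param ligand_res index of the residue whose amide the ligand binds
#' @param seed seed for the coordinate jitter; with `jitter = 0` the
#'   geometry is fully deterministic and equal seeds trivially give
#'   identical bytes
#' @param jitter standard deviation (Angstrom) of Gaussian coordinate
#'   noise. The default 0 keeps the planted geometries exact (hand-
#'   evaluable potentials); a small value (~0.1) breaks the perfect
#'   translational symmetry of the idealized chain, which is needed when
#'   surrogate-site sampling must find sites of strictly smaller
#'   diameter. Planted interactions stay within their detection windows
#'   for jitter up to ~0.1.
#' @param path optional file to write the PDB text to
#' @return list with `pdb` (character lines), `model` (parsed
#'   `bp_structure`) and `truth` (list: atom counts, covalent bond
#'   count, planted hydrogen bonds and hydrophobic contacts)
#' @export
make_mini_pdb <- function(n_res = 8, sequence = NULL, ligand = TRUE,
                          ligand_res = ceiling(n_res / 2), seed = 1,
                          jitter = 0, path = NULL) {
  stopifnot(n_res >= 2)
  if (is.null(sequence))
    sequence <- rep(c("ALA", "ALA", "SER", "ALA", "CYS", "ALA", "GLY", "ALA"),
                    length.out = n_res)
  stopifnot(all(sequence %in% names(MINI_RES_OFFSETS)[-1]))
  rows <- list()
  serial <- 0
  emit <- function(name, el, res_name, res_seq, xyz, het = FALSE) {
    serial <<- serial + 1
    rows[[length(rows) + 1]] <<- data.frame(
      record = if (het) "HETATM" else "ATOM", serial = serial, name = name,
      res_name = res_name, res_seq = res_seq, x = xyz[1], y = xyz[2],
      z = xyz[3], element = el, stringsAsFactors = FALSE)
  }
  n_heavy_bonds <- 0; n_h_bonds <- 0
  for (i in seq_len(n_res)) {
    org <- c((i - 1) * MINI_PITCH, 0, 0)
    offs <- c(MINI_RES_OFFSETS$common, MINI_RES_OFFSETS[[sequence[i]]])
    if (i == n_res) offs$OXT <- c(2.99, -1.23, 0)
    for (nm in names(offs)) {
      el <- if (grepl("^H", nm)) "H" else substr(nm, 1, 1)
      emit(nm, el, sequence[i], i, org + offs[[nm]])
    }
    n_heavy_bonds <- n_heavy_bonds +
      switch(sequence[i], GLY = 3, ALA = 4, SER = 5, CYS = 5) +
      (i == n_res)  # OXT
    n_h_bonds <- n_h_bonds + sum(grepl("^H", names(offs)))
  }
  hb <- NULL
  if (ligand) {
    xk <- (ligand_res - 1) * MINI_PITCH
    emit("O1", "O", "LIG", n_res + 1, c(xk, -2.91, 0), het = TRUE)
    emit("C1", "C", "LIG", n_res + 1, c(xk, -4.11, 0), het = TRUE)
    n_heavy_bonds <- n_heavy_bonds + 1
    hb <- data.frame(donor = sprintf("A:%d:N", ligand_res),
                     acceptor = sprintf("A:%d:O1", n_res + 1),
                     r_DA = 2.91, angle = 180)
  }
  adj <- sequence[-n_res] %in% c("ALA", "CYS") & sequence[-1] %in% c("ALA", "CYS")
  hydrophobic <- data.frame(res_i = which(adj), res_j = which(adj) + 1,
                            atom = "CB", dist = MINI_PITCH)
  df <- do.call(rbind, rows)
  if (jitter > 0) {
    set.seed(seed)
    df$x <- df$x + rnorm(nrow(df), 0, jitter)
    df$y <- df$y + rnorm(nrow(df), 0, jitter)
    df$z <- df$z + rnorm(nrow(df), 0, jitter)
  }
  lines <- sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   df$record, df$serial,
                   ifelse(nchar(df$name) >= 4, sprintf("%-4s", df$name),
                          sprintf(" %-3s", df$name)),
                   df$res_name, "A", df$res_seq, df$x, df$y, df$z, 1, 0,
                   df$element)
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  truth <- list(
    seed = seed, n_res = n_res, sequence = sequence,
    n_atoms = nrow(df),
    n_covalent = n_heavy_bonds + n_h_bonds + (n_res - 1),  # + peptide links
    hydrogen_bonds = hb,
    hydrophobic_contacts = hydrophobic,
    ligand = if (ligand) sprintf("A:LIG:%d", n_res + 1) else NULL)
  list(pdb = lines, model = parse_pdb(lines), truth = truth)
}

#' Generate a random connected weighted graph with coordinates
#'
#' A spanning tree plus random extra edges, positive uniform weights,
#' uniform coordinates in a cubic box, and residues assigned in
#' consecutive blocks, shaped exactly like an atomistic graph so every
#' downstream stage (Laplacian, propensities, scoring, surrogates)
#' accepts it.
#'
#' @param n nodes (>= 3)
#' @param extra_edges edges added beyond the spanning tree
#' @param block_size atoms per pseudo-residue
#' @param box box side length, Angstrom
#' @param seed RNG seed
#' @return a `bp_graph`
#' @export
make_random_graph <- function(n = 20, extra_edges = round(n / 2),
                              block_size = 4, box = 30, seed = 1) {
  stopifnot(n >= 3)
  set.seed(seed)
  i <- integer(); j <- integer()
  for (v in 2:n) {
    u <- sample.int(v - 1, 1)
    i <- c(i, u); j <- c(j, v)
  }
  tries <- 0
  while (extra_edges > 0 && tries < 50 * extra_edges) {
    tries <- tries + 1
    uv <- sort(sample.int(n, 2))
    if (!any(i == uv[1] & j == uv[2])) {
      i <- c(i, uv[1]); j <- c(j, uv[2])
      extra_edges <- extra_edges - 1
    }
  }
  m <- length(i)
  w <- runif(m, 0.5, 3)
  xyz <- matrix(runif(3 * n, 0, box), n, 3)
  res_seq <- (seq_len(n) - 1) %/% block_size + 1
  atoms <- data.frame(
    record = "ATOM", serial = seq_len(n), name = "X", altloc = "",
    res_name = "RES", chain = "A", res_seq = res_seq, icode = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occupancy = 1, bfactor = 0,
    element = "C", category = "protein",
    res_uid = residue_uid("A", res_seq, ""), atom_id = seq_len(n),
    stringsAsFactors = FALSE)
  ord <- order(i, j)
  bonds <- data.frame(
    edge_id = seq_len(m), i = i[ord], j = j[ord], kind = "generic",
    weight = w[ord],
    dist = sqrt(rowSums((xyz[i[ord], , drop = FALSE] -
                           xyz[j[ord], , drop = FALSE])^2)),
    mx = (xyz[i[ord], 1] + xyz[j[ord], 1]) / 2,
    my = (xyz[i[ord], 2] + xyz[j[ord], 2]) / 2,
    mz = (xyz[i[ord], 3] + xyz[j[ord], 3]) / 2)
  structure(list(atoms = atoms, bonds = bonds, n = n, m = m,
                 log = sprintf("random graph n=%d m=%d seed=%d", n, m, seed)),
            class = "bp_graph")
}

#' Generate propensity data with a planted exponential distance decay
#'
#' Draws distances uniformly on (0, `dmax`) and log propensities as
#' `intercept + slope * d + N(0, noise_sd)`, the generative model the
#' quantile-regression stage assumes.
#'
#' @param n sample size (>= 100)
#' @param intercept,slope planted linear coefficients for log propensity
#' @param noise_sd Gaussian noise standard deviation (0 allowed)
#' @param dmax maximum distance, Angstrom
#' @param seed RNG seed
#' @return data.frame with columns `prop` and `dist`; planted parameters
#'   attached as attribute `"truth"`
#' @export
make_planted_decay <- function(n = 1000, intercept = -8, slope = -0.3,
                               noise_sd = 1, dmax = 30, seed = 1) {
  stopifnot(n >= 100)
  set.seed(seed)
  d <- runif(n, 0, dmax)
  lp <- intercept + slope * d + rnorm(n, 0, noise_sd)
  out <- data.frame(prop = exp(lp), dist = d)
  attr(out, "truth") <- list(intercept = intercept, slope = slope,
                             noise_sd = noise_sd, dmax = dmax, seed = seed)
  out
}
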