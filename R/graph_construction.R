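# Heavy-atom connectivity templates for the 20 standard amino acids.
# Backbone bonds (N-CA, CA-C, C=O, CA-CB) are shared; entries here list
# side-chain bonds as c(atom1, atom2, order).
BACKBONE_BONDS <- list(c("N", "CA", 1), c("CA", "C", 1), c("C", "O", 2))

SIDECHAIN_BONDS <- list(
  ALA = list(),
  ARG = list(c("CB","CG",1), c("CG","CD",1), c("CD","NE",1), c("NE","CZ",1),
             c("CZ","NH1",2), c("CZ","NH2",1)),
  ASN = list(c("CB","CG",1), c("CG","OD1",2), c("CG","ND2",1)),
  ASP = list(c("CB","CG",1), c("CG","OD1",2), c("CG","OD2",1)),
  CYS = list(c("CB","SG",1)),
  GLN = list(c("CB","CG",1), c("CG","CD",1), c("CD","OE1",2), c("CD","NE2",1)),
  GLU = list(c("CB","CG",1), c("CG","CD",1), c("CD","OE1",2), c("CD","OE2",1)),
  GLY = list(),
  HIS = list(c("CB","CG",1), c("CG","ND1",1), c("CG","CD2",2),
             c("ND1","CE1",2), c("CD2","NE2",1), c("CE1","NE2",1)),
  ILE = list(c("CB","CG1",1), c("CB","CG2",1), c("CG1","CD1",1)),
  LEU = list(c("CB","CG",1), c("CG","CD1",1), c("CG","CD2",1)),
  LYS = list(c("CB","CG",1), c("CG","CD",1), c("CD","CE",1), c("CE","NZ",1)),
  MET = list(c("CB","CG",1), c("CG","SD",1), c("SD","CE",1)),
  PHE = list(c("CB","CG",1), c("CG","CD1",2), c("CD1","CE1",1), c("CE1","CZ",2),
             c("CZ","CE2",1), c("CE2","CD2",2), c("CD2","CG",1)),
  PRO = list(c("CB","CG",1), c("CG","CD",1), c("CD","N",1)),
  SER = list(c("CB","OG",1)),
  THR = list(c("CB","OG1",1), c("CB","CG2",1)),
  TRP = list(c("CB","CG",1), c("CG","CD1",2), c("CD1","NE1",1), c("NE1","CE2",1),
             c("CE2","CD2",1), c("CD2","CG",1), c("CD2","CE3",2), c("CE3","CZ3",1),
             c("CZ3","CH2",2), c("CH2","CZ2",1), c("CZ2","CE2",2)),
  TYR = list(c("CB","CG",1), c("CG","CD1",2), c("CD1","CE1",1), c("CE1","CZ",2),
             c("CZ","CE2",1), c("CE2","CD2",2), c("CD2","CG",1), c("CZ","OH",1)),
  VAL = list(c("CB","CG1",1), c("CB","CG2",1))
)

residue_template_bonds <- function(res_name, atom_names) {
  tpl <- c(BACKBONE_BONDS,
           if (res_name != "GLY") list(c("CA", "CB", 1)),
           SIDECHAIN_BONDS[[res_name]],
           if ("OXT" %in% atom_names) list(c("C", "OXT", 1)))
  Filter(function(b) b[1] %in% atom_names && b[2] %in% atom_names, tpl)
}

# All index pairs (rows of a 2-column matrix) with inter-point distance
# <= cutoff, between point sets X and Y (n x 3 matrices), via cell
# binning so cost stays near-linear in the number of atoms.
pairs_within <- function(X, Y, cutoff, ix = seq_len(nrow(X)), iy = seq_len(nrow(Y))) {
  if (length(ix) == 0 || length(iy) == 0)
    return(data.frame(i = integer(), j = integer(), d = numeric()))
  Xs <- X[ix, , drop = FALSE]; Ys <- Y[iy, , drop = FALSE]
  cell <- function(M) floor(sweep(M, 2, apply(rbind(Xs, Ys), 2, min)) / cutoff)
  cy <- cell(Ys)
  keyy <- paste(cy[, 1], cy[, 2], cy[, 3])
  ymap <- split(seq_along(iy), keyy)
  cx <- cell(Xs)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_i <- integer(); out_j <- integer(); out_d <- numeric()
  for (a in seq_along(ix)) {
    keys <- paste(cx[a, 1] + off[, 1], cx[a, 2] + off[, 2], cx[a, 3] + off[, 3])
    cand <- unlist(ymap[keys], use.names = FALSE)
    if (!length(cand)) next
    dd <- sqrt(colSums((t(Ys[cand, , drop = FALSE]) - Xs[a, ])^2))
    ok <- dd <= cutoff
    if (any(ok)) {
      out_i <- c(out_i, rep(ix[a], sum(ok)))
      out_j <- c(out_j, iy[cand[ok]])
      out_d <- c(out_d, dd[ok])
    }
  }
  data.frame(i = out_i, j = out_j, d = out_d)
}

atom_dist <- function(atoms, i, j) {
  sqrt((atoms$x[i] - atoms$x[j])^2 + (atoms$y[i] - atoms$y[j])^2 +
         (atoms$z[i] - atoms$z[j])^2)
}

#' Detect covalent bonds
#'
#' Intra-residue bonds for the 20 standard amino acids come from a
#' residue-template dictionary; hydrogens are attached to the nearest
#' heavy atom of their residue; peptide C-N links, disulfides and
#' ligand/non-template bonds are detected by covalent-radius distance
#' criteria. Each bond is weighted by the standard bond energy (kJ/mol)
#' for its element pair and bond order.
#'
#' @param model a protonated `bp_structure`
#' @param params energy parameters from [default_energy_parameters()]
#' @return data.frame of bonds: columns `i`, `j` (atom ids), `kind`,
#'   `weight`, `dist`
#' @export
detect_covalent <- function(model, params = default_energy_parameters()) {
  a <- model$atoms
  bonds_i <- integer(); bonds_j <- integer(); weight <- numeric()
  add <- function(i, j, order = 1) {
    bonds_i <<- c(bonds_i, i); bonds_j <<- c(bonds_j, j)
    weight <<- c(weight, covalent_energy(params, a$element[i], a$element[j], order))
  }
  res_split <- split(seq_len(nrow(a)), a$res_uid)
  templated <- logical(nrow(a))
  for (idx in res_split) {
    rn <- a$res_name[idx[1]]
    heavy <- idx[a$element[idx] != "H"]
    hyd <- idx[a$element[idx] == "H"]
    if (rn %in% STANDARD_AA) {
      templated[idx] <- TRUE
      nm <- a$name[heavy]
      for (b in residue_template_bonds(rn, nm)) {
        i <- heavy[match(b[1], nm)]; j <- heavy[match(b[2], nm)]
        add(i, j, as.numeric(b[3]))
      }
    } else if (length(heavy) > 1) {
      # non-template group: covalent-radius criterion within the group
      ri <- params$covalent_radii[a$element[heavy]]
      ri[is.na(ri)] <- 0.77
      pr <- pairs_within(as.matrix(a[heavy, c("x", "y", "z")]),
                         as.matrix(a[heavy, c("x", "y", "z")]),
                         max(ri) * 2 + params$covalent_tolerance)
      pr <- pr[pr$i < pr$j, ]
      keep <- pr$d <= ri[pr$i] + ri[pr$j] + params$covalent_tolerance
      for (k in which(keep)) add(heavy[pr$i[k]], heavy[pr$j[k]])
    }
    # hydrogens: nearest heavy atom of the same residue
    for (h in hyd) {
      if (!length(heavy)) next
      d <- atom_dist(a, h, heavy)
      if (min(d) <= params$hydrogen_attach_max) add(h, heavy[which.min(d)])
    }
  }
  # peptide bonds: consecutive residues (author numbering) within a chain
  prot <- a[a$category == "protein", ]
  for (ch in unique(prot$chain)) {
    sub <- unique(prot[prot$chain == ch, c("res_uid", "res_seq", "icode")])
    uids <- sub$res_uid[order(sub$res_seq, sub$icode)]
    if (length(uids) < 2) next
    for (k in seq_len(length(uids) - 1)) {
      ci <- a$atom_id[a$res_uid == uids[k] & a$name == "C"]
      ni <- a$atom_id[a$res_uid == uids[k + 1] & a$name == "N"]
      if (length(ci) == 1 && length(ni) == 1 && atom_dist(a, ci, ni) < 1.8)
        add(ci, ni)
    }
  }
  # disulfides
  sg <- which(a$name == "SG" & a$res_name == "CYS")
  if (length(sg) > 1) {
    pr <- pairs_within(as.matrix(a[sg, c("x", "y", "z")]),
                       as.matrix(a[sg, c("x", "y", "z")]), 2.3)
    pr <- pr[pr$i < pr$j, ]
    for (k in seq_len(nrow(pr))) add(sg[pr$i[k]], sg[pr$j[k]])
  }
  # covalent ligand-protein links (rare): radius criterion across groups
  lig <- which(a$category == "ligand" & a$element != "H")
  prot_heavy <- which(a$category == "protein" & a$element != "H")
  if (length(lig) && length(prot_heavy)) {
    pr <- pairs_within(as.matrix(a[, c("x", "y", "z")]),
                       as.matrix(a[, c("x", "y", "z")]), 2.2,
                       ix = lig, iy = prot_heavy)
    ri <- params$covalent_radii
    for (k in seq_len(nrow(pr))) {
      r1 <- ri[a$element[pr$i[k]]]; r2 <- ri[a$element[pr$j[k]]]
      if (is.na(r1)) r1 <- 0.77
      if (is.na(r2)) r2 <- 0.77
      if (pr$d[k] <= r1 + r2 + params$covalent_tolerance) add(pr$i[k], pr$j[k])
    }
  }
  data.frame(i = bonds_i, j = bonds_j,
             kind = rep("covalent", length(bonds_i)), weight = weight,
             dist = atom_dist(a, bonds_i, bonds_j), stringsAsFactors = FALSE)
}

# neighbor sets up to 2 covalent bonds, used to exclude 1-2 and 1-3
# pairs from non-covalent detection
covalent_exclusion <- function(n, cov) {
  nb <- vector("list", n)
  for (k in seq_len(nrow(cov))) {
    nb[[cov$i[k]]] <- c(nb[[cov$i[k]]], cov$j[k])
    nb[[cov$j[k]]] <- c(nb[[cov$j[k]]], cov$i[k])
  }
  excl <- new.env(hash = TRUE, size = max(n, 16L))
  mark <- function(i, j) assign(paste(min(i, j), max(i, j)), TRUE, envir = excl)
  for (i in seq_len(n)) {
    for (j in nb[[i]]) {
      if (j > i) mark(i, j)
      for (k in nb[[j]]) if (k != i && k > i) mark(i, k)
    }
  }
  excl
}

is_excluded <- function(excl, i, j) {
  i < 0 || exists(paste(min(i, j), max(i, j)), envir = excl, inherits = FALSE)
}

#' Detect non-covalent interactions
#'
#' Four interaction types are detected by geometric criteria and weighted
#' by the corresponding potential evaluated at the observed geometry:
#' hydrogen bonds (12-10 angular-modulated well), hydrophobic contacts
#' (12-6 well between apolar C/S atoms), electrostatic/salt-bridge
#' contacts (screened Coulomb between formally charged atoms) and
#' aromatic ring stacking (12-6 well in the centroid distance of
#' near-parallel rings). The cutoffs here are detection criteria only; no
#' distance cutoff is applied anywhere downstream. Pairs that are 1-2 or
#' 1-3 covalent neighbors are excluded. Ligand atoms are typed by
#' element (donor/acceptor/hydrophobe), which is logged.
#'
#' @inheritParams detect_covalent
#' @param covalent data.frame from [detect_covalent()]
#' @return data.frame of bonds with columns `i`, `j`, `kind`, `weight`, `dist`
#' @export
detect_noncovalent <- function(model, params = default_energy_parameters(),
                               covalent = detect_covalent(model, params)) {
  a <- model$atoms
  n <- nrow(a)
  XYZ <- as.matrix(a[, c("x", "y", "z")])
  excl <- covalent_exclusion(n, covalent)
  hnb <- vector("list", n)  # attached hydrogens per heavy atom
  for (k in seq_len(nrow(covalent))) {
    i <- covalent$i[k]; j <- covalent$j[k]
    if (a$element[i] == "H") hnb[[j]] <- c(hnb[[j]], i)
    if (a$element[j] == "H") hnb[[i]] <- c(hnb[[i]], j)
  }
  heavy_nb <- vector("list", n)
  for (k in seq_len(nrow(covalent))) {
    i <- covalent$i[k]; j <- covalent$j[k]
    if (a$element[j] != "H") heavy_nb[[i]] <- c(heavy_nb[[i]], j)
    if (a$element[i] != "H") heavy_nb[[j]] <- c(heavy_nb[[j]], i)
  }
  out <- list()
  emit <- function(i, j, kind, energy) {
    out[[length(out) + 1]] <<- data.frame(
      i = i, j = j, kind = kind, weight = abs(energy),
      dist = atom_dist(a, i, j), stringsAsFactors = FALSE)
  }

  ## hydrogen bonds
  has_h <- lengths(hnb) > 0
  donors <- which(a$element %in% c("N", "O", "S") & has_h)
  acceptors <- which(a$element %in% c("O", "S") |
                       (a$element == "N" & !has_h))
  pr <- pairs_within(XYZ, XYZ, params$hbond$max_DA, donors, acceptors)
  for (k in seq_len(nrow(pr))) {
    d <- pr$i[k]; acc <- pr$j[k]
    if (d == acc || is_excluded(excl, d, acc)) next
    # best D-H...A angle over the donor's hydrogens
    best <- -Inf
    for (h in hnb[[d]]) {
      v1 <- XYZ[d, ] - XYZ[h, ]; v2 <- XYZ[acc, ] - XYZ[h, ]
      ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                 (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
      if (ang > best) best <- ang
    }
    if (best >= params$hbond$min_angle)
      emit(d, acc, "hydrogen_bond", hbond_energy(pr$d[k], best, params$hbond))
  }

  ## hydrophobic contacts: C/S atoms with no covalent N/O neighbor
  apolar <- which(a$element %in% c("C", "S") &
                    !vapply(seq_len(n), function(i)
                      any(a$element[heavy_nb[[i]]] %in% c("N", "O")), logical(1)))
  pr <- pairs_within(XYZ, XYZ, params$hydrophobic$max_dist, apolar, apolar)
  pr <- pr[pr$i < pr$j & a$res_uid[pr$i] != a$res_uid[pr$j], ]
  for (k in seq_len(nrow(pr))) {
    if (is_excluded(excl, pr$i[k], pr$j[k])) next
    emit(pr$i[k], pr$j[k], "hydrophobic",
         hydrophobic_energy(pr$d[k], params$hydrophobic))
  }

  ## electrostatics between formally charged atoms (opposite signs)
  qkey <- paste(a$res_name, a$name, sep = ":")
  q <- params$formal_charges[qkey]
  q[is.na(q)] <- 0
  charged <- which(q != 0)
  pr <- pairs_within(XYZ, XYZ, params$electrostatic$max_dist, charged, charged)
  pr <- pr[pr$i < pr$j, ]
  for (k in seq_len(nrow(pr))) {
    i <- pr$i[k]; j <- pr$j[k]
    if (q[i] * q[j] >= 0 || a$res_uid[i] == a$res_uid[j]) next
    if (is_excluded(excl, i, j)) next
    emit(i, j, "electrostatic",
         electrostatic_energy(pr$d[k], q[i], q[j], params$electrostatic))
  }

  ## aromatic ring stacking
  rings <- list()
  for (idx in split(seq_len(n), a$res_uid)) {
    rn <- a$res_name[idx[1]]
    for (ring_atoms in params$aromatic_rings[[rn]]) {
      ring_idx <- idx[match(ring_atoms, a$name[idx])]
      if (anyNA(ring_idx)) next
      P <- XYZ[ring_idx, , drop = FALSE]
      centroid <- colMeans(P)
      sv <- svd(sweep(P, 2, centroid))
      rings[[length(rings) + 1]] <- list(
        centroid = centroid, normal = sv$v[, 3],
        anchor = ring_idx[1], uid = a$res_uid[idx[1]])
    }
  }
  if (length(rings) > 1) {
    for (u in seq_len(length(rings) - 1)) for (v in (u + 1):length(rings)) {
      if (rings[[u]]$uid == rings[[v]]$uid) next
      d <- sqrt(sum((rings[[u]]$centroid - rings[[v]]$centroid)^2))
      if (d > params$pi_stacking$max_dist) next
      ang <- acos(pmin(1, abs(sum(rings[[u]]$normal * rings[[v]]$normal)))) * 180 / pi
      if (ang <= params$pi_stacking$max_angle)
        emit(rings[[u]]$anchor, rings[[v]]$anchor, "pi_pi",
             pi_stacking_energy(d, params$pi_stacking))
    }
  }
  if (!length(out))
    return(data.frame(i = integer(), j = integer(), kind = character(),
                      weight = numeric(), dist = numeric()))
  res <- do.call(rbind, out)
  res[res$weight > 0, , drop = FALSE]
}

#' Assemble the energy-weighted atomistic graph
#'
#' Merges covalent and non-covalent edges, deduplicates atom pairs
#' (keeping the strongest edge when several rules hit the same pair),
#' computes bond midpoints, drops isolated atoms with a log entry, and
#' reports per-type edge counts.
#'
#' @inheritParams detect_covalent
#' @return object of class `bp_graph`: list with `atoms`, `bonds`
#'   (edge table with `edge_id`, endpoints `i`/`j` as row indices into
#'   `atoms`, `kind`, `weight`, midpoint columns `mx`/`my`/`mz`),
#'   `n`, `m`, and `log`.
#' @export
assemble_graph <- function(model, params = default_energy_parameters()) {
  cov <- detect_covalent(model, params)
  ncv <- detect_noncovalent(model, params, cov)
  bonds <- rbind(cov, ncv)
  if (nrow(bonds) == 0) stop("assembled graph has no edges")
  ii <- pmin(bonds$i, bonds$j); jj <- pmax(bonds$i, bonds$j)
  bonds$i <- ii; bonds$j <- jj
  key <- paste(ii, jj)
  # covalent edges always win; otherwise keep the strongest
  bonds <- bonds[order(key, bonds$kind != "covalent", -bonds$weight), ]
  bonds <- bonds[!duplicated(paste(bonds$i, bonds$j)), ]
  bonds <- bonds[order(bonds$i, bonds$j), ]

  a <- model$atoms
  deg <- tabulate(c(bonds$i, bonds$j), nbins = nrow(a))
  keep <- which(deg > 0)
  dropped <- nrow(a) - length(keep)
  remap <- match(seq_len(nrow(a)), keep)
  atoms <- a[keep, , drop = FALSE]
  atoms$atom_id <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
  bonds$edge_id <- seq_len(nrow(bonds))
  bonds$mx <- (atoms$x[bonds$i] + atoms$x[bonds$j]) / 2
  bonds$my <- (atoms$y[bonds$i] + atoms$y[bonds$j]) / 2
  bonds$mz <- (atoms$z[bonds$i] + atoms$z[bonds$j]) / 2
  rownames(bonds) <- NULL
  counts <- table(bonds$kind)
  log <- c(model$log,
           sprintf("graph: n=%d atoms (%d isolated dropped), m=%d edges [%s]",
                   nrow(atoms), dropped, nrow(bonds),
                   paste(names(counts), as.integer(counts), sep = "=",
                         collapse = ", ")))
  if (any(a$category[keep] == "ligand"))
    log <- c(log, "ligand atoms typed by element for non-covalent detection")
  structure(list(atoms = atoms,
                 bonds = bonds[, c("edge_id", "i", "j", "kind", "weight",
                                   "dist", "mx", "my", "mz")],
                 n = nrow(atoms), m = nrow(bonds), log = log),
            class = "bp_graph")
}

#' @export
print.bp_graph <- function(x, ...) {
  counts <- table(x$bonds$kind)
  cat(sprintf("<bp_graph> n=%d atoms, m=%d edges (%s)\n", x$n, x$m,
              paste(names(counts), as.integer(counts), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' Incidence and weight matrices of an atomistic graph
#'
#' @param graph a `bp_graph`
#' @return list with `B`, the sparse n x m signed incidence matrix (one
#'   +1 and one -1 per edge column, orientation fixed as i -> j), and
#'   `W`, the m x m diagonal matrix of edge weights.
#' @export
incidence_and_weights <- function(graph) {
  m <- graph$m
  B <- Matrix::sparseMatrix(
    i = c(graph$bonds$i, graph$bonds$j),
    j = rep(seq_len(m), 2),
    x = rep(c(1, -1), each = m),
    dims = c(graph$n, m))
  list(B = B, W = Matrix::Diagonal(m, graph$bonds$weight))
}

#' Export the edge list for debugging
#'
#' Writes a tab-separated table (atom_i, atom_j, kind, weight, distance).
#'
#' @param graph a `bp_graph`
#' @param path output file
#' @export
write_edge_list <- function(graph, path) {
  b <- graph$bonds
  a <- graph$atoms
  df <- data.frame(
    atom_i = paste0(a$res_uid[b$i], ":", a$name[b$i]),
    atom_j = paste0(a$res_uid[b$j], ":", a$name[b$j]),
    kind = b$kind, weight = b$weight, distance = b$dist)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
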