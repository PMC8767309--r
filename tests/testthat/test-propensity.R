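# path graph 1-2-3 with unit weights, built by hand
path3 <- function(w = c(1, 1)) {
  atoms <- data.frame(
    record = "ATOM", serial = 1:3, name = "X", altloc = "", res_name = "RES",
    chain = "A", res_seq = 1:3, icode = "", x = c(0, 1, 2), y = 0, z = 0,
    occupancy = 1, bfactor = 0, element = "C", category = "protein",
    res_uid = paste0("A:", 1:3), atom_id = 1:3, stringsAsFactors = FALSE)
  bonds <- data.frame(edge_id = 1:2, i = 1:2, j = 2:3, kind = "generic",
                      weight = w, dist = 1, mx = c(0.5, 1.5), my = 0, mz = 0)
  structure(list(atoms = atoms, bonds = bonds, n = 3L, m = 2L, log = ""),
            class = "bp_graph")
}

src_of <- function(graph, edge_ids) {
  structure(list(edge_ids = edge_ids, atom_ids = unique(
    c(graph$bonds$i[edge_ids], graph$bonds$j[edge_ids])),
    mode = "residues", component = 1L, description = "test"),
    class = "bp_source")
}

test_that("weighted_laplacian matches its definition and B W B'", {
  L <- as.matrix(weighted_laplacian(path3()))
  expect_equal(unname(L), rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)))
  g <- make_random_graph(n = 25, seed = 4)
  Lg <- weighted_laplacian(g)
  expect_equal(max(abs(Lg %*% rep(1, g$n))), 0, tolerance = 1e-12)
  iw <- incidence_and_weights(g)
  expect_equal(as.matrix(Lg), as.matrix(iw$B %*% iw$W %*% Matrix::t(iw$B)),
               tolerance = 1e-12)
})

test_that("raw propensities match the dense pseudoinverse oracle", {
  # path: solve-based result equals 3-node dense oracle
  g <- path3()
  raw <- raw_propensities(g, src_of(g, 1L))
  oracle <- dense_raw_oracle(g, 1L)
  expect_equal(unname(raw), oracle, tolerance = 1e-10)
  # self-coupling |M_b0,b0| matches for a single-edge source
  g2 <- make_random_graph(n = 30, seed = 5)
  b0 <- 7L
  raw2 <- raw_propensities(g2, src_of(g2, b0))
  oracle2 <- dense_raw_oracle(g2, b0)
  expect_equal(unname(raw2[b0]), oracle2[b0], tolerance = 1e-8)
  scale <- max(oracle2)
  expect_lt(max(abs(raw2 - oracle2)) / scale, 1e-8)
})

test_that("4-cycle symmetry: edges adjacent to the source are equivalent", {
  atoms <- data.frame(
    record = "ATOM", serial = 1:4, name = "X", altloc = "", res_name = "RES",
    chain = "A", res_seq = 1:4, icode = "", x = c(0, 1, 1, 0), y = c(0, 0, 1, 1),
    z = 0, occupancy = 1, bfactor = 0, element = "C", category = "protein",
    res_uid = paste0("A:", 1:4), atom_id = 1:4, stringsAsFactors = FALSE)
  bonds <- data.frame(edge_id = 1:4, i = c(1, 2, 3, 1), j = c(2, 3, 4, 4),
                      kind = "generic", weight = 1, dist = 1,
                      mx = c(0.5, 1, 0.5, 0), my = c(0, 0.5, 1, 0.5), mz = 0)
  g <- structure(list(atoms = atoms, bonds = bonds, n = 4L, m = 4L, log = ""),
                 class = "bp_graph")
  raw <- raw_propensities(g, src_of(g, 1L))
  expect_equal(unname(raw[2]), unname(raw[4]), tolerance = 1e-12)
})

test_that("normalization sums to one and rejects degenerate input", {
  expect_equal(normalize_propensities(c(a = 1, b = 3)),
               c(a = 0.25, b = 0.75))
  expect_equal(sum(normalize_propensities(setNames(rep(2, 10), 1:10))), 1)
  expect_error(normalize_propensities(c(a = 0, b = 0)), "degenerate")
})

test_that("residue propensities aggregate bonds correctly", {
  g <- make_random_graph(n = 40, seed = 6)
  src <- src_of(g, 1L)
  norm <- normalize_propensities(raw_propensities(g, src), src)
  # exclusive membership conserves the total
  expect_equal(sum(residue_propensities(g, norm, "exclusive")), 1)
  # "any" membership equals a brute-force double loop
  rp <- residue_propensities(g, norm)
  b <- g$bonds[match(as.integer(names(norm)), g$bonds$edge_id), ]
  for (uid in names(rp)) {
    res_atoms <- which(g$atoms$res_uid == uid)
    manual <- sum(norm[b$i %in% res_atoms | b$j %in% res_atoms])
    expect_equal(unname(rp[uid]), manual)
  }
})

test_that("distances use midpoints (bonds) and atom pairs (residues)", {
  g <- path3()
  g$bonds$mx <- c(0, 3); g$bonds$my <- c(0, 4); g$bonds$mz <- c(0, 0)
  d <- source_distances(g, src_of(g, 1L))
  expect_equal(unname(d$bond), c(0, 5))  # source bond vs itself is 0
  # exhaustive min over several source bonds
  g2 <- make_random_graph(n = 30, seed = 9)
  src2 <- src_of(g2, c(2L, 5L, 11L))
  d2 <- source_distances(g2, src2)
  mids <- as.matrix(g2$bonds[, c("mx", "my", "mz")])
  for (k in c(1, 7, 20)) {
    manual <- min(sqrt(rowSums((mids[c(2, 5, 11), , drop = FALSE] -
                                  matrix(mids[k, ], 3, 3, byrow = TRUE))^2)))
    expect_equal(unname(d2$bond[k]), manual)
  }
  A <- as.matrix(g2$atoms[, c("x", "y", "z")])
  uid <- g2$atoms$res_uid[12]
  manual_r <- min(as.matrix(stats::dist(A))[which(g2$atoms$res_uid == uid),
                                            src2$atom_ids])
  expect_equal(unname(d2$residue[uid]), manual_r)
})

test_that("normalized propensities are scale- and relabeling-invariant", {
  g <- make_random_graph(n = 30, seed = 10)
  src <- src_of(g, 3L)
  norm1 <- normalize_propensities(raw_propensities(g, src), src)
  # uniform weight scaling cancels
  g2 <- g; g2$bonds$weight <- g$bonds$weight * 7.3
  norm2 <- normalize_propensities(raw_propensities(g2, src), src)
  expect_equal(norm1, norm2, tolerance = 1e-10)
  # node relabeling leaves edge propensities unchanged
  set.seed(1)
  perm <- sample(g$n)
  g3 <- g
  g3$atoms <- g$atoms[order(perm), ]
  g3$atoms$atom_id <- seq_len(g$n)
  g3$bonds$i <- perm[g$bonds$i]; g3$bonds$j <- perm[g$bonds$j]
  sw <- g3$bonds$i > g3$bonds$j
  tmp <- g3$bonds$i[sw]; g3$bonds$i[sw] <- g3$bonds$j[sw]; g3$bonds$j[sw] <- tmp
  src3 <- structure(list(edge_ids = src$edge_ids,
                         atom_ids = perm[src$atom_ids], mode = "residues",
                         component = 1L, description = "test"),
                    class = "bp_source")
  norm3 <- normalize_propensities(raw_propensities(g3, src3), src3)
  expect_equal(norm1, norm3, tolerance = 1e-10)
})

test_that("propensity decays with distance on a chain-like fixture", {
  fx <- make_mini_pdb(n_res = 20, sequence = rep("ALA", 20))
  g <- assemble_graph(fx$model)
  src <- perturbation_source(g, resolve_site(list(atoms = g$atoms),
                                             site_annotation(ligands = fx$truth$ligand)),
                             mode = "ligand")
  f <- propensity_field(g, src)
  d <- as.numeric(f$bond_distance); p <- as.numeric(f$normalized)
  bins <- cut(d, breaks = stats::quantile(d, c(0, 1/3, 2/3, 1)),
              include.lowest = TRUE)
  med <- tapply(p, bins, stats::median)
  expect_gt(med[1], med[3])
})

test_that("ligand-mode sources use only ligand-protein weak bonds", {
  fx <- make_mini_pdb(n_res = 8)
  g <- assemble_graph(fx$model)
  lig_atoms <- resolve_site(list(atoms = g$atoms),
                            site_annotation(ligands = fx$truth$ligand))
  src <- perturbation_source(g, lig_atoms, mode = "ligand")
  kinds <- g$bonds$kind[match(src$edge_ids, g$bonds$edge_id)]
  expect_true(all(kinds != "covalent"))
  expect_equal(length(src$edge_ids), 1)  # the planted hydrogen bond
})
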