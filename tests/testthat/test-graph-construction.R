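params <- default_energy_parameters()

test_that("covalent detection follows residue templates and peptide links", {
  fx <- make_mini_pdb(n_res = 2, sequence = c("ALA", "ALA"), ligand = FALSE)
  cov <- detect_covalent(fx$model, params)
  expect_equal(nrow(cov), fx$truth$n_covalent)
  # exactly one inter-residue bond, the peptide C-N
  a <- fx$model$atoms
  inter <- cov[a$res_seq[cov$i] != a$res_seq[cov$j], ]
  expect_equal(nrow(inter), 1)
  expect_setequal(a$name[c(inter$i, inter$j)], c("C", "N"))
  expect_equal(inter$weight, unname(params$covalent_energies["C-N"]))
})

test_that("disulfides are detected by the S-S distance criterion", {
  m <- toy_structure(
    at("CB", "CYS", 1, 0, 0, 0), at("SG", "CYS", 1, 1.81, 0, 0),
    at("CB", "CYS", 5, 5.67, 0, 0), at("SG", "CYS", 5, 3.86, 0, 0))
  cov <- detect_covalent(m, params)
  ss <- cov[m$atoms$name[cov$i] == "SG" & m$atoms$name[cov$j] == "SG", ]
  expect_equal(nrow(ss), 1)  # S-S at 2.05 A
  expect_equal(ss$weight, unname(params$covalent_energies["S-S"]))
})

test_that("hydrogen bonds get the configured potential at the observed geometry", {
  fx <- make_mini_pdb(n_res = 8)
  cov <- detect_covalent(fx$model, params)
  ncv <- detect_noncovalent(fx$model, params, cov)
  hb <- ncv[ncv$kind == "hydrogen_bond", ]
  expect_equal(nrow(hb), nrow(fx$truth$hydrogen_bonds))
  # planted: donor-acceptor 2.91 A, collinear N-H...O
  expect_equal(hb$weight, abs(hbond_energy(2.91, 180, params$hbond)),
               tolerance = 1e-10)
  a <- fx$model$atoms
  expect_setequal(a$name[c(hb$i, hb$j)], c("N", "O1"))
})

test_that("a donor-acceptor pair far apart yields no hydrogen bond", {
  m <- toy_structure(
    at("N", "ALA", 1, 0, 0, 0), at("H", "ALA", 1, 0, -1.01, 0, element = "H"),
    at("CA", "ALA", 1, 1.47, 0, 0),
    at("O1", "LIG", 2, 0, -15, 0, record = "HETATM"))
  cov <- detect_covalent(m, params)
  ncv <- detect_noncovalent(m, params, cov)
  expect_equal(sum(ncv$kind == "hydrogen_bond"), 0)
})

test_that("salt bridges get the screened-Coulomb weight", {
  m <- toy_structure(
    at("NZ", "LYS", 1, 0, 0, 0, element = "N"),
    at("OE1", "GLU", 9, 3.5, 0, 0, element = "O"))
  ncv <- detect_noncovalent(m, params, detect_covalent(m, params))
  el <- ncv[ncv$kind == "electrostatic", ]
  expect_equal(nrow(el), 1)
  expected <- abs(electrostatic_energy(3.5, 1, -0.5, params$electrostatic))
  expect_equal(el$weight, expected, tolerance = 1e-12)
})

test_that("parallel aromatic rings stack", {
  hexagon <- function(res_seq, z) {
    ang <- seq(0, 300, by = 60) * pi / 180
    nm <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
    do.call(c, lapply(seq_along(nm), function(k)
      list(at(nm[k], "PHE", res_seq, 1.39 * cos(ang[k]), 1.39 * sin(ang[k]), z))))
  }
  m <- do.call(toy_structure, c(hexagon(1, 0), hexagon(5, 3.8)))
  ncv <- detect_noncovalent(m, params, detect_covalent(m, params))
  pp <- ncv[ncv$kind == "pi_pi", ]
  expect_equal(nrow(pp), 1)
  expect_equal(pp$weight, abs(pi_stacking_energy(3.8, params$pi_stacking)),
               tolerance = 1e-10)
})

test_that("assemble_graph merges, deduplicates and drops isolated atoms", {
  fx <- make_mini_pdb(n_res = 8)
  g <- assemble_graph(fx$model, params)
  expect_s3_class(g, "bp_graph")
  expect_false(any(duplicated(paste(g$bonds$i, g$bonds$j))))
  expect_true(all(g$bonds$weight > 0))
  expect_true(all(g$bonds$i != g$bonds$j))
  # midpoints are endpoint means
  expect_equal(g$bonds$mx, (g$atoms$x[g$bonds$i] + g$atoms$x[g$bonds$j]) / 2)
  # planted interaction counts
  expect_equal(sum(g$bonds$kind == "hydrogen_bond"),
               nrow(fx$truth$hydrogen_bonds))
  expect_equal(sum(g$bonds$kind == "hydrophobic"),
               nrow(fx$truth$hydrophobic_contacts))
  expect_equal(sum(g$bonds$kind == "covalent"), fx$truth$n_covalent)
  # rerun is bit-identical
  g2 <- assemble_graph(fx$model, params)
  expect_identical(g$bonds, g2$bonds)
})

test_that("graph construction is invariant to atom input order", {
  fx <- make_mini_pdb(n_res = 6)
  g1 <- assemble_graph(fx$model, params)
  m2 <- fx$model
  set.seed(3)
  m2$atoms <- m2$atoms[sample(nrow(m2$atoms)), ]
  m2$atoms$atom_id <- seq_len(nrow(m2$atoms))
  g2 <- assemble_graph(m2, params)
  tag <- function(g) {
    a <- g$atoms
    sort(paste(pmin(paste0(a$res_uid[g$bonds$i], "/", a$name[g$bonds$i]),
                    paste0(a$res_uid[g$bonds$j], "/", a$name[g$bonds$j])),
               pmax(paste0(a$res_uid[g$bonds$i], "/", a$name[g$bonds$i]),
                    paste0(a$res_uid[g$bonds$j], "/", a$name[g$bonds$j])),
               g$bonds$kind, round(g$bonds$weight, 9)))
  }
  expect_equal(tag(g1), tag(g2))
})

test_that("incidence and weight matrices satisfy their contracts", {
  m <- toy_structure(at("X", "RES", 1, 0, 0, 0), at("Y", "RES", 2, 1, 0, 0))
  g <- structure(list(atoms = m$atoms,
                      bonds = data.frame(edge_id = 1L, i = 1L, j = 2L,
                                         kind = "generic", weight = 2,
                                         dist = 1, mx = .5, my = 0, mz = 0),
                      n = 2L, m = 1L, log = ""), class = "bp_graph")
  iw <- incidence_and_weights(g)
  expect_equal(as.numeric(iw$B[, 1]), c(1, -1))
  expect_equal(as.numeric(iw$W[1, 1]), 2)

  rg <- make_random_graph(n = 15, seed = 2)
  iw2 <- incidence_and_weights(rg)
  expect_equal(Matrix::colSums(iw2$B), rep(0, rg$m), ignore_attr = TRUE)
  expect_equal(length(iw2$B@x), 2 * rg$m)
  # adjacency implied by L is symmetric with positive weights
  L <- weighted_laplacian(rg)
  expect_equal(as.matrix(L), t(as.matrix(L)))
})

test_that("energy-parameter config files override defaults", {
  cfg <- tempfile()
  writeLines(c("# tweaks", "hbond.D0: 30", "covalent_default_energy: 250"), cfg)
  p <- read_energy_parameters(cfg)
  expect_equal(p$hbond$D0, 30)
  expect_equal(p$hbond$R0, default_energy_parameters()$hbond$R0)
  expect_equal(p$covalent_default_energy, 250)
  expect_error(read_energy_parameters({
    f <- tempfile(); writeLines("hbond.D0 = oops", f); f
  }), "malformed")
})
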