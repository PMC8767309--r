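# Shared builders for hand-constructed structures and independent oracles.

# Build a bp_structure directly from atom specs:
# list(name, res_name, chain, res_seq, x, y, z, element, record)
toy_structure <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(record = r$record %||% "ATOM", serial = NA_integer_,
               name = r$name, altloc = "", res_name = r$res_name,
               chain = r$chain %||% "A", res_seq = r$res_seq, icode = "",
               x = r$x, y = r$y, z = r$z, occupancy = 1, bfactor = 0,
               element = r$element %||% substr(r$name, 1, 1),
               stringsAsFactors = FALSE)))
  df$serial <- seq_len(nrow(df))
  df$category <- bondprop:::atom_category(df$record, df$res_name)
  df$res_uid <- bondprop:::residue_uid(df$chain, df$res_seq, df$icode)
  df$atom_id <- seq_len(nrow(df))
  structure(list(atoms = df, log = "toy"), class = "bp_structure")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

at <- function(name, res_name, res_seq, x, y, z, element = NULL,
               chain = "A", record = "ATOM") {
  list(name = name, res_name = res_name, chain = chain, res_seq = res_seq,
       x = x, y = y, z = z, element = element, record = record)
}

# Minimal PDB text: one ALA backbone fragment (N, CA, C)
TOY_PDB_3ATOMS <- c(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       1.470   0.000   0.000  1.00  0.00           C",
  "ATOM      3  C   ALA A   1       2.990   0.000   0.000  1.00  0.00           C",
  "END")

# Dense pseudoinverse oracle for raw propensities: forms the full
# edge-to-edge transfer matrix M = 1/2 W B' pinv(L) B and sums absolute
# couplings over the source columns.
dense_raw_oracle <- function(graph, source_edge_ids) {
  iw <- incidence_and_weights(graph)
  B <- as.matrix(iw$B)
  W <- as.matrix(iw$W)
  L <- B %*% W %*% t(B)
  M <- 0.5 * W %*% t(B) %*% MASS::ginv(L) %*% B
  rowSums(abs(M[, match(source_edge_ids, graph$bonds$edge_id), drop = FALSE]))
}

# a small protein-like fixture graph with a residue-mode source, shared
# across propensity/scoring/site tests
fixture_field <- function(n = 80, seed = 7, src_res = "A:1") {
  g <- make_random_graph(n = n, block_size = 4, seed = seed)
  src <- perturbation_source(g, which(g$atoms$res_uid == src_res),
                             mode = "residues")
  list(graph = g, source = src, field = propensity_field(g, src))
}
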