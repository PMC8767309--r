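# connected components by breadth-first search on the edge list
graph_components <- function(graph) {
  comp <- integer(graph$n)
  adj <- vector("list", graph$n)
  for (k in seq_len(graph$m)) {
    i <- graph$bonds$i[k]; j <- graph$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  cur <- 0L
  for (s in seq_len(graph$n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

#' Define a perturbation source from orthosteric annotations
#'
#' In residue mode the source is every edge with at least one endpoint
#' atom in the given residues. In ligand mode the source is the set of
#' non-covalent edges between the ligand atoms and protein atoms -- the
#' weak bonds the ligand forms with its surrounding residues; the
#' ligand's internal covalent bonds are excluded. Multiple sites or
#' ligands are pooled into one source.
#'
#' @param graph a `bp_graph`
#' @param atom_ids atom ids (row indices of `graph$atoms`) of the source
#'   residues or ligand, e.g. from [resolve_site()]
#' @param mode `"residues"` or `"ligand"`
#' @param description provenance text carried into logs
#' @return object of class `bp_source` with `edge_ids`, `atom_ids`,
#'   `description`
#' @export
perturbation_source <- function(graph, atom_ids, mode = c("residues", "ligand"),
                                description = NULL) {
  mode <- match.arg(mode)
  b <- graph$bonds
  in_src_i <- b$i %in% atom_ids
  in_src_j <- b$j %in% atom_ids
  if (mode == "residues") {
    edges <- b$edge_id[in_src_i | in_src_j]
  } else {
    is_lig_i <- graph$atoms$category[b$i] == "ligand"
    is_lig_j <- graph$atoms$category[b$j] == "ligand"
    edges <- b$edge_id[b$kind != "covalent" &
                         ((in_src_i & is_lig_i & !is_lig_j) |
                            (in_src_j & is_lig_j & !is_lig_i))]
  }
  if (!length(edges)) stop("perturbation source resolves to zero edges")
  comp <- graph_components(graph)
  src_comp <- unique(comp[c(b$i[match(edges, b$edge_id)])])
  if (length(src_comp) > 1)
    stop("perturbation source spans multiple connected components")
  structure(list(edge_ids = sort(edges), atom_ids = sort(atom_ids),
                 mode = mode, component = src_comp,
                 description = description %||%
                   sprintf("%s source, %d edges", mode, length(edges))),
            class = "bp_source")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Weighted graph Laplacian
#'
#' `L[i,j] = -w_ij` off the diagonal and row sums of weights on the
#' diagonal, so every row sums to zero. Equal to `B W B^T`.
#'
#' @param graph a `bp_graph`
#' @return sparse symmetric n x n matrix
#' @export
weighted_laplacian <- function(graph) {
  b <- graph$bonds
  A <- Matrix::sparseMatrix(i = c(b$i, b$j), j = c(b$j, b$i),
                            x = rep(b$weight, 2), dims = c(graph$n, graph$n))
  Matrix::Diagonal(graph$n, Matrix::rowSums(A)) - A
}

#' Raw bond-to-bond propensities from a perturbation source
#'
#' For every bond b, the raw propensity is the summed absolute coupling
#' `sum_{b' in source} |M[b, b']|` where `M = 1/2 W B^T Ldagger B` is the
#' edge-to-edge transfer matrix of the energy-weighted graph. Rather than
#' forming the Moore-Penrose pseudoinverse, the needed columns are
#' obtained by one sparse grounded-Laplacian solve per source edge
#' (incidence columns are orthogonal to the constant vector, so grounding
#' one node of the component gives the pseudoinverse solution up to an
#' irrelevant constant). Cost therefore scales near-linearly with the
#' number of edges.
#'
#' Bonds in components not containing the source receive 0 (logged once).
#'
#' @param graph a `bp_graph`
#' @param source a [perturbation_source()]
#' @return numeric vector of length m, named by edge id
#' @export
raw_propensities <- function(graph, source) {
  iw <- incidence_and_weights(graph)
  comp <- graph_components(graph)
  in_comp <- which(comp == source$component)
  if (length(in_comp) < graph$n)
    message(sprintf("propensity: %d atoms outside the source component contribute 0",
                    graph$n - length(in_comp)))
  edge_in <- graph$bonds$i %in% in_comp  # both endpoints share a component
  Bc <- iw$B[in_comp, edge_in, drop = FALSE]
  wc <- graph$bonds$weight[edge_in]
  Lc <- Bc %*% Matrix::Diagonal(sum(edge_in), wc) %*% Matrix::t(Bc)
  # ground the first node of the component: SPD system, factor once
  ng <- length(in_comp)
  Lg <- Lc[-1, -1, drop = FALSE]
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Lg), LDL = FALSE, perm = TRUE)
  src_local <- match(source$edge_ids, graph$bonds$edge_id[edge_in])
  if (anyNA(src_local)) stop("source edge outside the source component")
  raw_c <- numeric(sum(edge_in))
  half_w <- 0.5 * wc
  for (b1 in src_local) {
    rhs <- Bc[, b1]
    y <- numeric(ng)
    y[-1] <- as.numeric(Matrix::solve(ch, rhs[-1]))
    # column b1 of M restricted to the component
    col <- half_w * as.numeric(Matrix::crossprod(Bc, y))
    raw_c <- raw_c + abs(col)
  }
  raw <- numeric(graph$m)
  raw[edge_in] <- raw_c
  names(raw) <- graph$bonds$edge_id
  raw
}

#' Normalize raw propensities
#'
#' Divides by the total so the field sums to one. By default the source
#' bonds are excluded from both the numerator set and the denominator:
#' they are the perturbation, not the response, and their near-field
#' values distort the distance-decay fit near d = 0. Set
#' `exclude_source = FALSE` to keep them.
#'
#' @param raw named vector from [raw_propensities()]
#' @param source optional [perturbation_source()] whose edges to exclude
#' @param exclude_source logical
#' @return named numeric vector summing to 1 over its entries
#' @export
normalize_propensities <- function(raw, source = NULL, exclude_source = TRUE) {
  keep <- rep(TRUE, length(raw))
  if (exclude_source && !is.null(source))
    keep <- !(names(raw) %in% as.character(source$edge_ids))
  x <- raw[keep]
  tot <- sum(x)
  if (tot <= 0) stop("degenerate source: all raw propensities are zero")
  x / tot
}

#' Residue propensities
#'
#' Sums normalized bond propensities over the bonds of each residue. A
#' bond belongs to residue R when at least one endpoint atom lies in R
#' (`membership = "any"`, the definition used for scoring), so a bond
#' bridging two residues counts for both. With
#' `membership = "exclusive"` each bond is assigned only to the residue
#' of its first endpoint, making the residue field sum to exactly 1.
#'
#' @param graph a `bp_graph`
#' @param normalized named vector from [normalize_propensities()]
#' @param membership `"any"` or `"exclusive"`
#' @return named numeric vector over residue uids
#' @export
residue_propensities <- function(graph, normalized,
                                 membership = c("any", "exclusive")) {
  membership <- match.arg(membership)
  b <- graph$bonds[match(as.integer(names(normalized)), graph$bonds$edge_id), ]
  uid_i <- graph$atoms$res_uid[b$i]
  uid_j <- graph$atoms$res_uid[b$j]
  if (membership == "exclusive") {
    tapply(normalized, uid_i, sum)
  } else {
    same <- uid_i == uid_j
    v <- c(normalized, normalized[!same])
    u <- c(uid_i, uid_j[!same])
    res <- tapply(v, u, sum)
    res
  }
}

#' Distances from the perturbation source
#'
#' The bond distance `d_b` is the minimum Euclidean distance between the
#' midpoint of bond b and the midpoint of any source bond (0 for a
#' source bond compared with itself). The residue distance `d_R` is the
#' minimum atom-atom distance between the atoms of residue R and the
#' atoms of the perturbation source.
#'
#' @param graph a `bp_graph`
#' @param source a [perturbation_source()]
#' @return list with `bond` (length m, named by edge id) and `residue`
#'   (named by residue uid)
#' @export
source_distances <- function(graph, source) {
  b <- graph$bonds
  mids <- as.matrix(b[, c("mx", "my", "mz")])
  src_rows <- match(source$edge_ids, b$edge_id)
  Ms <- mids[src_rows, , drop = FALSE]
  d_b <- vapply(seq_len(nrow(mids)), function(k)
    sqrt(min(colSums((t(Ms) - mids[k, ])^2))), numeric(1))
  names(d_b) <- b$edge_id
  A <- as.matrix(graph$atoms[, c("x", "y", "z")])
  Sa <- A[source$atom_ids, , drop = FALSE]
  uids <- graph$atoms$res_uid
  d_R <- vapply(split(seq_len(graph$n), uids), function(idx) {
    min(vapply(idx, function(k) min(colSums((t(Sa) - A[k, ])^2)), numeric(1)))
  }, numeric(1))
  d_R <- sqrt(d_R)
  list(bond = d_b, residue = d_R)
}

#' Compute the full propensity field for a protein
#'
#' Convenience wrapper running [raw_propensities()],
#' [normalize_propensities()], [residue_propensities()] and
#' [source_distances()] in one call.
#'
#' @param graph a `bp_graph`
#' @param source a [perturbation_source()]
#' @param exclude_source exclude source bonds from the normalized field
#' @return object of class `bp_field`: list with `raw`, `normalized`,
#'   `residue`, `bond_distance` (aligned with `normalized`),
#'   `residue_distance` (aligned with `residue`), `source`, `graph`
#' @export
propensity_field <- function(graph, source, exclude_source = TRUE) {
  raw <- raw_propensities(graph, source)
  norm <- normalize_propensities(raw, source, exclude_source)
  resid <- residue_propensities(graph, norm)
  dd <- source_distances(graph, source)
  structure(list(
    raw = raw,
    normalized = norm,
    residue = resid,
    bond_distance = dd$bond[names(norm)],
    residue_distance = dd$residue[names(resid)],
    source = source,
    graph = graph), class = "bp_field")
}

#' Write per-bond and per-residue propensity tables
#'
#' @param field a `bp_field`
#' @param bond_path,residue_path output CSV paths (`NULL` to skip)
#' @return invisibly, a list of the two data.frames
#' @export
write_propensity_tables <- function(field, bond_path = NULL, residue_path = NULL) {
  g <- field$graph
  b <- g$bonds[match(as.integer(names(field$normalized)), g$bonds$edge_id), ]
  bond_df <- data.frame(
    edge_id = b$edge_id,
    atom_i = paste0(g$atoms$res_uid[b$i], ":", g$atoms$name[b$i]),
    atom_j = paste0(g$atoms$res_uid[b$j], ":", g$atoms$name[b$j]),
    kind = b$kind, weight = b$weight,
    d_b = as.numeric(field$bond_distance),
    prop_raw = as.numeric(field$raw[names(field$normalized)]),
    prop = as.numeric(field$normalized))
  uid <- names(field$residue)
  first <- match(uid, g$atoms$res_uid)
  res_df <- data.frame(
    chain = g$atoms$chain[first], res_seq = g$atoms$res_seq[first],
    res_name = g$atoms$res_name[first],
    d_R = as.numeric(field$residue_distance),
    prop_R = as.numeric(field$residue))
  if (!is.null(bond_path)) write.csv(bond_df, bond_path, row.names = FALSE)
  if (!is.null(residue_path)) write.csv(res_df, residue_path, row.names = FALSE)
  invisible(list(bond = bond_df, residue = res_df))
}
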