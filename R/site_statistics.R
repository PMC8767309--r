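#' Collect the scores of a candidate site
#'
#' The site's bond set contains every scored bond with at least one
#' endpoint atom in the site residues; bonds touching ligand atoms are
#' excluded (a bound allosteric ligand is not part of the site).
#'
#' @param graph a `bp_graph`
#' @param scores a `bp_scores` from [score_protein()]
#' @param site_residues character vector of residue uids
#'   (`"chain:res_seq"`) defining the candidate site
#' @param ref optional output of [reference_scores()]
#' @return object of class `bp_site_scores` with bond/residue score
#'   vectors, optional reference score vectors, `n_bonds`, `n_residues`
#' @export
site_scores <- function(graph, scores, site_residues, ref = NULL) {
  a <- graph$atoms
  site_atoms <- which(a$res_uid %in% site_residues & a$category != "ligand")
  if (!length(site_atoms)) stop("site residues not found in graph")
  b <- graph$bonds[match(scores$bond$edge_id, graph$bonds$edge_id), ]
  lig <- a$category == "ligand"
  in_site <- (b$i %in% site_atoms | b$j %in% site_atoms) & !lig[b$i] & !lig[b$j]
  res_rows <- match(intersect(site_residues, scores$residue$res_uid),
                    scores$residue$res_uid)
  if (!any(in_site) || !length(res_rows))
    stop("candidate site has no scored bonds or residues")
  out <- list(site_residues = site_residues,
              bond_scores = scores$bond$score[in_site],
              residue_scores = scores$residue$score[res_rows],
              n_bonds = sum(in_site), n_residues = length(res_rows))
  if (!is.null(ref)) {
    out$bond_scores_ref <- ref$bond$score_ref[in_site]
    out$residue_scores_ref <- ref$residue$score_ref[res_rows]
  }
  structure(out, class = "bp_site_scores")
}

#' The six site statistics
#'
#' Computes, for a candidate site: (1) the mean bond quantile score, (2)
#' the mean residue quantile score, (3) the proportion of site bonds
#' with score strictly above 0.95, (4) the mean reference bond score,
#' (5) the proportion of site residues with score strictly above 0.95,
#' and (6) the mean reference residue score. Measures 4 and 6 are `NA`
#' when no reference ensemble is supplied.
#'
#' @param ss a `bp_site_scores`
#' @return named numeric vector `c(m1, m2, m3, m4, m5, m6)`
#' @export
measure_suite <- function(ss) {
  c(m1 = mean(ss$bond_scores),
    m2 = mean(ss$residue_scores),
    m3 = mean(ss$bond_scores > 0.95),
    m4 = if (is.null(ss$bond_scores_ref)) NA_real_ else mean(ss$bond_scores_ref),
    m5 = mean(ss$residue_scores > 0.95),
    m6 = if (is.null(ss$residue_scores_ref)) NA_real_
         else mean(ss$residue_scores_ref))
}

# max pairwise distance within a coordinate matrix
coord_diameter <- function(X) {
  if (nrow(X) < 2) return(0)
  max(stats::dist(X))
}

#' Sample surrogate sites by structural bootstrap
#'
#' Draws `n_sites` random surrogate sites from the protein, each obeying
#' the two structural rules: the surrogate has exactly as many residues
#' as the candidate site, and its diameter (maximum atom-atom distance
#' within the site) is smaller than the candidate's. Sites are grown
#' from a uniformly random seed residue by repeatedly adding a residue
#' drawn uniformly among those keeping the running diameter below the
#' bound, restarting on dead ends (capped). For each surrogate the mean
#' bond and mean residue quantile scores are recorded.
#'
#' @param graph a `bp_graph`
#' @param scores a `bp_scores`
#' @param site_residues residue uids of the candidate site
#' @param n_sites number of surrogates (default 1000)
#' @param seed RNG seed (recorded in the result)
#' @param max_restarts cap on restarts across a single surrogate draw
#' @return object of class `bp_surrogates`: data.frame `stats`
#'   (mean_bond, mean_residue per surrogate), list `sites`, the `seed`,
#'   the candidate `diameter` and residue count `k`
#' @export
sample_surrogates <- function(graph, scores, site_residues, n_sites = 1000,
                              seed = 2021, max_restarts = 10000) {
  a <- graph$atoms
  XYZ <- as.matrix(a[, c("x", "y", "z")])
  site_atoms <- which(a$res_uid %in% site_residues & a$category != "ligand")
  D <- coord_diameter(XYZ[site_atoms, , drop = FALSE])
  k <- length(unique(a$res_uid[site_atoms]))
  # candidates: protein residues that carry a residue score (residues
  # made up solely of source bonds have no propensity and are skipped)
  cand <- intersect(unique(a$res_uid[a$category == "protein"]),
                    scores$residue$res_uid)
  if (length(cand) < k) stop("protein has fewer candidate residues than the site")
  res_atoms <- split(seq_len(nrow(a))[a$category != "ligand"],
                     a$res_uid[a$category != "ligand"])
  res_atoms <- res_atoms[cand]
  res_diam <- vapply(res_atoms, function(idx)
    coord_diameter(XYZ[idx, , drop = FALSE]), numeric(1))
  # residue -> rows of the scored bond table (for mean bond QS)
  b <- graph$bonds[match(scores$bond$edge_id, graph$bonds$edge_id), ]
  uid_i <- a$res_uid[b$i]; uid_j <- a$res_uid[b$j]
  bond_rows <- split(rep(seq_len(nrow(b)), 2), c(uid_i, uid_j))
  res_score <- setNames(scores$residue$score, scores$residue$res_uid)

  cross_ok <- function(set_xyz, idx) {
    # difference-first squared distances (cancellation-safe, matching
    # dist()), so the strict diameter rule holds exactly
    P <- XYZ[idx, , drop = FALSE]
    ns <- nrow(set_xyz); nc <- nrow(P)
    d2 <- (set_xyz[rep(seq_len(ns), nc), , drop = FALSE] -
             P[rep(seq_len(nc), each = ns), , drop = FALSE])^2
    sqrt(max(rowSums(d2))) < D
  }

  set.seed(seed)
  sites <- vector("list", n_sites)
  mean_bond <- numeric(n_sites); mean_res <- numeric(n_sites)
  restarts <- 0
  for (s in seq_len(n_sites)) {
    repeat {
      if (restarts > max_restarts)
        stop("surrogate sampling failed: diameter rule cannot be satisfied ",
             "after ", max_restarts, " restarts")
      root <- sample(cand, 1)
      if (res_diam[[root]] >= D) { restarts <- restarts + 1; next }
      set <- root
      set_xyz <- XYZ[res_atoms[[root]], , drop = FALSE]
      ok <- TRUE
      while (length(set) < k) {
        pool <- sample(setdiff(cand, set))
        added <- FALSE
        for (r in pool) {
          if (res_diam[[r]] < D && cross_ok(set_xyz, res_atoms[[r]])) {
            set <- c(set, r)
            set_xyz <- rbind(set_xyz, XYZ[res_atoms[[r]], , drop = FALSE])
            added <- TRUE
            break
          }
        }
        if (!added) { ok <- FALSE; break }
      }
      if (ok) break
      restarts <- restarts + 1
    }
    sites[[s]] <- sort(set)
    rows <- unique(unlist(bond_rows[set], use.names = FALSE))
    mean_bond[s] <- mean(scores$bond$score[rows])
    mean_res[s] <- mean(res_score[set])
  }
  structure(list(stats = data.frame(mean_bond = mean_bond,
                                    mean_residue = mean_res),
                 sites = sites, seed = seed, diameter = D, k = k,
                 restarts = restarts),
            class = "bp_surrogates")
}

#' Percentile bootstrap confidence interval of the mean
#'
#' @param x numeric sample (e.g. surrogate-site mean scores)
#' @param n_resamples bootstrap resamples with replacement (default 10000)
#' @param level confidence level (default 0.95)
#' @param seed RNG seed
#' @return numeric `c(lower, upper)`
#' @export
bootstrap_ci <- function(x, n_resamples = 10000, level = 0.95, seed = 2021) {
  stopifnot(length(x) >= 2)
  set.seed(seed)
  n <- length(x)
  means <- vapply(seq_len(n_resamples),
                  function(i) mean(x[sample.int(n, n, replace = TRUE)]),
                  numeric(1))
  alpha <- (1 - level) / 2
  as.numeric(stats::quantile(means, c(alpha, 1 - alpha), names = FALSE))
}

#' Verdicts for the six measures
#'
#' Success rules (all strict inequalities; a value exactly on the
#' boundary fails): the mean bond/residue scores (m1, m2) must exceed
#' the upper bound of their surrogate-site bootstrap confidence
#' interval; the >0.95 proportions (m3, m5) must exceed the expected
#' 0.05; the reference means (m4, m6) must exceed the expected 0.5.
#'
#' @param values named vector from [measure_suite()]
#' @param ci_m1,ci_m2 `c(lower, upper)` intervals for m1 and m2
#' @return object of class `bp_measure_report`: `values`, `ci_m1`,
#'   `ci_m2`, logical `verdicts`, `n_success`, `n_measures`
#' @export
verdicts <- function(values, ci_m1, ci_m2) {
  v <- c(m1 = unname(values["m1"] > ci_m1[2]),
         m2 = unname(values["m2"] > ci_m2[2]),
         m3 = unname(values["m3"] > 0.05),
         m4 = if (is.na(values["m4"])) NA else unname(values["m4"] > 0.5),
         m5 = unname(values["m5"] > 0.05),
         m6 = if (is.na(values["m6"])) NA else unname(values["m6"] > 0.5))
  structure(list(values = values, ci_m1 = ci_m1, ci_m2 = ci_m2,
                 verdicts = v, n_success = sum(v, na.rm = TRUE),
                 n_measures = sum(!is.na(v))),
            class = "bp_measure_report")
}

#' @export
print.bp_measure_report <- function(x, ...) {
  lab <- c(m1 = "mean bond QS", m2 = "mean residue QS",
           m3 = "P(bond QS > 0.95)", m4 = "mean reference bond QS",
           m5 = "P(residue QS > 0.95)", m6 = "mean reference residue QS")
  thr <- c(sprintf("> %.3f", x$ci_m1[2]), sprintf("> %.3f", x$ci_m2[2]),
           "> 0.05", "> 0.5", "> 0.05", "> 0.5")
  cat("Site statistics\n")
  for (i in seq_along(lab)) {
    val <- x$values[names(lab)[i]]
    if (is.na(val)) { cat(sprintf("  %-26s (no reference)\n", lab[i])); next }
    cat(sprintf("  %-26s %.3f (%s)  %s\n", lab[i], val, thr[i],
                if (isTRUE(x$verdicts[names(lab)[i]])) "Success" else "Failure"))
  }
  cat(sprintf("  detected by %d of %d measures\n", x$n_success, x$n_measures))
  invisible(x)
}

#' Evaluate a candidate site end to end
#'
#' Convenience wrapper: collects the site's scores, computes the six
#' measures, samples the surrogate ensemble, bootstraps the confidence
#' intervals for the two mean-score measures and fills in verdicts.
#'
#' @inheritParams site_scores
#' @param n_surrogates surrogate sites (default 1000)
#' @param n_resamples bootstrap resamples (default 10000)
#' @param surrogate_seed,bootstrap_seed RNG seeds
#' @return a `bp_measure_report`; the surrogate ensemble is attached as
#'   attribute `"surrogates"`
#' @export
evaluate_site <- function(graph, scores, site_residues, ref = NULL,
                          n_surrogates = 1000, n_resamples = 10000,
                          surrogate_seed = 2021, bootstrap_seed = 2021) {
  ss <- site_scores(graph, scores, site_residues, ref)
  values <- measure_suite(ss)
  sur <- sample_surrogates(graph, scores, site_residues,
                           n_sites = n_surrogates, seed = surrogate_seed)
  ci1 <- bootstrap_ci(sur$stats$mean_bond, n_resamples, seed = bootstrap_seed)
  ci2 <- bootstrap_ci(sur$stats$mean_residue, n_resamples, seed = bootstrap_seed)
  rep <- verdicts(values, ci1, ci2)
  attr(rep, "surrogates") <- sur
  rep
}

#' Average the measures over multiple allosteric sites
#'
#' When a protein has several annotated allosteric sites, each is
#' evaluated separately and the per-measure arithmetic mean (including
#' the mean of the confidence-interval bounds for m1/m2) decides
#' detection, with verdicts applied to the averages.
#'
#' @param reports list of `bp_measure_report`
#' @return a `bp_measure_report` for the averaged measures
#' @export
aggregate_multi_site <- function(reports) {
  stopifnot(length(reports) >= 1)
  vals <- colMeans(do.call(rbind, lapply(reports, `[[`, "values")))
  ci1 <- colMeans(do.call(rbind, lapply(reports, `[[`, "ci_m1")))
  ci2 <- colMeans(do.call(rbind, lapply(reports, `[[`, "ci_m2")))
  verdicts(vals, ci1, ci2)
}
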