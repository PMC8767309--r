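#' Configuration for a single analysis run
#'
#' Captures one (structure, condition) combination: the perturbation
#' source (orthosteric residues or orthosteric ligand -- exactly one
#' mode), the candidate allosteric site(s), whether a bound allosteric
#' ligand is retained or removed, parameter overrides and seeds. The
#' four benchmark regimes (with/without allosteric ligand;
#' ligand-source/residue-source) are explicit flags, never inferred from
#' the file.
#'
#' @param structure path to a PDB file, or a `bp_structure`
#' @param orthosteric_residues residues (`"chain:res_seq"`) used as the
#'   perturbation source in residue mode
#' @param orthosteric_ligand ligand id (`"chain:res_name:res_seq"` or
#'   residue name) used as the source in ligand mode
#' @param allosteric_sites list of character vectors, each one candidate
#'   site's residue uids (multiple sites are evaluated separately and
#'   averaged)
#' @param allosteric_ligand ligand id of a bound allosteric ligand
#' @param remove_allosteric_ligand drop that ligand before analysis
#' @param keep_ligands additional hetero groups to retain
#' @param reference optional list of `bp_field` objects forming the
#'   reference ensemble for absolute scores (m4/m6 are skipped if NULL)
#' @param params energy parameters
#' @param p_grid quantile grid
#' @param n_surrogates,n_resamples resampling sizes
#' @param surrogate_seed,bootstrap_seed seeds (always logged)
#' @param protonate_cmd optional external protonation command
#' @param hydrogen_threshold minimum H fraction accepted without it
#' @param out_dir optional directory for artifacts (CSVs, scored PDB, log)
#' @return list of class `bp_run_config`
#' @export
run_config <- function(structure,
                       orthosteric_residues = NULL,
                       orthosteric_ligand = NULL,
                       allosteric_sites,
                       allosteric_ligand = NULL,
                       remove_allosteric_ligand = FALSE,
                       keep_ligands = character(),
                       reference = NULL,
                       params = default_energy_parameters(),
                       p_grid = default_p_grid(),
                       n_surrogates = 1000, n_resamples = 10000,
                       surrogate_seed = 2021, bootstrap_seed = 2021,
                       protonate_cmd = NULL, hydrogen_threshold = 0.25,
                       out_dir = NULL) {
  if (is.null(orthosteric_residues) == is.null(orthosteric_ligand))
    stop("exactly one of orthosteric_residues / orthosteric_ligand must be given")
  if (is.character(allosteric_sites)) allosteric_sites <- list(allosteric_sites)
  structure(as.list(environment()), class = "bp_run_config")
}

#' Run the full pipeline on one structure
#'
#' parse -> clean -> protonation check -> graph -> propensities ->
#' quantile scores -> site statistics. Each annotated allosteric site is
#' evaluated separately; with several sites the per-measure averages
#' (and averaged confidence bounds) decide detection. Any stage error is
#' re-raised with the stage name. If `out_dir` is set, per-bond and
#' per-residue CSVs, the quantile-model table, a residue-score-annotated
#' PDB (B-factor = 100 x score) and a run log recording every setting
#' in force are written there.
#'
#' @param config a [run_config()]
#' @return a `bp_measure_report` (the averaged report when several sites
#'   are annotated) with attributes `site_reports`, `scores`, `field`,
#'   `graph`
#' @export
run_single <- function(config) {
  stopifnot(inherits(config, "bp_run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  model <- stage("parse", {
    if (inherits(config$structure, "bp_structure")) config$structure
    else parse_pdb(config$structure)
  })
  keep <- c(config$keep_ligands,
            if (!is.null(config$orthosteric_ligand)) config$orthosteric_ligand,
            if (!config$remove_allosteric_ligand && !is.null(config$allosteric_ligand))
              config$allosteric_ligand)
  model <- stage("clean", clean_structure(
    model, keep_ligands = keep,
    remove_ligands = if (config$remove_allosteric_ligand)
      config$allosteric_ligand else character()))
  model <- stage("protonation", require_hydrogens(
    model, threshold = config$hydrogen_threshold,
    protonate_cmd = config$protonate_cmd))
  graph <- stage("graph", assemble_graph(model, config$params))
  gmodel <- list(atoms = graph$atoms)
  source <- stage("source", {
    if (!is.null(config$orthosteric_ligand)) {
      ann <- site_annotation(ligands = config$orthosteric_ligand)
      perturbation_source(graph, resolve_site(gmodel, ann), mode = "ligand",
                          description = "orthosteric ligand")
    } else {
      ann <- site_annotation(residues = config$orthosteric_residues)
      perturbation_source(graph, resolve_site(gmodel, ann), mode = "residues",
                          description = "orthosteric residues")
    }
  })
  field <- stage("propensity", propensity_field(graph, source))
  scores <- stage("scoring", score_protein(field, config$p_grid))
  ref <- if (!is.null(config$reference))
    stage("reference", reference_scores(
      field, build_reference_pool(config$reference), config$p_grid))
  site_reports <- lapply(seq_along(config$allosteric_sites), function(k) {
    stage(sprintf("site %d", k), evaluate_site(
      graph, scores, config$allosteric_sites[[k]], ref = ref,
      n_surrogates = config$n_surrogates, n_resamples = config$n_resamples,
      surrogate_seed = config$surrogate_seed,
      bootstrap_seed = config$bootstrap_seed))
  })
  report <- if (length(site_reports) == 1) site_reports[[1]]
            else aggregate_multi_site(site_reports)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    write_propensity_tables(field, p("bonds.csv"), p("residues.csv"))
    write_quantile_model(scores$bond_model, p("qmodel_bond.tsv"))
    write_quantile_model(scores$residue_model, p("qmodel_residue.tsv"))
    sc <- setNames(scores$residue$score, scores$residue$res_uid)
    write_scored_pdb(model, sc, p("scored.pdb"))
    rows <- lapply(seq_along(site_reports), function(k) {
      r <- site_reports[[k]]
      data.frame(site = k, t(r$values), ci_m1_low = r$ci_m1[1],
                 ci_m1_up = r$ci_m1[2], ci_m2_low = r$ci_m2[1],
                 ci_m2_up = r$ci_m2[2], n_success = r$n_success,
                 n_measures = r$n_measures)
    })
    write.csv(do.call(rbind, rows), p("measures.csv"), row.names = FALSE)
    writeLines(c(graph$log,
                 sprintf("source: %s", source$description),
                 sprintf("seeds: surrogate=%d bootstrap=%d",
                         config$surrogate_seed, config$bootstrap_seed),
                 sprintf("surrogates=%d resamples=%d grid_levels=%d",
                         config$n_surrogates, config$n_resamples,
                         length(config$p_grid)),
                 sprintf("remove_allosteric_ligand=%s",
                         config$remove_allosteric_ligand)),
               p("run.log"))
  }
  attr(report, "site_reports") <- site_reports
  attr(report, "scores") <- scores
  attr(report, "field") <- field
  attr(report, "graph") <- graph
  report
}

#' Run a batch of configurations
#'
#' Executes each configuration independently; a failing row is isolated
#' in the failure table and the batch continues. Returns the per-row
#' reports, a detection histogram over the number of successful
#' measures, and "detected by at least k measures" counts.
#'
#' @param configs list of [run_config()] objects
#' @return list of class `bp_batch_result`: `reports`, `histogram`
#'   (table over n_success 0..6), `at_least` (named vector), `failures`
#'   (data.frame row/error)
#' @export
run_batch <- function(configs) {
  stopifnot(length(configs) >= 1)
  reports <- vector("list", length(configs))
  fail_row <- integer(); fail_msg <- character()
  for (k in seq_along(configs)) {
    r <- tryCatch(run_single(configs[[k]]), error = function(e) e)
    if (inherits(r, "error")) {
      fail_row <- c(fail_row, k)
      fail_msg <- c(fail_msg, conditionMessage(r))
    } else reports[[k]] <- r
  }
  ok <- !vapply(reports, is.null, logical(1))
  ns <- vapply(reports[ok], `[[`, numeric(1), "n_success")
  hist <- table(factor(ns, levels = 0:6))
  at_least <- vapply(1:6, function(k) sum(ns >= k), numeric(1))
  names(at_least) <- paste0(">=", 1:6)
  structure(list(reports = reports, histogram = hist, at_least = at_least,
                 failures = data.frame(row = fail_row, error = fail_msg)),
            class = "bp_batch_result")
}

#' @export
print.bp_batch_result <- function(x, ...) {
  cat("<bp_batch_result>\n  detection histogram (n_success):\n")
  print(x$histogram)
  if (nrow(x$failures)) cat(sprintf("  %d failed rows\n", nrow(x$failures)))
  invisible(x)
}

# ---- command-line interface -------------------------------------------

cli_flag <- function(args, name, default = NULL) {
  hit <- which(args == name)
  if (!length(hit)) return(default)
  if (hit[1] == length(args)) stop("missing value for ", name)
  args[hit[1] + 1]
}

#' Command-line entry point
#'
#' Subcommands: `run` (single structure), `batch` (manifest CSV, one row
#' per structure/condition) and `fixtures` (write synthetic test data).
#' Example:
#' \preformatted{
#' Rscript -e 'bondprop::bp_cli()' run --structure x.pdb \
#'   --orthosteric A:14,A:24 --allosteric A:40,A:41 --out results/
#' }
#' Sites are comma-separated residues; multiple allosteric sites are
#' separated by ";". The manifest for `batch` needs columns `structure`,
#' `orthosteric` (residues, or `ligand:<id>`), `allosteric`; optional
#' `remove_allosteric_ligand`, `allosteric_ligand`.
#'
#' @param args command-line arguments (default: from the command line)
#' @return invisibly, the computed result
#' @export
bp_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: bp_cli run|batch|fixtures [flags]")
  cmd <- args[1]; args <- args[-1]
  seed <- as.integer(cli_flag(args, "--seed", "2021"))
  parse_one <- function(structure, ortho, allo, remove_lig = FALSE,
                        allo_lig = NULL, out_dir = NULL) {
    sites <- lapply(strsplit(allo, ";", fixed = TRUE)[[1]],
                    function(s) strsplit(s, ",", fixed = TRUE)[[1]])
    lig_mode <- startsWith(ortho, "ligand:")
    run_config(
      structure = structure,
      orthosteric_residues = if (!lig_mode)
        strsplit(ortho, ",", fixed = TRUE)[[1]],
      orthosteric_ligand = if (lig_mode) sub("^ligand:", "", ortho),
      allosteric_sites = sites,
      allosteric_ligand = allo_lig,
      remove_allosteric_ligand = isTRUE(as.logical(remove_lig)),
      n_surrogates = as.integer(cli_flag(args, "--surrogates", "1000")),
      n_resamples = as.integer(cli_flag(args, "--resamples", "10000")),
      surrogate_seed = seed, bootstrap_seed = seed,
      out_dir = out_dir)
  }
  if (cmd == "run") {
    cfg <- parse_one(cli_flag(args, "--structure"),
                     cli_flag(args, "--orthosteric"),
                     cli_flag(args, "--allosteric"),
                     cli_flag(args, "--remove-allosteric-ligand", "FALSE"),
                     cli_flag(args, "--allosteric-ligand"),
                     cli_flag(args, "--out"))
    rep <- run_single(cfg)
    print(rep)
    return(invisible(rep))
  }
  if (cmd == "batch") {
    man <- utils::read.csv(cli_flag(args, "--manifest"),
                           stringsAsFactors = FALSE)
    configs <- lapply(seq_len(nrow(man)), function(k)
      parse_one(man$structure[k], man$orthosteric[k], man$allosteric[k],
                if ("remove_allosteric_ligand" %in% names(man))
                  man$remove_allosteric_ligand[k] else FALSE,
                if ("allosteric_ligand" %in% names(man) &&
                      nzchar(man$allosteric_ligand[k]))
                  man$allosteric_ligand[k]))
    res <- run_batch(configs)
    print(res)
    return(invisible(res))
  }
  if (cmd == "fixtures") {
    out <- cli_flag(args, "--out", "fixture.pdb")
    kind <- cli_flag(args, "--kind", "mini_pdb")
    if (kind == "mini_pdb") {
      fx <- make_mini_pdb(n_res = as.integer(cli_flag(args, "--n-res", "8")),
                          jitter = as.numeric(cli_flag(args, "--jitter", "0")),
                          seed = seed, path = out)
      message("wrote ", out, " (", fx$truth$n_atoms, " atoms)")
      return(invisible(fx))
    }
    stop("unknown fixture kind: ", kind)
  }
  stop("unknown subcommand: ", cmd)
}
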