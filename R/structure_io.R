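#' @importFrom stats ave rnorm runif quantile sd setNames
#' @importFrom utils head write.csv
NULL

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")
WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O", "TIP", "SOL")

#' Parse a protein structure from PDB text
#'
#' Reads ATOM/HETATM records of the first MODEL, resolves alternate
#' locations by keeping the highest-occupancy conformer (ties broken by
#' altloc letter order), and groups atoms into residues identified by
#' (chain, residue number, insertion code) using the author numbering
#' verbatim.
#'
#' @param pdb_text character scalar (whole file) or character vector of
#'   lines; alternatively a file path to read.
#' @return An object of class `bp_structure`: a list with `atoms` (a
#'   data.frame, one row per accepted atom) and `log` (cleaning and
#'   provenance messages).
#' @export
parse_pdb <- function(pdb_text) {
  if (length(pdb_text) == 1 && !grepl("\n", pdb_text) && file.exists(pdb_text)) {
    src <- pdb_text
    lines <- readLines(pdb_text, warn = FALSE)
  } else {
    src <- "<text>"
    lines <- if (length(pdb_text) == 1) strsplit(pdb_text, "\n", fixed = TRUE)[[1]] else pdb_text
  }
  rec <- substr(lines, 1, 6)
  # only MODEL 1 of multi-model files
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) > 1) {
    endm <- which(trimws(rec) == "ENDMDL")
    if (length(endm) >= 1) lines <- lines[seq_len(endm[1])]
    rec <- substr(lines, 1, 6)
  }
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) {
    bad <- which(nzchar(trimws(lines)))[1]
    stop("no ATOM/HETATM records found; first line: ",
         if (is.na(bad)) "<empty file>" else lines[bad])
  }
  al <- lines[is_atom]
  fx <- function(a, b) trimws(substr(al, a, b))
  num <- function(a, b) suppressWarnings(as.numeric(substr(al, a, b)))
  atoms <- data.frame(
    record = trimws(rec[is_atom]),
    serial = suppressWarnings(as.integer(substr(al, 7, 11))),
    name = fx(13, 16),
    altloc = fx(17, 17),
    res_name = fx(18, 20),
    chain = fx(22, 22),
    res_seq = suppressWarnings(as.integer(substr(al, 23, 26))),
    icode = fx(27, 27),
    x = num(31, 38), y = num(39, 46), z = num(47, 54),
    occupancy = num(55, 60),
    bfactor = num(61, 66),
    element = toupper(fx(77, 78)),
    stringsAsFactors = FALSE
  )
  bad <- which(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z) |
                 is.na(atoms$res_seq))
  if (length(bad)) stop("malformed ATOM/HETATM record: ", al[bad[1]])
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  atoms$bfactor[is.na(atoms$bfactor)] <- 0
  miss <- !nzchar(atoms$element)
  if (any(miss)) atoms$element[miss] <- guess_element(atoms$name[miss])

  # altloc resolution: highest occupancy, ties by altloc letter order
  key <- paste(atoms$chain, atoms$res_seq, atoms$icode, atoms$res_name,
               atoms$name, sep = "|")
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  atoms <- atoms[ord, ]
  dup <- duplicated(paste(atoms$chain, atoms$res_seq, atoms$icode,
                          atoms$res_name, atoms$name, sep = "|"))
  n_alt <- sum(dup)
  atoms <- atoms[!dup, ]
  atoms <- atoms[order(atoms$serial), ]

  atoms$category <- atom_category(atoms$record, atoms$res_name)
  atoms$res_uid <- residue_uid(atoms$chain, atoms$res_seq, atoms$icode)
  atoms$atom_id <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  log <- c(sprintf("parsed %d atoms, %d residues from %s", nrow(atoms),
                   length(unique(atoms$res_uid)), src),
           if (n_alt > 0) sprintf("altloc: dropped %d alternate conformers", n_alt))
  structure(list(atoms = atoms, log = log), class = "bp_structure")
}

guess_element <- function(name) {
  stripped <- sub("^[0-9]+", "", name)
  two <- toupper(substr(stripped, 1, 2))
  el <- toupper(substr(stripped, 1, 1))
  el[two %in% c("FE", "ZN", "MG", "MN", "CL", "BR", "SE", "NA", "CU", "NI")] <-
    two[two %in% c("FE", "ZN", "MG", "MN", "CL", "BR", "SE", "NA", "CU", "NI")]
  # hydrogens named like 1HB2 / HG11
  el[grepl("^[0-9]*H", name)] <- "H"
  el
}

atom_category <- function(record, res_name) {
  cat <- rep("other", length(record))
  cat[res_name %in% STANDARD_AA] <- "protein"
  cat[res_name %in% WATER_NAMES] <- "water"
  cat[record == "HETATM" & !(res_name %in% c(STANDARD_AA, WATER_NAMES))] <- "ligand"
  cat
}

residue_uid <- function(chain, res_seq, icode) {
  paste0(chain, ":", res_seq, ifelse(nzchar(icode), icode, ""))
}

#' @export
print.bp_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<bp_structure> %d atoms, %d residues (%s)\n", nrow(a),
              length(unique(a$res_uid)),
              paste(sprintf("%s: %d", names(table(a$category)),
                            as.integer(table(a$category))), collapse = ", ")))
  invisible(x)
}

#' Remove waters and unwanted hetero groups
#'
#' All water molecules are removed (unless `keep_water`). Hetero groups
#' named in `remove_ligands` are always removed; remaining hetero groups
#' are kept only if listed in `keep_ligands` (`"*"` keeps all). A ligand
#' identifier is either a residue name (`"FMN"`) or
#' `"chain:res_name:res_seq"`. Every removed group is logged. The
#' operation is idempotent.
#'
#' @param model a `bp_structure`
#' @param keep_ligands,remove_ligands character vectors of ligand ids
#' @param keep_water keep water molecules (default FALSE)
#' @return the cleaned `bp_structure`
#' @export
clean_structure <- function(model, keep_ligands = character(),
                            remove_ligands = character(), keep_water = FALSE) {
  a <- model$atoms
  lig_key <- paste(a$chain, a$res_name, a$res_seq, sep = ":")
  matches <- function(ids) a$res_name %in% ids | lig_key %in% ids
  for (id in remove_ligands) {
    if (!any(a$res_name == id | lig_key == id))
      warning("remove_ligands entry not present in structure: ", id)
  }
  drop <- rep(FALSE, nrow(a))
  if (!keep_water) drop <- drop | a$category == "water"
  hetero <- a$category == "ligand"
  if (!("*" %in% keep_ligands))
    drop <- drop | (hetero & !matches(keep_ligands))
  drop <- drop | matches(remove_ligands)
  removed <- unique(paste(a$res_name[drop], a$res_uid[drop]))
  a <- a[!drop, , drop = FALSE]
  if (nrow(a) == 0) stop("clean_structure removed every atom")
  a$atom_id <- seq_len(nrow(a))
  rownames(a) <- NULL
  model$atoms <- a
  model$log <- c(model$log,
                 if (length(removed)) paste("removed group:", removed)
                 else "clean: nothing to remove")
  model
}

#' Check (or establish) protonation of a structure
#'
#' The analysis graph needs explicit hydrogens. If the fraction of
#' hydrogen atoms among protein atoms is below `threshold`, either an
#' external protonation command is invoked on the structure and the
#' result re-parsed, or an error instructs the user to pre-protonate.
#'
#' @param model a `bp_structure`
#' @param threshold minimum hydrogen fraction among protein atoms
#'   (default 0.25; protonated structures sit near 0.5)
#' @param protonate_cmd optional external command template containing
#'   `%in` and `%out` placeholders for PDB file paths
#' @return the (possibly re-parsed) protonated `bp_structure`
#' @export
require_hydrogens <- function(model, threshold = 0.25, protonate_cmd = NULL) {
  prot <- model$atoms[model$atoms$category == "protein", ]
  frac <- if (nrow(prot) == 0) 1 else mean(prot$element == "H")
  if (frac >= threshold) return(model)
  if (is.null(protonate_cmd)) {
    stop(sprintf(paste0("structure not protonated (hydrogen fraction %.2f < %.2f); ",
                        "add hydrogens upstream (e.g. with Reduce) or configure ",
                        "protonate_cmd"), frac, threshold))
  }
  fin <- tempfile(fileext = ".pdb"); fout <- tempfile(fileext = ".pdb")
  write_pdb(model, fin)
  cmd <- sub("%in", fin, sub("%out", fout, protonate_cmd, fixed = TRUE), fixed = TRUE)
  status <- system(cmd, ignore.stdout = FALSE)
  if (status != 0 || !file.exists(fout))
    stop("external protonation command failed (exit ", status, "): ", cmd)
  out <- parse_pdb(fout)
  out$log <- c(model$log, paste("protonated via:", protonate_cmd), out$log)
  out
}

#' Define a site annotation
#'
#' @param residues residues as `"chain:res_seq"` strings (insertion code
#'   appended, e.g. `"A:100A"`) or a data.frame with columns
#'   `chain`, `res_seq` and optionally `icode`
#' @param ligands ligand groups as `"chain:res_name:res_seq"` strings or
#'   plain residue names
#' @param role `"orthosteric"` or `"allosteric"`
#' @return object of class `bp_site_annotation`
#' @export
site_annotation <- function(residues = NULL, ligands = NULL,
                            role = c("orthosteric", "allosteric")) {
  role <- match.arg(role)
  if (is.character(residues)) {
    parts <- strsplit(residues, ":", fixed = TRUE)
    residues <- data.frame(
      chain = vapply(parts, `[`, "", 1),
      res_seq = as.integer(sub("[A-Za-z]$", "", vapply(parts, `[`, "", 2))),
      icode = sub("^[0-9-]+", "", vapply(parts, `[`, "", 2)),
      stringsAsFactors = FALSE)
  }
  if (!is.null(residues) && is.null(residues$icode)) residues$icode <- ""
  if (is.null(residues) && is.null(ligands))
    stop("site annotation needs at least one residue or ligand")
  structure(list(residues = residues, ligands = ligands, role = role),
            class = "bp_site_annotation")
}

#' Resolve a site annotation to atom ids
#'
#' @param model a `bp_structure`
#' @param annotation a [site_annotation()]
#' @return integer vector of atom ids (sorted, deterministic); unresolved
#'   entries raise a warning, zero resolvable entries an error.
#' @export
resolve_site <- function(model, annotation) {
  a <- model$atoms
  ids <- integer()
  missing <- character()
  res <- annotation$residues
  if (!is.null(res)) {
    for (k in seq_len(nrow(res))) {
      uid <- residue_uid(res$chain[k], res$res_seq[k], res$icode[k])
      hit <- a$atom_id[a$res_uid == uid]
      if (length(hit)) ids <- c(ids, hit) else missing <- c(missing, uid)
    }
  }
  for (lg in annotation$ligands) {
    hit <- if (grepl(":", lg)) {
      a$atom_id[paste(a$chain, a$res_name, a$res_seq, sep = ":") == lg]
    } else a$atom_id[a$res_name == lg]
    if (length(hit)) ids <- c(ids, hit) else missing <- c(missing, lg)
  }
  if (length(missing))
    warning("unresolved site entries: ", paste(missing, collapse = ", "))
  if (!length(ids)) stop("no site entry could be resolved against the structure")
  sort(unique(ids))
}

#' Write a structure to PDB format
#'
#' @param model a `bp_structure`
#' @param path output file; if `NULL` the lines are returned invisibly
#' @return character vector of PDB lines, invisibly
#' @export
write_pdb <- function(model, path = NULL) {
  a <- model$atoms
  name4 <- ifelse(nchar(a$name) >= 4 | nchar(a$element) == 2,
                  sprintf("%-4s", substr(a$name, 1, 4)),
                  sprintf(" %-3s", a$name))
  lines <- sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   ifelse(a$category %in% c("ligand", "water"), "HETATM", "ATOM"),
                   a$atom_id %% 100000, name4, "", a$res_name, a$chain,
                   a$res_seq, ifelse(nzchar(a$icode), a$icode, " "),
                   a$x, a$y, a$z, a$occupancy, a$bfactor, a$element)
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Write a PDB with residue quantile scores in the B-factor column
#'
#' Scores (in \[0,1\]) are written as B-factors scaled by 100 so standard
#' viewers can color the structure by connectivity to the perturbation
#' source.
#'
#' @param model a `bp_structure`
#' @param residue_scores named numeric vector, names are residue uids
#'   (`"chain:res_seq"`)
#' @param path output file
#' @return invisibly, the PDB lines
#' @export
write_scored_pdb <- function(model, residue_scores, path = NULL) {
  sc <- residue_scores[model$atoms$res_uid]
  sc[is.na(sc)] <- 0
  model$atoms$bfactor <- round(100 * as.numeric(sc), 2)
  write_pdb(model, path)
}
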