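#' @name ensemble_io
#' @title Reading, writing and standardizing solvation ensembles
#' @description
#' An ensemble is a list of models; each model is a data frame of atoms with
#' columns `element`, `atom_name`, `residue_name`, `residue_index`,
#' `chain_id`, `x`, `y`, `z`, `b_factor` and (after
#' [standardize_species()]) `species`. B-factors are carried through I/O but
#' never used in any density or score. Insertion codes are unsupported and
#' raise an error; alternate locations keep the highest-occupancy copy.
NULL

# molecule species recognised throughout the package
.species_levels <- c("RNA", "water", "Mg2+", "Na+", "Cl-", "K+")

.atom_columns <- c("element", "atom_name", "residue_name", "residue_index",
                   "chain_id", "x", "y", "z", "species", "b_factor")

new_atom_table <- function(df) {
  if (!"species" %in% names(df)) df$species <- NA_character_
  df <- df[, .atom_columns]
  rownames(df) <- NULL
  stopifnot(all(is.finite(df$x)), all(is.finite(df$y)), all(is.finite(df$z)))
  df
}

atom_coords <- function(atoms) {
  unname(as.matrix(atoms[, c("x", "y", "z"), drop = FALSE]))
}

# heavy = element other than hydrogen
is_heavy <- function(atoms) toupper(atoms$element) != "H"

normalize_element <- function(el) {
  el <- toupper(trimws(el))
  paste0(substr(el, 1, 1), tolower(substr(el, 2, nchar(el))))
}

new_solvent_ensemble <- function(models, source_label = "") {
  if (length(models) < 1L) stop("ensemble has zero models")
  if (length(models) > 1000L) stop("ensemble has more than 1000 models")
  structure(list(models = models, source_label = source_label),
            class = "solvent_ensemble")
}

#' @export
print.solvent_ensemble <- function(x, ...) {
  n <- vapply(x$models, nrow, integer(1))
  cat(sprintf("<solvent_ensemble> '%s': %d model(s), %d-%d atoms/model\n",
              x$source_label, length(x$models), min(n), max(n)))
  sp <- x$models[[1]]$species
  if (!all(is.na(sp)))
    cat("  species (model 1):",
        paste(sprintf("%s=%d", names(table(sp)), table(sp)), collapse = " "), "\n")
  invisible(x)
}

#' Read a multi-model coordinate file into a solvation ensemble
#'
#' Accepts multi-`MODEL` PDB files and mmCIF files whose `atom_site` loop
#' carries `pdbx_PDB_model_num`. A file without model records yields a
#' one-model ensemble. Atom order within each model is preserved. Species
#' are left unassigned; call [standardize_species()] next.
#'
#' PDB model blocks are parsed with \pkg{bio3d}; mmCIF `atom_site` loops are
#' parsed directly (models may differ in atom count, e.g. from per-model
#' solvent occupancy).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return A `solvent_ensemble`.
#' @export
read_ensemble <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  models <- if (format == "pdb") read_pdb_models(path) else read_cif_models(path)
  if (length(models) == 0L)
    stop("no models found in '", path, "'")
  new_solvent_ensemble(models, source_label = basename(path))
}

read_pdb_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  chunks <- if (length(starts) == 0L) {
    list(lines)
  } else {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(starts))
      stop("unbalanced MODEL/ENDMDL records in '", path, "'")
    Map(function(s, e) lines[s:e], starts, ends)
  }
  chunks <- Filter(function(ch) any(grepl("^(ATOM|HETATM)", ch)), chunks)
  if (length(chunks) == 0L) stop("no ATOM/HETATM records in '", path, "'")
  lapply(chunks, function(ch) {
    tf <- tempfile(fileext = ".pdb")
    on.exit(unlink(tf))
    writeLines(c(ch, "END"), tf)
    pdb <- tryCatch(bio3d::read.pdb(tf, verbose = FALSE, rm.alt = FALSE),
                    error = function(e) stop("unparseable PDB record near '",
                                             ch[grep("^(ATOM|HETATM)", ch)[1]],
                                             "': ", conditionMessage(e)))
    atoms_from_bio3d(pdb$atom)
  })
}

atoms_from_bio3d <- function(at) {
  if (any(!is.na(at$insert) & nzchar(at$insert)))
    stop("insertion codes are unsupported")
  # sodium's residue code is the string "NA"; guard against NA coercion
  resid <- at$resid
  resid[is.na(resid)] <- "NA"
  elesy <- at$elesy
  miss <- is.na(elesy) | !nzchar(trimws(elesy))
  elesy[miss] <- substr(gsub("[^A-Za-z].*$", "", trimws(at$elety[miss])), 1, 1)
  df <- data.frame(
    element = normalize_element(elesy),
    atom_name = trimws(at$elety),
    residue_name = toupper(trimws(resid)),
    residue_index = as.integer(at$resno),
    chain_id = ifelse(is.na(at$chain), "A", at$chain),
    x = at$x, y = at$y, z = at$z,
    b_factor = ifelse(is.na(at$b), 0, at$b),
    occupancy = ifelse(is.na(at$o), 1, at$o),
    alt = ifelse(is.na(at$alt), "", at$alt),
    stringsAsFactors = FALSE
  )
  new_atom_table(resolve_altlocs(df))
}

# keep the highest-occupancy altloc per atom; ties keep the first encountered
resolve_altlocs <- function(df) {
  key <- paste(df$chain_id, df$residue_index, df$residue_name, df$atom_name)
  if (!anyDuplicated(key)) return(df)
  ord <- order(match(key, unique(key)), -df$occupancy)
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(paste(df$chain_id, df$residue_index,
                             df$residue_name, df$atom_name)), , drop = FALSE]
  df
}

read_cif_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^_atom_site\\.", lines)
  if (length(hdr_idx) == 0L)
    stop("no _atom_site loop found in '", path, "'")
  cols <- sub("^_atom_site\\.", "", trimws(lines[hdr_idx]))
  i <- max(hdr_idx) + 1L
  rows <- list()
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || grepl("^(_|loop_|#|data_)", ln)) break
    toks <- scan(text = ln, what = character(), quiet = TRUE, quote = "\"'")
    if (length(toks) != length(cols))
      stop("malformed atom_site row at line ", i, " of '", path, "'")
    rows[[length(rows) + 1L]] <- toks
    i <- i + 1L
  }
  if (length(rows) == 0L) stop("empty atom_site loop in '", path, "'")
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(tab) <- cols
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(tab)) return(tab[[nm]])
    stop("atom_site loop lacks required column: ", ..1)
  }
  ins <- if ("pdbx_PDB_ins_code" %in% names(tab)) tab$pdbx_PDB_ins_code else "?"
  if (any(!ins %in% c("?", ".", "", NA)))
    stop("insertion codes are unsupported")
  occ <- suppressWarnings(as.numeric(pick("occupancy")))
  occ[is.na(occ)] <- 1
  bval <- suppressWarnings(as.numeric(pick("B_iso_or_equiv")))
  bval[is.na(bval)] <- 0
  alt <- if ("label_alt_id" %in% names(tab)) tab$label_alt_id else "."
  df <- data.frame(
    element = normalize_element(pick("type_symbol")),
    atom_name = pick("auth_atom_id", "label_atom_id"),
    residue_name = toupper(pick("auth_comp_id", "label_comp_id")),
    residue_index = as.integer(pick("auth_seq_id", "label_seq_id")),
    chain_id = pick("auth_asym_id", "label_asym_id"),
    x = as.numeric(pick("Cartn_x")),
    y = as.numeric(pick("Cartn_y")),
    z = as.numeric(pick("Cartn_z")),
    b_factor = bval, occupancy = occ,
    alt = ifelse(alt %in% c(".", "?"), "", alt),
    stringsAsFactors = FALSE
  )
  model_num <- if ("pdbx_PDB_model_num" %in% names(tab))
    as.integer(tab$pdbx_PDB_model_num) else 1L
  lapply(split(df, model_num), function(m) new_atom_table(resolve_altlocs(m)))
}

#' Write an ensemble as a multi-model PDB file
#'
#' Models are emitted between `MODEL`/`ENDMDL` records; RNA atoms as `ATOM`,
#' solvent as `HETATM` (species unassigned atoms as `ATOM`). Coordinates are
#' written at 3 decimal places (the PDB fixed-width limit).
#'
#' @param ensemble a `solvent_ensemble` (or a single atom table).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  models <- if (inherits(ensemble, "solvent_ensemble")) ensemble$models else list(ensemble)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(models)) {
    at <- models[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    rec <- ifelse(!is.na(at$species) & at$species != "RNA", "HETATM", "ATOM")
    name4 <- ifelse(nchar(at$element) == 1 & nchar(at$atom_name) < 4,
                    sprintf(" %-3s", at$atom_name),
                    sprintf("%-4s", at$atom_name))
    lines <- sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     rec, seq_len(nrow(at)) %% 100000L, name4,
                     substr(at$residue_name, 1, 3), substr(at$chain_id, 1, 1),
                     at$residue_index, at$x, at$y, at$z, 1, at$b_factor,
                     toupper(at$element))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Species standardization table
#'
#' Maps PDB residue codes to the molecule species used by the pipeline.
#' Residue codes not in the table are assigned as water by design (the
#' assessment accounts for RNA, water, Mg2+, Na+, Cl- and K+ only).
#'
#' @return named character vector: residue code -> species.
#' @export
species_map <- function() {
  rna <- c("A", "C", "G", "U", "RA", "RC", "RG", "RU",
           "ADE", "CYT", "GUA", "URA",
           "A3", "A5", "C3", "C5", "G3", "G5", "U3", "U5")
  c(setNames(rep("RNA", length(rna)), rna),
    HOH = "water", WAT = "water", H2O = "water",
    MG = "Mg2+", "NA" = "Na+", CL = "Cl-", K = "K+")
}

#' Assign molecule species from residue names
#'
#' Recognized RNA codes become `"RNA"`; HOH/WAT/H2O become `"water"`; MG,
#' NA, CL, K become the respective ions; every other residue code is
#' assigned as water. Total and idempotent by construction.
#'
#' @param x a `solvent_ensemble`, a single atom table, or a
#'   `reference_structure`.
#' @param map residue-code to species mapping, default [species_map()].
#' @return `x` with the `species` column filled.
#' @export
standardize_species <- function(x, map = species_map()) {
  std <- function(at) {
    sp <- unname(map[at$residue_name])
    sp[is.na(sp)] <- "water"
    at$species <- sp
    at
  }
  if (inherits(x, "solvent_ensemble")) {
    x$models <- lapply(x$models, std)
    x
  } else if (inherits(x, "reference_structure")) {
    x$atoms <- std(x$atoms)
    x
  } else std(x)
}

#' Trim solvent to the assessment zone around the RNA
#'
#' A non-RNA atom is kept iff its minimum distance to any RNA heavy atom of
#' the same model is at most `cutoff` (inclusive). Waters are kept or
#' removed as whole residues keyed on the oxygen atom (hydrogens follow the
#' oxygen); ions are judged individually. RNA atoms are never removed. The
#' trim is measured against each model's own RNA, matching how predictors
#' trimmed their own frames.
#'
#' @param x a `solvent_ensemble` or a single atom table with species
#'   assigned.
#' @param cutoff \enc{Å}{A}, default 5.
#' @return the trimmed object.
#' @export
trim_solvent <- function(x, cutoff = 5.0) {
  if (inherits(x, "solvent_ensemble")) {
    x$models <- lapply(x$models, trim_solvent, cutoff = cutoff)
    return(x)
  }
  at <- x
  if (anyNA(at$species)) stop("species must be assigned before trimming")
  rna <- at$species == "RNA"
  if (!any(rna)) stop("model contains no RNA atoms")
  rna_xyz <- atom_coords(at[rna & is_heavy(at), , drop = FALSE])
  keep <- rep(TRUE, nrow(at))
  solv <- which(!rna)
  if (length(solv)) {
    d <- cpp_min_dist(atom_coords(at[solv, , drop = FALSE]), rna_xyz)$dist
    ok <- d <= cutoff
    # waters decided by their oxygen; other water-residue atoms follow it
    w <- at$species[solv] == "water"
    if (any(w)) {
      key <- paste(at$chain_id[solv], at$residue_index[solv])
      oxy <- w & toupper(at$element[solv]) == "O"
      res_ok <- tapply(ok[oxy], key[oxy], any)
      ok[w] <- res_ok[key[w]]
      ok[is.na(ok)] <- FALSE
    }
    keep[solv] <- ok
  }
  at[keep, , drop = FALSE]
}

#' Parse residue ranges like "63-88,229-245"
#'
#' @param spec character scalar of comma-separated indices or ranges.
#' @return integer vector of residue indices.
#' @export
parse_residue_ranges <- function(spec) {
  if (is.numeric(spec)) return(as.integer(spec))
  parts <- strsplit(gsub("\\s", "", spec), ",")[[1]]
  out <- lapply(parts, function(p) {
    if (grepl("-", p)) {
      ab <- as.integer(strsplit(p, "-")[[1]])
      seq.int(ab[1], ab[2])
    } else as.integer(p)
  })
  unique(unlist(out))
}

#' Read a single-model reference RNA structure
#'
#' Non-RNA atoms are dropped after species standardization. Poorly resolved
#' residues to exclude from the comparison can be given as indices or a
#' range string (e.g. `"63-88,229-245"`); their shell voxels are dropped by
#' [compute_shell()].
#'
#' @param path PDB or mmCIF file.
#' @param format see [read_ensemble()].
#' @param excluded_residues integer vector or range string.
#' @return a `reference_structure` (list with `atoms`, `excluded_residues`).
#' @export
read_reference <- function(path, format = c("auto", "pdb", "cif"),
                           excluded_residues = integer()) {
  ens <- read_ensemble(path, format)
  if (length(ens$models) > 1L)
    warning("reference file has ", length(ens$models), " models; using the first")
  at <- standardize_species(ens$models[[1]])
  reference_structure(at[at$species == "RNA", , drop = FALSE], excluded_residues)
}

#' Construct a reference structure from an atom table
#'
#' @param atoms atom table (RNA atoms only are kept if species is assigned).
#' @param excluded_residues integer vector or range string of residues whose
#'   shell voxels must not be scored.
#' @return a `reference_structure`.
#' @export
reference_structure <- function(atoms, excluded_residues = integer()) {
  if (!anyNA(atoms$species)) atoms <- atoms[atoms$species == "RNA", , drop = FALSE]
  if (nrow(atoms) == 0L) stop("reference structure has no RNA atoms")
  structure(list(atoms = new_atom_table(atoms),
                 excluded_residues = parse_residue_ranges(excluded_residues)),
            class = "reference_structure")
}

#' @export
print.reference_structure <- function(x, ...) {
  cat(sprintf("<reference_structure> %d residues, %d atoms, %d excluded residue(s)\n",
              length(unique(x$atoms$residue_index)), nrow(x$atoms),
              length(x$excluded_residues)))
  invisible(x)
}
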