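#' @importFrom rlang .data
NULL

# Backbone atom names excluded from side-chain centroids.
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", UNK = "X"
)

# Common chemical modifications mapped to their standard parent, applied when
# the coordinate file carries no explicit MODRES / pdbx_struct_mod_residue
# record for the residue.
BUILTIN_MODRES <- c(
  MSE = "MET", SEP = "SER", TPO = "THR", PTR = "TYR", CSO = "CYS",
  CME = "CYS", CSD = "CYS", OCS = "CYS", MLY = "LYS", M3L = "LYS",
  ALY = "LYS", KCX = "LYS", HYP = "PRO", FME = "MET", PCA = "GLN",
  DAL = "ALA", AIB = "ALA", NLE = "LEU", ORN = "ALA", SAR = "GLY"
)

#' Construct a structure object from an atom table
#'
#' A `kih_structure` is a thin wrapper around a tidy heavy-atom table:
#' one row per atom, ordered by chain, then author residue number and
#' insertion code, then atom. The residue key used throughout the package
#' is `res_uid = "<chain>|<resno><ins>"`.
#'
#' @param atoms Tibble with columns `chain`, `resno` (integer author
#'   number), `ins` (insertion code, `""` if none), `resid` (3-letter
#'   residue code), `elety` (atom name), `elesy` (element symbol),
#'   `x`, `y`, `z` (Angstrom), `het` (logical, HETATM origin).
#' @param modres Tibble of modified-residue records with columns
#'   `het_code`, `chain`, `resno`, `ins`, `parent_code`.
#' @param source_format `"pdb"`, `"mmcif"` or `"generated"`.
#' @param model_id Model number the coordinates came from.
#' @return An object of class `kih_structure`.
#' @export
new_structure <- function(atoms,
                          modres = empty_modres(),
                          source_format = "generated",
                          model_id = 1L) {
  stopifnot(all(c("chain", "resno", "ins", "resid", "elety", "elesy",
                  "x", "y", "z", "het") %in% names(atoms)))
  atoms <- tibble::as_tibble(atoms)
  atoms$resno <- as.integer(atoms$resno)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("atom coordinates must be finite", call. = FALSE)
  }
  if (any(!nzchar(atoms$elety))) stop("atom names must be non-empty", call. = FALSE)
  atoms <- dplyr::arrange(atoms, .data$chain, .data$resno, .data$ins)
  atoms$res_uid <- res_uid(atoms$chain, atoms$resno, atoms$ins)
  if (!"parent" %in% names(atoms)) atoms$parent <- atoms$resid
  if (!"is_modified" %in% names(atoms)) atoms$is_modified <- FALSE
  structure(
    list(atoms = atoms, modres = tibble::as_tibble(modres),
         source_format = source_format, model_id = as.integer(model_id)),
    class = "kih_structure"
  )
}

empty_modres <- function() {
  tibble::tibble(het_code = character(), chain = character(),
                 resno = integer(), ins = character(),
                 parent_code = character())
}

res_uid <- function(chain, resno, ins) {
  paste0(chain, "|", resno, ifelse(nzchar(ins), ins, ""))
}

#' @export
print.kih_structure <- function(x, ...) {
  res <- residue_table(x)
  cat(sprintf("<kih_structure> %d chains, %d residues, %d heavy atoms (%s, model %d)\n",
              length(unique(x$atoms$chain)), nrow(res), nrow(x$atoms),
              x$source_format, x$model_id))
  invisible(x)
}

#' One row per residue of a structure
#'
#' @param s A `kih_structure`.
#' @return Tibble with `res_uid`, `chain`, `resno`, `ins`, `resid`,
#'   `parent`, `is_modified`, `het`, `n_atoms`.
#' @export
residue_table <- function(s) {
  dplyr::summarise(
    dplyr::group_by(s$atoms, .data$res_uid, .data$chain, .data$resno, .data$ins),
    resid = .data$resid[1], parent = .data$parent[1],
    is_modified = .data$is_modified[1], het = any(.data$het),
    n_atoms = dplyr::n(), .groups = "drop"
  ) |>
    dplyr::arrange(.data$chain, .data$resno, .data$ins)
}

detect_format <- function(path, format_hint = NULL) {
  if (!is.null(format_hint)) {
    return(match.arg(format_hint, c("pdb", "mmcif")))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("cif", "mmcif")) return("mmcif")
  if (ext %in% c("pdb", "ent")) return("pdb")
  head <- readLines(path, n = 50L, warn = FALSE)
  if (any(grepl("^data_", head)) || any(grepl("^_atom_site\\.", head))) {
    return("mmcif")
  }
  "pdb"
}

#' Read a PDB or mmCIF coordinate file
#'
#' Parses the file into a [new_structure()] object: hydrogens are
#' stripped, only the first model is kept, and for alternate locations
#' the highest-occupancy conformer is retained (ties broken by altloc
#' label, `'A'` first). Waters and het-groups without a CA atom are
#' dropped; CA-bearing heteroresidues are retained so that modified and
#' nonnatural amino acids stay eligible as knobs and holes.
#' Modified-residue annotations (PDB `MODRES`, mmCIF
#' `pdbx_struct_mod_residue`) are applied via [apply_modres()].
#'
#' @param path Path to a `.pdb`/`.ent` or `.cif`/`.mmcif` file.
#' @param format_hint Optional `"pdb"` or `"mmcif"`; by default the
#'   format is detected from the extension or content.
#' @return A `kih_structure`.
#' @export
read_structure <- function(path, format_hint = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  fmt <- detect_format(path, format_hint)
  s <- if (fmt == "pdb") read_structure_pdb(path) else read_structure_mmcif(path)
  if (nrow(s$atoms) == 0L) {
    stop("no protein residues with coordinates found in ", path, call. = FALSE)
  }
  apply_modres(s)
}

# Normalise a bio3d atom data.frame (one model) into the tidy atom table:
# drop hydrogens/deuteriums, resolve altlocs by occupancy, drop residues
# without a CA atom (waters, non-polymer ligands).
normalise_atoms <- function(at) {
  at <- tibble::tibble(
    chain = ifelse(is.na(at$chain) | !nzchar(at$chain), "A", at$chain),
    resno = as.integer(at$resno),
    ins = ifelse(is.na(at$insert), "", at$insert),
    resid = at$resid,
    elety = at$elety,
    elesy = toupper(trimws(ifelse(is.na(at$elesy), "", at$elesy))),
    alt = ifelse(is.na(at$alt) | at$alt == ".", "", at$alt),
    o = ifelse(is.na(at$o), 1, at$o),
    x = at$x, y = at$y, z = at$z,
    het = at$type == "HETATM"
  )
  guess <- is.na(at$elesy) | !nzchar(at$elesy)
  if (any(guess)) {
    # fall back to the first alphabetic character of the atom name
    at$elesy[guess] <- substr(gsub("^[0-9]*", "", at$elety[guess]), 1, 1)
  }
  at <- dplyr::filter(at, !.data$elesy %in% c("H", "D"))
  # highest occupancy wins per (residue, atom name); ties by altloc label
  at <- at |>
    dplyr::group_by(.data$chain, .data$resno, .data$ins, .data$elety) |>
    dplyr::arrange(dplyr::desc(.data$o), .data$alt, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  has_ca <- at |>
    dplyr::group_by(.data$chain, .data$resno, .data$ins) |>
    dplyr::summarise(ca = any(.data$elety == "CA"), .groups = "drop")
  at <- dplyr::semi_join(at, dplyr::filter(has_ca, .data$ca),
                         by = c("chain", "resno", "ins"))
  dplyr::select(at, -"alt", -"o")
}

read_structure_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # first model only
  mdl <- grep("^ENDMDL", lines)
  model_id <- 1L
  if (length(mdl) > 0L) {
    first <- grep("^MODEL", lines)
    if (length(first) > 0L) {
      model_id <- suppressWarnings(as.integer(substr(lines[first[1]], 11, 14)))
      if (is.na(model_id)) model_id <- 1L
    }
    lines <- lines[seq_len(mdl[1])]
  }
  modres <- parse_modres_records(lines)
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(tf, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("could not parse PDB file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  new_structure(normalise_atoms(pdb$atom), modres = modres,
                source_format = "pdb", model_id = model_id)
}

parse_modres_records <- function(lines) {
  ml <- lines[startsWith(lines, "MODRES")]
  if (length(ml) == 0L) return(empty_modres())
  tibble::tibble(
    het_code = trimws(substr(ml, 13, 15)),
    chain = trimws(substr(ml, 17, 17)),
    resno = suppressWarnings(as.integer(trimws(substr(ml, 19, 22)))),
    ins = trimws(substr(ml, 23, 23)),
    parent_code = trimws(substr(ml, 25, 27))
  )
}

read_structure_mmcif <- function(path) {
  cif <- tryCatch(
    suppressWarnings(bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("could not parse mmCIF file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  new_structure(normalise_atoms(cif$atom),
                modres = parse_mmcif_modres(path),
                source_format = "mmcif", model_id = 1L)
}

# Minimal reader for the pdbx_struct_mod_residue category (loop_ or
# single-row key-value form).
parse_mmcif_modres <- function(path) {
  lines <- readLines(path, warn = FALSE)
  idx <- grep("^_pdbx_struct_mod_residue\\.", lines)
  if (length(idx) == 0L) return(empty_modres())
  fields <- sub("^_pdbx_struct_mod_residue\\.(\\S+).*$", "\\1", lines[idx])
  in_loop <- any(grepl("^\\s*loop_\\s*$", lines[seq_len(idx[1])]) &
                   seq_len(idx[1]) == max(grep("^\\s*loop_\\s*$",
                                               lines[seq_len(idx[1])]), 0))
  get_field <- function(rec, nm) {
    j <- match(nm, fields)
    if (is.na(j)) NA_character_ else rec[j]
  }
  recs <- list()
  if (grepl("^_pdbx_struct_mod_residue\\.\\S+\\s+\\S", lines[idx[1]])) {
    # key-value form: one record spread over the category's lines
    vals <- sub("^_pdbx_struct_mod_residue\\.\\S+\\s+", "", lines[idx])
    recs <- list(vals)
  } else {
    body <- lines[seq(max(idx) + 1L, length(lines))]
    stop_at <- grep("^(#|loop_|_\\S|data_)", body)
    if (length(stop_at) > 0L) body <- body[seq_len(stop_at[1] - 1L)]
    body <- body[nzchar(trimws(body))]
    recs <- lapply(body, function(l) scan(text = l, what = character(),
                                          quiet = TRUE))
  }
  out <- lapply(recs, function(r) {
    tibble::tibble(
      het_code = get_field(r, "label_comp_id"),
      chain = get_field(r, "auth_asym_id"),
      resno = suppressWarnings(as.integer(get_field(r, "auth_seq_id"))),
      ins = {
        ic <- get_field(r, "PDB_ins_code")
        if (is.na(ic) || ic %in% c("?", ".")) "" else ic
      },
      parent_code = get_field(r, "parent_comp_id")
    )
  })
  dplyr::bind_rows(out)
}

#' Annotate modified residues with their standard parent
#'
#' Every heteroresidue in a polymer chain that matches a `MODRES` /
#' `pdbx_struct_mod_residue` record -- or, failing that, a built-in table
#' of common modifications (e.g. MSE to MET) -- gets its `parent` set and
#' `is_modified = TRUE`. Unmatched non-standard residues are retained
#' with `parent = "UNK"` so that nonnatural amino acids remain eligible
#' as knobs and holes. Annotation only: all geometry downstream uses the
#' atoms actually present, never the parent identity.
#'
#' @param s A `kih_structure`.
#' @return The structure with `parent` / `is_modified` columns filled in.
#' @export
apply_modres <- function(s) {
  at <- s$atoms
  at$parent <- at$resid
  at$is_modified <- FALSE
  nonstd <- !(at$resid %in% STANDARD_AA)
  if (any(nonstd)) {
    key <- res_uid(at$chain, at$resno, at$ins)
    if (nrow(s$modres) > 0L) {
      mr <- s$modres
      mr_key <- res_uid(mr$chain, mr$resno, mr$ins)
      hit <- match(key, mr_key)
      ok <- !is.na(hit) & nonstd & at$resid == mr$het_code[ifelse(is.na(hit), 1L, hit)]
      at$parent[ok] <- mr$parent_code[hit[ok]]
      at$is_modified[ok] <- TRUE
      nonstd <- nonstd & !ok
    }
    builtin <- nonstd & at$resid %in% names(BUILTIN_MODRES)
    at$parent[builtin] <- BUILTIN_MODRES[at$resid[builtin]]
    at$is_modified[builtin] <- TRUE
    rest <- nonstd & !builtin
    at$parent[rest] <- "UNK"
    at$is_modified[rest] <- TRUE
  }
  s$atoms <- at
  s
}

#' Write a structure as a PDB file
#'
#' Emits ATOM/HETATM records (plus MODRES records for annotated modified
#' residues) with coordinates at the format's 3-decimal precision, one
#' TER per chain.
#'
#' @param s A `kih_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(s, path) {
  at <- s$atoms
  out <- character(0)
  if (any(at$is_modified & at$parent != "UNK")) {
    res <- residue_table(s)
    mod <- dplyr::filter(res, .data$is_modified, .data$parent != "UNK")
    out <- sprintf("MODRES XXXX %3s %1s %4d%1s %3s", mod$resid, mod$chain,
                   mod$resno, ifelse(nzchar(mod$ins), mod$ins, " "),
                   mod$parent)
  }
  eleno <- 0L
  for (ch in unique(at$chain)) {
    ca <- at[at$chain == ch, ]
    nm <- ifelse(nchar(ca$elety) < 4 & nchar(ca$elesy) == 1,
                 sprintf(" %-3s", ca$elety), sprintf("%-4s", ca$elety))
    rec <- sprintf("%-6s%5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   ifelse(ca$het, "HETATM", "ATOM"),
                   eleno + seq_len(nrow(ca)), nm, ca$resid, ca$chain,
                   ca$resno, ifelse(nzchar(ca$ins), ca$ins, " "),
                   ca$x, ca$y, ca$z, 1, 0, ca$elesy)
    eleno <- eleno + nrow(ca)
    out <- c(out, rec, sprintf("TER   %5d      %3s %1s%4d",
                               eleno + 1L, ca$resid[nrow(ca)], ch,
                               ca$resno[nrow(ca)]))
    eleno <- eleno + 1L
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Write a structure as a minimal mmCIF file
#'
#' Emits the `atom_site` loop (and `pdbx_struct_mod_residue` records for
#' annotated modified residues) sufficient to round-trip through
#' [read_structure()].
#'
#' @inheritParams write_structure_pdb
#' @return `path`, invisibly.
#' @export
write_structure_mmcif <- function(s, path) {
  at <- s$atoms
  header <- c(
    "data_kihscan",
    "#",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num"
  )
  rec <- sprintf("%-6s %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f 1.00 0.00 %d %s %s %s 1",
                 ifelse(at$het, "HETATM", "ATOM"), seq_len(nrow(at)),
                 at$elesy, at$elety, at$resid, at$chain, at$resno,
                 ifelse(nzchar(at$ins), at$ins, "?"),
                 at$x, at$y, at$z, at$resno, at$resid, at$chain, at$elety)
  out <- c(header, rec, "#")
  res <- residue_table(s)
  mod <- dplyr::filter(res, .data$is_modified, .data$parent != "UNK")
  if (nrow(mod) > 0L) {
    out <- c(out,
             "loop_",
             "_pdbx_struct_mod_residue.id",
             "_pdbx_struct_mod_residue.label_comp_id",
             "_pdbx_struct_mod_residue.auth_asym_id",
             "_pdbx_struct_mod_residue.auth_seq_id",
             "_pdbx_struct_mod_residue.PDB_ins_code",
             "_pdbx_struct_mod_residue.parent_comp_id",
             sprintf("%d %s %s %d %s %s", seq_len(nrow(mod)), mod$resid,
                     mod$chain, mod$resno,
                     ifelse(nzchar(mod$ins), mod$ins, "?"), mod$parent),
             "#")
  }
  writeLines(out, path)
  invisible(path)
}
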