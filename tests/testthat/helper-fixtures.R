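# Canonical test fixtures built from the Crick generator. Barrel radii
# keep the neighbour-helix separation at the canonical dimer value
# (2 * 4.9 A) and scale the pitch to preserve the supercoil pitch angle.

DIMER_R0 <- 4.9
DIMER_PITCH <- 148
PITCH_ANGLE <- atan2(2 * pi * DIMER_R0, DIMER_PITCH)

barrel_crick_params <- function(n, ...) {
  R0 <- DIMER_R0 / sin(pi / n)
  crick_params(n_helices = n, R0 = R0,
               pitch = 2 * pi * R0 / tan(PITCH_ANGLE), ...)
}

fx_dimer <- function(...) crick_backbone(crick_params(...))

fx_anti_dimer <- function(...) {
  crick_backbone(crick_params(orientation = "antiparallel", ...))
}

fx_barrel <- function(n, ...) crick_backbone(barrel_crick_params(n, ...))

# straight helix at the ideal laboratory twist (no supercoil frame)
fx_straight <- function(n_res = 21, ...) {
  tw <- 2 * pi / kihscan:::helix_template()$twist
  crick_backbone(crick_params(n_helices = 1, n_res = n_res, R0 = 0,
                              residues_per_turn = tw, ...))
}

# fully extended chain (phi = psi ~ 180): no helix anywhere
fx_extended <- function(n_res = 12) {
  at <- kihscan:::ideal_helix_atoms(n_res, phi = -179.9, psi = 179.9)
  rows <- do.call(rbind, lapply(seq_len(n_res), function(i) {
    data.frame(chain = "A", resno = i, ins = "", resid = "ALA",
               elety = c("N", "CA", "C", "O", "CB"),
               elesy = c("N", "C", "C", "O", "C"),
               x = c(at$N[i, 1], at$CA[i, 1], at$C[i, 1], at$O[i, 1], at$CB[i, 1]),
               y = c(at$N[i, 2], at$CA[i, 2], at$C[i, 2], at$O[i, 2], at$CB[i, 2]),
               z = c(at$N[i, 3], at$CA[i, 3], at$C[i, 3], at$O[i, 3], at$CB[i, 3]),
               het = FALSE)
  }))
  new_structure(rows)
}

# minimal one-residue PDB text (ALA with N, CA, C, O, CB)
minimal_ala_pdb <- function() {
  c("ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      10.762   6.828  -4.167  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       9.581   7.024  -4.426  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1      11.820   4.619  -4.713  1.00  0.00           C",
    "TER", "END")
}

minimal_ala_mmcif <- function() {
  c("data_test", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 11.104 6.134 -6.504 1.00 0.00 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 11.639 6.071 -5.147 1.00 0.00 1 ALA A CA 1",
    "ATOM 3 C C . ALA A 1 1 ? 10.762 6.828 -4.167 1.00 0.00 1 ALA A C 1",
    "ATOM 4 O O . ALA A 1 1 ? 9.581 7.024 -4.426 1.00 0.00 1 ALA A O 1",
    "ATOM 5 C CB . ALA A 1 1 ? 11.820 4.619 -4.713 1.00 0.00 1 ALA A CB 1",
    "#")
}

write_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# set-comparable key for knob records (knob + target helix + hole set)
knob_key <- function(k) {
  paste(k$knob_uid, k$knob_helix, k$hole_helix,
        vapply(k$hole_residues, function(u) paste(sort(u), collapse = "+"), ""))
}

# intended heptad letter of each knob residue, looked up per helix/chain
intended_letters_of <- function(s, knob_uids) {
  reg <- attr(s, "intended_register")
  chain <- sub("\\|.*$", "", knob_uids)
  resno <- as.integer(sub("^.*\\|", "", knob_uids))
  vapply(seq_along(knob_uids), function(i) {
    reg[[match(chain[i], LETTERS)]][resno[i]]
  }, "")
}
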