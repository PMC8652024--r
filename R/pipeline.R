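#' Run the full knobs-into-holes pipeline
#'
#' Executes the whole analysis: structure ingest, helix assignment
#' (classic DSSP file or the internal assigner), optional helix
#' extension, side-chain centers, inter-helix contacts at the packing
#' cutoff, knob/hole detection and classification, helix-pair
#' interfaces, coiled-coil assembly, heptad-register assignment and
#' helix-axis geometry. The pipeline is deterministic: identical inputs
#' and configuration yield identical results (and byte-identical
#' rendered outputs).
#'
#' @param input Path to a PDB/mmCIF file, or a `kih_structure`.
#' @param dssp Optional path to a classic DSSP output file; when `NULL`
#'   the internal assigner is used.
#' @param cutoff Packing cutoff, Angstrom (default 7; dial range 6-8
#'   unless `force = TRUE`).
#' @param extension Helix extension, residues (default 0).
#' @param min_helix_len Minimum helix length (default 7).
#' @param min_knobs Minimum total knobs for an interface (default 3).
#' @param format_hint Optional `"pdb"` / `"mmcif"` for file inputs.
#' @param force Allow cutoffs outside the 6-8 A dial range.
#' @return An object of class `kih_result`: a list of tibbles
#'   (`helices`, `axes`, `contacts`, `knobs`, `interfaces`,
#'   `assemblies`, `registers`, `residues`, `pairs`) plus the input
#'   `structure` and the `config` used.
#' @export
kihscan <- function(input, dssp = NULL, cutoff = 7, extension = 0L,
                    min_helix_len = 7L, min_knobs = 3L,
                    format_hint = NULL, force = FALSE) {
  if (!force && (cutoff < 6 || cutoff > 8)) {
    stop("packing cutoff must be within 6-8 A (use force = TRUE to ",
         "override)", call. = FALSE)
  }
  if (extension < 0) stop("extension must be >= 0", call. = FALSE)
  s <- if (inherits(input, "kih_structure")) input
       else read_structure(input, format_hint)
  ssmap <- if (is.null(dssp)) assign_helices_internal(s)
           else parse_dssp(dssp, s)
  helices <- build_helices(ssmap, s, min_len = min_helix_len)
  helices <- extend_helices(helices, s, ext = extension)
  centers <- side_chain_centers(s)
  contacts <- contact_map(helices, centers, cutoff = cutoff)
  knobs <- classify_knobs(find_knobs(contacts, centers), centers,
                          cutoff = cutoff)
  interfaces <- pair_interfaces(knobs, min_knobs = min_knobs)
  assemblies <- assemble_coiled_coils(interfaces, helices)
  axes <- fit_helix_axes(helices, s)
  pairs <- assembly_pair_table(assemblies, interfaces, axes)
  registers <- assembly_registers(assemblies, helices, knobs)
  residues <- assembly_residue_table(assemblies, helices, registers,
                                     knobs, s)
  structure(
    list(structure = s, ssmap = ssmap, helices = helices, axes = axes,
         centers = centers, contacts = contacts, knobs = knobs,
         interfaces = interfaces, assemblies = assemblies,
         registers = registers, residues = residues, pairs = pairs,
         config = list(cutoff = cutoff, extension = as.integer(extension),
                       min_helix_len = as.integer(min_helix_len),
                       min_knobs = as.integer(min_knobs),
                       ss_source = attr(ssmap, "source"))),
    class = "kih_result"
  )
}

#' @export
print.kih_result <- function(x, ...) {
  cat(sprintf("<kih_result> %d helix segment(s), %d knob(s), %d coiled coil(s)\n",
              nrow(x$helices), nrow(x$knobs), nrow(x$assemblies)))
  for (i in seq_len(nrow(x$assemblies))) {
    a <- x$assemblies[i, ]
    cat(sprintf("  CC %d: order %d, %s, helices [%s]\n", a$cc_id, a$order,
                a$topology, paste(a$helix_ids[[1]], collapse = ", ")))
  }
  invisible(x)
}

# Pair-level table: per assembly, every member interface with its
# orientation and interhelix angle.
assembly_pair_table <- function(assemblies, interfaces, axes) {
  out <- tibble::tibble(cc_id = integer(), helix_a = integer(),
                        helix_b = integer(), angle = numeric(),
                        orientation = character(),
                        n_knobs = integer(), n_complementary = integer())
  for (i in seq_len(nrow(assemblies))) {
    ids <- assemblies$helix_ids[[i]]
    sub <- interfaces[interfaces$is_coiled_coil &
                        interfaces$helix_a %in% ids &
                        interfaces$helix_b %in% ids, ]
    for (j in seq_len(nrow(sub))) {
      po <- pair_orientation(axes[axes$helix_id == sub$helix_a[j], ],
                             axes[axes$helix_id == sub$helix_b[j], ])
      out <- dplyr::bind_rows(out, tibble::tibble(
        cc_id = assemblies$cc_id[i],
        helix_a = sub$helix_a[j], helix_b = sub$helix_b[j],
        angle = po$angle, orientation = po$orientation,
        n_knobs = sub$n_knobs_ab[j] + sub$n_knobs_ba[j],
        n_complementary = sub$n_complementary[j]
      ))
    }
  }
  out
}

# Register assignment for every helix of every assembly, driven by the
# knobs that helix projects into other members of the same assembly.
assembly_registers <- function(assemblies, helices, knobs) {
  out <- tibble::tibble(cc_id = integer(), helix_id = integer(),
                        assigned = logical(), anchor_residue = character(),
                        anchor_letter = character(), conflicts = integer(),
                        letters = list())
  for (i in seq_len(nrow(assemblies))) {
    ids <- assemblies$helix_ids[[i]]
    for (h in ids) {
      hx <- helices[helices$helix_id == h, ]
      kk <- knobs[knobs$knob_helix == h & knobs$hole_helix %in% ids, ]
      ra <- assign_register(hx, kk$knob_uid)
      out <- dplyr::bind_rows(out, tibble::tibble(
        cc_id = assemblies$cc_id[i], helix_id = h,
        assigned = ra$assigned, anchor_residue = ra$anchor_residue,
        anchor_letter = ra$anchor_letter, conflicts = ra$conflicts,
        letters = list(ra$letters)
      ))
    }
  }
  out
}

# Residue-level table covering every residue of every member helix.
assembly_residue_table <- function(assemblies, helices, registers, knobs,
                                   s) {
  res <- residue_table(s)
  out <- list()
  for (i in seq_len(nrow(registers))) {
    h <- registers$helix_id[i]
    hx <- helices[helices$helix_id == h, ]
    uids <- hx$residues[[1]]
    m <- match(uids, res$res_uid)
    kk <- knobs[knobs$knob_helix == h, ]
    ktype <- integer(length(uids))
    isk <- uids %in% kk$knob_uid
    ktype[isk] <- vapply(uids[isk], function(u) {
      max(kk$knob_type[kk$knob_uid == u])
    }, integer(1))
    out[[i]] <- tibble::tibble(
      cc_id = registers$cc_id[i], helix_id = h,
      chain = res$chain[m], resno = res$resno[m], ins = res$ins[m],
      resid = res$resid[m], parent = res$parent[m],
      register = registers$letters[[i]],
      is_knob = isk,
      knob_type = ifelse(isk, ktype, NA_integer_)
    )
  }
  dplyr::bind_rows(out)
}
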