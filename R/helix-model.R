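#' Parse a classic DSSP output file
#'
#' Reads the fixed-column data block of a classic (non-mmCIF) DSSP
#' output file and returns the per-residue secondary-structure map.
#' Chain-break markers (`!`) are kept as break rows so that segments are
#' never built across them. Codes other than H, G, I, E collapse to
#' `"other"`.
#'
#' @param path Path to a `.dssp` file.
#' @param s The `kih_structure` the assignments belong to; every
#'   DSSP-listed residue must exist in it.
#' @return A tibble with columns `chain`, `resno`, `ins`, `ss`
#'   (`H`/`G`/`I`/`E`/`other`), `res_uid`, `is_break`, and attribute
#'   `source = "dssp_file"`.
#' @export
parse_dssp <- function(path, s) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0L) {
    stop("not a classic DSSP file (no '  #  RESIDUE' header line); ",
         "the mmCIF DSSP dialect is not supported -- regenerate with ",
         "classic output or use internal_ss = TRUE", call. = FALSE)
  }
  body <- lines[seq(hdr[1] + 1L, length(lines))]
  body <- body[nchar(trimws(body)) > 0]
  body <- formatC(body, width = -17)   # pad short (break) lines
  aa <- substr(body, 14, 14)
  brk <- aa == "!"
  map <- tibble::tibble(
    chain = trimws(substr(body, 12, 12)),
    resno = suppressWarnings(as.integer(trimws(substr(body, 6, 10)))),
    ins = trimws(substr(body, 11, 11)),
    ss = substr(body, 17, 17),
    is_break = brk
  )
  map$ss <- ifelse(map$ss %in% c("H", "G", "I", "E"), map$ss, "other")
  map$ss[brk] <- "other"
  map$res_uid <- res_uid(map$chain, map$resno, map$ins)
  known <- residue_table(s)$res_uid
  missing <- setdiff(map$res_uid[!brk], known)
  if (length(missing) > 0L) {
    stop("DSSP residues absent from structure: ",
         paste(utils::head(missing, 10L), collapse = ", "),
         if (length(missing) > 10L) " ..." else "", call. = FALSE)
  }
  attr(map, "source") <- "dssp_file"
  map
}

# Kabsch-Sander electrostatic H-bond energy coupling constant,
# kcal/(mol A): q1*q2*f = 0.42 * 0.20 * 332.
KS_COUPLING <- 27.888
KS_CUTOFF <- -0.5

#' Assign alpha-helices from backbone geometry
#'
#' Internal secondary-structure assigner following the Kabsch-Sander
#' hydrogen-bond model: the amide H is reconstructed from the preceding
#' peptide plane (1 A from N along the previous C=O bond direction) and
#' the bond energy is
#' `E = 27.888 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol, a bond
#' forming when `E < -0.5`. A residue is labelled `H` when it lies in a
#' run supported by two consecutive `i -> i+4` turns, matching DSSP's
#' alpha-helix convention. Removes the external-DSSP requirement; only
#' the alpha-helix assignment is implemented (no sheets, turns or
#' bridges).
#'
#' @param s A `kih_structure` with backbone atoms N, CA, C, O.
#' @return Secondary-structure map in the same shape as [parse_dssp()],
#'   with attribute `source = "internal"`.
#' @export
assign_helices_internal <- function(s) {
  res <- residue_table(s)
  at <- s$atoms
  bb <- function(name) {
    m <- matrix(NA_real_, nrow(res), 3)
    sel <- at[at$elety == name, ]
    idx <- match(sel$res_uid, res$res_uid)
    m[idx, ] <- as.matrix(sel[, c("x", "y", "z")])
    m
  }
  N <- bb("N"); CA <- bb("CA"); C <- bb("C"); O <- bb("O")
  ok <- stats::complete.cases(N) & stats::complete.cases(CA) &
    stats::complete.cases(C) & stats::complete.cases(O)
  if (any(!ok)) {
    warning(sum(!ok), " residue(s) lack backbone atoms; labelled 'other'",
            call. = FALSE)
  }
  n <- nrow(res)
  # contiguity: same chain, author numbering advancing by 1
  contig <- c(FALSE, res$chain[-1] == res$chain[-n] &
                res$resno[-1] - res$resno[-n] == 1L)
  # amide H from the preceding peptide plane
  H <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)[-1]) {
    if (contig[i] && ok[i] && ok[i - 1]) {
      d <- C[i - 1, ] - O[i - 1, ]
      H[i, ] <- N[i, ] + d / sqrt(sum(d^2))
    }
  }
  hbond_energy <- function(i, j) {
    # CO of residue i accepting from NH of residue j
    if (!ok[i] || !ok[j] || any(is.na(H[j, ]))) return(NA_real_)
    rON <- sqrt(sum((O[i, ] - N[j, ])^2))
    rCH <- sqrt(sum((C[i, ] - H[j, ])^2))
    rOH <- sqrt(sum((O[i, ] - H[j, ])^2))
    rCN <- sqrt(sum((C[i, ] - N[j, ])^2))
    if (min(rON, rCH, rOH, rCN) < 0.5) return(NA_real_)
    KS_COUPLING * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
  }
  same_run <- function(i, j) {
    # i..j contiguous on one chain
    j <= n && i >= 1 && all(contig[seq(i + 1L, j)])
  }
  turn4 <- logical(n)
  for (i in seq_len(n)) {
    if (i + 4L <= n && same_run(i, i + 4L)) {
      e <- hbond_energy(i, i + 4L)
      turn4[i] <- !is.na(e) && e < KS_CUTOFF
    }
  }
  ss <- rep("other", n)
  # minimal 4-helix i..i+3 requires turns at i-1 and i
  for (i in seq_len(n)) {
    if (i > 1 && turn4[i - 1] && turn4[i] && same_run(i - 1L, i + 4L)) {
      ss[i:(i + 3L)] <- "H"
    }
  }
  map <- tibble::tibble(
    chain = res$chain, resno = res$resno, ins = res$ins,
    ss = ss, is_break = FALSE, res_uid = res$res_uid
  )
  attr(map, "source") <- "internal"
  map
}

#' Build helix segments from a secondary-structure map
#'
#' Maximal runs of consecutive `H` residues on one chain (contiguous in
#' author numbering, never across a DSSP chain-break marker) of at least
#' `min_len` residues become helix segments, ordered by chain and first
#' residue. 3-10 (`G`) and pi (`I`) codes do not seed segments unless
#' `include_310_pi = TRUE`.
#'
#' @param ssmap Map from [parse_dssp()] or [assign_helices_internal()].
#' @param s The corresponding `kih_structure`.
#' @param min_len Minimum segment length in residues (default 7, one
#'   heptad).
#' @param include_310_pi Also accept `G`/`I` codes as helical.
#' @return Tibble of helix segments: `helix_id`, `chain`, `first_resno`,
#'   `last_resno`, `n_res`, `extended_n`, `extended_c`, and a `residues`
#'   list-column of `res_uid`s in N-to-C order.
#' @export
build_helices <- function(ssmap, s, min_len = 7L, include_310_pi = FALSE) {
  res <- residue_table(s)
  helical_codes <- if (include_310_pi) c("H", "G", "I") else "H"
  keyed <- ssmap[!ssmap$is_break, ]
  hel <- res$res_uid %in% keyed$res_uid[keyed$ss %in% helical_codes]
  # break runs at chain changes, numbering gaps, or DSSP '!' markers
  n <- nrow(res)
  if (n == 0L) return(empty_helices())
  contig <- c(FALSE, res$chain[-1] == res$chain[-n] &
                res$resno[-1] - res$resno[-n] == 1L)
  brk <- dssp_breaks(ssmap, res)
  contig[brk] <- FALSE
  run_id <- cumsum(!(hel & contig)) # increments when a run cannot extend
  segs <- list()
  for (g in split(seq_len(n)[hel], run_id[hel])) {
    if (length(g) >= min_len) segs[[length(segs) + 1L]] <- g
  }
  if (length(segs) == 0L) return(empty_helices())
  ord <- order(vapply(segs, function(g) res$chain[g[1]], ""),
               vapply(segs, function(g) res$resno[g[1]], 1L))
  segs <- segs[ord]
  tibble::tibble(
    helix_id = seq_along(segs),
    chain = vapply(segs, function(g) res$chain[g[1]], ""),
    first_resno = vapply(segs, function(g) res$resno[g[1]], 1L),
    last_resno = vapply(segs, function(g) res$resno[g[length(g)]], 1L),
    n_res = lengths(segs),
    extended_n = 0L, extended_c = 0L,
    residues = lapply(segs, function(g) res$res_uid[g])
  )
}

empty_helices <- function() {
  tibble::tibble(helix_id = integer(), chain = character(),
                 first_resno = integer(), last_resno = integer(),
                 n_res = integer(), extended_n = integer(),
                 extended_c = integer(), residues = list())
}

# Indices (into the residue table) immediately after a DSSP '!' marker:
# contiguity is severed there even if author numbering continues.
dssp_breaks <- function(ssmap, res) {
  if (!any(ssmap$is_break)) return(integer(0))
  pos <- which(ssmap$is_break)
  after <- pos + 1L
  after <- after[after <= nrow(ssmap)]
  match(ssmap$res_uid[after], res$res_uid, nomatch = 0L)
}

#' Extend helix segments by a fixed number of residues
#'
#' Implements the "helix extension" dial: each segment grows by up to
#' `ext` residues at each end, one residue per round in helix order,
#' only over residues that exist on the same chain with contiguous
#' numbering and that are not (and do not become) members of another
#' segment. Segments that would touch are never merged.
#'
#' @param helices Output of [build_helices()].
#' @param s The corresponding `kih_structure`.
#' @param ext Non-negative residue count (default 0, a no-op).
#' @return The helices tibble with grown `residues`, updated bounds and
#'   `extended_n` / `extended_c` counts.
#' @export
extend_helices <- function(helices, s, ext = 0L) {
  stopifnot(ext >= 0)
  if (ext == 0L || nrow(helices) == 0L) return(helices)
  res <- residue_table(s)
  taken <- unlist(helices$residues, use.names = FALSE)
  idx_of <- function(uid) match(uid, res$res_uid)
  n <- nrow(res)
  contig_prev <- function(i) {
    i > 1 && res$chain[i - 1] == res$chain[i] &&
      res$resno[i] - res$resno[i - 1] == 1L
  }
  for (round in seq_len(ext)) {
    for (h in seq_len(nrow(helices))) {
      uids <- helices$residues[[h]]
      i1 <- idx_of(uids[1])
      if (contig_prev(i1) && !(res$res_uid[i1 - 1] %in% taken)) {
        uids <- c(res$res_uid[i1 - 1], uids)
        taken <- c(taken, res$res_uid[i1 - 1])
        helices$extended_n[h] <- helices$extended_n[h] + 1L
      }
      i2 <- idx_of(uids[length(uids)])
      if (i2 < n && contig_prev(i2 + 1L) &&
          !(res$res_uid[i2 + 1] %in% taken)) {
        uids <- c(uids, res$res_uid[i2 + 1])
        taken <- c(taken, res$res_uid[i2 + 1])
        helices$extended_c[h] <- helices$extended_c[h] + 1L
      }
      helices$residues[[h]] <- uids
    }
  }
  for (h in seq_len(nrow(helices))) {
    uids <- helices$residues[[h]]
    helices$first_resno[h] <- res$resno[idx_of(uids[1])]
    helices$last_resno[h] <- res$resno[idx_of(uids[length(uids)])]
    helices$n_res[h] <- length(uids)
  }
  helices
}
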