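#' Side-chain centers for all residues of a structure
#'
#' The side-chain center is the unweighted centroid of the heavy atoms
#' from CB outward (backbone N, CA, C, O, OXT excluded; hydrogens were
#' stripped on ingest). Glycine -- or any residue with no side-chain
#' heavy atoms -- uses its CA position. Residues with an incomplete side
#' chain use the centroid of the atoms present, with a warning; residues
#' with neither CA nor side-chain atoms are skipped with a warning.
#'
#' @param s A `kih_structure`.
#' @return Tibble with one row per residue: `res_uid`, `chain`, `resno`,
#'   `ins`, `resid`, `parent`, side-chain center `x`, `y`, `z`,
#'   `n_atoms` (side-chain heavy atoms used; 0 means CA fallback) and CA
#'   coordinates `ca_x`, `ca_y`, `ca_z`.
#' @export
side_chain_centers <- function(s) {
  at <- s$atoms
  sc <- at[!(at$elety %in% BACKBONE_ATOMS), ]
  ca <- at[at$elety == "CA", ]
  res <- residue_table(s)
  ctr <- dplyr::summarise(
    dplyr::group_by(sc, .data$res_uid),
    sx = mean(.data$x), sy = mean(.data$y), sz = mean(.data$z),
    sc_n = dplyr::n(), .groups = "drop"
  )
  out <- dplyr::left_join(res, ctr, by = "res_uid")
  cam <- match(out$res_uid, ca$res_uid)
  out$ca_x <- ca$x[cam]; out$ca_y <- ca$y[cam]; out$ca_z <- ca$z[cam]
  no_ca <- is.na(out$ca_x)
  no_sc <- is.na(out$sx)
  drop <- no_ca & no_sc
  if (any(drop)) {
    warning(sum(drop), " residue(s) with neither CA nor side-chain atoms ",
            "skipped", call. = FALSE)
    out <- out[!drop, ]
    no_sc <- is.na(out$sx)
  }
  # glycine / missing side chain: fall back to CA
  out$sx[no_sc] <- out$ca_x[no_sc]
  out$sy[no_sc] <- out$ca_y[no_sc]
  out$sz[no_sc] <- out$ca_z[no_sc]
  out$sc_n[no_sc] <- 0L
  tibble::tibble(
    res_uid = out$res_uid, chain = out$chain, resno = out$resno,
    ins = out$ins, resid = out$resid, parent = out$parent,
    x = out$sx, y = out$sy, z = out$sz, n_atoms = out$sc_n,
    ca_x = out$ca_x, ca_y = out$ca_y, ca_z = out$ca_z
  )
}

# Map res_uid -> helix_id for residues belonging to helix segments.
helix_membership <- function(helices) {
  if (nrow(helices) == 0L) {
    return(tibble::tibble(res_uid = character(), helix_id = integer()))
  }
  tibble::tibble(
    res_uid = unlist(helices$residues, use.names = FALSE),
    helix_id = rep(helices$helix_id, lengths(helices$residues))
  )
}

#' Inter-helix side-chain contacts
#'
#' All unordered pairs of helix residues on *different* helix segments
#' whose side-chain centers lie within the packing cutoff (inclusive
#' boundary). Intra-helix pairs are never reported.
#'
#' @param helices Helix segments from [build_helices()].
#' @param centers Side-chain centers from [side_chain_centers()].
#' @param cutoff Packing cutoff in Angstrom (default 7).
#' @return Tibble with `res_a`, `res_b` (res_uids, `helix_a <= helix_b`
#'   order), `helix_a`, `helix_b`, `distance`.
#' @export
contact_map <- function(helices, centers, cutoff = 7) {
  stopifnot(cutoff > 0)
  mem <- helix_membership(helices)
  cen <- dplyr::inner_join(centers, mem, by = "res_uid")
  n <- nrow(cen)
  if (n < 2L) return(empty_contacts())
  xyz <- as.matrix(cen[, c("x", "y", "z")])
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
  d2[d2 < 0] <- 0
  cross <- outer(cen$helix_id, cen$helix_id, "!=")
  hit <- which(upper.tri(d2) & cross & d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(empty_contacts())
  i <- hit[, 1]; j <- hit[, 2]
  swap <- cen$helix_id[i] > cen$helix_id[j]
  a <- ifelse(swap, j, i); b <- ifelse(swap, i, j)
  tibble::tibble(
    res_a = cen$res_uid[a], res_b = cen$res_uid[b],
    helix_a = cen$helix_id[a], helix_b = cen$helix_id[b],
    distance = sqrt(d2[cbind(i, j)])
  ) |>
    dplyr::arrange(.data$helix_a, .data$helix_b, .data$res_a, .data$res_b)
}

empty_contacts <- function() {
  tibble::tibble(res_a = character(), res_b = character(),
                 helix_a = integer(), helix_b = integer(),
                 distance = numeric())
}

#' Find knob residues and their four-residue holes
#'
#' A residue is a knob into helix H when its side-chain center lies
#' within the cutoff of at least four side-chain centers of residues on
#' H; its hole is the four contacted residues nearest to the knob
#' center, distance ties broken by ascending residue number. A residue
#' may be a knob into several helices (one record per target helix).
#'
#' @param contacts Output of [contact_map()] (same cutoff).
#' @param centers Side-chain centers from [side_chain_centers()].
#' @return Tibble with one row per (knob residue, target helix):
#'   `knob_uid`, `knob_helix`, `hole_helix`, `hole_residues`
#'   (list-column of 4 res_uids ordered by distance), `hole_distances`
#'   (list-column), and hole centroid `hole_x`, `hole_y`, `hole_z`.
#' @export
find_knobs <- function(contacts, centers) {
  if (nrow(contacts) == 0L) return(empty_knobs())
  # directional view: each contact seen from both residues
  dir_ <- dplyr::bind_rows(
    tibble::tibble(knob_uid = contacts$res_a, knob_helix = contacts$helix_a,
                   partner = contacts$res_b, hole_helix = contacts$helix_b,
                   distance = contacts$distance),
    tibble::tibble(knob_uid = contacts$res_b, knob_helix = contacts$helix_b,
                   partner = contacts$res_a, hole_helix = contacts$helix_a,
                   distance = contacts$distance)
  )
  key <- match(dir_$partner, centers$res_uid)
  dir_$p_resno <- centers$resno[key]
  dir_$p_ins <- centers$ins[key]
  grp <- dplyr::group_by(dir_, .data$knob_uid, .data$knob_helix,
                         .data$hole_helix)
  knobs <- grp |>
    dplyr::arrange(.data$distance, .data$p_resno, .data$p_ins,
                   .by_group = TRUE) |>
    dplyr::filter(dplyr::n() >= 4L) |>
    dplyr::summarise(
      hole_residues = list(.data$partner[1:4]),
      hole_distances = list(.data$distance[1:4]),
      .groups = "drop"
    )
  if (nrow(knobs) == 0L) return(empty_knobs())
  hxyz <- t(vapply(knobs$hole_residues, function(u) {
    m <- match(u, centers$res_uid)
    c(mean(centers$x[m]), mean(centers$y[m]), mean(centers$z[m]))
  }, numeric(3)))
  knobs$hole_x <- hxyz[, 1]; knobs$hole_y <- hxyz[, 2]; knobs$hole_z <- hxyz[, 3]
  dplyr::arrange(knobs, .data$knob_helix, .data$hole_helix, .data$knob_uid)
}

empty_knobs <- function() {
  tibble::tibble(knob_uid = character(), knob_helix = integer(),
                 hole_helix = integer(), hole_residues = list(),
                 hole_distances = list(), hole_x = numeric(),
                 hole_y = numeric(), hole_z = numeric())
}

#' Classify knobs by insertion depth and compute packing angles
#'
#' The packing angle is measured in degrees between the knob's
#' CA-to-side-chain-center vector and its CA-to-hole-center vector (0
#' degrees = the side chain points straight at the hole). The 4-level
#' insertion type is: type 4 when the knob's CA is itself within the
#' cutoff of all four hole side-chain centers *and* the packing angle is
#' below 45 degrees; type 3 when only the angle criterion holds; type 2
#' for angles in [45, 90); type 1 otherwise. Glycine knobs (side-chain
#' center equal to CA) have an undefined angle, reported as `NA`, and
#' type 1.
#'
#' @param knobs Output of [find_knobs()].
#' @param centers Side-chain centers from [side_chain_centers()].
#' @param cutoff Packing cutoff in Angstrom (same dial as the contacts).
#' @param angle_core Type boundary between core-pointing and lateral
#'   knobs, degrees (default 45).
#' @param angle_peripheral Boundary between lateral and peripheral
#'   knobs, degrees (default 90).
#' @return `knobs` with `packing_angle` (degrees) and `knob_type` (1-4)
#'   columns added.
#' @export
classify_knobs <- function(knobs, centers, cutoff = 7,
                           angle_core = 45, angle_peripheral = 90) {
  if (nrow(knobs) == 0L) {
    knobs$packing_angle <- numeric(0)
    knobs$knob_type <- integer(0)
    return(knobs)
  }
  m <- match(knobs$knob_uid, centers$res_uid)
  ca <- cbind(centers$ca_x[m], centers$ca_y[m], centers$ca_z[m])
  sc <- cbind(centers$x[m], centers$y[m], centers$z[m])
  hc <- cbind(knobs$hole_x, knobs$hole_y, knobs$hole_z)
  v1 <- sc - ca
  v2 <- hc - ca
  n1 <- sqrt(rowSums(v1^2)); n2 <- sqrt(rowSums(v2^2))
  cosang <- rowSums(v1 * v2) / (n1 * n2)
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  ang[n1 < 1e-6 | n2 < 1e-6] <- NA_real_
  ca_in_hole <- vapply(seq_len(nrow(knobs)), function(i) {
    hm <- match(knobs$hole_residues[[i]], centers$res_uid)
    hxyz <- cbind(centers$x[hm], centers$y[hm], centers$z[hm])
    all(sqrt(rowSums(sweep(hxyz, 2, ca[i, ])^2)) <= cutoff)
  }, logical(1))
  type <- rep(1L, nrow(knobs))
  defined <- !is.na(ang)
  type[defined & ang < angle_peripheral] <- 2L
  type[defined & ang < angle_core] <- 3L
  type[defined & ang < angle_core & ca_in_hole] <- 4L
  knobs$packing_angle <- ang
  knobs$knob_type <- type
  knobs
}

#' Group knobs into helix-pair interfaces
#'
#' For each unordered helix pair with at least one knob in either
#' direction, knobs are collected both ways and complementary pairs are
#' identified: knobs `k1` (A into B) and `k2` (B into A) are
#' complementary when each sits in the other's hole. A pair of helices
#' forms a coiled-coil interface when it has at least one complementary
#' pair and at least `min_knobs` knobs in total (both directions);
#' single spurious contacts are thereby suppressed.
#'
#' @param knobs Classified knobs from [classify_knobs()].
#' @param min_knobs Minimum total knob count for acceptance (default 3).
#' @return Tibble with `helix_a`, `helix_b` (`helix_a < helix_b`),
#'   `n_knobs_ab`, `n_knobs_ba`, `n_complementary`,
#'   `complementary_pairs` (list-column of two-column matrices of
#'   res_uids) and `is_coiled_coil`.
#' @export
pair_interfaces <- function(knobs, min_knobs = 3L) {
  if (nrow(knobs) == 0L) return(empty_interfaces())
  ha <- pmin(knobs$knob_helix, knobs$hole_helix)
  hb <- pmax(knobs$knob_helix, knobs$hole_helix)
  keys <- unique(paste(ha, hb))
  out <- lapply(keys, function(k) {
    hs <- as.integer(strsplit(k, " ")[[1]])
    a <- hs[1]; b <- hs[2]
    kab <- knobs[knobs$knob_helix == a & knobs$hole_helix == b, ]
    kba <- knobs[knobs$knob_helix == b & knobs$hole_helix == a, ]
    comp <- list()
    for (i in seq_len(nrow(kab))) {
      for (j in seq_len(nrow(kba))) {
        if (kba$knob_uid[j] %in% kab$hole_residues[[i]] &&
            kab$knob_uid[i] %in% kba$hole_residues[[j]]) {
          comp[[length(comp) + 1L]] <- c(kab$knob_uid[i], kba$knob_uid[j])
        }
      }
    }
    cp <- if (length(comp) > 0L) do.call(rbind, comp) else
      matrix(character(0), ncol = 2)
    tibble::tibble(
      helix_a = a, helix_b = b,
      n_knobs_ab = nrow(kab), n_knobs_ba = nrow(kba),
      n_complementary = nrow(cp),
      complementary_pairs = list(cp),
      is_coiled_coil = nrow(cp) >= 1L && (nrow(kab) + nrow(kba)) >= min_knobs
    )
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$helix_a, .data$helix_b)
}

empty_interfaces <- function() {
  tibble::tibble(helix_a = integer(), helix_b = integer(),
                 n_knobs_ab = integer(), n_knobs_ba = integer(),
                 n_complementary = integer(), complementary_pairs = list(),
                 is_coiled_coil = logical())
}
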