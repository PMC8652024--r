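#' Brute-force knob detection oracle
#'
#' Literal, loop-based re-derivation of the knob definition with no
#' vectorisation or spatial indexing: side-chain centers are recomputed
#' by explicit atom averaging, all pairwise center distances are taken,
#' the at-least-four-contacts-on-one-helix rule and the
#' four-nearest-hole rule are applied directly. Intended as an
#' independent check of [find_knobs()]; its output is comparable
#' set-wise via the `knob_uid`/`knob_helix`/`hole_helix` key and the
#' sorted hole residue sets.
#'
#' @param s A `kih_structure`.
#' @param helices Helix segments from [build_helices()].
#' @param cutoff Packing cutoff, Angstrom.
#' @return Tibble with `knob_uid`, `knob_helix`, `hole_helix` and
#'   `hole_residues` (list-column of 4 res_uids ordered by distance).
#' @export
brute_force_knobs <- function(s, helices, cutoff = 7) {
  res <- residue_table(s)
  at <- s$atoms
  # residue -> helix map
  hel_of <- rep(NA_integer_, nrow(res))
  for (h in seq_len(nrow(helices))) {
    hel_of[match(helices$residues[[h]], res$res_uid)] <- helices$helix_id[h]
  }
  keep <- which(!is.na(hel_of))
  centers <- matrix(NA_real_, nrow(res), 3)
  for (i in keep) {
    rows <- at[at$res_uid == res$res_uid[i], ]
    sc <- rows[!(rows$elety %in% BACKBONE_ATOMS), ]
    if (nrow(sc) == 0L) sc <- rows[rows$elety == "CA", ]
    if (nrow(sc) == 0L) next
    centers[i, ] <- c(mean(sc$x), mean(sc$y), mean(sc$z))
  }
  out <- list()
  for (i in keep) {
    if (anyNA(centers[i, ])) next
    for (h in unique(hel_of[keep])) {
      if (identical(h, hel_of[i])) next
      partners <- integer(0)
      dists <- numeric(0)
      for (j in keep[hel_of[keep] == h]) {
        if (anyNA(centers[j, ])) next
        d <- sqrt(sum((centers[i, ] - centers[j, ])^2))
        if (d <= cutoff) {
          partners <- c(partners, j)
          dists <- c(dists, d)
        }
      }
      if (length(partners) >= 4L) {
        ord <- order(dists, res$resno[partners], res$ins[partners])
        hole <- partners[ord][1:4]
        out[[length(out) + 1L]] <- tibble::tibble(
          knob_uid = res$res_uid[i], knob_helix = hel_of[i],
          hole_helix = h,
          hole_residues = list(res$res_uid[hole])
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(knob_uid = character(), knob_helix = integer(),
                          hole_helix = integer(), hole_residues = list()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$knob_helix, .data$hole_helix,
                 .data$knob_uid)
}
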