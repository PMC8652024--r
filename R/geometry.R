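#' Fit a straight axis to each helix segment
#'
#' CA positions are first smoothed with a running mean over roughly two
#' helical turns (window 7, shrunk for short segments) to suppress the
#' helical wiggle; the axis direction is the principal component of the
#' smoothed points (largest-variance axis of the centered cloud),
#' sign-fixed so that it points N to C. The centroid is the CA mean and
#' the rmsd is the root-mean-square perpendicular deviation of the
#' smoothed axis trace from the fitted line (near zero for an ideal
#' straight helix, growing with supercoil curvature). Helices with
#' fewer than `min_ca` CA atoms get an `NA` axis.
#'
#' @param helices Helix segments from [build_helices()].
#' @param s The corresponding `kih_structure`.
#' @param min_ca Minimum number of CA atoms required for a fit.
#' @return Tibble with `helix_id`, centroid `cx`, `cy`, `cz`, direction
#'   `dir_x`, `dir_y`, `dir_z` (unit length, N->C) and `rmsd` (A).
#' @export
fit_helix_axes <- function(helices, s, min_ca = 7L) {
  ca <- s$atoms[s$atoms$elety == "CA", ]
  rows <- lapply(seq_len(nrow(helices)), function(h) {
    uids <- helices$residues[[h]]
    m <- ca[match(uids, ca$res_uid), ]
    m <- m[!is.na(m$res_uid), ]
    if (nrow(m) < min_ca) {
      return(tibble::tibble(helix_id = helices$helix_id[h],
                            cx = NA_real_, cy = NA_real_, cz = NA_real_,
                            dir_x = NA_real_, dir_y = NA_real_,
                            dir_z = NA_real_, rmsd = NA_real_))
    }
    xyz <- as.matrix(m[, c("x", "y", "z")])
    n <- nrow(xyz)
    w <- min(7L, n - 1L)
    sm <- t(vapply(seq_len(n - w + 1L), function(i) {
      colMeans(xyz[i:(i + w - 1L), , drop = FALSE])
    }, numeric(3)))
    ctr <- colMeans(xyz)
    rel <- sweep(sm, 2, colMeans(sm))
    sv <- svd(rel)
    d <- sv$v[, 1]
    if (sum(d * (xyz[n, ] - xyz[1, ])) < 0) d <- -d
    perp2 <- rowSums(rel^2) - (rel %*% d)^2
    tibble::tibble(helix_id = helices$helix_id[h],
                   cx = ctr[1], cy = ctr[2], cz = ctr[3],
                   dir_x = d[1], dir_y = d[2], dir_z = d[3],
                   rmsd = sqrt(mean(pmax(perp2, 0))))
  })
  dplyr::bind_rows(rows)
}

#' Angle between two helix axes
#'
#' @param a,b Unit direction 3-vectors (N->C).
#' @return Angle in degrees in `[0, 180]` (arccosine of the clamped dot
#'   product).
#' @export
interhelix_angle <- function(a, b) {
  d <- sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  acos(pmin(1, pmax(-1, d))) * 180 / pi
}

#' Per-knob packing-angle table for an assembly
#'
#' One row per knob of the assembly with its packing angle and insertion
#' type, suitable for the report module's distribution plot and CSV.
#' Knobs with an undefined angle (glycine) keep an `NA` angle.
#'
#' @param assembly One row of the assemblies tibble.
#' @param knobs Classified knobs from [classify_knobs()].
#' @return Tibble with `cc_id`, `knob_uid`, `knob_helix`, `hole_helix`,
#'   `packing_angle`, `knob_type`.
#' @export
knob_packing_angles <- function(assembly, knobs) {
  ids <- assembly$helix_ids[[1]]
  k <- knobs[knobs$knob_helix %in% ids & knobs$hole_helix %in% ids, ]
  tibble::tibble(
    cc_id = assembly$cc_id, knob_uid = k$knob_uid,
    knob_helix = k$knob_helix, hole_helix = k$hole_helix,
    packing_angle = k$packing_angle, knob_type = k$knob_type
  )
}
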