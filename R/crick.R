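cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Crick parameters for idealised coiled-coil generation
#'
#' Bundles the two-level helix parameterisation used by
#' [crick_backbone()]: an ideal \eqn{\alpha}-helix (minor helix, CA
#' radius `R1`) wound onto a left-handed superhelix of radius `R0` and
#' pitch `P`. Defaults follow canonical parallel-dimer values from the
#' coiled-coil literature (R0 = 4.9 A, R1 = 2.26 A, pitch 148 A).
#'
#' @param n_helices Number of helices (>= 1).
#' @param n_res Residues per helix (>= 7).
#' @param R0 Superhelical radius, Angstrom (0 gives a straight helix).
#' @param R1 Minor-helix (CA) radius, Angstrom.
#' @param pitch Superhelical pitch P, Angstrom (> 0).
#' @param residues_per_turn Minor-helix periodicity measured in the
#'   supercoil-following frame. The default 3.5 (= 7/2) is the canonical
#'   heptad value and corresponds to roughly 3.6 residues per turn in
#'   the laboratory frame for the default supercoil.
#' @param orientation Either a single `"parallel"` / `"antiparallel"`
#'   keyword or a vector of +1/-1 per helix. `"antiparallel"` alternates
#'   +1, -1, +1, ... around the bundle.
#' @param phase0 Superhelical phase offsets per helix, radians; default
#'   places helix i at `2*pi*(i-1)/n_helices` (Cn arrangement).
#' @param interface_phase Minor-helix phase (radians) of residue 1,
#'   measured from the outward radial direction. The default (`NULL`)
#'   points the heptad's a/d seam of CB pseudo-side chains at the
#'   superhelix axis so that residue 1 is an `a` position (intended
#'   register `a` for residues 1, 8, 15, ...).
#' @param rise Rise per residue along the helix axis, Angstrom.
#' @param jitter Gaussian coordinate noise s.d., Angstrom (< 0.3 so
#'   that knob assignments stay stable); 0 disables.
#' @param seed Integer seed used when `jitter > 0`.
#' @return An object of class `crick_params`.
#' @export
crick_params <- function(n_helices = 2L, n_res = 28L, R0 = 4.9, R1 = 2.26,
                         pitch = 148, residues_per_turn = 3.5,
                         orientation = "parallel", phase0 = NULL,
                         interface_phase = NULL, rise = 1.495,
                         jitter = 0, seed = 1L) {
  if (n_helices < 1L) stop("n_helices must be >= 1", call. = FALSE)
  if (n_res < 7L) stop("n_res must be >= 7", call. = FALSE)
  if (R0 < 0) stop("R0 must be >= 0", call. = FALSE)
  if (pitch <= 0) stop("pitch must be > 0", call. = FALSE)
  if (jitter < 0 || jitter >= 0.3) {
    if (jitter < 0) stop("jitter must be >= 0", call. = FALSE)
    stop("jitter must stay below 0.3 A", call. = FALSE)
  }
  if (is.character(orientation)) {
    orientation <- match.arg(orientation, c("parallel", "antiparallel"))
    orientation <- if (orientation == "parallel") rep(1L, n_helices)
                   else rep_len(c(1L, -1L), n_helices)
  }
  if (length(orientation) != n_helices || !all(orientation %in% c(-1, 1))) {
    stop("orientation must be +1/-1 per helix", call. = FALSE)
  }
  if (is.null(phase0)) phase0 <- 2 * pi * (seq_len(n_helices) - 1L) / n_helices
  if (length(phase0) != n_helices) {
    stop("phase0 must have one entry per helix", call. = FALSE)
  }
  # NULL interface_phase = resolved by crick_backbone(): the CB atoms of
  # positions a (residue 1) and d (residue 4) straddle the superhelix
  # axis, i.e. psi_a = pi + w1/4 - dphase_CB
  structure(
    list(n_helices = as.integer(n_helices), n_res = as.integer(n_res),
         R0 = R0, R1 = R1, pitch = pitch,
         residues_per_turn = residues_per_turn,
         orientation = as.integer(orientation), phase0 = phase0,
         interface_phase = interface_phase, rise = rise,
         jitter = jitter, seed = as.integer(seed)),
    class = "crick_params"
  )
}

# --- ideal straight-helix template -----------------------------------------

# Place atom D given reference atoms A, B, C, a bond length |CD|, a bond
# angle B-C-D (deg) and a torsion A-B-C-D (deg). Standard NeRF chain
# extension.
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Ideal tetrahedral C-beta from backbone N, CA, C (standard constants).
place_cb <- function(n, ca, c) {
  b <- ca - n
  cc <- c - ca
  a <- cross3(b, cc)
  ca + (-0.58273431) * a + 0.56802827 * b + (-0.54067466) * cc
}

# Build an ideal straight alpha-helix (phi = -57.8, psi = -47.0,
# omega = 180) with N, CA, C, O, CB per residue. Returns a list of
# n_res x 3 matrices.
ideal_helix_atoms <- function(n_res, phi = -57.8, psi = -47.0) {
  N <- CA <- C <- O <- CB <- matrix(NA_real_, n_res, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  C[1, ] <- nerf_place(c(-1, 0.5, 0), N[1, ], CA[1, ], 1.525, 111.2, psi + 120)
  for (i in seq_len(n_res)) {
    if (i > 1) {
      N[i, ] <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           1.329, 116.2, psi)
      CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ],
                            1.458, 121.7, 180)
      C[i, ] <- nerf_place(C[i - 1, ], N[i, ], CA[i, ], 1.525, 111.2, phi)
    }
    CB[i, ] <- place_cb(N[i, ], CA[i, ], C[i, ])
  }
  for (i in seq_len(n_res)) {
    # carbonyl O anti to the next amide N about the CA-C bond
    O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], 1.231, 120.8, psi - 180)
  }
  list(N = N, CA = CA, C = C, O = O, CB = CB)
}

# Cylindrical template of an ideal alpha-helix: per atom type, radius,
# phase offset and axial offset relative to the same residue's CA, plus
# the CA radius, twist per residue and rise measured from the built
# helix. Phases are measured in a right-handed frame about the N->C
# axis.
helix_template <- function() {
  n <- 21L
  at <- ideal_helix_atoms(n)
  ca <- at$CA
  ctr <- colMeans(ca)
  sv <- svd(sweep(ca, 2, ctr))
  ax <- sv$v[, 1]
  if (sum(ax * (ca[n, ] - ca[1, ])) < 0) ax <- -ax
  # right-handed orthonormal frame (e1, e2, ax)
  e1 <- c(ax[2], -ax[1], 0)
  if (sqrt(sum(e1^2)) < 1e-6) e1 <- c(1, 0, 0)
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(ax, e1)
  cyl <- function(m) {
    rel <- sweep(m, 2, ctr)
    u <- rel %*% e1
    v <- rel %*% e2
    list(r = sqrt(u^2 + v^2), phase = atan2(v, u), z = rel %*% ax)
  }
  cca <- cyl(ca)
  mid <- 5:(n - 5)   # interior residues, end effects excluded
  twist <- mean(diff(unwrap_phase(cca$phase[mid])))
  rise <- mean(diff(cca$z[mid]))
  per_atom <- function(m) {
    cc <- cyl(m)
    dphase <- atan2(sin(cc$phase - cca$phase), cos(cc$phase - cca$phase))
    c(r = mean(cc$r[mid]), dphase = mean(dphase[mid]),
      dz = mean((cc$z - cca$z)[mid]))
  }
  list(
    r_ca = mean(cca$r[mid]), twist = twist, rise = rise,
    atoms = list(N = per_atom(at$N), CA = per_atom(ca),
                 C = per_atom(at$C), O = per_atom(at$O),
                 CB = per_atom(at$CB))
  )
}

unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}

the <- new.env(parent = emptyenv())

get_helix_template <- function() {
  if (is.null(the$template)) the$template <- helix_template()
  the$template
}

# --- supercoiled backbone ---------------------------------------------------

#' Generate an idealised coiled-coil structure from Crick parameters
#'
#' CA positions follow the standard two-level parameterisation: a minor
#' helix of radius `R1` wound on a left-handed superhelix of radius `R0`
#' and pitch `pitch`. N, C, O and a single pseudo-side-chain CB atom are
#' placed around the CA trace using the cylindrical geometry of an ideal
#' straight \eqn{\alpha}-helix, expressed in the local
#' (radial, binormal, tangent) frame of the superhelical path. Helix `i`
#' is rotated to superhelical phase `phase0[i]`; antiparallel helices
#' are built with reversed axial direction. Residues are poly-alanine
#' (`ALA` with atoms N, CA, C, O, CB).
#'
#' @param p A [crick_params()] object.
#' @return A `kih_structure` with chains `A`, `B`, ... and an
#'   `intended_register` attribute giving the generator's heptad letter
#'   for each residue index (`a` at residue 1 under the default
#'   interface phase).
#' @export
crick_backbone <- function(p) {
  stopifnot(inherits(p, "crick_params"))
  tmpl <- get_helix_template()
  w1 <- 2 * pi / p$residues_per_turn
  if (is.null(p$interface_phase)) p$interface_phase <- default_interface_phase(p)
  straight <- p$R0 < 1e-9
  # superhelix geometry: left-handed, so the phase decreases as z grows
  alpha <- atan2(2 * pi * p$R0, p$pitch)
  h_z <- p$rise * cos(alpha)                 # z advance per residue
  w0 <- -2 * pi * h_z / p$pitch              # superhelix phase per residue
  if (straight) { w0 <- 0; h_z <- p$rise }
  rscale <- p$R1 / tmpl$r_ca
  atom_names <- c("N", "CA", "C", "O", "CB")
  elesy <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C")

  # minor-phase correction for reversed helices: after the axial flip,
  # residue i of a parallel helix faces residue n+1-i of the reversed
  # one; shifting the reversed helix's minor phase by w1*((2*i_star + 1
  # - n) mod 7), with i_star the central intended 'a' position,
  # re-aligns the two core seams at the bundle mid-plane (a packs
  # against the d' seam, as in real antiparallel coiled coils)
  i_star <- 1L + 7L * round(((p$n_res + 1) / 2 - 1) / 7)
  anti_shift <- w1 * ((2L * i_star + 1L - p$n_res) %% 7L)
  chains <- lapply(seq_len(p$n_helices), function(j) {
    t0 <- (p$n_res - 1) / 2
    rows <- vector("list", p$n_res * length(atom_names))
    k <- 0L
    for (i in seq_len(p$n_res)) {
      t <- (i - 1) - t0                      # z-centred residue index
      th <- w0 * t
      cz <- h_z * t
      if (straight) {
        ctr <- c(0, 0, cz)
        Tv <- c(0, 0, 1); Rv <- c(1, 0, 0)
      } else {
        ctr <- c(p$R0 * cos(th), p$R0 * sin(th), cz)
        Tv <- c(-p$R0 * w0 * sin(th), p$R0 * w0 * cos(th), h_z)
        Tv <- Tv / sqrt(sum(Tv^2))
        Rv <- c(cos(th), sin(th), 0)         # outward radial
        Rv <- Rv - sum(Rv * Tv) * Tv
        Rv <- Rv / sqrt(sum(Rv^2))
      }
      Bv <- cross3(Tv, Rv)
      psi_ca <- w1 * (i - 1) + p$interface_phase +
        if (p$orientation[j] < 0) anti_shift else 0
      for (a in atom_names) {
        prm <- tmpl$atoms[[a]]
        r <- prm[["r"]] * rscale
        psi <- psi_ca + prm[["dphase"]]
        pos <- ctr + r * (cos(psi) * Rv + sin(psi) * Bv) + prm[["dz"]] * Tv
        k <- k + 1L
        rows[[k]] <- c(i, match(a, atom_names), pos)
      }
    }
    m <- do.call(rbind, rows)
    xyz <- m[, 3:5, drop = FALSE]
    if (p$orientation[j] < 0) {
      # flip about the x-axis: reverses the axial direction while
      # preserving superhelix handedness and helix chirality
      xyz[, 2] <- -xyz[, 2]
      xyz[, 3] <- -xyz[, 3]
    }
    beta <- p$phase0[j]
    rot <- matrix(c(cos(beta), sin(beta), 0,
                    -sin(beta), cos(beta), 0,
                    0, 0, 1), 3, 3)
    xyz <- xyz %*% rot
    tibble::tibble(
      chain = LETTERS[j], resno = as.integer(m[, 1]), ins = "",
      resid = "ALA", elety = atom_names[m[, 2]],
      elesy = unname(elesy[atom_names[m[, 2]]]),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], het = FALSE
    )
  })
  atoms <- dplyr::bind_rows(chains)
  if (p$jitter > 0) {
    set.seed(p$seed)
    n <- nrow(atoms)
    atoms$x <- atoms$x + stats::rnorm(n, 0, p$jitter)
    atoms$y <- atoms$y + stats::rnorm(n, 0, p$jitter)
    atoms$z <- atoms$z + stats::rnorm(n, 0, p$jitter)
  }
  s <- new_structure(atoms, source_format = "generated")
  attr(s, "crick_params") <- p
  attr(s, "intended_register") <- intended_register(p)
  s
}

# Default minor-helix phase of residue 1: chosen so that the CB
# pseudo-side chains of positions a (residue 1) and d (residue 4)
# straddle the core direction (psi = pi, towards the superhelix axis),
# which is what knob detection sees.
default_interface_phase <- function(p) {
  w1 <- 2 * pi / p$residues_per_turn
  pi + w1 / 4 - get_helix_template()$atoms$CB[["dphase"]]
}

# Heptad letters the generator intends, per helix: residue 1 of a
# parallel helix is 'a' under the default interface phase; reversed
# helices carry the antiparallel seam correction. Only meaningful for
# the heptad default residues_per_turn = 3.5.
intended_register <- function(p) {
  if (is.null(p$interface_phase)) p$interface_phase <- default_interface_phase(p)
  w1 <- 2 * pi / p$residues_per_turn
  off <- (p$interface_phase - default_interface_phase(p)) / w1
  i_star <- 1L + 7L * round(((p$n_res + 1) / 2 - 1) / 7)
  anti <- (2L * i_star + 1L - p$n_res) %% 7L
  lapply(seq_len(p$n_helices), function(j) {
    shift <- (as.integer(round(off)) +
                if (p$orientation[j] < 0) anti else 0L) %% 7L
    letters[((seq_len(p$n_res) - 1L + shift) %% 7L) + 1L]
  })
}
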