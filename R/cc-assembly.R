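#' Assemble coiled coils from helix-pair interfaces
#'
#' Builds a graph with helices as nodes and accepted coiled-coil
#' interfaces as edges; every connected component with at least two
#' nodes is one coiled-coil assembly. There is no upper bound on the
#' number of helices. The topology is `"cyclic"` (the alpha-helical
#' barrel signature) when the component contains a graph cycle, i.e.
#' has at least as many edges as nodes, and `"open"` otherwise.
#' Assemblies are numbered by (smallest chain, smallest first residue)
#' of their member helices for stable output ordering.
#'
#' @param interfaces Output of [pair_interfaces()].
#' @param helices Helix segments the interfaces refer to.
#' @return Tibble with `cc_id`, `order` (helix count), `topology`
#'   (`open`/`cyclic`) and `helix_ids` (list-column).
#' @export
assemble_coiled_coils <- function(interfaces, helices) {
  cc_if <- interfaces[interfaces$is_coiled_coil, , drop = FALSE]
  if (nrow(cc_if) == 0L) {
    return(tibble::tibble(cc_id = integer(), order = integer(),
                          topology = character(), helix_ids = list()))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(cc_if$helix_a),
               to = as.character(cc_if$helix_b)),
    directed = FALSE,
    vertices = data.frame(name = as.character(helices$helix_id))
  )
  comp <- igraph::components(g)
  memb <- comp$membership
  out <- lapply(which(comp$csize >= 2L), function(ci) {
    ids <- sort(as.integer(names(memb)[memb == ci]))
    sub <- igraph::induced_subgraph(g, as.character(ids))
    hsub <- helices[match(ids, helices$helix_id), ]
    tibble::tibble(
      order = length(ids),
      topology = if (igraph::ecount(sub) >= igraph::vcount(sub)) "cyclic"
                 else "open",
      helix_ids = list(ids),
      sort_chain = min(hsub$chain),
      sort_resno = min(hsub$first_resno[hsub$chain == min(hsub$chain)])
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(out), .data$sort_chain,
                        .data$sort_resno)
  tibble::tibble(cc_id = seq_len(nrow(out)), order = out$order,
                 topology = out$topology, helix_ids = out$helix_ids)
}

#' Orientation of a helix pair
#'
#' The interhelix angle is the arccosine of the dot product of the two
#' N-to-C unit axis directions, in `[0, 180]` degrees; the pair is
#' parallel for angles up to 90 degrees (the tie goes to parallel) and
#' antiparallel beyond.
#'
#' @param axis_a,axis_b Rows of the axis table from [fit_helix_axes()]
#'   (or any list with `dir_x`, `dir_y`, `dir_z`).
#' @return A list with `angle` (degrees) and `orientation`
#'   (`"parallel"`, `"antiparallel"`, or `NA` if either axis is
#'   unavailable).
#' @export
pair_orientation <- function(axis_a, axis_b) {
  va <- c(axis_a$dir_x, axis_a$dir_y, axis_a$dir_z)
  vb <- c(axis_b$dir_x, axis_b$dir_y, axis_b$dir_z)
  if (anyNA(va) || anyNA(vb)) {
    return(list(angle = NA_real_, orientation = NA_character_))
  }
  ang <- interhelix_angle(va, vb)
  list(angle = ang,
       orientation = if (ang <= 90) "parallel" else "antiparallel")
}

HEPTAD <- letters[1:7]

#' Assign an a-to-g heptad register to one helix
#'
#' Knob residues anchor the register: for consecutive knob residues at
#' ordinal spacing 3 the first is `a` (and the second `d`); at spacing 4
#' the first is `d` (and the second `a`). Each spacing in \{3, 4\}
#' proposes a register phase for the whole segment; the majority phase
#' wins (ties broken towards the smaller phase) and disagreeing anchors
#' are counted as conflicts. Letters then propagate over the entire
#' segment by heptad arithmetic, so `letter(i + 7) = letter(i)`. With
#' fewer than two knobs, or only spacings outside \{3, 4\}, the register
#' is left unassigned.
#'
#' @param helix One row of the helices tibble.
#' @param knob_uids `res_uid`s of knob residues on this helix.
#' @return A list with `assigned` (logical), `phase` (0-6 or NA),
#'   `letters` (character vector along the segment, NA when
#'   unassigned), `anchor_residue`, `anchor_letter` and `conflicts`.
#' @export
assign_register <- function(helix, knob_uids) {
  uids <- helix$residues[[1]]
  n <- length(uids)
  unassigned <- list(assigned = FALSE, phase = NA_integer_,
                     letters = rep(NA_character_, n),
                     anchor_residue = NA_character_,
                     anchor_letter = NA_character_, conflicts = 0L)
  pos <- sort(unique(match(knob_uids, uids)))
  pos <- pos[!is.na(pos)]
  if (length(pos) < 2L) return(unassigned)
  sp <- diff(pos)
  anchors <- integer(0)
  for (k in seq_along(sp)) {
    off <- if (sp[k] == 3L) 0L else if (sp[k] == 4L) 3L else NA_integer_
    if (!is.na(off)) {
      # phase p such that letter(ordinal j) = HEPTAD[(j - 1 + p) %% 7 + 1]
      anchors <- c(anchors, (off - (pos[k] - 1L)) %% 7L)
    }
  }
  if (length(anchors) == 0L) return(unassigned)
  tab <- table(anchors)
  best <- as.integer(names(tab)[order(-tab, as.integer(names(tab)))][1])
  conflicts <- sum(anchors != best)
  lets <- HEPTAD[((seq_len(n) - 1L + best) %% 7L) + 1L]
  first_knob <- pos[1]
  list(assigned = TRUE, phase = best, letters = lets,
       anchor_residue = uids[first_knob],
       anchor_letter = lets[first_knob], conflicts = as.integer(conflicts))
}
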