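#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the tables of a coiled-coil analysis
#'
#' @param x A `kih_result` from [kihscan()].
#' @param table Which table to return: `"residues"` (default; one row
#'   per residue of every coiled-coil helix with its register letter),
#'   `"knobs"`, `"pairs"`, `"assemblies"` or `"helices"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy kih_result
#' @export
tidy.kih_result <- function(x, table = c("residues", "knobs", "pairs",
                                         "assemblies", "helices"), ...) {
  table <- match.arg(table)
  if (table == "helices") {
    return(dplyr::select(x$helices, -"residues"))
  }
  table_views(x)[[table]]
}

#' One-row summary of a coiled-coil analysis
#'
#' @param x A `kih_result`.
#' @param ... Unused.
#' @return A one-row tibble with helix, knob and assembly counts, the
#'   largest assembly order, the number of cyclic (barrel) assemblies
#'   and the configuration dials used.
#' @method glance kih_result
#' @export
glance.kih_result <- function(x, ...) {
  tibble::tibble(
    n_helices = nrow(x$helices),
    n_knobs = nrow(x$knobs),
    n_coiled_coils = nrow(x$assemblies),
    max_order = if (nrow(x$assemblies) > 0L) max(x$assemblies$order) else 0L,
    n_cyclic = sum(x$assemblies$topology == "cyclic"),
    cutoff = x$config$cutoff,
    extension = x$config$extension
  )
}

#' Histograms of interface geometry
#'
#' `type = "pair_angles"` plots the distribution of interhelix angles of
#' all coiled-coil helix pairs; `type = "packing_angles"` the
#' distribution of per-knob packing angles -- the two distributions a
#' coiled-coil analysis usually inspects first.
#'
#' @param object A `kih_result`.
#' @param type `"pair_angles"` or `"packing_angles"`.
#' @param binwidth Histogram bin width in degrees.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kih_result
#' @export
autoplot.kih_result <- function(object, type = c("pair_angles",
                                                 "packing_angles"),
                                binwidth = 5, ...) {
  type <- match.arg(type)
  if (type == "pair_angles") {
    dat <- object$pairs
    p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$angle)) +
      ggplot2::labs(x = "interhelix angle (deg)", y = "helix pairs")
  } else {
    dat <- object$knobs[!is.na(object$knobs$packing_angle), ]
    p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$packing_angle)) +
      ggplot2::labs(x = "knob packing angle (deg)", y = "knobs")
  }
  p + ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                              fill = "steelblue", colour = "grey20") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname autoplot.kih_result
#' @export
plot_pair_angles <- function(object, binwidth = 5) {
  autoplot(object, type = "pair_angles", binwidth = binwidth)
}

#' @rdname autoplot.kih_result
#' @export
plot_packing_angles <- function(object, binwidth = 5) {
  autoplot(object, type = "packing_angles", binwidth = binwidth)
}
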