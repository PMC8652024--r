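fmt1 <- function(x) ifelse(is.na(x), "NA", sprintf("%.1f", x))
fmt2 <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", x))

one_letter <- function(parent) {
  out <- unname(AA_THREE_TO_ONE[parent])
  out[is.na(out)] <- "X"
  out
}

#' Render the human-readable text report
#'
#' One block per coiled-coil assembly: order and topology, member
#' helices with residue ranges, per-pair orientation and interhelix
#' angle, per-helix one-letter sequence with the a-to-g register string
#' aligned 1:1 beneath it (gaps where unassigned), and the knob list
#' with hole residues, insertion type, center distance and packing
#' angle. Deterministic: identical results render byte-identically.
#'
#' @param result A `kih_result` from [kihscan()].
#' @param path Optional output file; when `NULL` the lines are returned.
#' @return Character vector of report lines (invisibly when written).
#' @export
render_text_report <- function(result, path = NULL) {
  cfg <- result$config
  out <- c(
    "kihscan report (format 1)",
    sprintf("packing cutoff: %.1f A | helix extension: %d | helix assignment: %s",
            cfg$cutoff, cfg$extension, cfg$ss_source),
    sprintf("helix segments: %d | knobs: %d | coiled coils: %d",
            nrow(result$helices), nrow(result$knobs),
            nrow(result$assemblies)),
    ""
  )
  if (nrow(result$helices) == 0L) {
    return(finish_report(c(out, "no alpha-helices found"), path))
  }
  if (nrow(result$assemblies) == 0L) {
    return(finish_report(c(out, "no coiled coils found (zero assemblies)"),
                         path))
  }
  res <- residue_table(result$structure)
  for (i in seq_len(nrow(result$assemblies))) {
    a <- result$assemblies[i, ]
    topo <- if (a$topology == "cyclic") "cyclic (alpha-helical barrel)"
            else "open"
    out <- c(out, sprintf("coiled coil %d: order %d, topology %s",
                          a$cc_id, a$order, topo))
    for (h in a$helix_ids[[1]]) {
      hx <- result$helices[result$helices$helix_id == h, ]
      out <- c(out, sprintf("  helix %d: chain %s residues %d-%d (%d aa)",
                            h, hx$chain, hx$first_resno, hx$last_resno,
                            hx$n_res))
    }
    prs <- result$pairs[result$pairs$cc_id == a$cc_id, ]
    for (j in seq_len(nrow(prs))) {
      out <- c(out, sprintf(
        "  pair %d-%d: %s, interhelix angle %s deg, %d knobs, %d complementary",
        prs$helix_a[j], prs$helix_b[j], prs$orientation[j],
        fmt1(prs$angle[j]), prs$n_knobs[j], prs$n_complementary[j]))
    }
    regs <- result$registers[result$registers$cc_id == a$cc_id, ]
    for (j in seq_len(nrow(regs))) {
      h <- regs$helix_id[j]
      hx <- result$helices[result$helices$helix_id == h, ]
      uids <- hx$residues[[1]]
      m <- match(uids, res$res_uid)
      seq1 <- paste(one_letter(res$parent[m]), collapse = "")
      lets <- regs$letters[[j]]
      regline <- paste(ifelse(is.na(lets), "-", lets), collapse = "")
      out <- c(out,
               sprintf("  helix %d sequence/register:", h),
               paste0("    ", seq1),
               paste0("    ", regline))
    }
    ks <- result$knobs[result$knobs$knob_helix %in% a$helix_ids[[1]] &
                         result$knobs$hole_helix %in% a$helix_ids[[1]], ]
    out <- c(out, sprintf("  knobs (%d):", nrow(ks)))
    for (j in seq_len(nrow(ks))) {
      out <- c(out, sprintf(
        "    %s (helix %d) -> hole [%s] on helix %d | type %d | dmax %s A | packing angle %s deg",
        ks$knob_uid[j], ks$knob_helix[j],
        paste(ks$hole_residues[[j]], collapse = ", "), ks$hole_helix[j],
        ks$knob_type[j], fmt2(max(ks$hole_distances[[j]])),
        fmt1(ks$packing_angle[j])))
    }
    out <- c(out, "")
  }
  finish_report(out, path)
}

finish_report <- function(lines, path) {
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Render a PyMOL visualisation script
#'
#' The `.pml` script colours each helix of each coiled coil distinctly,
#' shows knob residues as sticks, and defines one named selection per
#' helix, per knob set and per register letter present (so registers can
#' be rainbow-coded a-to-g offline). With zero coiled coils the script
#' is a comment header only.
#'
#' @inheritParams render_text_report
#' @return Character vector of script lines (invisibly when written).
#' @export
render_pymol_script <- function(result, path = NULL) {
  out <- c("# kihscan coiled-coil visualisation script",
           "# load your structure first, then run this script")
  helix_colors <- c("marine", "orange", "forest", "magenta", "yellow",
                    "salmon", "teal", "violet", "wheat", "slate")
  reg_colors <- c(a = "red", b = "orange", c = "yellow", d = "green",
                  e = "cyan", f = "blue", g = "purple")
  if (nrow(result$assemblies) > 0L) {
    out <- c(out, "hide everything", "show cartoon", "color grey80")
  }
  res <- residue_table(result$structure)
  for (i in seq_len(nrow(result$assemblies))) {
    a <- result$assemblies[i, ]
    ci <- 0L
    for (h in a$helix_ids[[1]]) {
      hx <- result$helices[result$helices$helix_id == h, ]
      ci <- ci + 1L
      sel <- sprintf("cc%d_helix%d", a$cc_id, h)
      out <- c(out,
               sprintf("select %s, chain %s and resi %d-%d", sel, hx$chain,
                       hx$first_resno, hx$last_resno),
               sprintf("color %s, %s",
                       helix_colors[(ci - 1L) %% length(helix_colors) + 1L],
                       sel))
    }
    ks <- result$knobs[result$knobs$knob_helix %in% a$helix_ids[[1]] &
                         result$knobs$hole_helix %in% a$helix_ids[[1]], ]
    kres <- res[match(unique(ks$knob_uid), res$res_uid), ]
    if (nrow(kres) > 0L) {
      sel <- sprintf("cc%d_knobs", a$cc_id)
      parts <- sprintf("(chain %s and resi %s)", kres$chain,
                       paste0(kres$resno, ifelse(nzchar(kres$ins), kres$ins, "")))
      out <- c(out,
               sprintf("select %s, %s", sel, paste(parts, collapse = " or ")),
               sprintf("show sticks, %s", sel))
    }
  }
  rr <- result$residues
  if (!is.null(rr) && nrow(rr) > 0L) {
    for (l in HEPTAD) {
      sub <- rr[!is.na(rr$register) & rr$register == l, ]
      if (nrow(sub) == 0L) next
      parts <- vapply(split(sub, sub$chain), function(d) {
        sprintf("(chain %s and resi %s)", d$chain[1],
                paste0(d$resno, ifelse(nzchar(d$ins), d$ins, ""),
                       collapse = "+"))
      }, "")
      out <- c(out, sprintf("select register_%s, %s", l,
                            paste(parts, collapse = " or ")))
    }
    out <- c(out, paste0("# rainbow by register: color ",
                         paste(sprintf("%s=register_%s", reg_colors[HEPTAD],
                                       HEPTAD), collapse = ", ")))
  }
  finish_report(out, path)
}

# Flat (list-column free) serialisable views of the three report tables.
table_views <- function(result) {
  rr <- result$residues
  residues <- tibble::tibble(
    cc_id = rr$cc_id, helix_id = rr$helix_id, chain = rr$chain,
    resno = rr$resno, ins = rr$ins, resid = rr$resid, parent = rr$parent,
    register = rr$register, is_knob = rr$is_knob, knob_type = rr$knob_type
  )
  pr <- result$pairs
  pairs <- tibble::tibble(
    cc_id = pr$cc_id, helix_a = pr$helix_a, helix_b = pr$helix_b,
    orientation = pr$orientation, angle = round(pr$angle, 1),
    n_knobs = pr$n_knobs, n_complementary = pr$n_complementary
  )
  as_ <- result$assemblies
  assemblies <- tibble::tibble(
    cc_id = as_$cc_id, order = as_$order, topology = as_$topology,
    helices = vapply(as_$helix_ids, function(x) paste(x, collapse = "+"), "")
  )
  kn <- result$knobs
  knobs <- tibble::tibble(
    knob = kn$knob_uid, knob_helix = kn$knob_helix,
    hole_helix = kn$hole_helix,
    hole = vapply(kn$hole_residues, function(x) paste(x, collapse = "+"), ""),
    max_distance = round(vapply(kn$hole_distances, max, 0), 2),
    packing_angle = round(kn$packing_angle, 1), knob_type = kn$knob_type
  )
  list(residues = residues, pairs = pairs, assemblies = assemblies,
       knobs = knobs)
}

#' Write machine-readable result tables
#'
#' Writes the residue-level, pair-level, assembly-level and knob tables
#' as CSV files and/or a single JSON file mirroring the CSV content
#' field-by-field.
#'
#' @param result A `kih_result`.
#' @param dir Output directory (created if needed).
#' @param formats Any of `"json"`, `"csv"`.
#' @return Character vector of files written, invisibly.
#' @export
render_tables <- function(result, dir, formats = c("json", "csv")) {
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  views <- table_views(result)
  files <- character(0)
  if ("csv" %in% formats) {
    for (nm in names(views)) {
      f <- file.path(dir, paste0("kihscan_", nm, ".csv"))
      readr::write_csv(views[[nm]], f, progress = FALSE)
      files <- c(files, f)
    }
  }
  if ("json" %in% formats) {
    f <- file.path(dir, "kihscan_tables.json")
    jsonlite::write_json(views, f, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, f)
  }
  invisible(files)
}

#' Write the full set of report artifacts
#'
#' Convenience wrapper used by the command-line entry point: writes the
#' text report, the PyMOL script, JSON/CSV tables and (optionally)
#' angle-distribution histogram PNGs into one directory.
#'
#' @param result A `kih_result`.
#' @param dir Output directory.
#' @param text,json,csv,pymol,plots Emit flags.
#' @return Tibble manifest of files written, invisibly.
#' @export
render_outputs <- function(result, dir, text = TRUE, json = TRUE,
                           csv = TRUE, pymol = TRUE, plots = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (text) {
    f <- file.path(dir, "kihscan_report.txt")
    render_text_report(result, f)
    files <- c(files, f)
  }
  if (pymol) {
    f <- file.path(dir, "kihscan_view.pml")
    render_pymol_script(result, f)
    files <- c(files, f)
  }
  fmts <- c(if (json) "json", if (csv) "csv")
  if (length(fmts) > 0L) files <- c(files, render_tables(result, dir, fmts))
  if (plots && nrow(result$pairs) > 0L) {
    for (tp in c("pair_angles", "packing_angles")) {
      f <- file.path(dir, paste0("kihscan_", tp, ".png"))
      grDevices::png(f, width = 800, height = 600)
      print(ggplot2::autoplot(result, type = tp))
      grDevices::dev.off()
      files <- c(files, f)
    }
  }
  invisible(tibble::tibble(file = files))
}
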