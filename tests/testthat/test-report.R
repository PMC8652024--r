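test_that("the pipeline config dials are validated", {
  s <- fx_dimer()
  expect_error(kihscan(s, cutoff = 5), "6-8")
  expect_error(kihscan(s, extension = -1), "extension")
  expect_s3_class(kihscan(s, cutoff = 5.5, force = TRUE), "kih_result")
})

test_that("structures without helices or coiled coils report cleanly", {
  r <- kihscan(fx_extended())
  expect_equal(nrow(r$helices), 0L)
  expect_equal(nrow(r$assemblies), 0L)
  txt <- render_text_report(r)
  expect_true(any(grepl("no alpha-helices", txt)))
  # single helix: helices but zero assemblies
  r1 <- kihscan(fx_straight())
  expect_equal(nrow(r1$assemblies), 0L)
  expect_true(any(grepl("zero assemblies", render_text_report(r1))))
  # PyMOL script degrades to a comment header
  pml <- render_pymol_script(r1)
  expect_true(all(grepl("^#", pml)))
})

test_that("identical runs render byte-identical artifacts", {
  s <- fx_dimer()
  d1 <- file.path(tempdir(), "kih_det_1")
  d2 <- file.path(tempdir(), "kih_det_2")
  render_outputs(kihscan(s), d1, pymol = TRUE)
  render_outputs(kihscan(s), d2, pymol = TRUE)
  files <- list.files(d1)
  expect_gt(length(files), 3L)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("the register line aligns 1:1 under the sequence", {
  r <- kihscan(fx_dimer())
  txt <- render_text_report(r)
  i <- grep("sequence/register", txt)
  expect_equal(length(i), 2L)
  for (j in i) {
    seq_line <- sub("^\\s+", "", txt[j + 1])
    reg_line <- sub("^\\s+", "", txt[j + 2])
    expect_equal(nchar(reg_line), nchar(seq_line))
    expect_true(grepl("^[a-g-]+$", reg_line))
  }
  # unassigned register renders as all gaps
  r$registers$letters[[1]] <- rep(NA_character_, r$helices$n_res[1])
  txt2 <- render_text_report(r)
  reg_line <- sub("^\\s+", "", txt2[i[1] + 2])
  expect_true(grepl("^-+$", reg_line))
})

test_that("barrel reports are labelled as alpha-helical barrels", {
  r <- kihscan(fx_barrel(5))
  txt <- render_text_report(r)
  expect_true(any(grepl("cyclic (alpha-helical barrel)", txt, fixed = TRUE)))
})

test_that("the PyMOL script defines the advertised selections", {
  r <- kihscan(fx_dimer())
  pml <- render_pymol_script(r)
  sel <- grep("^select ", pml, value = TRUE)
  expect_true(any(grepl("cc1_helix1, chain A", sel)))
  expect_true(any(grepl("cc1_helix2, chain B", sel)))
  expect_true(any(grepl("cc1_knobs", sel)))
  # one selection per register letter present
  present <- sort(unique(stats::na.omit(r$residues$register)))
  for (l in present) {
    expect_true(any(grepl(paste0("register_", l, ","), sel)), label = l)
  }
  # selection lines parse as "select <name>, <expression>"
  expect_true(all(grepl("^select [A-Za-z0-9_]+, .+$", sel)))
  # knob selection covers exactly the knob table's residues
  kline <- sel[grepl("cc1_knobs", sel)]
  expect_equal(lengths(regmatches(kline, gregexpr("resi", kline))),
               length(unique(r$knobs$knob_uid)))
})

test_that("JSON and CSV tables agree field by field", {
  r <- kihscan(fx_dimer())
  dir <- file.path(tempdir(), "kih_tabs")
  render_tables(r, dir)
  js <- jsonlite::read_json(file.path(dir, "kihscan_tables.json"),
                            simplifyVector = TRUE)
  for (nm in c("residues", "pairs", "assemblies", "knobs")) {
    csv <- utils::read.csv(file.path(dir, paste0("kihscan_", nm, ".csv")),
                           stringsAsFactors = FALSE,
                           colClasses = c(ins = "character")[
                             intersect("ins", names(js[[nm]]))])
    jdf <- as.data.frame(js[[nm]])
    csv$ins <- NULL; jdf$ins <- NULL
    expect_equal(jdf, csv, tolerance = 1e-9, label = nm)
  }
  # pair table has exactly one row for a dimer
  expect_equal(nrow(js$pairs), 1L)
  # residue table covers every member-helix residue
  r1 <- kihscan(fx_dimer())
  expect_equal(nrow(js$residues), sum(r1$helices$n_res))
})

test_that("knob counts agree across text, JSON and PyMOL artifacts", {
  r <- kihscan(fx_barrel(5))
  txt <- render_text_report(r)
  pml <- render_pymol_script(r)
  dir <- file.path(tempdir(), "kih_consistency")
  render_tables(r, dir, "json")
  js <- jsonlite::read_json(file.path(dir, "kihscan_tables.json"),
                            simplifyVector = TRUE)
  n_knobs <- nrow(r$knobs)
  expect_equal(nrow(js$knobs), n_knobs)
  expect_true(any(grepl(sprintf("knobs (%d):", n_knobs), txt, fixed = TRUE)))
  expect_equal(sum(js$residues$is_knob),
               length(unique(r$knobs$knob_uid)))
})

test_that("tidy and glance views mirror the result object", {
  r <- kihscan(fx_dimer())
  g <- glance(r)
  expect_equal(g$n_coiled_coils, 1L)
  expect_equal(g$max_order, 2L)
  expect_equal(g$cutoff, 7)
  expect_equal(nrow(tidy(r, "knobs")), nrow(r$knobs))
  expect_equal(nrow(tidy(r, "helices")), 2L)
  expect_s3_class(autoplot(r, "pair_angles"), "ggplot")
  expect_s3_class(plot_packing_angles(r), "ggplot")
})

test_that("the command-line entry point runs end to end", {
  skip_on_os("windows")
  script <- system.file("exec", "kihscan.R", package = "kihscan")
  fixture_script <- system.file("exec", "kihscan-fixtures.R",
                                package = "kihscan")
  skip_if(script == "" || fixture_script == "")
  pdb <- tempfile(fileext = ".pdb")
  out <- file.path(tempdir(), "kih_cli_out")
  lib_env <- paste0("R_LIBS=", paste(.libPaths(), collapse = ":"))
  rc1 <- system2("Rscript", c(fixture_script, "--out", pdb), stdout = TRUE,
                 stderr = TRUE, env = lib_env)
  expect_true(file.exists(pdb))
  rc2 <- system2("Rscript", c(script, "-f", pdb, "-o", out, "--json"),
                 stdout = TRUE, stderr = TRUE, env = lib_env)
  expect_true(file.exists(file.path(out, "kihscan_report.txt")))
  expect_true(file.exists(file.path(out, "kihscan_tables.json")))
  # usage error -> exit 1
  rc3 <- suppressWarnings(system2("Rscript", script, stdout = NULL,
                                  stderr = NULL, env = lib_env))
  expect_equal(rc3, 1L)
})
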