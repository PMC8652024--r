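fake_centers <- function(df) {
  tibble::tibble(
    res_uid = df$res_uid, chain = sub("\\|.*", "", df$res_uid),
    resno = as.integer(sub(".*\\|", "", df$res_uid)), ins = "",
    resid = "ALA", parent = "ALA",
    x = df$x, y = df$y, z = df$z, n_atoms = 1L,
    ca_x = df$x, ca_y = df$y, ca_z = df$z
  )
}

test_that("side-chain centers follow the centroid / glycine / CA rules", {
  mk <- function(resid, elety, xyz) {
    data.frame(chain = "A", resno = 1L, ins = "", resid = resid,
               elety = elety, elesy = substr(elety, 1, 1),
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], het = FALSE)
  }
  # ALA: single CB
  s <- new_structure(mk("ALA", c("N", "CA", "CB"),
                        rbind(c(0, 0, 0), c(0, 1, 0), c(1, 2, 3))))
  cen <- side_chain_centers(s)
  expect_equal(unlist(cen[1, c("x", "y", "z")], use.names = FALSE), c(1, 2, 3))
  expect_equal(cen$n_atoms, 1L)
  # GLY: falls back to CA
  s <- new_structure(mk("GLY", c("N", "CA", "C"),
                        rbind(c(1, 1, 1), c(0, 0, 0), c(-1, 0, 0))))
  cen <- side_chain_centers(s)
  expect_equal(unlist(cen[1, c("x", "y", "z")], use.names = FALSE), c(0, 0, 0))
  expect_equal(cen$n_atoms, 0L)
  # four side-chain atoms: arithmetic mean
  s <- new_structure(mk("LEU", c("CA", "CB", "CG", "CD1", "CD2"),
                        rbind(c(9, 9, 9), c(0, 0, 0), c(2, 0, 0),
                              c(0, 2, 0), c(0, 0, 2))))
  cen <- side_chain_centers(s)
  expect_equal(unlist(cen[1, c("x", "y", "z")], use.names = FALSE),
               c(0.5, 0.5, 0.5))
  expect_equal(cen$n_atoms, 4L)
})

test_that("hydrogens never shift side-chain centers", {
  f1 <- write_tmp(minimal_ala_pdb(), ".pdb")
  with_h <- c(minimal_ala_pdb()[1:5],
    "ATOM      6  HB1 ALA A   1      99.000  99.000  99.000  1.00  0.00           H",
    "END")
  f2 <- write_tmp(with_h, ".pdb")
  c1 <- side_chain_centers(read_structure(f1))
  c2 <- side_chain_centers(read_structure(f2))
  expect_equal(c1$x, c2$x)
  expect_equal(c1$y, c2$y)
})

test_that("contacts respect the cutoff inclusively and never intra-helix", {
  cen <- fake_centers(data.frame(
    res_uid = c("A|1", "A|2", "B|1", "B|2"),
    x = c(0, 0, 3, 7), y = c(0, 5, 4, 0), z = 0))
  hel <- tibble::tibble(helix_id = 1:2, chain = c("A", "B"),
                        first_resno = 1L, last_resno = 2L, n_res = 2L,
                        extended_n = 0L, extended_c = 0L,
                        residues = list(c("A|1", "A|2"), c("B|1", "B|2")))
  ct <- contact_map(hel, cen, cutoff = 7)
  # A|1-B|1 at 5 (3-4-5), A|1-B|2 at exactly 7 (inclusive), A|2-B|1 at sqrt(10)
  expect_true(all(ct$helix_a != ct$helix_b))
  key <- paste(ct$res_a, ct$res_b)
  expect_true("A|1 B|1" %in% key)
  expect_equal(ct$distance[key == "A|1 B|1"], 5)
  expect_true("A|1 B|2" %in% key)          # boundary is inclusive
  expect_false("A|1 A|2" %in% key)         # same helix, distance 5
  # three cross-helix pairs within 7 A (A|2-B|2 lies at 8.6 A)
  expect_equal(nrow(ct), 3L)
})

test_that("knobs need four contacts on one target helix", {
  # r = A|1; helix 2 offers 3 residues, helix 3 offers 2: no knob anywhere
  cen <- fake_centers(data.frame(
    res_uid = c("A|1", "B|1", "B|2", "B|3", "C|1", "C|2"),
    x = c(0, 3, 3, 3, -3, -3), y = c(0, 0, 1, 2, 0, 1), z = 0))
  hel <- tibble::tibble(helix_id = 1:3, chain = c("A", "B", "C"),
                        first_resno = 1L, last_resno = 3L, n_res = 3L,
                        extended_n = 0L, extended_c = 0L,
                        residues = list("A|1", c("B|1", "B|2", "B|3"),
                                        c("C|1", "C|2")))
  ct <- contact_map(hel, cen, cutoff = 7)
  k <- find_knobs(ct, cen)
  expect_equal(nrow(k[k$knob_uid == "A|1", ]), 0L)
  # add a fourth residue on helix 2: now exactly one knob record
  cen2 <- fake_centers(data.frame(
    res_uid = c("A|1", "B|1", "B|2", "B|3", "B|4"),
    x = c(0, 3, 3, 3, 3), y = c(0, 0, 1, 2, 3), z = 0))
  hel2 <- hel[1:2, ]
  hel2$residues[[2]] <- c("B|1", "B|2", "B|3", "B|4")
  k2 <- find_knobs(contact_map(hel2, cen2, cutoff = 7), cen2)
  expect_equal(sum(k2$knob_uid == "A|1"), 1L)
  expect_setequal(k2$hole_residues[[which(k2$knob_uid == "A|1")]],
                  c("B|1", "B|2", "B|3", "B|4"))
})

test_that("the hole is the four nearest contacts with ties by residue number", {
  cen <- fake_centers(data.frame(
    res_uid = c("A|1", "B|1", "B|2", "B|3", "B|4", "B|5", "B|6"),
    x = c(0, 4, 6, 5, 6.5, 7, 5), y = 0, z = 0))
  hel <- tibble::tibble(helix_id = 1:2, chain = c("A", "B"),
                        first_resno = 1L, last_resno = 6L, n_res = 6L,
                        extended_n = 0L, extended_c = 0L,
                        residues = list("A|1", paste0("B|", 1:6)))
  k <- find_knobs(contact_map(hel, cen, cutoff = 7), cen)
  krow <- k[k$knob_uid == "A|1", ]
  # distances: B|1=4, B|3=5, B|6=5, B|2=6, B|4=6.5, B|5=7 -> nearest four,
  # with the 5 A tie ordered B|3 before B|6
  expect_equal(krow$hole_residues[[1]], c("B|1", "B|3", "B|6", "B|2"))
})

test_that("knob classification spans the four insertion types", {
  base <- data.frame(
    res_uid = c("A|1", "B|1", "B|2", "B|3", "B|4"),
    x = c(0, 4, 4, 4, 4), y = c(0, 1, -1, 0, 0), z = c(0, 0, 0, 1, -1))
  cen <- fake_centers(base)
  # side-chain center displaced from CA toward the hole: angle 0, CA in hole
  cen$x[1] <- 1.5
  cen$ca_x[1] <- 0
  hel <- tibble::tibble(helix_id = 1:2, chain = c("A", "B"),
                        first_resno = 1L, last_resno = 4L, n_res = 4L,
                        extended_n = 0L, extended_c = 0L,
                        residues = list("A|1", paste0("B|", 1:4)))
  k <- classify_knobs(find_knobs(contact_map(hel, cen, 7), cen), cen, 7)
  expect_equal(k$packing_angle, 0)
  expect_equal(k$knob_type, 4L)
  # perpendicular side chain: 90 degrees, type 1
  cen2 <- cen
  cen2$x[1] <- 0; cen2$y[1] <- 1.5
  k2 <- classify_knobs(find_knobs(contact_map(hel, cen2, 7), cen2), cen2, 7)
  expect_equal(k2$packing_angle, 90)
  expect_equal(k2$knob_type, 1L)
  # glycine knob: undefined angle, type 1
  cen3 <- fake_centers(base)
  k3 <- classify_knobs(find_knobs(contact_map(hel, cen3, 7), cen3), cen3, 7)
  expect_true(is.na(k3$packing_angle))
  expect_equal(k3$knob_type, 1L)
  # core-pointing but CA too far for type 4: type 3
  far <- base; far$x <- c(0, 7.2, 7.2, 7.2, 7.2)
  cen4 <- fake_centers(far)
  cen4$x[1] <- 1.5
  k4 <- classify_knobs(find_knobs(contact_map(hel, cen4, 7), cen4), cen4, 7)
  expect_equal(k4$knob_type, 3L)
})

test_that("an a-position knob of the ideal dimer is deeply inserted", {
  r <- kihscan(fx_dimer())
  a_knobs <- r$knobs[intended_letters_of(r$structure, r$knobs$knob_uid) == "a", ]
  expect_gt(nrow(a_knobs), 0L)
  expect_true(all(a_knobs$knob_type >= 3L))
})

test_that("complementarity requires reciprocal hole membership", {
  r <- kihscan(fx_dimer())
  iface <- r$interfaces
  expect_true(all(iface$is_coiled_coil))
  cp <- iface$complementary_pairs[[1]]
  expect_gt(nrow(cp), 0L)
  for (i in seq_len(nrow(cp))) {
    k1 <- r$knobs[r$knobs$knob_uid == cp[i, 1] &
                    r$knobs$hole_helix == iface$helix_b[1], ]
    k2 <- r$knobs[r$knobs$knob_uid == cp[i, 2] &
                    r$knobs$hole_helix == iface$helix_a[1], ]
    expect_true(cp[i, 2] %in% k1$hole_residues[[1]])
    expect_true(cp[i, 1] %in% k2$hole_residues[[1]])
  }
  # empty knob set -> no interfaces
  expect_equal(nrow(pair_interfaces(r$knobs[0, ])), 0L)
})

test_that("one-directional knobs do not make a coiled coil", {
  kn <- tibble::tibble(
    knob_uid = c("A|1", "A|5", "A|8"), knob_helix = 1L, hole_helix = 2L,
    hole_residues = list(paste0("B|", 1:4), paste0("B|", 4:7),
                         paste0("B|", 7:10)),
    hole_distances = list(rep(5, 4), rep(5, 4), rep(5, 4)),
    hole_x = 0, hole_y = 0, hole_z = 0,
    packing_angle = 10, knob_type = 3L)
  iface <- pair_interfaces(kn)
  expect_equal(nrow(iface), 1L)
  expect_false(iface$is_coiled_coil)
  expect_equal(iface$n_complementary, 0L)
})

test_that("production knobs equal the brute-force oracle on mixed fixtures", {
  for (s in list(fx_dimer(), fx_anti_dimer(), fx_barrel(5))) {
    r <- kihscan(s)
    bf <- brute_force_knobs(s, r$helices, 7)
    expect_setequal(knob_key(r$knobs), knob_key(bf))
  }
  # degenerate inputs
  s1 <- fx_straight()
  r1 <- kihscan(s1)
  expect_equal(nrow(brute_force_knobs(s1, r1$helices, 7)), 0L)
  expect_equal(nrow(r1$knobs), 0L)
})

test_that("knob sets grow monotonically with the cutoff, holes fixed", {
  s <- fx_dimer()
  r1 <- kihscan(s, cutoff = 6.5)
  r2 <- kihscan(s, cutoff = 7.5)
  k1 <- paste(r1$knobs$knob_uid, r1$knobs$hole_helix)
  k2 <- paste(r2$knobs$knob_uid, r2$knobs$hole_helix)
  expect_true(all(k1 %in% k2))
  h1 <- vapply(r1$knobs$hole_residues, function(u) paste(sort(u), collapse = "+"), "")
  h2 <- vapply(r2$knobs$hole_residues, function(u) paste(sort(u), collapse = "+"), "")
  expect_equal(h1, h2[match(k1, k2)])
})

test_that("barrel symmetry maps the knob set onto itself", {
  s <- fx_barrel(5)
  r <- kihscan(s)
  # rotate chain labels by one position: A->B, ..., E->A
  keys <- paste(r$knobs$knob_uid, r$knobs$hole_helix)
  shift_chain <- function(uid, by, n) {
    ch <- match(sub("\\|.*", "", uid), LETTERS)
    paste0(LETTERS[(ch - 1L + by) %% n + 1L], "|", sub(".*\\|", "", uid))
  }
  shifted <- paste(shift_chain(r$knobs$knob_uid, 1L, 5L),
                   (r$knobs$hole_helix %% 5L) + 1L)
  expect_setequal(shifted, keys)
})
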