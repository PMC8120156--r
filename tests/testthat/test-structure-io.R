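test_that("PDB and mmCIF fixtures parse to the same model", {
  xyz <- fx_helix_ca(4)
  fp <- fx_write_pdb(xyz, tempfile(fileext = ".pdb"))
  fc <- fx_write_cif(xyz, tempfile(fileext = ".cif"))
  mp <- read_structure(fp)
  mc <- read_structure(fc)
  expect_named(mp, "A")
  expect_equal(nrow(mp$A$atoms), 4L)
  expect_equal(mp$A$atoms$x, xyz[, 1], tolerance = 1e-3)
  expect_equal(mc$A$atoms[, c("resno", "x", "y", "z")],
               mp$A$atoms[, c("resno", "x", "y", "z")], tolerance = 1e-9)
  expect_error(read_structure(tempfile()), "not found")
  # a HETATM-only file has no polymer residues
  fh <- tempfile(fileext = ".pdb")
  writeLines(c(paste0("HETATM    1  O   HOH A 101      ",
                      "10.000  10.000  10.000  1.00  0.00           O"), "END"), fh)
  expect_length(read_structure(fh), 0L)
})

test_that("ca_geometry assigns a helix to an ideal helical trace", {
  model <- fx_ca_model(fx_helix_ca(12))
  segs <- assign_sses(model, "ca_geometry")
  expect_length(segs, 1L)
  expect_identical(segs[[1]]$sse_type, "H")
  expect_gte(segs[[1]]$end_res - segs[[1]]$start_res + 1L, 8L)
})

test_that("ca_geometry assigns a strand to an extended trace", {
  model <- fx_ca_model(fx_strand_ca(10))
  segs <- assign_sses(model, "ca_geometry")
  expect_length(segs, 1L)
  expect_identical(segs[[1]]$sse_type, "E")
  expect_equal(c(segs[[1]]$start_res, segs[[1]]$end_res), c(1L, 10L))
})

test_that("external segment files pass through and overlaps are rejected", {
  model <- fx_ca_model(fx_helix_ca(30))
  f <- tempfile()
  writeLines(c("A H 5 17", "A E 22 27"), f)
  segs <- assign_sses(model, "external_file", sse_file = f)
  expect_length(segs, 2L)
  expect_identical(vapply(segs, `[[`, character(1), "sse_type"), c("H", "E"))
  expect_equal(vapply(segs, `[[`, integer(1), "start_res"), c(5L, 22L))
  expect_equal(vapply(segs, `[[`, integer(1), "end_res"), c(17L, 27L))
  writeLines(c("A H 5 17", "A E 15 20"), f)
  expect_error(assign_sses(model, "external_file", sse_file = f), "overlapping")
})

test_that("axis fitting recovers exact lines and respects N-to-C orientation", {
  pts <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2))
  ax <- fit_axis(sse_segment(1, "H", 1, 3, pts))
  expect_equal(ax$direction, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(ax$point, c(0, 0, 1), tolerance = 1e-12)
  ax_rev <- fit_axis(sse_segment(1, "H", 1, 3, pts[3:1, ]))
  expect_equal(ax_rev$direction, c(0, 0, -1), tolerance = 1e-12)
  expect_equal(sqrt(sum(ax$direction^2)), 1, tolerance = 1e-9)
  expect_error(fit_axis(sse_segment(1, "H", 1, 3, rbind(c(1, 1, 1), c(1, 1, 1),
                                                        c(1, 1, 1)))),
               "degenerate")
  # helix axis recovered within 5 degrees of the generation axis (+z)
  hax <- fit_axis(sse_segment(1, "H", 1, 12, fx_helix_ca(12)))
  angle_to_z <- acos(sum(hax$direction * c(0, 0, 1))) * 180 / pi
  expect_lt(angle_to_z, 5)
})

test_that("interaxial angles follow the dihedral convention", {
  ax <- function(p, d) structure(list(point = p, direction = d / sqrt(sum(d^2))),
                                 class = "sse_axis")
  # parallel offset axes: 0 degrees, flagged degenerate
  a1 <- ax(c(0, 0, 0), c(0, 0, 1))
  a2 <- ax(c(1, 0, 0), c(0, 0, 1))
  r <- interaxial_angle(a1, a2)
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "degenerate"))
  # antiparallel: 180 (wrapped)
  r2 <- interaxial_angle(a1, ax(c(1, 0, 0), c(0, 0, -1)))
  expect_equal(abs(as.numeric(r2)), 180)
  # skew perpendicular case against a brute-force four-point dihedral
  a3 <- ax(c(1, 0, 0), c(0, 1, 0))
  got <- as.numeric(interaxial_angle(a1, a3))
  # closest points are the origin and (1,0,0); four explicit points:
  four_point_dihedral <- function(p1, p2, p3, p4) {
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])
    atan2(sqrt(sum(b2^2)) * sum(b1 * cr(b2, b3)),
          sum(cr(b1, b2) * cr(b2, b3))) * 180 / pi
  }
  want <- four_point_dihedral(c(0, 0, 1), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(got, want, tolerance = 1e-9)
  expect_equal(abs(got), 90, tolerance = 1e-9)
})

test_that("contact decisions follow the van der Waals threshold", {
  mk_pair <- function(sep) {
    xyz <- rbind(cbind(c(0, 1.5, 3), 0, 0), cbind(c(0, 1.5, 3), sep, 0))
    model <- fx_ca_model(xyz, resno = c(1:3, 11:13))
    s1 <- sse_segment(1, "H", 1, 3, xyz[1:3, ])
    s2 <- sse_segment(2, "H", 11, 13, xyz[4:6, ])
    sse_contact(s1, s2, model)
  }
  # carbon-carbon threshold is 1.7 + 1.7 + 1.0 = 4.4 A
  expect_false(mk_pair(5.0))
  expect_true(mk_pair(4.3))
  # unknown elements fall back with a warning
  xyz <- rbind(cbind(c(0, 1.5, 3), 0, 0), cbind(c(0, 1.5, 3), 4.3, 0))
  model <- atom_model("A", c(1:3, 11:13), rep("XX", 6), xyz, elesy = "X")
  s1 <- sse_segment(1, "H", 1, 3, xyz[1:3, ])
  s2 <- sse_segment(2, "H", 11, 13, xyz[4:6, ])
  w <- capture_warnings(res <- sse_contact(s1, s2, model))
  expect_match(w, "unknown element", all = TRUE)
  expect_true(res)
})

test_that("contact decisions equal a brute-force all-pairs atom scan", {
  set.seed(51)
  fix <- fx_orthogonal_model()
  model <- fix$model; segs <- fix$segments
  brute <- function(s1, s2) {
    a <- model$atoms
    x1 <- as.matrix(a[a$resno >= s1$start_res & a$resno <= s1$end_res,
                      c("x", "y", "z")])
    x2 <- as.matrix(a[a$resno >= s2$start_res & a$resno <= s2$end_res,
                      c("x", "y", "z")])
    any(as.matrix(dist(rbind(x1, x2)))[seq_len(nrow(x1)),
                                       nrow(x1) + seq_len(nrow(x2))] < 4.4)
  }
  for (i in 1:2) for (j in (i + 1):3) {
    expect_identical(sse_contact(segs[[i]], segs[[j]], model),
                     brute(segs[[i]], segs[[j]]))
  }
})

test_that("build_tableau captures the designed geometry", {
  fix <- fx_orthogonal_model()
  t <- build_tableau(fix$model, fix$segments, id = "ortho")
  expect_identical(t$sse_string, "HHH")
  expect_true(t$contacts[1, 2] && t$contacts[2, 3] && !t$contacts[1, 3])
  expect_equal(abs(t$angles[1, 2]), 90, tolerance = 1e-6)
  expect_equal(abs(t$angles[2, 3]), 90, tolerance = 1e-6)
  # empty and single-segment cases
  expect_equal(tableau_size(build_tableau(fix$model, list(), id = "none")), 0L)
  t1 <- build_tableau(fix$model, fix$segments[1], id = "one")
  expect_equal(tableau_size(t1), 1L)
})

test_that("tableaux are invariant under rigid motions", {
  set.seed(52)
  fix <- fx_orthogonal_model()
  t0 <- build_tableau(fix$model, fix$segments, id = "ref")
  for (rep in 1:20) {
    moved <- fx_rigid_motion(fix$model, fix$segments)
    t1 <- build_tableau(moved$model, moved$segments, id = "ref")
    expect_identical(t1$contacts, t0$contacts)
    expect_lt(max(abs(t1$angles - t0$angles)), 1e-6)
  }
})

test_that("reversing a segment's chain direction shifts its angles by 180", {
  fix <- fx_orthogonal_model()
  t0 <- build_tableau(fix$model, fix$segments, id = "ref")
  segs2 <- fix$segments
  s <- segs2[[2]]
  segs2[[2]] <- sse_segment(s$ordinal, s$sse_type, s$start_res, s$end_res,
                            s$ca_coords[nrow(s$ca_coords):1, ])
  t1 <- build_tableau(fix$model, segs2, id = "rev")
  for (j in c(1, 3)) {
    shift <- abs(wrap_angle(t1$angles[2, j] - t0$angles[2, j]))
    expect_equal(shift, 180, tolerance = 1e-6)
  }
  expect_identical(t1$contacts, t0$contacts)
})
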