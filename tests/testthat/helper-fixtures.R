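# Shared fixtures, all generated in code.

fx_spec <- code_spec()

# random tableau with the synthetic generator's band-contact model
fx_random_tableau <- function(id = "t", n = sample(3:8, 1)) {
  p <- synth_params(n_tableaux = 1, sse_range = c(max(2, n), max(2, n)),
                    motif = NULL)
  random_tableau(p, id, fx_spec)
}

# random dictionary of up to k concepts extracted from random tableaux
fx_random_dictionary <- function(k, spec = fx_spec) {
  cons <- list()
  guard <- 0L
  while (length(cons) < k && guard < 50L) {
    guard <- guard + 1L
    src <- fx_random_tableau(paste0("src", guard), sample(3:6, 1))
    m <- sample(2:3, 1)
    st <- sample(tableau_size(src) - m + 1L, 1)
    cc <- tryCatch(extract_candidate(src, c(st, st + m - 1L), spec),
                   error = function(e) NULL)
    if (!is.null(cc)) cons[[length(cons) + 1L]] <- cc
  }
  for (i in seq_along(cons)) cons[[i]]$id <- sprintf("c_%04d", i)
  new_dictionary(cons, spec)
}

# ---- coordinate fixtures ----------------------------------------------------

# ideal alpha-helical C-alpha trace along +z (rise per residue, twist deg)
fx_helix_ca <- function(nres, rise = 1.5, twist = 100, radius = 2.3) {
  ang <- (seq_len(nres) - 1L) * twist * pi / 180
  cbind(radius * cos(ang), radius * sin(ang), (seq_len(nres) - 1L) * rise)
}

# extended-strand zigzag along +x
fx_strand_ca <- function(nres, rise = 3.35, wobble = 0.5) {
  cbind((seq_len(nres) - 1L) * rise,
        wobble * (-1)^(seq_len(nres)), rep(0, nres))
}

fx_ca_model <- function(xyz, chain = "A", resno = seq_len(nrow(xyz))) {
  atom_model(chain, resno, rep("CA", nrow(xyz)), xyz)
}

# three mutually orthogonal 4-residue stick segments where only pairs
# (1,2) and (2,3) touch (C-C contact threshold: 1.7 + 1.7 + 1 = 4.4 A)
fx_orthogonal_model <- function() {
  seg1 <- cbind(0, 0, seq(0, 4.5, by = 1.5))             # along +z
  seg2 <- cbind(3, seq(0, 4.5, by = 1.5), 4.5)           # along +y, 3 A off seg1 top
  seg3 <- cbind(3 + seq(1.5, 6, by = 1.5), 7.5, 5.0)     # along +x, skew to seg2
  xyz <- rbind(seg1, seg2, seg3)
  model <- fx_ca_model(xyz, resno = 1:12)
  segs <- list(sse_segment(1, "H", 1, 4, seg1),
               sse_segment(2, "H", 5, 8, seg2),
               sse_segment(3, "H", 9, 12, seg3))
  list(model = model, segments = segs)
}

# random proper rotation + translation applied to a model and its segments
fx_rigid_motion <- function(model, segments) {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  shift <- rnorm(3, sd = 20)
  move <- function(xyz) sweep(xyz %*% t(q), 2, shift, `+`)
  at <- model$atoms
  xyz2 <- move(as.matrix(at[, c("x", "y", "z")]))
  model2 <- atom_model(model$chain, at$resno, at$elety, xyz2, at$elesy, at$resid)
  segments2 <- lapply(segments, function(s) {
    sse_segment(s$ordinal, s$sse_type, s$start_res, s$end_res, move(s$ca_coords))
  })
  list(model = model2, segments = segments2)
}

# minimal PDB text for a C-alpha-only chain
fx_write_pdb <- function(xyz, path, chain = "A", resno = seq_len(nrow(xyz))) {
  lines <- c(sprintf(
    "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(xyz)), "CA", "ALA", chain, resno,
    xyz[, 1], xyz[, 2], xyz[, 3], "C"), "END")
  writeLines(lines, path)
  path
}

# the same chain as minimal mmCIF
fx_write_cif <- function(xyz, path, chain = "A", resno = seq_len(nrow(xyz))) {
  hdr <- c("data_fixture", "#", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                    "auth_comp_id", "auth_asym_id", "auth_atom_id",
                    "pdbx_PDB_model_num")))
  rows <- sprintf("ATOM %d C CA . ALA %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d ALA %s CA 1",
                  seq_len(nrow(xyz)), chain, resno, xyz[, 1], xyz[, 2], xyz[, 3],
                  resno, chain)
  writeLines(c(hdr, rows, "#"), path)
  path
}
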