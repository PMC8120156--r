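#' Read a protein structure into per-chain atom models
#'
#' Thin wrapper over bio3d's PDB/mmCIF readers.  Only polymer `ATOM` records
#' are kept (HETATM, waters and ligands are excluded from tableau
#' construction); for alternate locations the first-listed altloc of each atom
#' is retained.
#'
#' @param path structure file.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension).
#' @return A named list of `atom_model` objects, one per chain.  Each model
#'   holds `chain` and an `atoms` data frame (`resno`, `resid`, `elety`,
#'   `elesy`, `x`, `y`, `z`).  An empty chain yields an empty model.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    suppressWarnings(
      if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
      else bio3d::read.cif(path, verbose = FALSE)),
    error = function(e) stop("parse error reading '", path, "' as ", format,
                             ": ", conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) > 0L) {
    # first-listed altloc per atom site
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
    at <- at[!duplicated(key), , drop = FALSE]
  }
  if (is.na(at$elesy[1]) && nrow(at) > 0L) {
    at$elesy <- substr(gsub("[0-9]", "", at$elety), 1, 1)
  }
  chains <- unique(at$chain)
  if (length(chains) == 0L) chains <- character(0)
  models <- lapply(chains, function(ch) {
    sub <- at[at$chain == ch, c("resno", "resid", "elety", "elesy", "x", "y", "z")]
    rownames(sub) <- NULL
    structure(list(chain = ch, atoms = sub), class = "atom_model")
  })
  names(models) <- chains
  structure(models, class = "chain_models")
}

#' @export
print.atom_model <- function(x, ...) {
  cat(sprintf("atom_model chain '%s': %d atoms, %d residues\n",
              x$chain, nrow(x$atoms), length(unique(x$atoms$resno))))
  invisible(x)
}

#' Build an atom model from residue records
#'
#' Programmatic counterpart of [read_structure()] used for generated
#' geometries: supply one row per atom.
#'
#' @param chain chain id.
#' @param resno integer residue numbers.
#' @param elety atom names (e.g. `"CA"`).
#' @param xyz numeric matrix (n x 3) of coordinates in Angstroms.
#' @param elesy element symbols; derived from `elety` when omitted.
#' @param resid residue names; defaults to `"ALA"`.
#' @return an `atom_model`.
#' @export
atom_model <- function(chain, resno, elety, xyz, elesy = NULL, resid = "ALA") {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  if (is.null(elesy)) elesy <- substr(gsub("[0-9]", "", elety), 1, 1)
  atoms <- data.frame(resno = as.integer(resno), resid = resid,
                      elety = elety, elesy = elesy,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  structure(list(chain = chain, atoms = atoms), class = "atom_model")
}

#' Construct an SSE segment
#'
#' @param ordinal 1-based position along the chain.
#' @param sse_type `"H"` or `"E"`.
#' @param start_res,end_res residue span, 1-based inclusive.
#' @param ca_coords matrix (>= 3 rows x 3) of C-alpha coordinates in N-to-C
#'   order.
#' @return object of class `sse_segment`.
#' @export
sse_segment <- function(ordinal, sse_type, start_res, end_res, ca_coords) {
  stopifnot(sse_type %in% c("H", "E"), start_res <= end_res)
  ca_coords <- matrix(as.numeric(ca_coords), ncol = 3)
  if (nrow(ca_coords) < 3L) stop("segment needs >= 3 C-alpha coordinates")
  structure(list(ordinal = as.integer(ordinal), sse_type = sse_type,
                 start_res = as.integer(start_res), end_res = as.integer(end_res),
                 ca_coords = ca_coords),
            class = "sse_segment")
}

ca_trace <- function(model) {
  ca <- model$atoms[model$atoms$elety == "CA", , drop = FALSE]
  ca <- ca[order(seq_len(nrow(ca))), , drop = FALSE]
  list(resno = ca$resno, xyz = as.matrix(ca[, c("x", "y", "z")]))
}

#' Assign secondary structure segments
#'
#' Two routes: `external_file` passes through a whitespace-separated segment
#' table (`chain type start end`, type in `{H, E}`), as produced by an
#' external secondary-structure program; `ca_geometry` applies built-in
#' C-alpha-only distance criteria (helix: `d(i, i+3)` in 4.7--5.7 A for at
#' least 4 consecutive `i`; strand: `d(i, i+2)` in 6.0--7.2 A for at least 3
#' consecutive `i`; minimum lengths H = 4, E = 3 residues; helices take
#' precedence where marks overlap).  The built-in assigner is a deliberate
#' approximation that keeps the tool self-contained; use the adapter for
#' fidelity to a dedicated assignment program.
#'
#' @param model an `atom_model`.
#' @param method `"ca_geometry"` or `"external_file"`.
#' @param sse_file path to the external segment table (for `external_file`).
#' @return ordered list of `sse_segment`, non-overlapping.
#' @export
assign_sses <- function(model, method = c("ca_geometry", "external_file"),
                        sse_file = NULL) {
  method <- match.arg(method)
  tr <- ca_trace(model)
  if (method == "external_file") {
    stopifnot(!is.null(sse_file))
    tab <- utils::read.table(sse_file, col.names = c("chain", "type", "start", "end"),
                             colClasses = c("character", "character", "integer", "integer"))
    tab <- tab[tab$chain == model$chain, , drop = FALSE]
    if (nrow(tab) == 0L) return(list())
    if (!all(tab$type %in% c("H", "E"))) stop("segment type must be H or E")
    tab <- tab[order(tab$start), , drop = FALSE]
    if (nrow(tab) > 1L) {
      overlap <- which(tab$start[-1] <= tab$end[-nrow(tab)])
      if (length(overlap) > 0L) {
        stop("overlapping segments in external file at rows: ",
             paste(overlap, overlap + 1L, sep = "&", collapse = ", "))
      }
    }
    spans <- Map(c, tab$start, tab$end)
    types <- tab$type
  } else {
    n <- length(tr$resno)
    if (n < 5L) stop("ca_geometry needs >= 5 consecutive C-alpha atoms")
    d_at <- function(k) sqrt(rowSums((tr$xyz[seq_len(n - k), , drop = FALSE] -
                                      tr$xyz[(1 + k):n, , drop = FALSE])^2))
    d3 <- d_at(3L); d2 <- d_at(2L)
    hmark <- d3 >= 4.7 & d3 <= 5.7
    emark <- d2 >= 6.0 & d2 <= 7.2
    taken <- logical(n)
    spans <- list(); types <- character(0)
    for (r in mark_runs(hmark, 4L)) {
      idx <- r[1]:(r[2] + 3L)          # residues covered by the i..i+3 windows
      if (length(idx) >= 4L && !any(taken[idx])) {
        taken[idx] <- TRUE
        spans <- c(spans, list(c(tr$resno[idx[1]], tr$resno[idx[length(idx)]])))
        types <- c(types, "H")
      }
    }
    for (r in mark_runs(emark, 3L)) {
      idx <- r[1]:(r[2] + 2L)
      idx <- idx[!taken[idx]]
      if (length(idx) >= 3L && all(diff(idx) == 1L)) {
        taken[idx] <- TRUE
        spans <- c(spans, list(c(tr$resno[idx[1]], tr$resno[idx[length(idx)]])))
        types <- c(types, "E")
      }
    }
    ord <- order(vapply(spans, `[`, numeric(1), 1))
    spans <- spans[ord]; types <- types[ord]
  }
  segs <- vector("list", length(spans))
  for (k in seq_along(spans)) {
    sel <- tr$resno >= spans[[k]][1] & tr$resno <= spans[[k]][2]
    if (sum(sel) < 3L) {
      stop(sprintf("segment %s %d-%d has fewer than 3 C-alpha atoms in model",
                   types[k], spans[[k]][1], spans[[k]][2]))
    }
    segs[[k]] <- sse_segment(k, types[k], spans[[k]][1], spans[[k]][2],
                             tr$xyz[sel, , drop = FALSE])
  }
  segs
}

# maximal runs of TRUE of at least min_len, as (start, end) index pairs
mark_runs <- function(mark, min_len) {
  r <- rle(mark)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  Map(c, starts[keep], ends[keep])
}

#' Fit the least-squares axis of an SSE segment
#'
#' Total least squares (principal axis of the centered C-alpha set), oriented
#' from the N- to the C-terminus.
#'
#' @param segment an `sse_segment`.
#' @return object of class `sse_axis`: `point` (centroid) and unit `direction`.
#' @export
fit_axis <- function(segment) {
  xyz <- segment$ca_coords
  ctr <- colMeans(xyz)
  centered <- sweep(xyz, 2, ctr)
  if (max(abs(centered)) < 1e-12) stop("degenerate geometry: all points identical")
  dir <- svd(centered, nu = 0, nv = 1)$v[, 1]
  span <- xyz[nrow(xyz), ] - xyz[1, ]
  if (sum(dir * span) < 0) dir <- -dir
  dir <- dir / sqrt(sum(dir^2))
  structure(list(point = ctr, direction = dir), class = "sse_axis")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Interaxial angle between two SSE axes
#'
#' The dihedral angle of the two axis directions about their mutual
#' perpendicular: for closest points `q1`, `q2` of the two axis lines, the
#' torsion of the four points `q1 + d1, q1, q2, q2 + d2`.  Parallel axes give
#' 0 degrees (the coplanar limit); identical axis lines give 0 with a
#' `degenerate` attribute.  The result is wrapped to `(-180, 180]`.
#'
#' @param a1,a2 `sse_axis` objects.
#' @return angle in degrees; attribute `degenerate` is TRUE for
#'   parallel/identical axes.
#' @export
interaxial_angle <- function(a1, a2) {
  d1 <- a1$direction; d2 <- a2$direction
  cr <- cross3(d1, d2)
  if (sqrt(sum(cr^2)) < 1e-9) {
    # parallel axes: coplanar limit 0; antiparallel wraps to 180
    return(structure(if (sum(d1 * d2) > 0) 0 else 180, degenerate = TRUE))
  }
  # closest points of the two lines
  w0 <- a1$point - a2$point
  b <- sum(d1 * d2)
  dd <- sum(d1 * w0); e <- sum(d2 * w0)
  denom <- 1 - b^2
  s <- (b * e - dd) / denom
  tt <- (e - b * dd) / denom
  q1 <- a1$point + s * d1
  q2 <- a2$point + tt * d2
  u1 <- -d1
  u2 <- q2 - q1
  if (sqrt(sum(u2^2)) < 1e-9) {
    # intersecting lines: zero-length mutual perpendicular segment, but its
    # direction is still defined
    u2 <- cr / sqrt(sum(cr^2))
    flag <- FALSE
  } else flag <- FALSE
  u3 <- d2
  n1 <- cross3(u1, u2)
  n2 <- cross3(u2, u3)
  ang <- atan2(sqrt(sum(u2^2)) * sum(u1 * n2), sum(n1 * n2)) * 180 / pi
  structure(wrap_angle(ang), degenerate = flag)
}

# Bondi heavy-atom radii; hydrogens are excluded from contact computation
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

vdw_radius <- function(elesy) {
  r <- VDW_RADII[toupper(elesy)]
  if (any(is.na(r))) {
    warning("unknown element(s) ", paste(unique(elesy[is.na(r)]), collapse = ", "),
            "; using fallback radius 1.70 A")
    r[is.na(r)] <- 1.70
  }
  unname(r)
}

#' Are two SSE segments in physical contact?
#'
#' TRUE iff some residue pair (one residue from each segment) has a heavy-atom
#' pair closer than the sum of their van der Waals radii plus `slack`
#' (default 1 A).
#'
#' @param seg1,seg2 `sse_segment` objects belonging to `model`.
#' @param model the `atom_model` holding the atoms.
#' @param slack additive distance allowance in Angstroms.
#' @return logical scalar.
#' @export
sse_contact <- function(seg1, seg2, model, slack = 1.0) {
  heavy <- function(seg) {
    a <- model$atoms
    sel <- a$resno >= seg$start_res & a$resno <= seg$end_res &
      toupper(a$elesy) != "H"
    a[sel, , drop = FALSE]
  }
  a1 <- heavy(seg1); a2 <- heavy(seg2)
  if (nrow(a1) == 0L || nrow(a2) == 0L) return(FALSE)
  r1 <- vdw_radius(a1$elesy); r2 <- vdw_radius(a2$elesy)
  x1 <- as.matrix(a1[, c("x", "y", "z")])
  x2 <- as.matrix(a2[, c("x", "y", "z")])
  for (i in seq_len(nrow(x1))) {
    d <- sqrt(colSums((t(x2) - x1[i, ])^2))
    if (any(d < r1[i] + r2 + slack)) return(TRUE)
  }
  FALSE
}

#' Build a tableau from an atom model and its SSE segments
#'
#' @param model an `atom_model`.
#' @param segments ordered list of `sse_segment` (e.g. from [assign_sses()]).
#' @param id tableau id; defaults to the model's chain.
#' @param slack contact slack in Angstroms passed to [sse_contact()].
#' @return a `tableau`.
#' @export
build_tableau <- function(model, segments, id = model$chain, slack = 1.0) {
  n <- length(segments)
  sse <- paste(vapply(segments, `[[`, character(1), "sse_type"), collapse = "")
  contacts <- matrix(FALSE, n, n)
  angles <- matrix(0, n, n)
  if (n > 1L) {
    axes <- lapply(segments, fit_axis)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        ang <- as.numeric(interaxial_angle(axes[[i]], axes[[j]]))
        angles[i, j] <- angles[j, i] <- ang
        ct <- sse_contact(segments[[i]], segments[[j]], model, slack)
        contacts[i, j] <- contacts[j, i] <- ct
      }
    }
  }
  tableau(id, sse, contacts, angles)
}
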