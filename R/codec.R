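#' Default kappa grid for the von Mises concentration parameter
#'
#' Zero (the uniform limit) plus 64 geometrically spaced values on
#' `[0.1, 1000]`.  A concept's concentration is coded by its index into this
#' public grid, so every kappa a dictionary can state is decodable.
#'
#' @return numeric vector of length 65, strictly increasing, first element 0.
#' @export
default_kappa_grid <- function() {
  c(0, exp(seq(log(0.1), log(1000), length.out = 64)))
}

#' Codec settings
#'
#' @param epsilon_deg angle quantization step in degrees; must divide 360
#'   exactly.  Losslessness is defined at this precision.
#' @param kappa_grid admissible von Mises concentrations; strictly increasing,
#'   first element 0.
#' @param flip_prob Bernoulli probability of a contact-cell mismatch inside a
#'   concept region, in (0, 0.5).
#' @return An object of class `code_spec`.
#' @export
code_spec <- function(epsilon_deg = 1, kappa_grid = default_kappa_grid(),
                      flip_prob = 0.05) {
  stopifnot(epsilon_deg > 0, abs(360 / epsilon_deg - round(360 / epsilon_deg)) < 1e-9)
  stopifnot(is.numeric(kappa_grid), length(kappa_grid) >= 2L,
            kappa_grid[1] == 0, all(diff(kappa_grid) > 0))
  stopifnot(flip_prob > 0, flip_prob < 0.5)
  structure(list(epsilon_deg = epsilon_deg, kappa_grid = kappa_grid,
                 flip_prob = flip_prob),
            class = "code_spec")
}

#' @export
print.code_spec <- function(x, ...) {
  cat(sprintf("code_spec: epsilon = %g deg, |kappa grid| = %d (max %g), flip_prob = %g\n",
              x$epsilon_deg, length(x$kappa_grid), max(x$kappa_grid), x$flip_prob))
  invisible(x)
}

#' Message length with a labelled breakdown
#'
#' @param breakdown named numeric vector with entries among
#'   `structure`, `contacts`, `angles`, `labels`, `dictionary`.
#' @return object of class `message_length`; `$bits` is the total.
#' @export
message_length <- function(breakdown) {
  parts <- c(structure = 0, contacts = 0, angles = 0, labels = 0, dictionary = 0)
  parts[names(breakdown)] <- breakdown
  structure(list(bits = sum(parts), breakdown = parts), class = "message_length")
}

#' @export
print.message_length <- function(x, ...) {
  cat(sprintf("%.3f bits (", x$bits))
  nz <- x$breakdown[x$breakdown != 0]
  cat(paste(sprintf("%s %.3f", names(nz), nz), collapse = ", "), ")\n")
  invisible(x)
}

#' Elias gamma code length for a positive integer
#'
#' @param n positive integer(s).
#' @return `2 * floor(log2(n)) + 1` bits.
#' @export
universal_int_len <- function(n) {
  if (any(n < 1)) stop("universal_int_len requires n >= 1")
  2 * floor(log2(n) + 1e-12) + 1
}

#' Krichevsky-Trofimov adaptive code length of a binary sequence
#'
#' Each symbol is coded with probability `(c + 1/2) / (t + 1)` where `c` is the
#' count of that symbol among the preceding `t` symbols.
#'
#' @param x binary sequence: an integer/logical vector or a string of 0/1.
#' @return total code length in bits (0 for an empty sequence).
#' @export
adaptive_binary_len <- function(x) {
  x <- parse_bits(x)
  if (length(x) == 0L) return(0)
  sum(kt_seq_costs(x))
}

# turn "0101", logicals or ints into an integer 0/1 vector
parse_bits <- function(x) {
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    if (!nzchar(x)) return(integer(0))
    x <- as.integer(strsplit(x, "")[[1]])
  }
  x <- as.integer(x)
  stopifnot(all(x %in% c(0L, 1L)))
  x
}

# per-symbol KT costs, conditioning each symbol on all earlier ones
kt_seq_costs <- function(x) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  prior1 <- cumsum(x) - x
  prior <- ifelse(x == 1L, prior1, seq_len(n) - 1L - prior1)
  -log2((prior + 0.5) / seq_len(n))
}

# total KT code length of a binary sequence with n0 zeros and n1 ones;
# the KT product is exchangeable, so the total depends only on the counts
kt_total <- function(n0, n1) {
  (lgamma(n0 + n1 + 1) - lgamma(n0 + 0.5) - lgamma(n1 + 0.5) +
     2 * lgamma(0.5)) / log(2)
}

#' Null (uniform) code length for one angle
#'
#' @param spec a `code_spec`.
#' @return `log2(360 / epsilon_deg)` bits.
#' @export
uniform_angle_len <- function(spec = code_spec()) {
  log2(360 / spec$epsilon_deg)
}

#' von Mises code length for an angular deviation
#'
#' Codes a deviation `delta` (degrees, wrapped to `(-180, 180]`) from a
#' concept's archetype angle under a von Mises density with mean 0 and
#' concentration `kappa`, at quantization `epsilon_deg`.  The length is floored
#' at 0 bits because density times bin width may exceed 1 at large kappa.
#'
#' @param delta angular deviation(s) in degrees.
#' @param kappa concentration; must be a value of `spec$kappa_grid`.
#' @param spec a `code_spec`.
#' @return code length(s) in bits.
#' @export
von_mises_angle_len <- function(delta, kappa, spec = code_spec()) {
  if (!any(abs(spec$kappa_grid - kappa) < 1e-12)) {
    stop("kappa is not on the codable grid")
  }
  d <- wrap_angle(delta) * pi / 180
  # -log2(f * eps_rad), f = exp(kappa cos d) / (2 pi I0(kappa)), written with
  # the exponentially scaled Bessel so kappa up to 1000 stays finite
  bits <- kappa * (1 - cos(d)) * log2(exp(1)) + vm_const_bits(kappa, spec)
  pmax(0, bits)
}

# log2(2 pi I0(kappa) e^-kappa) - log2(eps_rad): the delta-independent part
vm_const_bits <- function(kappa, spec) {
  eps_rad <- spec$epsilon_deg * pi / 180
  log2(2 * pi * besselI(kappa, 0, expon.scaled = TRUE)) - log2(eps_rad)
}

# ---- per-tableau precomputed null costs ------------------------------------
# The adaptive KT models for SSE symbols and contact cells condition on ALL
# previously transmitted or concept-implied symbols, so each position's null
# cost is a constant of the tableau and the dissection objective decomposes
# additively over regions.

# upper-triangle cells in row-major order: (1,2)..(1,n),(2,3)..
cell_order <- function(n) {
  if (n < 2L) return(matrix(integer(0), 0, 2))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

# list(sse: per-SSE KT bits, cell: n x n matrix of per-cell KT bits)
tableau_kt_costs <- function(t) {
  n <- tableau_size(t)
  sse <- as.integer(strsplit(t$sse_string, "")[[1]] == "E")
  sse_costs <- kt_seq_costs(sse)
  cellm <- matrix(0, n, n)
  ord <- cell_order(n)
  if (nrow(ord) > 0L) {
    cells <- as.integer(t$contacts[ord])
    cc <- kt_seq_costs(cells)
    for (k in seq_len(nrow(ord))) {
      cellm[ord[k, 1], ord[k, 2]] <- cellm[ord[k, 2], ord[k, 1]] <- cc[k]
    }
  }
  list(sse = sse_costs, cell = cellm)
}

#' Null-model message length of a tableau
#'
#' Codes, without any dictionary: the SSE count (Elias gamma of `n + 1`), the
#' SSE string (adaptive KT), the upper-triangle contact cells in row-major
#' order (adaptive KT), and one uniform angle per contacting pair.
#'
#' @param t a `tableau`.
#' @param spec a `code_spec`.
#' @return a `message_length`.
#' @export
null_tableau_len <- function(t, spec = code_spec()) {
  n <- tableau_size(t)
  kt <- tableau_kt_costs(t)
  ncontacts <- if (n > 1L) sum(t$contacts[upper.tri(t$contacts)]) else 0L
  message_length(c(
    structure = universal_int_len(n + 1) + sum(kt$sse),
    contacts = if (n > 1L) sum(kt$cell[upper.tri(kt$cell)]) else 0,
    angles = ncontacts * uniform_angle_len(spec)
  ))
}

#' Statement length of a dictionary (first part of the two-part message)
#'
#' The number of concepts is coded with the Elias gamma code; each concept is
#' stated as the null encoding of its archetype subtableau plus the index of
#' its kappa on the public grid.
#'
#' @param C a `fold_dictionary`.
#' @param spec a `code_spec`; defaults to the dictionary's own.
#' @return a `message_length` (all bits under the `dictionary` label).
#' @export
dictionary_len <- function(C, spec = NULL) {
  spec <- spec %||% C$spec
  bits <- universal_int_len(length(C$concepts) + 1)
  for (cc in C$concepts) {
    bits <- bits + null_tableau_len(cc$archetype, spec)$bits +
      log2(length(spec$kappa_grid))
  }
  message_length(c(dictionary = bits))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
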