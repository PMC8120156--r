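#' Construct a tableau
#'
#' A tableau records a protein folding pattern: the SSE string over `{H, E}`,
#' a symmetric logical contact matrix (FALSE diagonal), and a symmetric matrix
#' of interaxial angles in degrees on `(-180, 180]`.  Angles are defined for
#' every off-diagonal pair; the contact matrix flags which of them describe
#' physically contacting pairs (only those participate in coding).
#'
#' @param id character identifier.
#' @param sse_string character scalar over `H`/`E` (may be empty).
#' @param contacts symmetric logical n x n matrix, FALSE diagonal.
#' @param angles symmetric numeric n x n matrix of degrees in `(-180, 180]`;
#'   the diagonal is ignored (stored as 0).
#' @return An object of class `tableau`.
#' @export
tableau <- function(id, sse_string = "", contacts = NULL, angles = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sse_string), length(sse_string) == 1L)
  n <- nchar(sse_string)
  if (n > 0L && !grepl("^[HE]+$", sse_string)) {
    stop("sse_string must contain only 'H' and 'E'")
  }
  if (is.null(contacts)) contacts <- matrix(FALSE, n, n)
  if (is.null(angles)) angles <- matrix(0, n, n)
  contacts <- as.matrix(contacts)
  angles <- as.matrix(angles)
  storage.mode(contacts) <- "logical"
  storage.mode(angles) <- "double"
  stopifnot(nrow(contacts) == n, ncol(contacts) == n,
            nrow(angles) == n, ncol(angles) == n)
  if (n > 0L) {
    if (!isTRUE(all(contacts == t(contacts)))) stop("contacts must be symmetric")
    if (any(diag(contacts))) stop("contacts diagonal must be FALSE")
    if (max(abs(angles - t(angles))) > 1e-9) stop("angles must be symmetric")
    offd <- angles[upper.tri(angles)]
    if (any(offd <= -180 - 1e-9) || any(offd > 180 + 1e-9)) {
      stop("angles must lie in (-180, 180]")
    }
    diag(angles) <- 0
  }
  dimnames(contacts) <- NULL
  dimnames(angles) <- NULL
  structure(list(id = id, sse_string = sse_string,
                 contacts = contacts, angles = angles),
            class = "tableau")
}

#' @export
print.tableau <- function(x, ...) {
  n <- tableau_size(x)
  cat(sprintf("tableau '%s': %d SSEs [%s], %d contacts\n",
              x$id, n, x$sse_string,
              if (n > 1L) sum(x$contacts[upper.tri(x$contacts)]) else 0L))
  invisible(x)
}

#' Number of SSEs in a tableau
#' @param t a `tableau`.
#' @return integer count.
#' @export
tableau_size <- function(t) nchar(t$sse_string)

#' Test for tableau objects
#' @param x object.
#' @return logical.
#' @export
is_tableau <- function(x) inherits(x, "tableau")

#' Restrict a tableau to a consecutive SSE span
#'
#' @param t a `tableau`.
#' @param span integer vector `c(start, end)`, 1-based inclusive.
#' @return A `tableau` over the span.
#' @export
subtableau <- function(t, span) {
  span <- as.integer(span)
  stopifnot(length(span) == 2L, span[1] >= 1L, span[2] <= tableau_size(t),
            span[1] <= span[2])
  idx <- span[1]:span[2]
  tableau(sprintf("%s[%d-%d]", t$id, span[1], span[2]),
          substr(t$sse_string, span[1], span[2]),
          t$contacts[idx, idx, drop = FALSE],
          t$angles[idx, idx, drop = FALSE])
}

#' Wrap angles in degrees to the interval (-180, 180]
#' @param a numeric vector of degrees.
#' @return wrapped values.
#' @export
wrap_angle <- function(a) a - 360 * ceiling((a - 180) / 360)

# ---- tableau text format ----------------------------------------------------
# line 1: "#TABLEAU <id> <n>"; line 2: the SSE string (blank line when n = 0);
# then n lines of the lower triangle, row i holding i-1 cells "angle/flag"
# with the angle printed to 2 decimals.

#' Write a tableau in the plain-text tableau format
#'
#' The writer/reader pair round-trips byte-exactly: `write_tableau(read_tableau(f))`
#' reproduces `f`.  Angles are printed to 2 decimals, so writing a tableau whose
#' angles carry more precision quantizes them at 0.01 degrees.
#'
#' @param t a `tableau`.
#' @param path output file path; `NULL` returns the lines invisibly.
#' @return (invisibly) the character vector of lines.
#' @export
write_tableau <- function(t, path = NULL) {
  n <- tableau_size(t)
  lines <- c(sprintf("#TABLEAU %s %d", t$id, n), t$sse_string)
  if (n > 0L) {
    for (i in seq_len(n)) {
      if (i == 1L) { lines <- c(lines, ""); next }
      cells <- vapply(seq_len(i - 1L), function(j) {
        sprintf("%.2f/%d", t$angles[i, j], as.integer(t$contacts[i, j]))
      }, character(1))
      lines <- c(lines, paste(cells, collapse = " "))
    }
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read a tableau from the plain-text tableau format
#'
#' @param path input file path, or a character vector of lines via `text`.
#' @param text optional character vector of lines (used when `path` is NULL).
#' @return A `tableau`.
#' @export
read_tableau <- function(path = NULL, text = NULL) {
  lines <- if (is.null(path)) text else readLines(path)
  if (length(lines) < 1L || !startsWith(lines[1], "#TABLEAU ")) {
    stop("not a tableau file: missing '#TABLEAU' header")
  }
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) != 3L) stop("malformed tableau header: ", lines[1])
  id <- hdr[2]
  n <- as.integer(hdr[3])
  sse <- if (length(lines) >= 2L) lines[2] else ""
  if (nchar(sse) != n) stop("SSE string length does not match header n")
  contacts <- matrix(FALSE, n, n)
  angles <- matrix(0, n, n)
  if (n > 0L) {
    body <- lines[-(1:2)]
    if (length(body) < n) stop("truncated tableau body: expected ", n, " rows")
    for (i in seq_len(n)) {
      if (i == 1L) next
      cells <- strsplit(trimws(body[i]), "\\s+")[[1]]
      if (length(cells) != i - 1L) {
        stop(sprintf("row %d has %d cells, expected %d", i, length(cells), i - 1L))
      }
      for (j in seq_len(i - 1L)) {
        parts <- strsplit(cells[j], "/", fixed = TRUE)[[1]]
        if (length(parts) != 2L) stop("malformed cell: ", cells[j])
        ang <- as.numeric(parts[1])
        flg <- as.integer(parts[2])
        if (is.na(ang) || !(flg %in% c(0L, 1L))) stop("malformed cell: ", cells[j])
        angles[i, j] <- angles[j, i] <- ang
        contacts[i, j] <- contacts[j, i] <- flg == 1L
      }
    }
  }
  tableau(id, sse, contacts, angles)
}

#' Write a collection of tableaux to a directory
#' @param collection list of `tableau` objects.
#' @param dir output directory (created if needed).
#' @return (invisibly) the written file paths.
#' @export
write_collection <- function(collection, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(collection, function(t) {
    p <- file.path(dir, paste0(t$id, ".tab"))
    write_tableau(t, p)
    p
  }, character(1))
  invisible(paths)
}

#' Read all tableau files (*.tab) from a directory
#' @param dir directory containing `.tab` files.
#' @return list of `tableau` objects, sorted by file name.
#' @export
read_collection <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tab$", full.names = TRUE))
  lapply(files, read_tableau)
}

#' Tabulate a tableau's SSE pairs
#'
#' @param x a `tableau`.
#' @param ... unused.
#' @return data frame with one row per unordered SSE pair: `i`, `j`,
#'   `contact`, `angle_deg`.
#' @export
as.data.frame.tableau <- function(x, ...) {
  n <- tableau_size(x)
  if (n < 2L) {
    return(data.frame(i = integer(), j = integer(),
                      contact = logical(), angle_deg = numeric()))
  }
  idx <- which(upper.tri(x$contacts), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  data.frame(i = idx[, 1], j = idx[, 2],
             contact = x$contacts[idx],
             angle_deg = x$angles[idx])
}
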