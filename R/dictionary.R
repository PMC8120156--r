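#' Construct a concept
#'
#' A concept is an archetype subtableau spanning >= 2 consecutive SSEs whose
#' contact graph is connected, together with a von Mises concentration kappa
#' (how tightly usage angles cluster around the archetype's) and the
#' provenance of the archetype in its source tableau.
#'
#' @param id character id, conventionally `c_NNNN`.
#' @param archetype a `tableau` with `n >= 2` and a connected contact graph.
#' @param kappa concentration, a value of the codec's kappa grid.
#' @param provenance list with `source` (tableau id), `start`, `end`
#'   (1-based inclusive SSE span).
#' @return object of class `fold_concept`.
#' @export
concept <- function(id, archetype, kappa, provenance = NULL) {
  stopifnot(is_tableau(archetype))
  if (tableau_size(archetype) < 2L) stop("concept archetype needs >= 2 SSEs")
  if (!is_connected(archetype$contacts)) {
    stop("concept archetype contact graph is not connected")
  }
  structure(list(id = id, archetype = archetype, kappa = kappa,
                 provenance = provenance),
            class = "fold_concept")
}

#' @export
print.fold_concept <- function(x, ...) {
  cat(sprintf("concept %s: [%s], kappa = %.3g (from %s %d-%d)\n",
              x$id, x$archetype$sse_string, x$kappa,
              x$provenance$source %||% "?",
              x$provenance$start %||% NA, x$provenance$end %||% NA))
  invisible(x)
}

#' Construct a dictionary of concepts
#'
#' The null concept `c_0000` (one unexplained SSE) is implicit and never
#' stored.
#'
#' @param concepts list of `fold_concept`.
#' @param spec the `code_spec` under which the dictionary codes tableaux.
#' @return object of class `fold_dictionary`.
#' @export
new_dictionary <- function(concepts = list(), spec = code_spec()) {
  stopifnot(all(vapply(concepts, inherits, logical(1), "fold_concept")))
  ids <- vapply(concepts, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("concept ids must be unique")
  structure(list(concepts = concepts, spec = spec), class = "fold_dictionary")
}

#' @export
print.fold_dictionary <- function(x, ...) {
  cat(sprintf("dictionary of %d concepts (+ implicit null c_0000)\n",
              length(x$concepts)))
  for (cc in head(x$concepts, 10L)) {
    cat("  "); print(cc)
  }
  if (length(x$concepts) > 10L) cat("  ...\n")
  invisible(x)
}

#' Tabulate a dictionary's concepts
#' @param x a `fold_dictionary`.
#' @param ... unused.
#' @return data frame with `id`, `n_sse`, `sse_string`, `n_contacts`, `kappa`,
#'   `source`, `start`, `end`.
#' @export
as.data.frame.fold_dictionary <- function(x, ...) {
  do.call(rbind, lapply(x$concepts, function(cc) {
    a <- cc$archetype
    data.frame(id = cc$id, n_sse = tableau_size(a), sse_string = a$sse_string,
               n_contacts = sum(a$contacts[upper.tri(a$contacts)]),
               kappa = cc$kappa,
               source = cc$provenance$source %||% NA_character_,
               start = cc$provenance$start %||% NA_integer_,
               end = cc$provenance$end %||% NA_integer_)
  })) %||% data.frame()
}

#' Is a contact graph connected?
#'
#' Breadth-first search over the SSE contact graph.  A single vertex is
#' connected; an empty graph (n = 0) is treated as connected.
#'
#' @param contacts symmetric logical matrix.
#' @return logical scalar.
#' @export
is_connected <- function(contacts) {
  n <- nrow(contacts)
  if (is.null(n) || n <= 1L) return(TRUE)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[1L]
    queue <- queue[-1L]
    nb <- which(contacts[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Extract a candidate concept from a tableau span
#'
#' Any subtableau over >= 2 consecutive SSEs is a candidate concept provided
#' its contact graph is connected; otherwise the candidate is rejected naming
#' the isolated SSE(s).  Kappa is initialized to the grid median.
#'
#' @param t source `tableau`.
#' @param span `c(start, end)`, 1-based inclusive, length >= 2.
#' @param spec a `code_spec` (provides the kappa grid).
#' @param id id for the new concept.
#' @return a `fold_concept`.
#' @export
extract_candidate <- function(t, span, spec = code_spec(), id = "c_new") {
  span <- as.integer(span)
  if (span[2] - span[1] + 1L < 2L) {
    stop("candidate rejected: span must cover >= 2 SSEs")
  }
  arch <- subtableau(t, span)
  if (!is_connected(arch$contacts)) {
    comp <- graph_components(arch$contacts)
    main <- which(comp == comp[1])
    isolated <- setdiff(seq_len(tableau_size(arch)), main) + span[1] - 1L
    stop("candidate rejected: contact graph disconnected; isolated SSE(s): ",
         paste(isolated, collapse = ", "))
  }
  grid <- spec$kappa_grid
  kappa <- grid[ceiling(length(grid) / 2)]
  concept(id, arch, kappa,
          provenance = list(source = t$id, start = span[1], end = span[2]))
}

# component label per vertex (BFS)
graph_components <- function(contacts) {
  n <- nrow(contacts)
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(contacts[v, ] & comp == 0L)
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Reassign canonical concept ids
#'
#' Ids become `c_0001`, `c_0002`, ... ordered by decreasing archetype size
#' (number of SSEs), then lexicographic SSE string, then provenance
#' (source id, start) for determinism.  Idempotent.
#'
#' @param C a `fold_dictionary`.
#' @return the dictionary with ids reassigned.
#' @export
finalize_ids <- function(C) {
  if (length(C$concepts) == 0L) return(C)
  n <- vapply(C$concepts, function(cc) tableau_size(cc$archetype), integer(1))
  sse <- vapply(C$concepts, function(cc) cc$archetype$sse_string, character(1))
  src <- vapply(C$concepts, function(cc) cc$provenance$source %||% "", character(1))
  st <- vapply(C$concepts, function(cc) cc$provenance$start %||% 0L, numeric(1))
  ord <- order(-n, sse, src, st)
  C$concepts <- C$concepts[ord]
  for (i in seq_along(C$concepts)) {
    C$concepts[[i]]$id <- sprintf("c_%04d", i)
  }
  C
}

# ---- JSON serialization -----------------------------------------------------

DICTIONARY_FORMAT_VERSION <- "folddict-dictionary-1"

#' Save a dictionary to a JSON file
#'
#' Archetype contacts are stored as a run-length encoding of the row-major
#' upper triangle; angles are stored for contacting pairs only, to 2 decimals
#' (at or below half the default quantization step).  The codec settings are
#' embedded so dissection is reproducible bit-for-bit.
#'
#' @param C a `fold_dictionary`.
#' @param path output file.
#' @return (invisibly) `path`.
#' @export
save_dictionary <- function(C, path) {
  enc <- list(
    version = DICTIONARY_FORMAT_VERSION,
    spec = list(epsilon_deg = C$spec$epsilon_deg,
                kappa_grid = C$spec$kappa_grid,
                flip_prob = C$spec$flip_prob),
    concepts = lapply(C$concepts, function(cc) {
      a <- cc$archetype
      n <- tableau_size(a)
      ord <- cell_order(n)
      cells <- as.integer(a$contacts[ord])
      r <- rle(cells)
      contacting <- ord[cells == 1L, , drop = FALSE]
      list(id = cc$id,
           sse_string = a$sse_string,
           contacts = list(lengths = r$lengths, values = r$values),
           angles = if (nrow(contacting) > 0L) {
             lapply(seq_len(nrow(contacting)), function(k) {
               i <- contacting[k, 1]; j <- contacting[k, 2]
               list(i = i, j = j, angle = round(a$angles[i, j], 2))
             })
           } else list(),
           kappa = cc$kappa,
           provenance = cc$provenance)
    })
  )
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a dictionary from a JSON file
#'
#' @param path file written by [save_dictionary()].
#' @return a `fold_dictionary`.
#' @export
load_dictionary <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("cannot parse dictionary file: ",
                                           conditionMessage(e)))
  if (!identical(obj$version, DICTIONARY_FORMAT_VERSION)) {
    stop("dictionary format version mismatch: found '",
         obj$version %||% "<missing>", "', expected '",
         DICTIONARY_FORMAT_VERSION, "'")
  }
  spec <- code_spec(epsilon_deg = obj$spec$epsilon_deg,
                    kappa_grid = unlist(obj$spec$kappa_grid),
                    flip_prob = obj$spec$flip_prob)
  concepts <- lapply(obj$concepts, function(co) {
    sse <- co$sse_string
    n <- nchar(sse)
    cells <- inverse.rle(list(lengths = unlist(co$contacts$lengths),
                              values = unlist(co$contacts$values)))
    ord <- cell_order(n)
    if (length(cells) != nrow(ord)) stop("corrupt contact run-length data")
    contacts <- matrix(FALSE, n, n)
    angles <- matrix(0, n, n)
    for (k in seq_len(nrow(ord))) {
      if (cells[k] == 1L) {
        contacts[ord[k, 1], ord[k, 2]] <- contacts[ord[k, 2], ord[k, 1]] <- TRUE
      }
    }
    for (an in co$angles) {
      angles[an$i, an$j] <- angles[an$j, an$i] <- an$angle
    }
    concept(co$id, tableau(co$id, sse, contacts, angles), co$kappa,
            provenance = if (!is.null(co$provenance)) {
              list(source = co$provenance$source,
                   start = as.integer(co$provenance$start),
                   end = as.integer(co$provenance$end))
            })
  })
  new_dictionary(concepts, spec)
}
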