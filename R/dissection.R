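# ---- packing for the C++ dynamic-programming core ---------------------------

sse_as_int <- function(sse_string) {
  if (!nzchar(sse_string)) return(integer(0))
  as.integer(strsplit(sse_string, "")[[1]] == "E")
}

pack_tableau <- function(t, spec) {
  n <- tableau_size(t)
  kt <- tableau_kt_costs(t)
  cellbase <- kt$cell
  if (n > 1L) {
    ub <- uniform_angle_len(spec)
    cellbase[t$contacts] <- cellbase[t$contacts] + ub
  }
  base_total <- universal_int_len(n + 1) +
    (if (n > 1L) sum(cellbase[upper.tri(cellbase)]) else 0)
  list(n = n, sse = sse_as_int(t$sse_string),
       contact = t$contacts, angle = t$angles,
       kt_sse = kt$sse, cellbase = cellbase, base_total = base_total)
}

pack_concept <- function(archetype, kappa, spec) {
  list(n = tableau_size(archetype), sse = sse_as_int(archetype$sse_string),
       contact = archetype$contacts, angle = archetype$angles,
       kappa = kappa, const_bits = vm_const_bits(kappa, spec))
}

pack_dictionary <- function(C) {
  lapply(C$concepts, function(cc) pack_concept(cc$archetype, cc$kappa, C$spec))
}

flip_bits <- function(spec) {
  c(match = -log2(1 - spec$flip_prob), mismatch = -log2(spec$flip_prob))
}

# ---- match cost -------------------------------------------------------------

#' Cost of explaining a tableau span by a concept
#'
#' The validity gate requires the span's SSE string to equal the archetype's
#' and every archetype contact to be present in the tableau over the span
#' (extra contacts in the tableau are permitted as flips).  When valid, the
#' cost is: each within-span contact cell coded under the Bernoulli flip model
#' relative to the archetype, plus, for each pair in contact in the tableau,
#' a von Mises code of the angular deviation from the archetype angle (when
#' the pair contacts in the archetype) or a uniform angle code (when it does
#' not).
#'
#' @param t a `tableau`.
#' @param span `c(start, end)`, 1-based inclusive; length must equal the
#'   archetype's SSE count.
#' @param c a `fold_concept`.
#' @param spec a `code_spec`.
#' @return cost in bits, or `NA` when the gate fails (INVALID).
#' @export
match_cost <- function(t, span, c, spec = code_spec()) {
  span <- as.integer(span)
  arch <- c$archetype
  m <- tableau_size(arch)
  stopifnot(span[2] - span[1] + 1L == m, span[1] >= 1L,
            span[2] <= tableau_size(t))
  idx <- span[1]:span[2]
  if (substr(t$sse_string, span[1], span[2]) != arch$sse_string) return(NA_real_)
  fb <- flip_bits(spec)
  bits <- 0
  for (p in seq_len(m - 1L)) {
    for (q in (p + 1L):m) {
      tc <- t$contacts[idx[p], idx[q]]
      ac <- arch$contacts[p, q]
      if (ac && !tc) return(NA_real_)
      bits <- bits + if (tc == ac) fb[["match"]] else fb[["mismatch"]]
      if (tc) {
        bits <- bits + if (ac) {
          von_mises_angle_len(t$angles[idx[p], idx[q]] - arch$angles[p, q],
                              c$kappa, spec)
        } else uniform_angle_len(spec)
      }
    }
  }
  bits
}

# ---- dissection object ------------------------------------------------------

new_dissection <- function(tableau_id, regions, total_bits) {
  structure(list(tableau_id = tableau_id, regions = regions,
                 total_bits = total_bits),
            class = "dissection")
}

#' @export
print.dissection <- function(x, ...) {
  cat(sprintf("dissection of '%s': %d regions, %.3f bits\n",
              x$tableau_id, nrow(x$regions), x$total_bits$bits))
  print(x$regions)
  invisible(x)
}

#' Tabulate a dissection's regions
#' @param x a `dissection`.
#' @param ... unused.
#' @return the regions data frame (`start`, `end`, `concept_id`, `region_bits`).
#' @export
as.data.frame.dissection <- function(x, ...) x$regions

# breakdown of a dissection total, recomputed in R from the chosen regions
dissection_breakdown <- function(t, C, regions) {
  n <- tableau_size(t)
  spec <- C$spec
  kt <- tableau_kt_costs(t)
  label_bits <- log2(length(C$concepts) + 1)
  fb <- flip_bits(spec)
  # which concept region (row index) covers each SSE, 0 = null
  cover <- integer(n)
  for (r in seq_len(nrow(regions))) {
    if (regions$concept_id[r] != "c_0000") {
      cover[regions$start[r]:regions$end[r]] <- r
    }
  }
  structure_bits <- universal_int_len(n + 1) + sum(kt$sse[cover == 0L])
  contacts_bits <- 0; angles_bits <- 0
  cid_index <- setNames(seq_along(C$concepts),
                        vapply(C$concepts, `[[`, character(1), "id"))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        tc <- t$contacts[i, j]
        inside <- cover[i] != 0L && cover[i] == cover[j]
        if (inside) {
          r <- cover[i]
          cc <- C$concepts[[cid_index[[regions$concept_id[r]]]]]
          p <- i - regions$start[r] + 1L
          q <- j - regions$start[r] + 1L
          ac <- cc$archetype$contacts[p, q]
          contacts_bits <- contacts_bits +
            if (tc == ac) fb[["match"]] else fb[["mismatch"]]
          if (tc) {
            angles_bits <- angles_bits + if (ac) {
              von_mises_angle_len(t$angles[i, j] - cc$archetype$angles[p, q],
                                  cc$kappa, spec)
            } else uniform_angle_len(spec)
          }
        } else {
          contacts_bits <- contacts_bits + kt$cell[i, j]
          if (tc) angles_bits <- angles_bits + uniform_angle_len(spec)
        }
      }
    }
  }
  message_length(c(structure = structure_bits,
                   contacts = contacts_bits,
                   angles = angles_bits,
                   labels = nrow(regions) * label_bits))
}

#' Optimal dissection of a tableau against a dictionary
#'
#' Partitions the tableau's SSEs into consecutive regions, each assigned to a
#' dictionary concept or to the null concept `c_0000` (one SSE), minimizing
#' the total message length by dynamic programming.  Each region start is
#' labelled with a uniform code over the `|C| + 1` options; cells outside
#' concept regions are coded under the null model, so the objective
#' decomposes and the optimum is exact.  Ties are broken deterministically:
#' fewer regions, then earlier concept id (null first).
#'
#' @param t a `tableau`.
#' @param C a `fold_dictionary`.
#' @return a `dissection`: `regions` data frame and `total_bits`
#'   (a `message_length` with breakdown).
#' @export
dissect <- function(t, C) {
  spec <- C$spec
  pt <- pack_tableau(t, spec)
  pc <- pack_dictionary(C)
  fb <- flip_bits(spec)
  res <- cpp_dissect(pt, pc, log2(length(pc) + 1), uniform_angle_len(spec),
                     fb[["match"]], fb[["mismatch"]])
  ids <- c("c_0000", vapply(C$concepts, `[[`, character(1), "id"))
  regions <- data.frame(start = res$start, end = res$end,
                        concept_id = ids[res$concept + 1L],
                        region_bits = res$region_bits)
  ml <- dissection_breakdown(t, C, regions)
  stopifnot(abs(ml$bits - res$total) < 1e-6)
  new_dissection(t$id, regions, ml)
}

#' Exhaustive dissection (test oracle)
#'
#' Enumerates every segmentation and assignment and returns the minimum-length
#' dissection, computing each candidate's total independently of the dynamic
#' program.  Refuses tableaux with more than 12 SSEs.
#'
#' @inheritParams dissect
#' @return a `dissection`.
#' @export
brute_force_dissect <- function(t, C) {
  n <- tableau_size(t)
  if (n > 12L) stop("brute_force_dissect is limited to n <= 12 SSEs")
  spec <- C$spec
  kt <- tableau_kt_costs(t)
  label_bits <- log2(length(C$concepts) + 1)
  sizes <- vapply(C$concepts, function(cc) tableau_size(cc$archetype), integer(1))
  best <- NULL; best_total <- Inf; best_nreg <- Inf

  base_cells <- function(cover) {
    # null-coded cells + uniform angles for their contacting pairs
    bits <- 0
    if (n > 1L) {
      for (i in seq_len(n - 1L)) {
        for (j in (i + 1L):n) {
          if (cover[i] != 0L && cover[i] == cover[j]) next
          bits <- bits + kt$cell[i, j] +
            (if (t$contacts[i, j]) uniform_angle_len(spec) else 0)
        }
      }
    }
    bits
  }

  evaluate <- function(regions) {
    cover <- integer(n)
    total <- universal_int_len(n + 1) + nrow(regions) * label_bits
    for (r in seq_len(nrow(regions))) {
      if (regions$concept[r] == 0L) {
        total <- total + kt$sse[regions$start[r]]
      } else {
        cover[regions$start[r]:regions$end[r]] <- r
        total <- total + regions$region_bits[r]
      }
    }
    total + base_cells(cover)
  }

  recurse <- function(pos, regions) {
    if (pos > n) {
      total <- evaluate(regions)
      nreg <- nrow(regions)
      if (total < best_total - 1e-9 ||
          (total <= best_total + 1e-9 && nreg < best_nreg)) {
        best_total <<- total; best_nreg <<- nreg; best <<- regions
      }
      return(invisible())
    }
    recurse(pos + 1L, rbind(regions, data.frame(start = pos, end = pos,
                                                concept = 0L, region_bits = NA)))
    for (ci in seq_along(C$concepts)) {
      m <- sizes[ci]
      if (pos + m - 1L > n) next
      mc <- match_cost(t, c(pos, pos + m - 1L), C$concepts[[ci]], spec)
      if (is.na(mc)) next
      recurse(pos + m, rbind(regions, data.frame(start = pos, end = pos + m - 1L,
                                                 concept = ci, region_bits = mc)))
    }
  }
  empty <- data.frame(start = integer(), end = integer(),
                      concept = integer(), region_bits = numeric())
  recurse(1L, empty)
  if (is.null(best)) best <- empty       # n = 0
  ids <- c("c_0000", vapply(C$concepts, `[[`, character(1), "id"))
  regions <- data.frame(start = best$start, end = best$end,
                        concept_id = ids[best$concept + 1L],
                        region_bits = ifelse(best$concept == 0L,
                                             kt$sse[best$start],
                                             best$region_bits))
  if (nrow(regions) == 0L) {
    best_total <- universal_int_len(n + 1)
  }
  ml <- dissection_breakdown(t, C, regions)
  new_dissection(t$id, regions, ml)
}

#' Two-part message length of a collection under a dictionary
#'
#' `dictionary_len(C)` plus the optimally dissected length of every tableau.
#'
#' @param collection list of `tableau` objects.
#' @param C a `fold_dictionary`.
#' @return a `message_length` (breakdown includes the `dictionary` part).
#' @export
total_collection_len <- function(collection, C) {
  parts <- dictionary_len(C)$breakdown
  for (t in collection) {
    parts <- parts + dissect(t, C)$total_bits$breakdown
  }
  message_length(parts)
}

# ---- reports ----------------------------------------------------------------

#' Write a dissection report with reference to the amino-acid sequence
#'
#' Produces a marked-up sequence text (60-residue blocks with a per-residue
#' concept track and a legend), a JSON record of the regions, and FASTA
#' records of the region subsequences with headers
#' `>tableauid|conceptid|start-end`.
#'
#' @param d a `dissection`.
#' @param sequence amino-acid string of the chain.
#' @param sse_spans data frame with one row per SSE (`start`, `end`,
#'   1-based inclusive residue positions into `sequence`).
#' @param out_prefix when given, writes `<prefix>.markup.txt`,
#'   `<prefix>.json`, `<prefix>.fasta`.
#' @return (invisibly) list with `markup`, `json` (text), `fasta` character
#'   vectors.
#' @export
write_dissection_report <- function(d, sequence, sse_spans, out_prefix = NULL) {
  nres <- nchar(sequence)
  n_sse <- max(c(0L, d$regions$end))
  if (nrow(sse_spans) < n_sse) stop("sse_spans has fewer rows than SSEs used")
  if (nrow(sse_spans) > 0L &&
      (any(sse_spans$end > nres) || any(sse_spans$start < 1L) ||
       any(sse_spans$start > sse_spans$end))) {
    stop("sse residue spans are inconsistent with the sequence length")
  }
  track <- rep(".", nres)
  legend <- character(0)
  fasta <- character(0)
  marker_pool <- c(LETTERS, letters)
  mk <- 0L
  regs <- d$regions
  concept_rows <- which(regs$concept_id != "c_0000")
  for (r in concept_rows) {
    res_start <- sse_spans$start[regs$start[r]]
    res_end <- sse_spans$end[regs$end[r]]
    mk <- mk + 1L
    sym <- marker_pool[(mk - 1L) %% length(marker_pool) + 1L]
    track[res_start:res_end] <- sym
    legend <- c(legend, sprintf("%s = %s (residues %d-%d)", sym,
                                regs$concept_id[r], res_start, res_end))
    fasta <- c(fasta,
               sprintf(">%s|%s|%d-%d", d$tableau_id, regs$concept_id[r],
                       res_start, res_end),
               substr(sequence, res_start, res_end))
  }
  markup <- c(sprintf("# dissection of %s: %.3f bits, %d regions",
                      d$tableau_id, d$total_bits$bits, nrow(regs)),
              legend)
  if (nres > 0L) {
    for (blk in seq(1L, nres, by = 60L)) {
      hi <- min(blk + 59L, nres)
      markup <- c(markup,
                  sprintf("%6d %s", blk, substr(sequence, blk, hi)),
                  sprintf("       %s", paste(track[blk:hi], collapse = "")))
    }
  }
  json <- jsonlite::toJSON(list(
    tableau_id = d$tableau_id,
    total_bits = d$total_bits$bits,
    regions = lapply(seq_len(nrow(regs)), function(r) {
      out <- list(start_sse = regs$start[r], end_sse = regs$end[r],
                  concept_id = regs$concept_id[r],
                  region_bits = regs$region_bits[r])
      if (regs$end[r] <= nrow(sse_spans)) {
        out$start_res <- sse_spans$start[regs$start[r]]
        out$end_res <- sse_spans$end[regs$end[r]]
      }
      out
    })), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out <- list(markup = markup, json = as.character(json), fasta = fasta)
  if (!is.null(out_prefix)) {
    writeLines(out$markup, paste0(out_prefix, ".markup.txt"))
    writeLines(out$json, paste0(out_prefix, ".json"))
    writeLines(out$fasta, paste0(out_prefix, ".fasta"))
  }
  invisible(out)
}
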