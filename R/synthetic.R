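#' Default planted motif used by the synthetic benchmark
#'
#' A four-SSE beta-alpha-alpha-beta unit (`EHHE`) with a connected contact
#' ring (1-2, 2-3, 3-4, 1-4) and packing-like interaxial angles, the kind of
#' supersecondary arrangement a concept dictionary is meant to recover.
#'
#' @param spec a `code_spec` (provides the kappa grid for the concept).
#' @return a `fold_concept` with id `c_motif`.
#' @export
default_motif <- function(spec = code_spec()) {
  contacts <- matrix(FALSE, 4, 4)
  for (p in list(c(1, 2), c(2, 3), c(3, 4), c(1, 4))) {
    contacts[p[1], p[2]] <- contacts[p[2], p[1]] <- TRUE
  }
  angles <- matrix(0, 4, 4)
  vals <- list(c(1, 2, -40.5), c(2, 3, 169.5), c(3, 4, -40.5), c(1, 4, -20.5),
               c(1, 3, 100.5), c(2, 4, -100.5))
  for (v in vals) angles[v[1], v[2]] <- angles[v[2], v[1]] <- v[3]
  grid <- spec$kappa_grid
  concept("c_motif", tableau("motif", "EHHE", contacts, angles),
          grid[ceiling(length(grid) / 2)],
          provenance = list(source = "motif", start = 1L, end = 4L))
}

#' Parameters of the synthetic tableau generator
#'
#' The defaults are the reference benchmark setting: 60 tableaux of 5--10
#' SSEs, dense near-diagonal contacts (adjacent pairs 0.9, distant pairs
#' 0.15, mimicking the locality of real folding patterns), the default
#' four-SSE motif planted in half the tableaux, and usage angles perturbed
#' around the archetype by a von Mises with concentration 50 (circular sd of
#' roughly 8 degrees).
#'
#' @param n_tableaux number of tableaux to generate.
#' @param sse_range `c(n_min, n_max)` SSE counts, drawn uniformly.
#' @param p_helix probability of `H` per SSE.
#' @param p_contact_adjacent contact probability for `|i - j| = 1`.
#' @param p_contact_far contact probability for `|i - j| > 1`.
#' @param motif a `fold_concept` to plant, or `NULL` for pure noise.
#' @param plant_fraction fraction of tableaux receiving the motif.
#' @param kappa_true von Mises concentration of usage angle noise.
#' @param seed integer RNG seed.
#' @return object of class `synth_params`.
#' @export
synth_params <- function(n_tableaux = 60, sse_range = c(5, 10), p_helix = 0.5,
                         p_contact_adjacent = 0.9, p_contact_far = 0.15,
                         motif = default_motif(), plant_fraction = 0.5,
                         kappa_true = 50, seed = 1) {
  stopifnot(p_helix >= 0, p_helix <= 1,
            p_contact_adjacent >= 0, p_contact_adjacent <= 1,
            p_contact_far >= 0, p_contact_far <= 1,
            plant_fraction >= 0, plant_fraction <= 1, kappa_true >= 0,
            sse_range[1] >= 2, sse_range[1] <= sse_range[2])
  if (!is.null(motif)) {
    stopifnot(inherits(motif, "fold_concept"),
              sse_range[1] >= tableau_size(motif$archetype))
  }
  structure(list(n_tableaux = as.integer(n_tableaux),
                 sse_range = as.integer(sse_range), p_helix = p_helix,
                 p_contact_adjacent = p_contact_adjacent,
                 p_contact_far = p_contact_far, motif = motif,
                 plant_fraction = plant_fraction, kappa_true = kappa_true,
                 seed = as.integer(seed)),
            class = "synth_params")
}

# quantize an angle to the center of its epsilon bin on (-180, 180]
quantize_angle <- function(a, epsilon_deg) {
  a <- wrap_angle(a)
  b <- ceiling((a + 180) / epsilon_deg)
  b[b < 1] <- 1
  -180 + (b - 0.5) * epsilon_deg
}

#' Draw from a von Mises distribution (Best-Fisher rejection sampler)
#'
#' @param n number of draws.
#' @param mu mean direction in radians.
#' @param kappa concentration (>= 0; 0 gives the circular uniform).
#' @return radians in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  if (kappa == 0) return(runif(n, -pi, pi))
  if (kappa > 5e4) return(rep(mu, n))    # numerically a point mass
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  out <- out + mu
  ifelse(out > pi, out - 2 * pi, ifelse(out <= -pi, out + 2 * pi, out))
}

#' Generate one random tableau
#'
#' SSE count uniform on `sse_range`; types i.i.d. Bernoulli(`p_helix`);
#' contacts independent with the band probabilities (adjacent vs distant
#' pairs); angles uniform on `(-180, 180]` quantized to the codec step.
#' Uses the current R random number stream.
#'
#' @param params a `synth_params`.
#' @param id tableau id.
#' @param spec a `code_spec` (for the angle quantization step).
#' @return a `tableau`.
#' @export
random_tableau <- function(params, id = "t1", spec = code_spec()) {
  n <- params$sse_range[1] +
    sample.int(params$sse_range[2] - params$sse_range[1] + 1L, 1L) - 1L
  sse <- paste(ifelse(runif(n) < params$p_helix, "H", "E"), collapse = "")
  contacts <- matrix(FALSE, n, n)
  angles <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      p <- if (j - i == 1L) params$p_contact_adjacent else params$p_contact_far
      ct <- runif(1) < p
      contacts[i, j] <- contacts[j, i] <- ct
      ang <- quantize_angle(runif(1, -180, 180), spec$epsilon_deg)
      angles[i, j] <- angles[j, i] <- ang
    }
  }
  tableau(id, sse, contacts, angles)
}

#' Plant a motif into a tableau
#'
#' Overwrites a random consecutive span: SSE types and all within-span
#' contact cells are copied from the archetype; each archetype-contact angle
#' becomes the archetype angle plus von Mises(0, `kappa_true`) noise, wrapped
#' and quantized.  The planted span always passes the [match_cost()] validity
#' gate by construction.  Uses the current R random number stream.
#'
#' @param t a `tableau`.
#' @param motif a `fold_concept`.
#' @param kappa_true noise concentration.
#' @param spec a `code_spec`.
#' @return list with the modified `tableau` and the planted `span`.
#' @export
plant_motif <- function(t, motif, kappa_true, spec = code_spec()) {
  arch <- motif$archetype
  m <- tableau_size(arch)
  n <- tableau_size(t)
  if (m > n) stop("motif does not fit: ", m, " SSEs into ", n)
  start <- sample.int(n - m + 1L, 1L)
  idx <- start:(start + m - 1L)
  sse <- strsplit(t$sse_string, "")[[1]]
  sse[idx] <- strsplit(arch$sse_string, "")[[1]]
  contacts <- t$contacts
  angles <- t$angles
  for (p in seq_len(m - 1L)) {
    for (q in (p + 1L):m) {
      i <- idx[p]; j <- idx[q]
      contacts[i, j] <- contacts[j, i] <- arch$contacts[p, q]
      if (arch$contacts[p, q]) {
        noise <- rvonmises(1, 0, kappa_true) * 180 / pi
        ang <- quantize_angle(arch$angles[p, q] + noise, spec$epsilon_deg)
        angles[i, j] <- angles[j, i] <- ang
      }
    }
  }
  list(tableau = tableau(t$id, paste(sse, collapse = ""), contacts, angles),
       span = c(start, start + m - 1L))
}

#' Generate a benchmark collection with ground truth
#'
#' `round(plant_fraction * n_tableaux)` randomly chosen tableaux receive the
#' motif; the rest are pure noise.  Reproducible from `params$seed`.
#'
#' @param params a `synth_params`.
#' @param spec a `code_spec`.
#' @return list: `collection` (list of `tableau`) and `truth` (class
#'   `ground_truth`: per-tableau planted span or NA, the motif archetype,
#'   `kappa_true`).
#' @export
make_benchmark <- function(params = synth_params(), spec = code_spec()) {
  set.seed(params$seed)
  n <- params$n_tableaux
  ids <- sprintf("synth_%03d", seq_len(n))
  n_plant <- if (is.null(params$motif)) 0L else round(params$plant_fraction * n)
  planted <- if (n_plant > 0L) sort(sample.int(n, n_plant)) else integer(0)
  collection <- vector("list", n)
  spans <- matrix(NA_integer_, n, 2)
  for (i in seq_len(n)) {
    t <- random_tableau(params, ids[i], spec)
    if (i %in% planted) {
      pl <- plant_motif(t, params$motif, params$kappa_true, spec)
      t <- pl$tableau
      spans[i, ] <- pl$span
    }
    collection[[i]] <- t
  }
  truth <- structure(list(spans = data.frame(id = ids, start = spans[, 1],
                                             end = spans[, 2]),
                          motif = params$motif,
                          kappa_true = params$kappa_true),
                     class = "ground_truth")
  list(collection = collection, truth = truth)
}

# circular mean absolute deviation between two angle sets, degrees
mean_abs_wrapped <- function(a, b) mean(abs(wrap_angle(a - b)))

#' Score motif recovery of an inferred dictionary
#'
#' The motif counts as recovered when some concept has the planted motif's
#' SSE string and contact matrix and its archetype angles deviate from the
#' planted archetype by less than `angle_tol_deg` on (circular) average over
#' the archetype-contact pairs.  Also reports the usage overlap: the fraction
#' of planted spans that the best-matching concept's usages reproduce exactly
#' when the collection is dissected with the inferred dictionary.
#'
#' @param inferred a `fold_dictionary`.
#' @param truth the `ground_truth` from [make_benchmark()].
#' @param angle_tol_deg tolerance on the mean absolute wrapped deviation.
#' @param collection optional: the benchmark collection, enabling the usage
#'   overlap report.
#' @return list: `motif_recovered`, `best_concept` (id or NA),
#'   `mean_abs_dev_deg`, `usage_overlap`.
#' @export
recovery_score <- function(inferred, truth, angle_tol_deg = 25,
                           collection = NULL) {
  arch <- truth$motif$archetype
  mask <- arch$contacts & upper.tri(arch$contacts)
  best_id <- NA_character_; best_dev <- Inf
  for (cc in inferred$concepts) {
    a <- cc$archetype
    if (a$sse_string != arch$sse_string) next
    if (!identical(a$contacts, arch$contacts)) next
    dev <- mean_abs_wrapped(a$angles[mask], arch$angles[mask])
    if (dev < best_dev) { best_dev <- dev; best_id <- cc$id }
  }
  recovered <- !is.na(best_id) && best_dev < angle_tol_deg
  overlap <- NA_real_
  if (recovered && !is.null(collection)) {
    planted <- truth$spans[!is.na(truth$spans$start), , drop = FALSE]
    if (nrow(planted) > 0L) {
      hit <- 0L
      for (r in seq_len(nrow(planted))) {
        t <- collection[[match(planted$id[r],
                               vapply(collection, `[[`, character(1), "id"))]]
        d <- dissect(t, inferred)
        ok <- any(d$regions$concept_id == best_id &
                    d$regions$start == planted$start[r] &
                    d$regions$end == planted$end[r])
        if (ok) hit <- hit + 1L
      }
      overlap <- hit / nrow(planted)
    }
  }
  list(motif_recovered = recovered, best_concept = best_id,
       mean_abs_dev_deg = if (is.finite(best_dev)) best_dev else NA_real_,
       usage_overlap = overlap)
}
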