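#' Annealing schedule parameters
#'
#' @param t0 initial temperature in bits.
#' @param alpha geometric cooling factor in (0, 1).
#' @param iters_per_temp proposals evaluated per temperature level.
#' @param t_min final temperature in bits.
#' @param stall_limit consecutive temperature levels with no accepted proposal
#'   before the search stops early.
#' @param seed integer RNG seed; the whole search trajectory is deterministic
#'   given the seed.
#' @return object of class `anneal_params`.
#' @export
anneal_params <- function(t0 = 1000, alpha = 0.95, iters_per_temp = 200,
                          t_min = 0.1, stall_limit = 20, seed = 1) {
  stopifnot(alpha > 0, alpha < 1, t0 > t_min, t_min > 0,
            iters_per_temp >= 1, stall_limit >= 1)
  structure(list(t0 = t0, alpha = alpha, iters_per_temp = iters_per_temp,
                 t_min = t_min, stall_limit = stall_limit,
                 seed = as.integer(seed)),
            class = "anneal_params")
}

# ---- internal search state --------------------------------------------------
# During the search a concept is a plain list:
#   src (collection index), start, end, kidx (kappa grid index),
#   packed (for the C++ core), null_len (statement cost of the archetype)
# so that proposals touch no S3 machinery in the hot loop.

search_concept <- function(collection, src, start, end, kidx, spec,
                           sse_ints) {
  m <- end - start + 1L
  if (m < 2L) return(NULL)
  t <- collection[[src]]
  idx <- start:end
  ct <- t$contacts[idx, idx, drop = FALSE]
  if (!is_connected(ct)) return(NULL)
  sse <- sse_ints[[src]][idx]
  n1_cells <- sum(ct[upper.tri(ct)])
  n_cells <- m * (m - 1L) / 2L
  null_len <- universal_int_len(m + 1) +
    kt_total(sum(sse == 0L), sum(sse == 1L)) +
    kt_total(n_cells - n1_cells, n1_cells) +
    n1_cells * uniform_angle_len(spec)
  kappa <- spec$kappa_grid[kidx]
  list(src = src, start = start, end = end, kidx = kidx,
       packed = list(n = m, sse = sse, contact = ct,
                     angle = t$angles[idx, idx, drop = FALSE],
                     kappa = kappa, const_bits = vm_const_bits(kappa, spec)),
       null_len = null_len)
}

state_total <- function(state, xcol, spec, fb) {
  k <- length(state)
  dict_bits <- universal_int_len(k + 1) +
    k * log2(length(spec$kappa_grid))
  for (sc in state) dict_bits <- dict_bits + sc$null_len
  dict_bits + cpp_collection_total(xcol, lapply(state, `[[`, "packed"),
                                   log2(k + 1), uniform_angle_len(spec),
                                   fb[[1L]], fb[[2L]])
}

# one perturbation draw; NULL when the drawn primitive produced an invalid
# or no-op candidate (caller redraws)
propose_once <- function(state, collection, env, spec) {
  grid_len <- length(spec$kappa_grid)
  n_applicable <- if (length(state) > 0L) 5L else 1L
  prim <- sample.int(n_applicable, 1L)
  kmed <- ceiling(grid_len / 2)
  if (prim == 1L) { # add
    src <- sample.int(length(collection), 1L)
    n <- env$sizes[src]
    if (n < 2L) return(NULL)
    start <- sample.int(n - 1L, 1L)
    end <- start + sample.int(n - start, 1L)
    cand <- search_concept(collection, src, start, end, kmed, spec, env$sse_ints)
    if (is.null(cand)) return(NULL)
    c(state, list(cand))
  } else if (prim == 2L) { # remove
    state[-sample.int(length(state), 1L)]
  } else if (prim == 3L) { # perturb length by one SSE w.r.t. the source
    i <- sample.int(length(state), 1L)
    sc <- state[[i]]
    n_src <- env$sizes[sc$src]
    moves <- list(c(sc$start - 1L, sc$end), c(sc$start + 1L, sc$end),
                  c(sc$start, sc$end - 1L), c(sc$start, sc$end + 1L))
    ok <- vapply(moves, function(m) {
      m[1] >= 1L && m[2] <= n_src && m[2] - m[1] + 1L >= 2L
    }, logical(1))
    if (!any(ok)) return(NULL)
    m <- moves[ok][[sample.int(sum(ok), 1L)]]
    cand <- search_concept(collection, sc$src, m[1], m[2], sc$kidx, spec,
                           env$sse_ints)
    if (is.null(cand)) return(NULL)
    state[[i]] <- cand
    state
  } else if (prim == 4L) { # perturb kappa on the grid
    i <- sample.int(length(state), 1L)
    sc <- state[[i]]
    step <- sample(c(-2L, -1L, 1L, 2L), 1L)
    kidx <- min(max(sc$kidx + step, 1L), grid_len)
    if (kidx == sc$kidx) return(NULL)
    state[[i]] <- search_concept(collection, sc$src, sc$start, sc$end, kidx,
                                 spec, env$sse_ints)
    state
  } else { # swap concept with a region currently encoded by it
    i <- sample.int(length(state), 1L)
    usages <- cpp_collection_usages(env$xcol, lapply(state, `[[`, "packed"),
                                    log2(length(state) + 1),
                                    uniform_angle_len(spec),
                                    env$fb[[1L]], env$fb[[2L]], i)
    if (nrow(usages) == 0L) return(NULL)
    u <- usages[sample.int(nrow(usages), 1L), ]
    cand <- search_concept(collection, u[1L], u[2L], u[3L],
                           state[[i]]$kidx, spec, env$sse_ints)
    if (is.null(cand)) return(NULL)
    state[[i]] <- cand
    state
  }
}

propose_valid <- function(state, collection, env, spec, max_tries = 50L) {
  for (k in seq_len(max_tries)) {
    cand <- propose_once(state, collection, env, spec)
    if (!is.null(cand)) return(cand)
  }
  # force an Add (always applicable on a collection with any n >= 2 tableau)
  repeat {
    src <- sample.int(length(collection), 1L)
    n <- env$sizes[src]
    if (n < 2L) next
    start <- sample.int(n - 1L, 1L)
    end <- start + sample.int(n - start, 1L)
    cand <- search_concept(collection, src, start, end,
                           ceiling(length(spec$kappa_grid) / 2), spec,
                           env$sse_ints)
    if (!is.null(cand)) return(c(state, list(cand)))
  }
}

# shared precomputed context for the search
search_env <- function(collection, spec) {
  env <- new.env(parent = emptyenv())
  env$sizes <- vapply(collection, tableau_size, integer(1))
  env$sse_ints <- lapply(collection, function(t) sse_as_int(t$sse_string))
  env$xcol <- cpp_pack_collection(lapply(collection, pack_tableau, spec = spec))
  fb <- flip_bits(spec)
  env$fb <- c(fb[["match"]], fb[["mismatch"]])
  env
}

#' Draw one perturbation of a dictionary
#'
#' One of five primitives, chosen uniformly among those applicable: add a
#' random connected subtableau from the collection as a concept; remove a
#' concept; extend/shorten a concept by one SSE with reference to its source;
#' perturb a concept's kappa on the grid; or swap a concept with a region the
#' current dissections encode by it.  Invalid draws (disconnected candidate,
#' no-op) are redrawn up to 50 times, after which an Add is forced.  Uses the
#' current R random number stream.
#'
#' @param C a `fold_dictionary` whose concepts carry provenance into
#'   `collection`.
#' @param collection list of `tableau` objects (the source collection).
#' @return a perturbed `fold_dictionary`.
#' @export
propose <- function(C, collection) {
  spec <- C$spec
  ids <- vapply(collection, `[[`, character(1), "id")
  env <- search_env(collection, spec)
  state <- lapply(C$concepts, function(cc) {
    src <- match(cc$provenance$source, ids)
    if (is.na(src)) stop("concept ", cc$id, " has no provenance in the collection")
    search_concept(collection, src, cc$provenance$start, cc$provenance$end,
                   which.min(abs(spec$kappa_grid - cc$kappa)), spec,
                   env$sse_ints)
  })
  cand <- propose_valid(state, collection, env, spec)
  state_to_dictionary(cand, collection, spec)
}

state_to_dictionary <- function(state, collection, spec) {
  concepts <- lapply(seq_along(state), function(i) {
    sc <- state[[i]]
    t <- collection[[sc$src]]
    extract <- subtableau(t, c(sc$start, sc$end))
    concept(sprintf("c_%04d", i), extract, spec$kappa_grid[sc$kidx],
            provenance = list(source = t$id, start = sc$start, end = sc$end))
  })
  finalize_ids(new_dictionary(concepts, spec))
}

#' Infer a concept dictionary by simulated annealing
#'
#' Starting from the empty dictionary, repeatedly perturbs the current
#' dictionary (see [propose()]) and accepts a candidate with the Metropolis
#' rule on the change in total two-part message length: always when the
#' length decreases, otherwise with probability `2^(-delta / Temp)` (lengths
#' are in bits, hence base 2).  The temperature cools geometrically from
#' `t0` by `alpha` per level down to `t_min`, stopping early after
#' `stall_limit` levels without an acceptance.  The best-seen dictionary is
#' subjected to the MML null-hypothesis test: if its two-part length is not
#' shorter than the null encoding of the collection, the empty dictionary is
#' returned.
#'
#' @param collection non-empty list of `tableau` objects.
#' @param params an `anneal_params`.
#' @param spec a `code_spec`.
#' @return a `fold_dictionary` with attributes `trace` (per-temperature log:
#'   temperature, current/best bits, dictionary size), `null_bits`,
#'   `best_bits` and `gain` (`null_bits` minus the best two-part length,
#'   never negative for a non-empty result).
#' @export
anneal <- function(collection, params = anneal_params(), spec = code_spec()) {
  stopifnot(length(collection) > 0L)
  set.seed(params$seed)
  env <- search_env(collection, spec)
  null_bits <- sum(vapply(collection, function(t) null_tableau_len(t, spec)$bits,
                          numeric(1)))
  state <- list()
  cur <- state_total(state, env$xcol, spec, env$fb)
  best_state <- state; best <- cur
  temp <- params$t0
  stall <- 0L
  trace <- list()
  while (temp >= params$t_min && stall < params$stall_limit) {
    accepted <- FALSE
    for (it in seq_len(params$iters_per_temp)) {
      cand <- propose_valid(state, collection, env, spec)
      cand_total <- state_total(cand, env$xcol, spec, env$fb)
      delta <- cand_total - cur
      if (delta < 0 || runif(1) < 2^(-delta / temp)) {
        state <- cand; cur <- cand_total; accepted <- TRUE
        if (cur < best) { best_state <- state; best <- cur }
      }
    }
    stall <- if (accepted) 0L else stall + 1L
    trace[[length(trace) + 1L]] <- data.frame(
      temperature = temp, current_bits = cur, best_bits = best,
      n_concepts = length(state))
    temp <- temp * params$alpha
  }
  # MML null-hypothesis test: accept the dictionary only if it beats the
  # independent (null) statement of the collection
  if (best >= null_bits) {
    best_state <- list()
    best <- state_total(list(), env$xcol, spec, env$fb)
  }
  out <- state_to_dictionary(best_state, collection, spec)
  attr(out, "trace") <- do.call(rbind, trace)
  attr(out, "null_bits") <- null_bits
  attr(out, "best_bits") <- best
  attr(out, "gain") <- null_bits - best
  out
}

#' Compression gained by a dictionary over the null model
#'
#' The null encoding length of the collection minus the total two-part length
#' under `C`; may be negative (an empty dictionary costs one bit of
#' overhead).
#'
#' @param collection list of `tableau` objects.
#' @param C a `fold_dictionary`.
#' @return gain in bits.
#' @export
compression_gain <- function(collection, C) {
  null_bits <- sum(vapply(collection,
                          function(t) null_tableau_len(t, C$spec)$bits,
                          numeric(1)))
  null_bits - total_collection_len(collection, C)$bits
}
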