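# ---- bit-level codec: a working arithmetic coder ---------------------------
# Proves the message-length accounting is honest: every tableau can actually
# be transmitted in (about) the number of bits the analytic formulas report
# and recovered exactly (SSE string and contacts bit-exact, angles to within
# half the quantization step).
#
# Conditional probabilities are quantized to integer frequencies summing to
# 2^20 (identical on both sides, so losslessness is unaffected); with a
# 32-bit coder the products stay within exact double-precision integers.

AC_BITS <- 2^32
AC_HALF <- 2^31
AC_QUARTER <- 2^30
AC_FREQ_TOTAL <- 2^20

# Elias gamma codeword of a positive integer, as a 0/1 vector
gamma_encode <- function(n) {
  stopifnot(n >= 1)
  nb <- floor(log2(n) + 1e-12) + 1
  code <- as.integer(intToBits(n))[seq_len(nb)]  # little-endian
  c(rep(0L, nb - 1L), rev(code))
}

gamma_decode <- function(bits, pos) {
  z <- 0L
  while (pos <= length(bits) && bits[pos] == 0L) { z <- z + 1L; pos <- pos + 1L }
  if (pos + z > length(bits) + 1L || pos > length(bits)) {
    stop("decode error: truncated gamma code")
  }
  val <- 0
  for (k in 0:z) {
    if (pos > length(bits)) stop("decode error: truncated gamma code")
    val <- val * 2 + bits[pos]
    pos <- pos + 1L
  }
  list(value = val, pos = pos)
}

quantize_freqs <- function(p) {
  f <- pmax(1, round(p * AC_FREQ_TOTAL))
  f[which.max(f)] <- f[which.max(f)] + (AC_FREQ_TOTAL - sum(f))
  stopifnot(all(f >= 1))
  f
}

kt_freqs <- function(counts) {
  quantize_freqs((counts + 0.5) / sum(counts + 0.5))
}

uniform_freqs <- function(m) {
  base <- AC_FREQ_TOTAL %/% m
  f <- rep(base, m)
  rem <- AC_FREQ_TOTAL - base * m
  if (rem > 0) f[seq_len(rem)] <- f[seq_len(rem)] + 1
  f
}

vm_freqs <- function(kappa, spec) {
  m <- round(360 / spec$epsilon_deg)
  centers <- (-180 + (seq_len(m) - 0.5) * spec$epsilon_deg) * pi / 180
  w <- exp(kappa * (cos(centers) - 1))
  quantize_freqs(w / sum(w))
}

angle_bin <- function(a, epsilon_deg) {
  a <- wrap_angle(a)
  b <- ceiling((a + 180) / epsilon_deg)
  max(1L, min(as.integer(b), as.integer(round(360 / epsilon_deg))))
}

bin_center <- function(b, epsilon_deg) -180 + (b - 0.5) * epsilon_deg

# -- encoder ------------------------------------------------------------------

ac_new_encoder <- function() {
  env <- new.env(parent = emptyenv())
  env$low <- 0; env$high <- AC_BITS - 1; env$pending <- 0L
  env$bits <- integer(0)
  env
}

ac_emit <- function(env, b) {
  env$bits <- c(env$bits, b)
  if (env$pending > 0L) {
    env$bits <- c(env$bits, rep(1L - b, env$pending))
    env$pending <- 0L
  }
}

ac_encode_sym <- function(env, freqs, sym) {
  cum <- c(0, cumsum(freqs))
  range <- env$high - env$low + 1
  env$high <- env$low + floor(range * cum[sym + 1L] / AC_FREQ_TOTAL) - 1
  env$low <- env$low + floor(range * cum[sym] / AC_FREQ_TOTAL)
  repeat {
    if (env$high < AC_HALF) {
      ac_emit(env, 0L)
    } else if (env$low >= AC_HALF) {
      ac_emit(env, 1L)
      env$low <- env$low - AC_HALF; env$high <- env$high - AC_HALF
    } else if (env$low >= AC_QUARTER && env$high < 3 * AC_QUARTER) {
      env$pending <- env$pending + 1L
      env$low <- env$low - AC_QUARTER; env$high <- env$high - AC_QUARTER
    } else break
    env$low <- env$low * 2
    env$high <- env$high * 2 + 1
  }
}

ac_finish <- function(env) {
  env$pending <- env$pending + 1L
  ac_emit(env, if (env$low < AC_QUARTER) 0L else 1L)
  env$bits
}

# -- decoder ------------------------------------------------------------------

ac_new_decoder <- function(bits, pos) {
  env <- new.env(parent = emptyenv())
  env$low <- 0; env$high <- AC_BITS - 1
  env$bits <- bits; env$pos <- pos
  env$consumed_pad <- 0L
  value <- 0
  for (k in 1:32) value <- value * 2 + ac_next_bit(env)
  env$value <- value
  env
}

ac_next_bit <- function(env) {
  if (env$pos <= length(env$bits)) {
    b <- env$bits[env$pos]
    env$pos <- env$pos + 1L
    b
  } else {
    env$consumed_pad <- env$consumed_pad + 1L
    if (env$consumed_pad > 32L) stop("decode error: truncated bit stream")
    0L
  }
}

ac_decode_sym <- function(env, freqs) {
  cum <- c(0, cumsum(freqs))
  range <- env$high - env$low + 1
  target <- floor(((env$value - env$low + 1) * AC_FREQ_TOTAL - 1) / range)
  sym <- findInterval(target, cum, rightmost.closed = FALSE)
  sym <- max(1L, min(sym, length(freqs)))
  env$high <- env$low + floor(range * cum[sym + 1L] / AC_FREQ_TOTAL) - 1
  env$low <- env$low + floor(range * cum[sym] / AC_FREQ_TOTAL)
  repeat {
    if (env$high < AC_HALF) {
      # nothing
    } else if (env$low >= AC_HALF) {
      env$low <- env$low - AC_HALF; env$high <- env$high - AC_HALF
      env$value <- env$value - AC_HALF
    } else if (env$low >= AC_QUARTER && env$high < 3 * AC_QUARTER) {
      env$low <- env$low - AC_QUARTER; env$high <- env$high - AC_QUARTER
      env$value <- env$value - AC_QUARTER
    } else break
    env$low <- env$low * 2
    env$high <- env$high * 2 + 1
    env$value <- env$value * 2 + ac_next_bit(env)
  }
  sym
}

# -- dissection-driven tableau codec ------------------------------------------

validate_dissection <- function(t, C, d) {
  n <- tableau_size(t)
  regs <- d$regions
  if (nrow(regs) > 0L) regs <- regs[order(regs$start), , drop = FALSE]
  covered <- integer(0)
  ids <- vapply(C$concepts, `[[`, character(1), "id")
  for (r in seq_len(nrow(regs))) {
    covered <- c(covered, regs$start[r]:regs$end[r])
    cid <- regs$concept_id[r]
    if (cid == "c_0000") {
      if (regs$end[r] != regs$start[r]) stop("invalid dissection: null region spans > 1 SSE")
    } else {
      ci <- match(cid, ids)
      if (is.na(ci)) stop("invalid dissection: unknown concept ", cid)
      mc <- match_cost(t, c(regs$start[r], regs$end[r]), C$concepts[[ci]], C$spec)
      if (is.na(mc)) stop("invalid dissection: region ", r, " fails the validity gate")
    }
  }
  if (!identical(covered, seq_len(n)) && !(n == 0L && length(covered) == 0L)) {
    stop("invalid dissection: regions do not tile 1..n")
  }
  regs
}

#' Encode a tableau as a bit string under a dictionary and dissection
#'
#' Transmits, in one arithmetic-coded stream after an Elias gamma code of the
#' SSE count: the region labels; the SSE symbols of null regions (concept
#' regions imply theirs); every contact cell (flip model inside concept
#' regions, adaptive KT elsewhere); and the angles of contacting pairs (von
#' Mises around the archetype inside concept regions, uniform elsewhere),
#' quantized at `spec$epsilon_deg`.  The adaptive models condition on all
#' previously transmitted or implied symbols, mirroring the analytic message
#' lengths.
#'
#' @param t a `tableau`.
#' @param C a `fold_dictionary`.
#' @param d a valid `dissection` of `t` against `C` (e.g. from [dissect()]).
#' @return integer 0/1 vector; its length is within the arithmetic coder's
#'   ~2-bit overhead of `d$total_bits$bits`.
#' @export
encode_tableau <- function(t, C, d) {
  spec <- C$spec
  regs <- validate_dissection(t, C, d)
  n <- tableau_size(t)
  ids <- vapply(C$concepts, `[[`, character(1), "id")
  K <- length(ids)
  enc <- ac_new_encoder()
  sse <- sse_as_int(t$sse_string)
  sse_counts <- c(0, 0)
  cover <- integer(n)
  # labels + SSE symbols, left to right
  for (r in seq_len(nrow(regs))) {
    cid <- regs$concept_id[r]
    lab <- if (cid == "c_0000") 1L else match(cid, ids) + 1L
    ac_encode_sym(enc, uniform_freqs(K + 1L), lab)
    if (cid == "c_0000") {
      j <- regs$start[r]
      ac_encode_sym(enc, kt_freqs(sse_counts), sse[j] + 1L)
      sse_counts[sse[j] + 1L] <- sse_counts[sse[j] + 1L] + 1
    } else {
      for (j in regs$start[r]:regs$end[r]) {
        sse_counts[sse[j] + 1L] <- sse_counts[sse[j] + 1L] + 1
      }
      cover[regs$start[r]:regs$end[r]] <- r
    }
  }
  # contact cells, row-major upper triangle
  cell_counts <- c(0, 0)
  fp <- spec$flip_prob
  flipf <- quantize_freqs(c(1 - fp, fp))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        s <- as.integer(t$contacts[i, j])
        inside <- cover[i] != 0L && cover[i] == cover[j]
        if (inside) {
          r <- cover[i]
          cc <- C$concepts[[match(regs$concept_id[r], ids)]]
          ac_ <- cc$archetype$contacts[i - regs$start[r] + 1L,
                                       j - regs$start[r] + 1L]
          ac_encode_sym(enc, flipf, (if (s == as.integer(ac_)) 1L else 2L))
        } else {
          ac_encode_sym(enc, kt_freqs(cell_counts), s + 1L)
        }
        cell_counts[s + 1L] <- cell_counts[s + 1L] + 1
      }
    }
    # angles of contacting pairs, row-major
    m <- round(360 / spec$epsilon_deg)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (!t$contacts[i, j]) next
        inside <- cover[i] != 0L && cover[i] == cover[j]
        if (inside) {
          r <- cover[i]
          cc <- C$concepts[[match(regs$concept_id[r], ids)]]
          p <- i - regs$start[r] + 1L; q <- j - regs$start[r] + 1L
          if (cc$archetype$contacts[p, q]) {
            delta <- t$angles[i, j] - cc$archetype$angles[p, q]
            ac_encode_sym(enc, vm_freqs(cc$kappa, spec),
                          angle_bin(delta, spec$epsilon_deg))
            next
          }
        }
        ac_encode_sym(enc, uniform_freqs(m), angle_bin(t$angles[i, j],
                                                       spec$epsilon_deg))
      }
    }
  }
  c(gamma_encode(n + 1), ac_finish(enc))
}

#' Decode a tableau bit string
#'
#' Inverse of [encode_tableau()] under the same dictionary and codec
#' settings.  The SSE string and contact matrix are recovered exactly; coded
#' angles are recovered as bin centers, within half the quantization step of
#' the originals.  Angles of non-contacting pairs are not transmitted and
#' decode as 0.
#'
#' @param bits integer 0/1 vector from [encode_tableau()].
#' @param C the `fold_dictionary` used to encode.
#' @param id id for the decoded tableau.
#' @return a `tableau`; attribute `regions` holds the decoded dissection
#'   regions.
#' @export
decode_tableau <- function(bits, C, id = "decoded") {
  spec <- C$spec
  g <- gamma_decode(bits, 1L)
  n <- as.integer(g$value - 1)
  ids <- vapply(C$concepts, `[[`, character(1), "id")
  K <- length(ids)
  if (n == 0L) return(tableau(id, ""))
  dec <- ac_new_decoder(bits, g$pos)
  sse <- integer(n)
  sse_counts <- c(0, 0)
  cover <- integer(n)
  regs <- data.frame(start = integer(), end = integer(),
                     concept_id = character())
  j <- 1L
  while (j <= n) {
    lab <- ac_decode_sym(dec, uniform_freqs(K + 1L))
    if (lab == 1L) {
      s <- ac_decode_sym(dec, kt_freqs(sse_counts)) - 1L
      sse[j] <- s
      sse_counts[s + 1L] <- sse_counts[s + 1L] + 1
      regs <- rbind(regs, data.frame(start = j, end = j, concept_id = "c_0000"))
      j <- j + 1L
    } else {
      cc <- C$concepts[[lab - 1L]]
      m_c <- tableau_size(cc$archetype)
      if (j + m_c - 1L > n) stop("decode error: concept region overruns tableau")
      asse <- sse_as_int(cc$archetype$sse_string)
      sse[j:(j + m_c - 1L)] <- asse
      for (s in asse) sse_counts[s + 1L] <- sse_counts[s + 1L] + 1
      regs <- rbind(regs, data.frame(start = j, end = j + m_c - 1L,
                                     concept_id = ids[lab - 1L]))
      cover[j:(j + m_c - 1L)] <- nrow(regs)
      j <- j + m_c
    }
  }
  contacts <- matrix(FALSE, n, n)
  cell_counts <- c(0, 0)
  fp <- spec$flip_prob
  flipf <- quantize_freqs(c(1 - fp, fp))
  for (i in seq_len(n - 1L)) {
    for (jj in (i + 1L):n) {
      inside <- cover[i] != 0L && cover[i] == cover[jj]
      if (inside) {
        r <- cover[i]
        cc <- C$concepts[[match(regs$concept_id[r], ids)]]
        ac_ <- cc$archetype$contacts[i - regs$start[r] + 1L,
                                     jj - regs$start[r] + 1L]
        sym <- ac_decode_sym(dec, flipf)
        s <- if (sym == 1L) as.integer(ac_) else 1L - as.integer(ac_)
      } else {
        s <- ac_decode_sym(dec, kt_freqs(cell_counts)) - 1L
      }
      contacts[i, jj] <- contacts[jj, i] <- s == 1L
      cell_counts[s + 1L] <- cell_counts[s + 1L] + 1
    }
  }
  angles <- matrix(0, n, n)
  m <- round(360 / spec$epsilon_deg)
  for (i in seq_len(n - 1L)) {
    for (jj in (i + 1L):n) {
      if (!contacts[i, jj]) next
      inside <- cover[i] != 0L && cover[i] == cover[jj]
      done <- FALSE
      if (inside) {
        r <- cover[i]
        cc <- C$concepts[[match(regs$concept_id[r], ids)]]
        p <- i - regs$start[r] + 1L; q <- jj - regs$start[r] + 1L
        if (cc$archetype$contacts[p, q]) {
          b <- ac_decode_sym(dec, vm_freqs(cc$kappa, spec))
          ang <- wrap_angle(cc$archetype$angles[p, q] +
                              bin_center(b, spec$epsilon_deg))
          done <- TRUE
        }
      }
      if (!done) {
        b <- ac_decode_sym(dec, uniform_freqs(m))
        ang <- bin_center(b, spec$epsilon_deg)
      }
      angles[i, jj] <- angles[jj, i] <- ang
    }
  }
  sse_string <- paste(c("H", "E")[sse + 1L], collapse = "")
  out <- tableau(id, sse_string, contacts, angles)
  attr(out, "regions") <- regs
  out
}
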