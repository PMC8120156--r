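test_that("match_cost gates on SSE string and archetype contacts", {
  spec <- fx_spec
  motif <- default_motif(spec)
  arch <- motif$archetype
  # a tableau that contains the archetype verbatim costs less than null coding
  # of the same cells (peaked density beats uniform at zero deviation)
  t <- arch; t$id <- "copy"
  big_kappa <- spec$kappa_grid[50]
  motif$kappa <- big_kappa
  mc <- match_cost(t, c(1, 4), motif, spec)
  n_contacts <- sum(arch$contacts[upper.tri(arch$contacts)])
  null_angles <- n_contacts * uniform_angle_len(spec)
  expect_lt(mc, null_angles)
  # removing an archetype contact invalidates the match
  t2 <- t
  t2$contacts[1, 2] <- t2$contacts[2, 1] <- FALSE
  expect_true(is.na(match_cost(t2, c(1, 4), motif, spec)))
  # SSE mismatch invalidates
  t3 <- t; t3$sse_string <- "HHHE"
  expect_true(is.na(match_cost(t3, c(1, 4), motif, spec)))
})

test_that("match_cost equals a straight-line recomputation on random cases", {
  set.seed(61)
  spec <- fx_spec
  straight <- function(t, span, cc) {
    idx <- span[1]:span[2]
    arch <- cc$archetype
    m <- length(idx)
    if (substr(t$sse_string, span[1], span[2]) != arch$sse_string) return(NA_real_)
    total <- 0
    for (p in 1:(m - 1)) for (q in (p + 1):m) {
      tc <- t$contacts[idx[p], idx[q]]; ac <- arch$contacts[p, q]
      if (ac && !tc) return(NA_real_)
      total <- total + (if (tc == ac) -log2(1 - spec$flip_prob)
                        else -log2(spec$flip_prob))
      if (tc) {
        if (ac) {
          d <- wrap_angle(t$angles[idx[p], idx[q]] - arch$angles[p, q]) * pi / 180
          dens <- exp(cc$kappa * cos(d)) /
            (2 * pi * besselI(cc$kappa, 0, expon.scaled = TRUE) * exp(cc$kappa))
          total <- total + max(0, -log2(dens * pi / 180))
        } else total <- total + log2(360)
      }
    }
    total
  }
  checked <- 0L
  for (i in 1:200) {
    t <- fx_random_tableau("mc", sample(3:7, 1))
    C <- fx_random_dictionary(1)
    if (length(C$concepts) == 0) next
    cc <- C$concepts[[1]]
    m <- tableau_size(cc$archetype)
    if (m > tableau_size(t)) next
    st <- sample(tableau_size(t) - m + 1L, 1)
    a <- match_cost(t, c(st, st + m - 1L), cc, spec)
    b <- straight(t, c(st, st + m - 1L), cc)
    expect_equal(a, b, tolerance = 1e-9)
    checked <- checked + 1L
  }
  expect_gt(checked, 100L)
})

test_that("empty dictionary yields the all-null dissection at the null length", {
  set.seed(62)
  C0 <- new_dictionary(list(), fx_spec)
  t <- fx_random_tableau("nulls", 5)
  d <- dissect(t, C0)
  expect_identical(unique(d$regions$concept_id), "c_0000")
  expect_equal(nrow(d$regions), 5L)
  expect_equal(d$total_bits$bits, null_tableau_len(t, fx_spec)$bits,
               tolerance = 1e-9)
  # n = 0 edge case
  d0 <- dissect(tableau("e", ""), C0)
  expect_equal(d0$total_bits$bits, universal_int_len(1))
  expect_equal(nrow(d0$regions), 0L)
})

test_that("a tableau that is a concept archetype dissects into that concept", {
  spec <- fx_spec
  motif <- default_motif(spec)
  motif$id <- "c_0001"
  C <- new_dictionary(list(motif), spec)
  t <- motif$archetype
  t$id <- "self"
  d <- dissect(t, C)
  expect_identical(d$regions$concept_id, "c_0001")
  expect_equal(nrow(d$regions), 1L)
  expect_lt(d$total_bits$bits, null_tableau_len(t, spec)$bits +
              log2(2))   # beats all-null even after the label cost
})

test_that("dissections tile the SSE range exactly", {
  set.seed(63)
  for (i in 1:15) {
    t <- fx_random_tableau("tile", sample(2:8, 1))
    C <- fx_random_dictionary(sample(0:3, 1))
    d <- dissect(t, C)
    covered <- unlist(Map(seq, d$regions$start, d$regions$end))
    expect_identical(sort(covered), seq_len(tableau_size(t)))
    # null regions span exactly one SSE; concept regions span the archetype
    ids <- vapply(C$concepts, `[[`, character(1), "id")
    for (r in seq_len(nrow(d$regions))) {
      w <- d$regions$end[r] - d$regions$start[r] + 1L
      if (d$regions$concept_id[r] == "c_0000") expect_equal(w, 1L)
      else expect_equal(w, tableau_size(
        C$concepts[[match(d$regions$concept_id[r], ids)]]$archetype))
    }
  }
})

test_that("total collection length is additive and gains behave", {
  set.seed(64)
  coll <- lapply(1:5, function(i) fx_random_tableau(sprintf("add%d", i), 4))
  C0 <- new_dictionary(list(), fx_spec)
  tot <- total_collection_len(coll, C0)
  nulls <- sum(vapply(coll, function(t) null_tableau_len(t, fx_spec)$bits,
                      numeric(1)))
  expect_equal(tot$bits, 1 + nulls, tolerance = 1e-9)
  expect_equal(compression_gain(coll, C0), -1, tolerance = 1e-9)
  # planted-motif fixture with the true concept supplied has positive gain
  bench <- make_benchmark(synth_params(n_tableaux = 20, seed = 64), fx_spec)
  motif <- default_motif(fx_spec)
  motif$id <- "c_0001"
  motif$kappa <- fx_spec$kappa_grid[44]
  C1 <- new_dictionary(list(motif), fx_spec)
  expect_gt(compression_gain(bench$collection, C1), 0)
})

test_that("brute force refuses oversized tableaux", {
  t <- fx_random_tableau("big", 13)
  expect_error(brute_force_dissect(t, new_dictionary(list(), fx_spec)),
               "n <= 12")
})

test_that("dissection reports render markup, JSON and FASTA consistently", {
  spec <- fx_spec
  motif <- default_motif(spec)
  motif$id <- "c_0001"
  C <- new_dictionary(list(motif), spec)
  set.seed(65)
  bench <- make_benchmark(synth_params(n_tableaux = 1, sse_range = c(6, 6),
                                       plant_fraction = 1, seed = 65), spec)
  t <- bench$collection[[1]]
  d <- dissect(t, C)
  n <- tableau_size(t)
  # invent a residue layout: SSE k covers residues 10k-5 .. 10k
  spans <- data.frame(start = 10 * seq_len(n) - 5, end = 10 * seq_len(n))
  seqlen <- max(spans$end)
  sequence <- paste(rep("ACDEFGHIKLMNPQRSTVWY", length.out = seqlen),
                    collapse = "")
  sequence <- paste(strsplit(sequence, "")[[1]][1:seqlen], collapse = "")
  rep_out <- write_dissection_report(d, sequence, spans)
  concept_rows <- which(d$regions$concept_id != "c_0000")
  expect_length(rep_out$fasta, 2L * length(concept_rows))
  for (k in seq_along(concept_rows)) {
    r <- concept_rows[k]
    hdr <- rep_out$fasta[2 * k - 1]
    expect_match(hdr, sprintf("^>%s\\|c_0001\\|%d-%d$", t$id,
                              spans$start[d$regions$start[r]],
                              spans$end[d$regions$end[r]]))
    body <- rep_out$fasta[2 * k]
    expect_equal(nchar(body),
                 spans$end[d$regions$end[r]] - spans$start[d$regions$start[r]] + 1L)
  }
  # JSON reload round trip
  parsed <- jsonlite::fromJSON(rep_out$json, simplifyVector = FALSE)
  expect_equal(parsed$tableau_id, t$id)
  expect_equal(length(parsed$regions), nrow(d$regions))
  expect_equal(parsed$total_bits, d$total_bits$bits, tolerance = 1e-9)
  # span/sequence mismatch errors
  bad <- spans; bad$end[n] <- seqlen + 50
  expect_error(write_dissection_report(d, sequence, bad), "inconsistent")
  # empty dissection gives an empty report
  d0 <- dissect(tableau("e", ""), C)
  r0 <- write_dissection_report(d0, "", data.frame(start = integer(),
                                                   end = integer()))
  expect_length(r0$fasta, 0L)
})
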