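test_that("contact probabilities hit their bands empirically", {
  spec <- fx_spec
  p0 <- synth_params(n_tableaux = 1, sse_range = c(6, 6),
                     p_contact_adjacent = 0, p_contact_far = 0, motif = NULL)
  p1 <- synth_params(n_tableaux = 1, sse_range = c(6, 6),
                     p_contact_adjacent = 1, p_contact_far = 1, motif = NULL)
  set.seed(91)
  t0 <- random_tableau(p0, "none", spec)
  expect_false(any(t0$contacts))
  t1 <- random_tableau(p1, "full", spec)
  expect_true(all(t1$contacts[upper.tri(t1$contacts)]))
  # adjacent-contact frequency within 3 standard errors over many draws
  pa <- 0.62
  pmix <- synth_params(n_tableaux = 1, sse_range = c(5, 5),
                       p_contact_adjacent = pa, p_contact_far = 0.1,
                       motif = NULL)
  set.seed(92)
  hits <- 0L; trials <- 0L
  for (i in 1:500) {
    t <- random_tableau(pmix, "m", spec)
    adj <- vapply(1:4, function(k) t$contacts[k, k + 1], logical(1))
    hits <- hits + sum(adj); trials <- trials + 4L
  }
  se <- sqrt(pa * (1 - pa) / trials)
  expect_lt(abs(hits / trials - pa), 3 * se)
})

test_that("planted spans always satisfy the match validity gate", {
  spec <- fx_spec
  motif <- default_motif(spec)
  set.seed(93)
  p <- synth_params(motif = motif)
  for (i in 1:50) {
    t <- random_tableau(p, "pl", spec)
    pl <- plant_motif(t, motif, kappa_true = 50, spec)
    expect_false(is.na(match_cost(pl$tableau, pl$span, motif, spec)))
  }
  # motif too large errors
  small <- random_tableau(synth_params(n_tableaux = 1, sse_range = c(2, 2),
                                       motif = NULL), "small", spec)
  expect_error(plant_motif(small, motif, 50, spec), "does not fit")
})

test_that("planting noise is centered and vanishes at huge concentration", {
  spec <- fx_spec
  motif <- default_motif(spec)
  mask <- motif$archetype$contacts & upper.tri(motif$archetype$contacts)
  # circular mean of deviations within 3 standard errors of zero
  set.seed(94)
  kappa_true <- 50
  devs <- c()
  for (i in 1:125) {
    t <- random_tableau(synth_params(motif = motif), "c", spec)
    pl <- plant_motif(t, motif, kappa_true, spec)
    idx <- pl$span[1]:pl$span[2]
    devs <- c(devs, wrap_angle(pl$tableau$angles[idx, idx][mask] -
                                 motif$archetype$angles[mask]))
  }
  circ_sd <- 180 / pi / sqrt(kappa_true)
  se <- circ_sd / sqrt(length(devs))
  expect_lt(abs(mean(devs)), 3 * se + spec$epsilon_deg / 2)
  # near-infinite concentration reproduces the archetype up to quantization
  t <- random_tableau(synth_params(motif = motif), "z", spec)
  pl <- plant_motif(t, motif, 1e6, spec)
  idx <- pl$span[1]:pl$span[2]
  expect_lte(max(abs(wrap_angle(pl$tableau$angles[idx, idx][mask] -
                                  motif$archetype$angles[mask]))),
             spec$epsilon_deg)
})

test_that("benchmarks are seed-reproducible with the right plant count", {
  spec <- fx_spec
  p <- synth_params(n_tableaux = 12, plant_fraction = 0.5, seed = 95)
  b1 <- make_benchmark(p, spec)
  b2 <- make_benchmark(p, spec)
  expect_identical(lapply(b1$collection, write_tableau),
                   lapply(b2$collection, write_tableau))
  expect_identical(b1$truth$spans, b2$truth$spans)
  expect_equal(sum(!is.na(b1$truth$spans$start)), round(0.5 * 12))
  # written and reloaded collection is identical at format precision
  dir <- tempfile()
  write_collection(b1$collection, dir)
  back <- read_collection(dir)
  expect_identical(lapply(back, write_tableau),
                   lapply(b1$collection, write_tableau))
})

test_that("recovery_score detects exact and perturbed recoveries", {
  spec <- fx_spec
  motif <- default_motif(spec)
  truth <- make_benchmark(synth_params(n_tableaux = 4, seed = 96), spec)$truth
  exact <- motif; exact$id <- "c_0001"
  C <- new_dictionary(list(exact), spec)
  rs <- recovery_score(C, truth)
  expect_true(rs$motif_recovered)
  expect_equal(rs$mean_abs_dev_deg, 0)
  expect_identical(rs$best_concept, "c_0001")
  # empty dictionary: not recovered
  rs0 <- recovery_score(new_dictionary(list(), spec), truth)
  expect_false(rs0$motif_recovered)
  # hand-computed deviation on a perturbed copy
  pert <- motif; pert$id <- "c_0001"
  mask <- motif$archetype$contacts & upper.tri(motif$archetype$contacts)
  shifts <- c(4, -6, 10, -2)
  ang <- pert$archetype$angles
  cells <- which(mask, arr.ind = TRUE)
  cells <- cells[order(cells[, 1], cells[, 2]), ]
  for (k in seq_len(nrow(cells))) {
    i <- cells[k, 1]; j <- cells[k, 2]
    ang[i, j] <- ang[j, i] <- wrap_angle(ang[i, j] + shifts[k])
  }
  pert$archetype$angles <- ang
  rs2 <- recovery_score(new_dictionary(list(pert), spec), truth)
  expect_true(rs2$motif_recovered)
  expect_equal(rs2$mean_abs_dev_deg, mean(abs(shifts)))
})

test_that("the von Mises sampler matches its target moments", {
  set.seed(97)
  kappa <- 20
  x <- rvonmises(4000, mu = 0.5, kappa = kappa)
  # circular mean near mu; mean resultant length near I1/I0
  mr <- atan2(mean(sin(x)), mean(cos(x)))
  expect_lt(abs(mr - 0.5), 0.05)
  R <- sqrt(mean(sin(x))^2 + mean(cos(x))^2)
  A <- besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
  expect_lt(abs(R - A), 0.02)
  # uniform limit
  u <- rvonmises(2000, 0, 0)
  expect_gt(suppressWarnings(ks.test(u, "punif", -pi, pi)$p.value), 1e-4)
})
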