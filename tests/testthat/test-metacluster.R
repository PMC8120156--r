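test_that("cosine similarity handles the degenerate and worked cases", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosine_similarity(c(1, 0, 0), c(0, 2, 0)), 0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 0)), 1 / sqrt(2))
  expect_equal(cosine_similarity(c(0, 0), c(0, 0)), 1)
  expect_equal(cosine_similarity(c(0, 0), c(1, 0)), 0)
  # symmetric and bounded on random count vectors
  set.seed(101)
  for (i in 1:50) {
    u <- rpois(6, 2); v <- rpois(6, 2)
    s <- cosine_similarity(u, v)
    expect_identical(s, cosine_similarity(v, u))
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("UPGMA reproduces the hand-computed four-leaf example", {
  # two leaves first
  s2 <- matrix(c(1, 0.6, 0.6, 1), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- upgma(s2)
  expect_equal(t2$heights, 0.2)
  expect_identical(to_newick(t2), "(A:0.2,B:0.2);")
  # d(AB)=0.2, d(CD)=0.4, all other pairs 0.8
  d <- matrix(0.8, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  d["A", "B"] <- d["B", "A"] <- 0.2
  d["C", "D"] <- d["D", "C"] <- 0.4
  tr <- upgma(1 - d)
  expect_equal(sort(tr$heights), c(0.1, 0.2, 0.4))
  cop <- cophenetic_upgma(tr)
  expect_equal(cop["A", "B"], 0.2)
  expect_equal(cop["C", "D"], 0.4)
  expect_equal(cop["A", "C"], 0.8)
  expect_error(upgma(matrix(c(1, 0.2, 0.6, 1), 2)), "symmetric")
})

test_that("UPGMA agrees with hclust average linkage on random matrices", {
  set.seed(102)
  for (rep in 1:50) {
    k <- sample(3:8, 1)
    d <- matrix(0, k, k)
    d[upper.tri(d)] <- runif(k * (k - 1) / 2, 0.05, 1)
    d <- d + t(d)
    rownames(d) <- colnames(d) <- paste0("L", seq_len(k))
    tr <- upgma(1 - d)
    hc <- hclust(as.dist(d), method = "average")
    expect_equal(sort(tr$heights), sort(hc$height / 2), tolerance = 1e-9)
    # full topology + heights via cophenetic distances
    expect_equal(cophenetic_upgma(tr)[rownames(d), rownames(d)],
                 as.matrix(cophenetic(hc))[rownames(d), rownames(d)],
                 tolerance = 1e-9)
  }
})

test_that("UPGMA trees are ultrametric and export valid Newick", {
  set.seed(103)
  k <- 6
  d <- matrix(0, k, k)
  d[upper.tri(d)] <- runif(k * (k - 1) / 2, 0.1, 1)
  d <- d + t(d)
  rownames(d) <- colnames(d) <- sprintf("c_%04d", 1:k)
  tr <- upgma(1 - d)
  expect_equal(max(tr$heights), tr$heights[length(tr$heights)])
  phy <- as_phylo(tr)
  depths <- ape::node.depth.edgelength(phy)[seq_len(k)]
  expect_equal(diff(range(depths)), 0, tolerance = 1e-12)
  # Newick round trip preserves topology (same cophenetic structure)
  phy2 <- ape::read.tree(text = to_newick(tr))
  expect_equal(sort(phy2$tip.label), sort(tr$labels))
  cop1 <- as.matrix(ape::cophenetic.phylo(phy))[tr$labels, tr$labels]
  cop2 <- as.matrix(ape::cophenetic.phylo(phy2))[tr$labels, tr$labels]
  expect_equal(cop1, cop2, tolerance = 1e-9)
  # single leaf
  expect_identical(to_newick(upgma(matrix(1, 1, 1,
                                          dimnames = list("X", "X")))), "X;")
})

test_that("feature vectors count meta-concept usages in archetype dissections", {
  spec <- fx_spec
  motif <- default_motif(spec)
  # meta-dictionary containing a 2-SSE piece of the motif
  piece <- extract_candidate(motif$archetype, c(2, 3), spec, "c_0001")
  piece$kappa <- spec$kappa_grid[60]
  meta <- new_dictionary(list(piece), spec)
  # a dictionary whose first concept IS the motif, second is unrelated
  other_t <- tableau("o", "EE", matrix(c(FALSE, TRUE, TRUE, FALSE), 2),
                     matrix(c(0, 90.5, 90.5, 0), 2))
  other <- extract_candidate(other_t, c(1, 2), spec, "c_0002")
  m1 <- motif; m1$id <- "c_0001_full"
  C <- new_dictionary(list(m1, other), spec)
  fv <- feature_vectors(C, meta)
  expect_equal(dim(fv), c(2L, 1L))
  # the motif archetype contains the HH piece once
  d <- dissect(motif$archetype, meta)
  expect_equal(fv[1, 1], sum(d$regions$concept_id == "c_0001"))
  # archetype dissected all-null gives a zero row
  d2 <- dissect(other$archetype, meta)
  expect_equal(fv[2, 1], sum(d2$regions$concept_id == "c_0001"))
  # an archetype equal to a meta-concept scores a unit count
  meta_self <- new_dictionary(list(m1), spec)
  fv_self <- feature_vectors(new_dictionary(list(motif), spec), meta_self)
  expect_equal(unname(fv_self[1, 1]), 1L)
})

test_that("meta-inference finds structure in near-identical archetypes", {
  spec <- fx_spec
  set.seed(104)
  bench <- make_benchmark(synth_params(n_tableaux = 8, sse_range = c(4, 4),
                                       plant_fraction = 1, kappa_true = 500,
                                       seed = 104), spec)
  cons <- lapply(seq_along(bench$collection), function(i) {
    extract_candidate(bench$collection[[i]], c(1, 4), spec,
                      sprintf("c_%04d", i))
  })
  C <- new_dictionary(cons, spec)
  meta <- infer_meta(C, anneal_params(seed = 104, t0 = 100,
                                      iters_per_temp = 60))
  expect_gt(length(meta$concepts), 0L)
  expect_error(infer_meta(new_dictionary(C$concepts[1], spec)),
               ">= 2 concepts")
  # determinism under seed
  meta2 <- infer_meta(C, anneal_params(seed = 104, t0 = 100,
                                       iters_per_temp = 60))
  expect_identical(as.data.frame(meta), as.data.frame(meta2))
})
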