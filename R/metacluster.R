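#' Infer meta-concepts over a dictionary's archetypes
#'
#' Treats the concept archetype subtableaux themselves as a source collection
#' and reruns the dictionary inference, yielding "concepts of concepts" that
#' best explain the dictionary.
#'
#' @param C a `fold_dictionary` with at least 2 concepts.
#' @param params an `anneal_params`.
#' @return a meta `fold_dictionary` (see [anneal()] for attributes).
#' @export
infer_meta <- function(C, params = anneal_params()) {
  if (length(C$concepts) < 2L) stop("infer_meta needs a dictionary with >= 2 concepts")
  archetypes <- lapply(C$concepts, function(cc) {
    a <- cc$archetype
    a$id <- cc$id
    a
  })
  anneal(archetypes, params, C$spec)
}

#' Bag-of-meta-concepts feature vectors
#'
#' Dissects each concept archetype against the meta-dictionary and counts how
#' often each meta-concept is used, giving one count vector per concept
#' (rows) over meta-concepts (columns).
#'
#' @param C a `fold_dictionary`.
#' @param meta a non-empty meta `fold_dictionary`.
#' @return integer matrix, `length(C$concepts)` x `length(meta$concepts)`,
#'   with concept/meta-concept ids as dimnames.
#' @export
feature_vectors <- function(C, meta) {
  if (length(meta$concepts) == 0L) stop("meta-dictionary is empty")
  meta_ids <- vapply(meta$concepts, `[[`, character(1), "id")
  out <- matrix(0L, length(C$concepts), length(meta_ids),
                dimnames = list(vapply(C$concepts, `[[`, character(1), "id"),
                                meta_ids))
  for (i in seq_along(C$concepts)) {
    d <- dissect(C$concepts[[i]]$archetype, meta)
    used <- d$regions$concept_id[d$regions$concept_id != "c_0000"]
    if (length(used) > 0L) {
      tb <- table(used)
      out[i, names(tb)] <- out[i, names(tb)] + as.integer(tb)
    }
  }
  out
}

#' Cosine similarity between two count vectors
#'
#' `(u . v) / (|u| |v|)`.  Two zero vectors are indistinguishable and score
#' 1; exactly one zero vector scores 0.  Non-negative counts keep the value
#' in `[0, 1]`.
#'
#' @param u,v numeric vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 && nv == 0) return(1)
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

#' Pairwise cosine similarity matrix of feature vectors
#'
#' @param fv matrix from [feature_vectors()] (rows = concepts).
#' @return symmetric similarity matrix with unit diagonal.
#' @export
similarity_matrix <- function(fv) {
  k <- nrow(fv)
  s <- diag(1, k)
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        s[i, j] <- s[j, i] <- cosine_similarity(fv[i, ], fv[j, ])
      }
    }
  }
  dimnames(s) <- list(rownames(fv), rownames(fv))
  s
}

#' UPGMA agglomeration of a similarity matrix
#'
#' Distances are `1 - similarity`.  Standard unweighted pair-group averaging:
#' at each step the closest pair of clusters is merged at height `d / 2`, and
#' distances to the merged cluster are size-weighted arithmetic means of the
#' members' distances.  Ties are broken by the lowest-index pair.  The result
#' is ultrametric: all leaves sit at depth equal to the root height.
#'
#' @param sim symmetric similarity matrix with unit diagonal; row names are
#'   used as leaf labels.
#' @return object of class `upgma_tree`: `merge` (hclust-style), `heights`
#'   (one per merge), `labels`, and `order` of leaves.
#' @export
upgma <- function(sim) {
  sim <- as.matrix(sim)
  k <- nrow(sim)
  stopifnot(k >= 1L, ncol(sim) == k)
  if (k > 1L && max(abs(sim - t(sim))) > 1e-9) {
    stop("similarity matrix must be symmetric")
  }
  if (max(abs(diag(sim) - 1)) > 1e-9) stop("similarity diagonal must be 1")
  labels <- rownames(sim) %||% paste0("L", seq_len(k))
  if (k == 1L) {
    return(structure(list(merge = matrix(integer(0), 0, 2),
                          heights = numeric(0), labels = labels, order = 1L),
                     class = "upgma_tree"))
  }
  d <- 1 - sim
  active <- seq_len(k)              # cluster id per active row: <0 leaf, >0 merge
  cl_id <- -seq_len(k)
  sizes <- rep(1L, k)
  merge <- matrix(0L, k - 1L, 2L)
  heights <- numeric(k - 1L)
  for (step in seq_len(k - 1L)) {
    m <- length(active)
    # lowest-index tie-break: scan pairs in row-major order
    bi <- 1L; bj <- 2L; bd <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        if (d[active[i], active[j]] < bd - 1e-12) {
          bd <- d[active[i], active[j]]; bi <- i; bj <- j
        }
      }
    }
    ai <- active[bi]; aj <- active[bj]
    merge[step, ] <- c(cl_id[ai], cl_id[aj])
    heights[step] <- bd / 2
    # size-weighted average distances to the merged cluster, stored in ai
    wi <- sizes[ai]; wj <- sizes[aj]
    others <- setdiff(active, c(ai, aj))
    for (o in others) {
      d[ai, o] <- d[o, ai] <- (wi * d[ai, o] + wj * d[aj, o]) / (wi + wj)
    }
    sizes[ai] <- wi + wj
    cl_id[ai] <- step
    active <- active[-bj]
  }
  ord <- tree_leaf_order(merge, k)
  structure(list(merge = merge, heights = heights, labels = labels,
                 order = ord),
            class = "upgma_tree")
}

tree_leaf_order <- function(merge, k) {
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  if (k == 1L) 1L else walk(nrow(merge))
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("UPGMA tree: %d leaves, root height %.4f\n",
              length(x$labels),
              if (length(x$heights) > 0L) max(x$heights) else 0))
  invisible(x)
}

#' Cophenetic distance matrix of a UPGMA tree
#'
#' Distance between two leaves is twice the height of their lowest common
#' ancestor; used to compare agglomerations.
#'
#' @param tree an `upgma_tree`.
#' @return symmetric matrix of distances.
#' @export
cophenetic_upgma <- function(tree) {
  k <- length(tree$labels)
  out <- matrix(0, k, k, dimnames = list(tree$labels, tree$labels))
  members <- vector("list", nrow(tree$merge))
  for (s in seq_len(nrow(tree$merge))) {
    grab <- function(node) if (node < 0L) -node else members[[node]]
    left <- grab(tree$merge[s, 1]); right <- grab(tree$merge[s, 2])
    for (a in left) for (b in right) {
      out[a, b] <- out[b, a] <- 2 * tree$heights[s]
    }
    members[[s]] <- c(left, right)
  }
  out
}

#' Convert a UPGMA tree to ape's phylo representation
#'
#' Branch lengths are height differences between a node and its parent, so
#' the tree stays ultrametric.
#'
#' @param tree an `upgma_tree`.
#' @return an `ape::phylo` object (single-leaf trees are not representable
#'   in phylo; see [to_newick()]).
#' @export
as_phylo <- function(tree) {
  k <- length(tree$labels)
  stopifnot(k >= 2L)
  n_merge <- nrow(tree$merge)
  # phylo numbering: leaves 1..k, root k+1, internals descending from root
  node_of_merge <- integer(n_merge)
  node_of_merge[n_merge] <- k + 1L
  nxt <- k + 2L
  for (s in seq(n_merge - 1L, by = -1L, length.out = max(0L, n_merge - 1L))) {
    node_of_merge[s] <- nxt
    nxt <- nxt + 1L
  }
  edges <- matrix(0L, 0, 2)
  lens <- numeric(0)
  for (s in seq_len(n_merge)) {
    for (child in tree$merge[s, ]) {
      if (child < 0L) {
        edges <- rbind(edges, c(node_of_merge[s], -child))
        lens <- c(lens, tree$heights[s])
      } else {
        edges <- rbind(edges, c(node_of_merge[s], node_of_merge[child]))
        lens <- c(lens, tree$heights[s] - tree$heights[child])
      }
    }
  }
  phy <- list(edge = edges, edge.length = lens, tip.label = tree$labels,
              Nnode = n_merge)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' Newick text of a UPGMA tree
#'
#' @param tree an `upgma_tree`.
#' @return a Newick string (single leaf: `"label;"`).
#' @export
to_newick <- function(tree) {
  if (length(tree$labels) == 1L) return(paste0(tree$labels, ";"))
  ape::write.tree(as_phylo(tree))
}

#' Write a similarity matrix as tab-separated values
#'
#' Header row of concept ids, then one labelled row per concept.
#'
#' @param sim similarity matrix.
#' @param path output file.
#' @return (invisibly) `path`.
#' @export
write_similarity_tsv <- function(sim, path) {
  ids <- rownames(sim) %||% paste0("L", seq_len(nrow(sim)))
  lines <- c(paste(c("id", ids), collapse = "\t"),
             vapply(seq_len(nrow(sim)), function(i) {
               paste(c(ids[i], sprintf("%.6f", sim[i, ])), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
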