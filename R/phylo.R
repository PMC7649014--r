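#' Labelled symmetric distance matrix
#'
#' @param m symmetric non-negative numeric matrix with dimnames.
#' @param kind `"p_distance"` or `"jc_protein"`.
#' @return an object of class `dist_matrix`.
#' @export
dist_matrix <- function(m, kind = c("p_distance", "jc_protein")) {
  kind <- match.arg(kind)
  m <- as.matrix(m)
  if (is.null(rownames(m))) stop("distance matrix needs labels")
  if (any(!is.finite(m))) stop("non-finite distances")
  if (any(abs(m - t(m)) > 1e-12)) stop("distance matrix not symmetric")
  if (any(diag(m) != 0)) stop("distance matrix diagonal must be zero")
  if (any(m < 0)) stop("negative distances")
  structure(list(labels = rownames(m), matrix = m, kind = kind),
            class = "dist_matrix")
}

#' Protein-adapted Jukes-Cantor distance correction
#'
#' The 20-state multiple-hit correction
#' \deqn{d = -\frac{19}{20}\,\ln\!\left(1 - \frac{20\,p}{19}\right)}
#' of an observed proportion of differing sites `p`.
#'
#' @param p observed p-distance(s), `0 <= p < 19/20`.
#' @param clamp if `TRUE`, saturated values (`p >= 19/20`) are clamped to
#'   the largest finite corrected distance in `p` instead of erroring.
#' @return corrected distance(s), `d >= p`.
#' @export
jc_protein_distance <- function(p, clamp = FALSE) {
  if (any(p < 0)) stop("p-distance must be non-negative")
  sat <- p >= 19 / 20
  if (any(sat) && !clamp)
    stop("saturated p-distance (p >= 19/20): corrected distance undefined")
  d <- rep(NA_real_, length(p))
  d[!sat] <- -(19 / 20) * log(1 - 20 * p[!sat] / 19)
  if (any(sat)) {
    mx <- if (any(!sat)) max(d[!sat]) else 0
    d[sat] <- mx
    warning(sum(sat), " saturated pair(s) clamped to max finite distance")
  }
  d
}

#' Pairwise distance matrix from a multiple alignment
#'
#' p-distances are computed per pair over the columns where neither row is
#' gapped (pairwise deletion); `kind = "jc_protein"` applies
#' [jc_protein_distance()] entrywise.
#'
#' @param msa a [protein_msa] with at least 2 rows.
#' @param kind `"p_distance"` or `"jc_protein"`.
#' @param clamp passed to [jc_protein_distance()].
#' @return a [dist_matrix].
#' @export
msa_distance_matrix <- function(msa, kind = c("jc_protein", "p_distance"),
                                clamp = FALSE) {
  kind <- match.arg(kind)
  m <- as.matrix(msa)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 aligned sequences")
  gap <- m == "-"
  out <- matrix(0, n, n, dimnames = list(msa$ids, msa$ids))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      comp <- !gap[i, ] & !gap[j, ]
      nc <- sum(comp)
      if (nc == 0)
        stop(sprintf("no comparable columns between '%s' and '%s'",
                     msa$ids[i], msa$ids[j]))
      p <- sum(m[i, comp] != m[j, comp]) / nc
      out[i, j] <- p
      out[j, i] <- p
    }
  }
  if (kind == "jc_protein") {
    v <- jc_protein_distance(out[upper.tri(out)], clamp = clamp)
    out[upper.tri(out)] <- v
    out <- pmax(out, t(out))
  }
  dist_matrix(out, kind)
}

#' UPGMA ultrametric clustering tree
#'
#' Iteratively merges the closest pair of clusters; the distance from a
#' merged cluster to the others is the size-weighted arithmetic average,
#' and the height of the new node is half the merge distance. Ties are
#' broken by the smallest pair indices in the current cluster ordering
#' (clusters in order of creation).
#'
#' @param dm a [dist_matrix] (or symmetric labelled matrix), n >= 2.
#' @return an object of class `upgma_tree`: hclust-style `merge` matrix
#'   (negative entries are leaves), `node_height` (half merge distances),
#'   `labels`, and optional `support`.
#' @export
upgma <- function(dm) {
  m <- if (inherits(dm, "dist_matrix")) dm$matrix else as.matrix(dm)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 taxa")
  labels <- rownames(m)
  # active clusters: id (negative leaf / positive merge), size
  active_id <- -seq_len(n)
  size <- rep(1L, n)
  d <- m
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    k <- length(active_id)
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        if (d[i, j] < best) { best <- d[i, j]; bi <- i; bj <- j }
      }
    }
    merge[step, ] <- c(active_id[bi], active_id[bj])
    height[step] <- best / 2
    # size-weighted average distance to the new cluster
    wi <- size[bi]; wj <- size[bj]
    newd <- (wi * d[bi, ] + wj * d[bj, ]) / (wi + wj)
    # the merged cluster takes the position of the first of the pair
    d[bi, ] <- newd
    d[, bi] <- newd
    d[bi, bi] <- 0
    keep <- setdiff(seq_len(k), bj)
    d <- d[keep, keep, drop = FALSE]
    active_id[bi] <- step
    size[bi] <- wi + wj
    active_id <- active_id[keep]
    size <- size[keep]
  }
  structure(list(merge = merge, node_height = height, labels = labels,
                 support = NULL),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("UPGMA tree: %d leaves, root height %.4g\n",
              length(x$labels), max(x$node_height)))
  invisible(x)
}

#' Leaf label sets of every internal node
#' @param tree an `upgma_tree`.
#' @return list of character vectors, one per merge, sorted.
#' @export
clade_sets <- function(tree) {
  sets <- vector("list", nrow(tree$merge))
  get <- function(k) if (k < 0) tree$labels[-k] else sets[[k]]
  for (s in seq_len(nrow(tree$merge))) {
    sets[[s]] <- sort(c(get(tree$merge[s, 1]), get(tree$merge[s, 2])))
  }
  sets
}

#' Convert a UPGMA tree to an ape phylo object
#' @param tree an `upgma_tree`.
#' @export
as_phylo <- function(tree) {
  hc <- structure(list(merge = tree$merge,
                       height = 2 * tree$node_height,
                       order = hclust_order(tree$merge),
                       labels = tree$labels, method = "average"),
                  class = "hclust")
  ape::as.phylo(hc)
}

hclust_order <- function(merge) {
  get <- function(k) {
    if (k < 0) return(-k)
    c(get(merge[k, 1]), get(merge[k, 2]))
  }
  get(nrow(merge))
}

#' Cut an ultrametric tree at a height
#'
#' Clusters are the maximal subtrees whose root height is strictly below
#' the threshold (singleton leaves included).
#'
#' @param tree an `upgma_tree`.
#' @param height non-negative cut height (on the node-height scale, i.e.
#'   half merge distances).
#' @return an object of class `tree_clustering`: `assignments` (named
#'   integer vector label -> cluster id, numbered by first appearance in
#'   the label ordering), `threshold`, `k`.
#' @export
cut_tree <- function(tree, height) {
  stopifnot(height >= 0)
  n <- length(tree$labels)
  comp <- seq_len(n)                 # union-find over leaves
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  sets <- clade_sets(tree)
  for (s in seq_len(nrow(tree$merge))) {
    if (tree$node_height[s] < height) {
      leaves <- match(sets[[s]], tree$labels)
      r <- find(leaves[1])
      for (l in leaves[-1]) comp[find(l)] <- r
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  ids <- match(roots, unique(roots))
  assignments <- setNames(ids, tree$labels)
  structure(list(assignments = assignments, threshold = height,
                 k = length(unique(ids))),
            class = "tree_clustering")
}

#' @export
print.tree_clustering <- function(x, ...) {
  cat(sprintf("clustering: %d clusters at height %.4g\n", x$k, x$threshold))
  invisible(x)
}

#' Automatic cluster-extraction threshold
#'
#' Returns the midpoint of the largest gap between consecutive sorted
#' merge heights (ties resolved towards the lowest gap), the package's
#' documented substitute for the unpublished manual threshold.
#'
#' @param tree an `upgma_tree` with at least 3 leaves.
#' @return a cut height.
#' @export
auto_threshold <- function(tree) {
  if (length(tree$labels) < 3) stop("need at least 3 leaves")
  h <- sort(tree$node_height)
  gaps <- diff(h)
  i <- which.max(gaps)               # which.max returns the first maximum
  (h[i] + h[i + 1]) / 2
}

#' Bootstrap clade supports for an ultrametric tree
#'
#' Columns of the alignment are resampled with replacement; the tree is
#' rebuilt per replicate and the support of each internal node of the
#' reference tree is the percentage of replicates containing a clade with
#' the same leaf set. Replicate r uses seed `seed + r`; replicates whose
#' distance matrix is undefined (e.g. a pair with no comparable columns)
#' are redrawn, at most 10 times each.
#'
#' @param msa a [protein_msa].
#' @param n_replicates number of bootstrap replicates (>= 1).
#' @param seed master seed.
#' @param tree_builder function `msa -> upgma_tree`; default JC-corrected
#'   distances + [upgma()].
#' @return the reference `upgma_tree` with a `support` vector in `[0,100]`.
#' @export
bootstrap_support <- function(msa, n_replicates = 100, seed = 1,
                              tree_builder = NULL) {
  stopifnot(n_replicates >= 1)
  if (is.null(tree_builder))
    tree_builder <- function(m) upgma(msa_distance_matrix(m, "jc_protein"))
  ref <- tree_builder(msa)
  ref_sets <- clade_sets(ref)
  keys <- vapply(ref_sets, paste, "", collapse = "\r")
  hits <- numeric(length(keys))
  nc <- msa_ncol(msa)
  mat <- as.matrix(msa)
  for (r in seq_len(n_replicates)) {
    set.seed(seed + r)
    tries <- 0L
    repeat {
      idx <- sample.int(nc, nc, replace = TRUE)
      rep_msa <- protein_msa(msa$ids,
                             apply(mat[, idx, drop = FALSE], 1, paste,
                                   collapse = ""))
      tr <- tryCatch(tree_builder(rep_msa), error = function(e) e)
      if (!inherits(tr, "error")) break
      tries <- tries + 1L
      message("bootstrap replicate ", r, " redrawn: ", conditionMessage(tr))
      if (tries >= 10L)
        stop("bootstrap replicate ", r, " failed after 10 redraws: ",
             conditionMessage(tr))
    }
    rep_keys <- vapply(clade_sets(tr), paste, "", collapse = "\r")
    hits <- hits + as.numeric(keys %in% rep_keys)
  }
  ref$support <- 100 * hits / n_replicates
  ref
}

#' Consensus-level ("specialized") phylogeny of sequence clusters
#'
#' Builds one consensus sequence per cluster, aligns the consensus
#' sequences together with any extra homolog records, computes protein
#' Jukes-Cantor distances, and returns a bootstrapped UPGMA tree.
#'
#' @param clusters named list: cluster name -> character vector of member
#'   ids (>= 1 member each); at least 2 clusters.
#' @param member_msas named list of [protein_msa], one per cluster.
#' @param extra_sequences optional [seq_records] appended to the consensus
#'   set (e.g. outgroup homologs).
#' @param n_replicates,seed bootstrap settings.
#' @param gap_rule_threshold consensus gap rule.
#' @param clamp clamp saturated JC pairs (consensus sequences of deeply
#'   diverged clusters can exceed the correction's domain).
#' @return an `upgma_tree` with bootstrap supports; the consensus records
#'   are attached as attribute `"consensus_records"`.
#' @export
specialized_phylogeny <- function(clusters, member_msas,
                                  extra_sequences = NULL,
                                  n_replicates = 100, seed = 1,
                                  gap_rule_threshold = 0.5, clamp = FALSE) {
  if (length(clusters) < 2) stop("need at least 2 clusters")
  if (any(lengths(clusters) < 1)) stop("cluster with no members")
  cons <- vapply(names(clusters), function(cl) {
    msa <- member_msas[[cl]]
    if (is.null(msa)) stop("missing member alignment for cluster ", cl)
    consensus(msa, gap_rule_threshold)
  }, character(1))
  recs <- seq_records(id = names(clusters), residues = cons,
                      description = "cluster consensus")
  if (!is.null(extra_sequences) && nrow(extra_sequences) > 0) {
    extra <- seq_records(extra_sequences$id, extra_sequences$residues,
                         extra_sequences$description,
                         extra_sequences$organism)
    recs <- rbind(recs, extra)
    class(recs) <- c("seq_records", "data.frame")
  }
  msa <- align_sequences(recs)
  builder <- function(m)
    upgma(msa_distance_matrix(m, "jc_protein", clamp = clamp))
  tree <- bootstrap_support(msa, n_replicates, seed, builder)
  attr(tree, "consensus_records") <- recs
  attr(tree, "consensus_msa") <- msa
  tree
}

#' Rand index between two partitions
#'
#' @param a,b cluster assignments over the same elements (named vectors
#'   are matched by name).
#' @return the Rand index in `[0, 1]`; 1 means identical partitions.
#' @export
rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  stopifnot(length(a) == length(b), !anyNA(b))
  n <- length(a)
  if (n < 2) return(1)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}
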