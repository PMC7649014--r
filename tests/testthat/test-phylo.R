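test_that("protein Jukes-Cantor correction matches its closed form", {
  expect_equal(jc_protein_distance(0), 0)
  expect_equal(jc_protein_distance(0.1), 0.1056644, tolerance = 1e-6)
  grid <- seq(0, 0.94, by = 0.01)
  expect_equal(jc_protein_distance(grid),
               -(19 / 20) * log(1 - 20 * grid / 19))
  # d >= p with equality only at 0; strictly increasing
  d <- jc_protein_distance(grid)
  expect_true(all(d[-1] > grid[-1]))
  expect_true(all(diff(d) > 0))
  expect_error(jc_protein_distance(0.95), "saturated")
  expect_warning(v <- jc_protein_distance(c(0.1, 0.96), clamp = TRUE),
                 "clamped")
  expect_equal(v[2], v[1])
})

test_that("MSA distance matrix uses pairwise deletion and entrywise JC", {
  msa <- protein_msa(c("a", "b"), c("AC-E", "ACDE"))
  dm <- msa_distance_matrix(msa, "p_distance")
  expect_equal(dm$matrix["a", "b"], 0)   # 3 comparable columns, all equal

  msa2 <- protein_msa(c("a", "b"), c("ACWE", "ACDE"))
  expect_equal(msa_distance_matrix(msa2, "p_distance")$matrix["a", "b"], 0.25)

  # identical rows: all-zero matrix
  msa3 <- protein_msa(c("a", "b", "c"), rep("MKWVTF", 3))
  expect_true(all(msa_distance_matrix(msa3, "jc_protein")$matrix == 0))

  # jc matrix equals the scalar correction applied entrywise
  rows <- c(a = "AAAAAAAAAA", b = "CAAAAAAAAA", c = "CCAAAAAAAA")
  msa4 <- protein_msa(names(rows), rows)
  p <- msa_distance_matrix(msa4, "p_distance")$matrix
  j <- msa_distance_matrix(msa4, "jc_protein")$matrix
  expect_equal(j[upper.tri(j)], jc_protein_distance(p[upper.tri(p)]))

  # a pair sharing no columns errors with the pair named
  msa5 <- protein_msa(c("a", "b"), c("AC--", "--DE"))
  expect_error(msa_distance_matrix(msa5), "'a' and 'b'")
})

test_that("UPGMA merges closest pairs with size-weighted averages", {
  m3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(m3)
  expect_equal(tr$node_height, c(1, 2))
  expect_equal(clade_sets(tr)[[1]], c("A", "B"))

  # n = 2: root height d/2
  m2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(upgma(m2)$node_height, 1.5)

  # all distances equal: tie rule gives the caterpillar over first indices
  m4 <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(m4) <- 0
  tr4 <- upgma(m4)
  expect_equal(tr4$node_height, rep(0.5, 3))
  expect_equal(clade_sets(tr4)[[1]], c("A", "B"))
  expect_equal(clade_sets(tr4)[[2]], c("A", "B", "C"))
})

test_that("UPGMA agrees with a brute-force full-rescan implementation", {
  set.seed(17)
  for (k in 1:200) {
    n <- sample(3:6, 1)
    m <- random_dist_matrix(n)
    a <- upgma(m)
    b <- brute_upgma(m)
    expect_equal(a$node_height, b$node_height, tolerance = 1e-12)
    expect_equal(clade_sets(a), clade_sets(b))
  }
})

test_that("UPGMA trees are ultrametric and reproduce ultrametric inputs", {
  set.seed(19)
  for (k in 1:20) {
    m <- random_dist_matrix(sample(3:7, 1))
    tr <- upgma(m)
    expect_true(all(diff(sort(tr$node_height)) >= -1e-12))
    coph <- ape::cophenetic.phylo(as_phylo(tr))
    # root-to-leaf path equal for all leaves (ultrametricity)
    ph <- as_phylo(tr)
    depths <- ape::node.depth.edgelength(ph)[seq_along(ph$tip.label)]
    expect_lt(diff(range(depths)), 1e-9)
    # on the tree's own cophenetic matrix, UPGMA reproduces the tree
    tr2 <- upgma(coph[rownames(m), rownames(m)])
    expect_equal(sort(tr2$node_height), sort(tr$node_height),
                 tolerance = 1e-9)
  }
})

test_that("cut_tree extracts maximal subtrees below the threshold", {
  m3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(m3)
  expect_equal(cut_tree(tr, 10)$k, 1)           # above root: one cluster
  cl <- cut_tree(tr, 1.5)
  expect_equal(cl$k, 2)
  expect_equal(unname(cl$assignments[c("A", "B", "C")]), c(1, 1, 2))
  expect_equal(cut_tree(tr, 0)$k, 3)            # height 0: all singletons
})

test_that("auto_threshold takes the midpoint of the largest height gap", {
  fake <- structure(list(merge = matrix(c(-1, -2, 1, -3, 2, -4), 3, 2,
                                        byrow = TRUE),
                         node_height = c(1, 2, 10),
                         labels = letters[1:4], support = NULL),
                    class = "upgma_tree")
  expect_equal(auto_threshold(fake), 6)
  # equally spaced heights: first largest gap wins
  fake$node_height <- c(1, 2, 3)
  expect_equal(auto_threshold(fake), 1.5)
  fake2 <- fake; fake2$labels <- letters[1:2]
  expect_error(auto_threshold(fake2), "at least 3")
})

test_that("bootstrap supports behave at the extremes and under row permutation", {
  anc <- make_ancestor(scaled_roster()[1, ], seed = 2)
  ca1 <- derive_clade_ancestor(anc, 0.15, seed = 21)
  ca2 <- derive_clade_ancestor(anc, 0.25, seed = 22)
  ev1 <- evolve_clade(ca1, 4, sub_rate = 0.01, indel_rate = 0, seed = 31,
                      id_prefix = "P")
  ev2 <- evolve_clade(ca2, 4, sub_rate = 0.01, indel_rate = 0, seed = 32,
                      id_prefix = "Q")
  recs <- rbind(ev1$records, ev2$records)
  class(recs) <- c("seq_records", "data.frame")
  msa <- align_sequences(recs)

  # a single replicate yields supports in {0, 100}
  tr1 <- bootstrap_support(msa, n_replicates = 1, seed = 1)
  expect_true(all(tr1$support %in% c(0, 100)))

  # permuting row order leaves the planted-split supports unchanged
  # (within-clade distances contain exact ties, so only tie-free clades
  # are order-invariant)
  perm <- sample(seq_along(msa$ids))
  msa_p <- protein_msa(msa$ids[perm], unname(msa$rows)[perm])
  tr <- bootstrap_support(msa, n_replicates = 25, seed = 5)
  tr_p <- bootstrap_support(msa_p, n_replicates = 25, seed = 5)
  key <- function(t) setNames(t$support,
                              vapply(clade_sets(t), paste, "", collapse = "|"))
  k1 <- key(tr); k2 <- key(tr_p)
  for (cl in c(paste(ev1$records$id, collapse = "|"),
               paste(ev2$records$id, collapse = "|"),
               paste(sort(recs$id), collapse = "|"))) {
    expect_true(cl %in% names(k1) && cl %in% names(k2))
    expect_equal(k1[[cl]], k2[[cl]])
  }
})

test_that("specialized phylogeny is reproducible and respects planted structure", {
  bm <- scaled_bench()
  truth <- bm$truth
  msa <- scaled_core_msa()
  tr <- upgma(msa_distance_matrix(msa, "jc_protein"))
  cl <- cut_tree(tr, auto_threshold(tr))
  cl_ids <- split(names(cl$assignments), cl$assignments)
  names(cl_ids) <- vapply(cl_ids, function(ids)
    truth$clade[match(ids[1], truth$id)], "")
  member_msas <- lapply(cl_ids, function(ids) notchfam:::subset_msa(msa, ids))
  outg <- scaled_curation()$records
  outg <- outg[outg$id %in% truth$id[truth$role == "outgroup"], ]
  class(outg) <- c("seq_records", "data.frame")

  st <- specialized_phylogeny(cl_ids, member_msas, outg,
                              n_replicates = 25, seed = 1)
  expect_equal(length(st$labels), length(cl_ids) + 2)
  sets <- clade_sets(st)
  # planted divergence ladder: Notch2 and Notch3 are each other's closest
  # clusters in the consensus tree
  expect_true(any(vapply(sets, function(s)
    identical(sort(s), c("Notch2", "Notch3")), logical(1))))
  # planted outgroups attach outside the four chordate paralog clades:
  # the smallest clade spanning all four paralogs contains no outgroup
  paralogs <- c("Notch1", "Notch2", "Notch3", "Notch4")
  spanning <- Filter(function(s) all(paralogs %in% s), sets)
  smallest <- spanning[[which.min(lengths(spanning))]]
  expect_lt(length(smallest), length(st$labels))
  expect_length(intersect(smallest, c("GLP1LIKE", "LIN12LIKE")), 0)
  # same seed, same supports
  st2 <- specialized_phylogeny(cl_ids, member_msas, outg,
                               n_replicates = 25, seed = 1)
  expect_identical(st$support, st2$support)

  expect_error(specialized_phylogeny(cl_ids[1], member_msas[1]),
               "at least 2")
})
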