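test_that("pairwise alignment handles identity, gaps and local mode", {
  al <- pairwise_align("ACDE", "ACDE")
  expect_equal(al$identity, 1)
  expect_false(grepl("-", al$aligned_a, fixed = TRUE))

  al2 <- pairwise_align("ACDE", "ACE")
  expect_equal(al2$aligned_a, "ACDE")
  expect_equal(nchar(al2$aligned_b), 4L)
  expect_equal(sum(strsplit(al2$aligned_b, "")[[1]] == "-"), 1L)

  # local alignment of a sequence against its exact substring scores the
  # substring's self-score
  seqfull <- "MKWVTFISLLFLFSSAYSRGV"
  sub <- substr(seqfull, 5, 15)
  S <- gonnet250(FALSE)
  self <- sum(diag(S)[match(strsplit(sub, "")[[1]], rownames(S))])
  expect_equal(pairwise_align(seqfull, sub, mode = "local")$score, self)

  expect_error(pairwise_align("", "ACDE"), "empty")
})

test_that("alignment removes to the original sequences (degap identity)", {
  set.seed(11)
  for (i in 1:10) {
    a <- random_protein(sample(5:60, 1))
    b <- random_protein(sample(5:60, 1))
    al <- pairwise_align(a, b)
    expect_equal(gsub("-", "", al$aligned_a, fixed = TRUE), a)
    expect_equal(gsub("-", "", al$aligned_b, fixed = TRUE), b)
    expect_equal(nchar(al$aligned_a), nchar(al$aligned_b))
  }
})

test_that("alignment scores match an independent implementation", {
  S <- gonnet250(FALSE)
  set.seed(42)
  for (k in 1:25) {
    a <- random_protein(sample(5:50, 1))
    b <- random_protein(sample(5:50, 1))
    for (mode in c("global", "local")) {
      mine <- pairwise_align(a, b, mode = mode)$score
      oracle <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(a), Biostrings::AAString(b),
        substitutionMatrix = S, gapOpening = 10, gapExtension = 0.5,
        type = mode, scoreOnly = TRUE)
      expect_equal(mine, oracle, tolerance = 1e-4)
    }
  }
})

test_that("pairwise p-distance counts mismatches over comparable columns", {
  expect_equal(pairwise_distance("ACDEF", "ACDEF"), 0)
  expect_equal(pairwise_distance("ACDE", "ACDF"), 0.25)
  expect_equal(pairwise_distance("AAAA", "TTTT"), 1)
  # symmetry
  set.seed(3)
  a <- random_protein(30); b <- random_protein(25)
  expect_equal(pairwise_distance(a, b), pairwise_distance(b, a))
})

test_that("NJ guide tree recovers additive topologies and handles edge cases", {
  # 2 taxa: a single cherry
  m2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr2 <- nj_guide_tree(m2)
  expect_setequal(tr2$tip.label, c("A", "B"))

  # additive matrix from ((A,B),(C,D)): NJ recovers the generating split
  tree_dist <- c(3, 5, 3, 6, 4, 4)  # AB, AC, AD, BC, BD, CD
  m4 <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  m4[lower.tri(m4)] <- c(3, 5, 3, 6, 4, 4)
  m4 <- m4 + t(m4)
  tr4 <- nj_guide_tree(m4)
  un <- ape::unroot(tr4)
  expect_true(ape::is.monophyletic(un, c("A", "B")) ||
                ape::is.monophyletic(un, c("C", "D")))

  # identical rows join first
  m3 <- matrix(c(0, 0, 5, 0, 0, 5, 5, 5, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- nj_guide_tree(m3)
  expect_true(ape::is.monophyletic(tr3, c("A", "B")))

  bad <- m3; bad[1, 2] <- bad[2, 1] <- NaN
  expect_error(nj_guide_tree(bad), "NaN")
})

test_that("progressive MSA reduces to pairwise for 2 records and is gap-free for clones", {
  recs <- seq_records(c("a", "b"), c("ACDEFGHIK", "ACDFGHIK"))
  msa <- progressive_msa(recs)
  al <- pairwise_align(recs$residues[1], recs$residues[2])
  expect_equal(unname(msa$rows), c(al$aligned_a, al$aligned_b))

  clones <- seq_records(c("x", "y", "z"), rep("MKWVTFISLL", 3))
  msa3 <- progressive_msa(clones)
  expect_equal(msa_ncol(msa3), 10L)
  expect_false(any(grepl("-", msa3$rows, fixed = TRUE)))

  expect_error(progressive_msa(recs, guide_tree = ape::read.tree(text = "(a,q);")),
               "guide tree leaves")
})

test_that("substitution-only clades align gap-free at ancestor length", {
  anc <- make_ancestor(scaled_roster()[5, ], seed = 3)
  ev <- evolve_clade(anc, 5, sub_rate = 0.03, indel_rate = 0, seed = 11)
  msa <- align_sequences(ev$records)
  expect_equal(msa_ncol(msa), anc$record$length)
  expect_false(any(grepl("-", msa$rows, fixed = TRUE)))
  # degapping returns inputs exactly
  expect_equal(unname(vapply(msa$rows, function(r)
    gsub("-", "", r, fixed = TRUE), character(1))), ev$records$residues)
})

test_that("progressive MSA score is bracketed by star and optimal pairwise bounds", {
  S <- gonnet250(FALSE)
  sum_of_pairs <- function(msa) {
    m <- as.matrix(msa)
    total <- 0
    for (i in seq_len(nrow(m) - 1)) for (j in seq(i + 1, nrow(m))) {
      ai <- m[i, ]; aj <- m[j, ]
      keep <- !(ai == "-" & aj == "-")
      ai <- ai[keep]; aj <- aj[keep]
      gap <- ai == "-" | aj == "-"
      total <- total + sum(S[cbind(ai[!gap], aj[!gap])])
      r <- rle(gap)
      total <- total - sum(10 + 0.5 * r$lengths[r$values])
    }
    total
  }
  set.seed(23)
  for (rep in 1:5) {
    seqs <- vapply(1:4, function(i) random_protein(sample(5:8, 1)), character(1))
    recs <- seq_records(paste0("s", 1:4), seqs)
    msa <- progressive_msa(recs)
    sp <- sum_of_pairs(msa)
    # upper bound: each pair's projection cannot beat its optimal DP score
    opt <- 0
    for (i in 1:3) for (j in (i + 1):4)
      opt <- opt + pairwise_align(seqs[i], seqs[j])$score
    expect_lte(sp, opt + 1e-9)
  }
})

test_that("conservation profile reports modal and top-2 statistics per column", {
  msa <- protein_msa(c("a", "b", "c", "d"), c("AFA-", "AFT-", "TYA-", "TYT-"))
  prof <- conservation_profile(msa)
  expect_equal(prof$modal[1], "A")       # tie A/T broken alphabetically
  expect_equal(prof$modal_freq[1], 0.5)
  expect_equal(prof$top2[2], "FY")
  expect_equal(prof$top2_freq[2], 1)
  expect_equal(prof$gap_fraction[4], 1)
  expect_true(is.na(prof$modal[4]))
  # modal frequency dominates every other residue frequency
  expect_true(all(prof$modal_freq[1:3] >= 1 - prof$top2_freq[1:3]))
})

test_that("consensus applies the majority rule with gap-rule omission", {
  msa <- protein_msa(c("a", "b", "c"), c("AAT", "AAT", "TAT"))
  expect_equal(consensus(msa), "AAT")
  # alphabetical tie-break
  msa2 <- protein_msa(c("a", "b", "c", "d"), c("A", "A", "T", "T"))
  expect_equal(consensus(msa2), "A")
  # 3 gaps of 4 rows: column omitted
  msa3 <- protein_msa(c("a", "b", "c", "d"), c("AG", "A-", "A-", "A-"))
  expect_equal(consensus(msa3), "A")
  # single-row alignment: identity
  msa4 <- protein_msa("a", "MKWV")
  expect_equal(consensus(msa4), "MKWV")
})
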