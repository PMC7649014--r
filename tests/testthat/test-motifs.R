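test_that("motif grammar compiles fixed, wildcard, class and range elements", {
  a <- compile_motif("CXNGGXC")
  expect_length(a$elements, 7)
  expect_equal(vapply(a$elements, `[[`, "", "type"),
               c("fixed", "wild", "fixed", "fixed", "fixed", "wild", "fixed"))

  b <- compile_motif("CXCXXG[FY]XG")
  expect_length(b$elements, 9)
  expect_equal(b$elements[[7]]$type, "class")
  expect_setequal(b$elements[[7]]$residues, c("F", "Y"))

  r <- compile_motif("C-x(2,14)-C")
  expect_equal(vapply(r$elements, `[[`, "", "type"),
               c("fixed", "range", "fixed"))
  expect_equal(r$elements[[2]]$min, 2L)
  expect_equal(r$elements[[2]]$max, 14L)

  expect_error(compile_motif("C[F"), "column 2")
  expect_error(compile_motif("Cx(5,2)C"), "min > max")
  expect_error(compile_motif("C?"), "column 2")
})

test_that("motif scanning finds documented occurrences", {
  hits <- scan_motif("MCANGGECW", notch_motifs()$A)
  expect_equal(hits$start, 2L)
  expect_equal(hits$end, 8L)
  expect_equal(hits$match, "CANGGEC")

  hitsB <- scan_motif("CACDEGFAG", notch_motifs()$B)
  expect_equal(hitsB$start, 1L)
  expect_equal(hitsB$end, 9L)

  expect_equal(nrow(scan_motif("CACDEGWAG", notch_motifs()$B)), 0L)

  # an input 'X' satisfies wildcards but never a fixed position or class
  expect_equal(nrow(scan_motif("CXNGGXC", notch_motifs()$A)), 1L)
  expect_equal(nrow(scan_motif("XANGGEC", notch_motifs()$A)), 0L)
  expect_equal(nrow(scan_motif("CACDEGXAG", notch_motifs()$B)), 0L)
})

test_that("motif scanner agrees with a naive backtracking matcher", {
  pats <- list(compile_motif("CXNGGXC"),
               compile_motif("CXCXXG[FY]XG"),
               compile_motif("C-x(2,14)-C-x(1,10)-C"),
               compile_motif("[DN]X[DN][EQ]"),
               compile_motif("GX-x(1,4)-[ST]G"))
  set.seed(29)
  # enrich the alphabet so motifs actually occur
  alpha <- c(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]],
             rep(c("C", "G", "N", "F", "Y", "D"), 4))
  n_checked <- 0
  for (k in 1:500) {
    s <- random_protein(sample(20:200, 1), alphabet = alpha)
    p <- pats[[((k - 1) %% length(pats)) + 1]]
    for (ov in c(TRUE, FALSE)) {
      mine <- scan_motif(s, p, allow_overlaps = ov)
      ref <- naive_scan(s, p, allow_overlaps = ov)
      expect_equal(mine$start, ref$start)
      expect_equal(mine$end, ref$end)
    }
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 500)
})

test_that("EGF repeat caller counts canonical units and records cysteines", {
  unit <- "CANGGECIDSCRCPPGFTGARSCEVC"
  r1 <- find_egf_repeats(unit)
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$cys, "1,7,11,13,23,26")
  expect_equal(r1$disulfides, "1-3,2-4,5-6")

  # k concatenated units with 5-residue linkers: k repeats
  for (k in c(2, 5)) {
    seqk <- paste(rep(unit, k), collapse = "GSTAH")
    rk <- find_egf_repeats(seqk)
    expect_equal(nrow(rk), k)
    # reported cysteines are a subset of the sequence's cysteines
    cys_all <- which(strsplit(seqk, "")[[1]] == "C")
    cys_rep <- as.integer(unlist(strsplit(rk$cys, ",")))
    expect_true(all(cys_rep %in% cys_all))
    # non-overlapping intervals
    expect_true(all(rk$start[-1] > rk$end[-k]))
  }

  expect_equal(nrow(find_egf_repeats(strrep("A", 200))), 0L)
})

test_that("calcium-binding classification reads the N-flank consensus", {
  unit <- "CANGGECIDSCRCPPGFTGARSCEVC"
  cb <- paste0("DIDEG", unit)
  reps <- find_egf_repeats(cb)
  expect_true(classify_cbEGF(cb, reps[1, ]))

  non <- paste0("AAAAA", unit)
  reps2 <- find_egf_repeats(non)
  expect_false(classify_cbEGF(non, reps2[1, ]))

  # too little flank: FALSE
  reps3 <- find_egf_repeats(unit)
  expect_false(classify_cbEGF(unit, reps3[1, ]))
})

test_that("digital signature encodes the repeat calcium plan in order", {
  unit <- "CANGGECIDSCRCPPGFTGARSCEVC"
  seqs <- paste0("MKLVH", "DIDES", unit, "GSTAH", "AAGSA", unit,
                 "GSTAH", "NIDQS", unit, "WPT")
  expect_equal(digital_signature(seqs), "101")
  expect_equal(digital_signature(strrep("A", 50)), "")

  # generator truth: the ancestor's signature equals its planted cb plan
  anc <- make_ancestor(scaled_roster()[5, ], seed = 9)
  expect_equal(digital_signature(anc$record$residues), anc$cb_plan)
  # and every planted cb repeat individually classifies TRUE
  reps <- find_egf_repeats(anc$record$residues)
  bits <- strsplit(anc$cb_plan, "")[[1]]
  for (i in seq_len(nrow(reps)))
    expect_equal(classify_cbEGF(anc$record$residues, reps[i, ]),
                 bits[i] == "1")
})

test_that("motif discovery symbolizes columns and windows as documented", {
  # 20 identical copies: fully fixed windows
  recs <- protein_msa(paste0("s", 1:20), rep("CANGGECIDSC", 20))
  pats <- discover_conserved_motifs(recs, min_len = 7)
  expect_true(all(!grepl("X", vapply(pats, `[[`, "", "source"))))

  # variability planted exactly at wildcard columns recovers Motif A
  set.seed(31)
  base <- strsplit("WWWCANGGECWWW", "")[[1]]
  rows <- vapply(1:40, function(i) {
    r <- base
    r[c(1, 2, 3, 11, 12, 13)] <- sample(setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z")), 6)
    r[c(5, 9)] <- sample(c("A", "E", "G", "K", "L", "S", "T", "V"), 2)
    paste(r, collapse = "")
  }, character(1))
  msa <- protein_msa(paste0("r", 1:40), rows)
  pats2 <- vapply(discover_conserved_motifs(msa), `[[`, "", "source")
  expect_true("CXNGGXC" %in% pats2)

  # an F/Y alternating column is reported as the class [FY]
  rows3 <- vapply(1:40, function(i) {
    r <- strsplit("CACDEGFAGCAC", "")[[1]]
    r[7] <- sample(c("F", "Y"), 1)
    paste(r, collapse = "")
  }, character(1))
  pats3 <- vapply(discover_conserved_motifs(protein_msa(paste0("q", 1:40),
                                                        rows3), min_len = 7),
                  `[[`, "", "source")
  expect_true(any(grepl("[FY]", pats3, fixed = TRUE)))

  # self-consistency: discovered patterns re-match the master sequence
  master <- paste(base, collapse = "")
  for (p in discover_conserved_motifs(msa))
    expect_gte(nrow(scan_motif(master, p)), 1)
})
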