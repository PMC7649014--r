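test_that("keyword filter rejects noise deflines and keeps true positives", {
  recs <- seq_records(
    id = c("r1", "r2", "r3", "r4", "r5"),
    residues = strrep("ACDEF", 10),
    description = c("strawberry notch homolog 1", "notch receptor 1",
                    "PREDICTED: notch-like", "hypothetical protein X",
                    "low quality protein: notch"))
  out <- filter_by_keywords(recs)
  expect_equal(out$kept$id, "r2")
  expect_setequal(out$rejected$id, c("r1", "r3", "r4", "r5"))
  expect_equal(out$rejected$reason[out$rejected$id == "r1"],
               "strawberry notch")
})

test_that("keyword filter validates patterns and records flags", {
  recs <- seq_records("r1", "ACDEF", description = "notch isoform X2")
  expect_error(filter_by_keywords(recs, exclude_patterns = "(unbalanced"),
               "invalid regular expression.*unbalanced")
  out <- filter_by_keywords(recs, flag_patterns = "isoform")
  expect_equal(out$kept$flags, "isoform")
})

test_that("reference screen keeps family members and rejects shuffles", {
  ref <- make_ancestor(scaled_roster()[5, ], seed = 3)$record
  # verbatim copy: normalized score exactly 1
  copy <- seq_records("q1", ref$residues)
  sc <- reference_screen(copy, ref)
  expect_equal(sc$scores, 1)
  expect_equal(sc$kept$id, "q1")

  # 100 seeded shuffles all fall below the default threshold
  set.seed(7)
  chars <- strsplit(ref$residues, "")[[1]]
  shuf <- vapply(1:100, function(i) paste(sample(chars), collapse = ""),
                 character(1))
  recs <- seq_records(sprintf("s%03d", 1:100), shuf)
  out <- reference_screen(recs, ref)
  expect_equal(nrow(out$kept), 0)
  expect_true(all(out$rejected$norm_score < 0.3))

  # 10% substitutions: clearly above threshold
  set.seed(8)
  idx <- sample(length(chars), round(0.1 * length(chars)))
  mut <- chars
  for (i in idx) mut[i] <- sample(setdiff(LETTERS[LETTERS %in% rownames(gonnet250(FALSE))],
                                          mut[i]), 1)
  out2 <- reference_screen(seq_records("m1", paste(mut, collapse = "")), ref)
  expect_equal(out2$kept$id, "m1")

  expect_error(reference_screen(copy, ref[0, ]), "empty reference")
})

test_that("dedup keeps the longest representative of each duplicate group", {
  a <- strrep("ACDEFGHIKL", 10)                      # 100 aa
  chars <- strsplit(a, "")[[1]]
  chars[c(10, 50, 90)] <- c("W", "W", "W")           # 3 substitutions
  b <- paste(chars, collapse = "")                   # identity 0.97
  recs <- seq_records(c("short", "long"), c(substr(b, 1, 100), a),
                      organism = "Homo sapiens")
  out <- dedup_by_identity(recs)
  expect_equal(out$kept$id, "long")
  expect_equal(out$removed_pairs$removed, "short")
  expect_gt(out$removed_pairs$identity, 0.95)

  # identical sequences, equal length: lexicographically smaller id kept
  recs2 <- seq_records(c("zz", "aa"), c(a, a), organism = "Homo sapiens")
  out2 <- dedup_by_identity(recs2)
  expect_equal(out2$kept$id, "aa")

  # identity 0.90 < threshold: both kept
  chars3 <- strsplit(a, "")[[1]]
  set.seed(1)
  pos <- sample(100, 10)
  for (i in pos) chars3[i] <- sample(setdiff(c("W", "Y", "H"), chars3[i]), 1)
  recs3 <- seq_records(c("x", "y"), c(a, paste(chars3, collapse = "")),
                       organism = "Homo sapiens")
  out3 <- dedup_by_identity(recs3)
  expect_equal(nrow(out3$kept), 2)

  # within-species mode never compares across organisms
  recs4 <- seq_records(c("h1", "m1"), c(a, a),
                       organism = c("Homo sapiens", "Mus musculus"))
  expect_equal(nrow(dedup_by_identity(recs4, within_species = TRUE)$kept), 2)
  expect_equal(nrow(dedup_by_identity(recs4, within_species = FALSE)$kept), 1)

  # empty input: empty output
  expect_equal(nrow(dedup_by_identity(recs4[0, ])$kept), 0)
})

test_that("curation recovers exactly the planted clean records on the benchmark", {
  bm <- scaled_bench()
  cur <- scaled_curation()
  truth <- bm$truth
  retained <- cur$records$id
  expect_true(all(truth$id[truth$role == "clean"] %in% retained))
  expect_true(all(truth$id[truth$role == "outgroup"] %in% retained))
  expect_false(any(truth$id[truth$role == "noise"] %in% retained))
  expect_false(any(truth$id[truth$role == "duplicate"] %in% retained))

  # report counts reconcile exactly and every rejection has one reason
  r <- cur$report
  expect_equal(r$n_input,
               r$n_retained + r$n_removed_by_keyword +
                 r$n_removed_by_reference_screen + r$n_removed_as_duplicates)
  expect_equal(sort(cur$rejections$id),
               sort(setdiff(bm$records$id, retained)))
  expect_false(anyDuplicated(cur$rejections$id) > 0)
  # duplicates are removed at the dedup stage, in favour of their source
  dup_ids <- truth$id[truth$role == "duplicate"]
  expect_setequal(cur$rejections$stage[cur$rejections$id %in% dup_ids],
                  "dedup")
})

test_that("dedup is deterministic under input reordering", {
  bm <- scaled_bench()
  recs <- bm$records[bm$records$id %in%
                       bm$truth$id[bm$truth$role %in% c("clean", "duplicate")], ]
  recs <- recs[recs$length < 200, ]     # small clades only, for speed
  class(recs) <- c("seq_records", "data.frame")
  out1 <- dedup_by_identity(recs)
  recs_rev <- recs[rev(seq_len(nrow(recs))), ]
  class(recs_rev) <- c("seq_records", "data.frame")
  out2 <- dedup_by_identity(recs_rev)
  expect_setequal(out1$kept$id, out2$kept$id)
})
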