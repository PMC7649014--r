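# Independent oracles used by the property and equivalence tests. These
# re-implement the checked operations from their definitions, on purpose
# sharing no code with the package internals.

# UPGMA by full rescan: cluster distance recomputed every step as the
# arithmetic mean over all member leaf pairs of the original matrix.
brute_upgma <- function(m) {
  labels <- rownames(m)
  n <- nrow(m)
  clusters <- lapply(seq_len(n), function(i) i)   # leaf indices
  ids <- -seq_len(n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    k <- length(clusters)
    best <- Inf; bi <- 0; bj <- 0
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        dd <- mean(m[clusters[[i]], clusters[[j]]])
        if (dd < best) { best <- dd; bi <- i; bj <- j }
      }
    }
    merge[step, ] <- c(ids[bi], ids[bj])
    height[step] <- best / 2
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    ids[bi] <- step
    clusters[[bj]] <- NULL
    ids <- ids[-bj]
  }
  structure(list(merge = merge, node_height = height, labels = labels,
                 support = NULL), class = "upgma_tree")
}

# naive backtracking motif matcher, minimal-first range expansion;
# returns the match length at position `start` or NA
naive_match_at <- function(chars, elements, start) {
  rec <- function(ei, pos) {
    if (ei > length(elements)) return(pos)   # one past the last consumed
    if (pos > length(chars) + 1) return(NA_integer_)
    e <- elements[[ei]]
    if (e$type == "fixed") {
      if (pos <= length(chars) && chars[pos] == e$residue)
        return(rec(ei + 1, pos + 1))
      return(NA_integer_)
    }
    if (e$type == "wild") {
      if (pos <= length(chars)) return(rec(ei + 1, pos + 1))
      return(NA_integer_)
    }
    if (e$type == "class") {
      if (pos <= length(chars) && chars[pos] %in% e$residues)
        return(rec(ei + 1, pos + 1))
      return(NA_integer_)
    }
    for (g in e$min:e$max) {             # minimal first
      if (pos + g - 1 > length(chars)) break
      r <- rec(ei + 1, pos + g)
      if (!is.na(r)) return(r)
    }
    NA_integer_
  }
  endpos <- rec(1, start)
  if (is.na(endpos)) NA_integer_ else endpos - start
}

naive_scan <- function(seqstr, pattern, allow_overlaps = TRUE) {
  chars <- strsplit(seqstr, "")[[1]]
  hits <- data.frame(start = integer(), end = integer())
  i <- 1L
  while (i <= length(chars)) {
    len <- naive_match_at(chars, pattern$elements, i)
    if (!is.na(len)) {
      hits <- rbind(hits, data.frame(start = i, end = i + len - 1L))
      i <- if (allow_overlaps) i + 1L else i + len
    } else {
      i <- i + 1L
    }
  }
  hits
}

random_protein <- function(n, alphabet = strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_dist_matrix <- function(n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, 0.05, 1)
  m <- m + t(m)
  dimnames(m) <- list(paste0("t", seq_len(n)), paste0("t", seq_len(n)))
  m
}

# scaled benchmark shared by several test files (built once per session)
.fixtures <- new.env()

scaled_bench <- function() {
  if (is.null(.fixtures$bm)) {
    ros <- scale_roster(canonical_roster(), 0.15)
    .fixtures$ros <- ros
    .fixtures$bm <- make_benchmark(ros, members_per_clade = 4, seed = 1)
  }
  .fixtures$bm
}

scaled_roster <- function() { scaled_bench(); .fixtures$ros }

scaled_core_msa <- function() {
  if (is.null(.fixtures$msa)) {
    bm <- scaled_bench()
    cur <- curate(bm$records, bm$references)
    core <- cur$records[
      !cur$records$id %in% bm$truth$id[bm$truth$role == "outgroup"], ]
    class(core) <- c("seq_records", "data.frame")
    .fixtures$cur <- cur
    .fixtures$core <- core
    .fixtures$msa <- align_sequences(core)
  }
  .fixtures$msa
}

scaled_curation <- function() { scaled_core_msa(); .fixtures$cur }
scaled_core <- function() { scaled_core_msa(); .fixtures$core }
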