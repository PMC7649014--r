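DEFAULT_EXCLUDE <- c("strawberry notch", "hypothetical", "partial",
                     "low quality", "PREDICTED", "synthetic construct")

check_patterns <- function(patterns) {
  for (p in patterns) {
    ok <- tryCatch({ grepl(p, "", ignore.case = TRUE, perl = TRUE); TRUE },
                   error = function(e) FALSE,
                   warning = function(w) FALSE)
    if (!ok) stop("invalid regular expression pattern: '", p, "'")
  }
  invisible(patterns)
}

#' Keyword/regular-expression header filter
#'
#' Records whose description matches any (case-insensitive) exclude
#' pattern are rejected; kept records have any matching flag patterns
#' recorded in their `flags` column.
#'
#' @param records a [seq_records] data frame.
#' @param exclude_patterns case-insensitive substring/regex rules; the
#'   defaults are the noise markers of NCBI Notch query hits.
#' @param flag_patterns patterns recorded as flags without rejecting.
#' @return list with `kept`, `rejected` (with a `reason` column).
#' @export
filter_by_keywords <- function(records, exclude_patterns = DEFAULT_EXCLUDE,
                               flag_patterns = character()) {
  check_patterns(c(exclude_patterns, flag_patterns))
  reason <- rep(NA_character_, nrow(records))
  for (p in exclude_patterns) {
    hit <- grepl(p, records$description, ignore.case = TRUE, perl = TRUE)
    reason[hit & is.na(reason)] <- p
  }
  kept <- records[is.na(reason), , drop = FALSE]
  if (length(flag_patterns) && nrow(kept)) {
    fl <- vapply(seq_len(nrow(kept)), function(i) {
      m <- flag_patterns[vapply(flag_patterns, function(p)
        grepl(p, kept$description[i], ignore.case = TRUE, perl = TRUE),
        logical(1))]
      paste(m, collapse = ";")
    }, character(1))
    kept$flags <- ifelse(nzchar(kept$flags) & nzchar(fl),
                         paste(kept$flags, fl, sep = ";"),
                         paste0(kept$flags, fl))
  }
  rejected <- records[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  rownames(kept) <- rownames(rejected) <- NULL
  class(kept) <- c("seq_records", "data.frame")
  list(kept = kept, rejected = rejected)
}

# best normalized local-alignment score of a record against references:
# score / self-score of the aligned reference segment
reference_norm_score <- function(residues, references, matrix, gap_open,
                                 gap_extend, stop_at = Inf) {
  best <- 0
  diagS <- diag(matrix[AA20, AA20])
  names(diagS) <- AA20
  for (r in seq_len(nrow(references))) {
    al <- pairwise_align(residues, references$residues[r], matrix,
                         gap_open, gap_extend, "local")
    if (al$score <= 0) next
    ref_pos <- al$bi[al$bi != 0L]
    if (!length(ref_pos)) next
    seg <- strsplit(substr(references$residues[r], min(ref_pos),
                           max(ref_pos)), "")[[1]]
    self <- sum(diagS[seg[seg %in% AA20]])
    if (self <= 0) next
    best <- max(best, al$score / self)
    if (best >= stop_at) return(best)
  }
  best
}

#' Reference-sequence local-alignment screen
#'
#' Each record is locally aligned (affine-gap Smith-Waterman, Gonnet-family
#' matrix) against every reference; a record is kept iff its best
#' `score / self-score of the aligned reference segment` reaches
#' `min_norm_score`.
#'
#' @param records a [seq_records] data frame.
#' @param references a small curated [seq_records] set of family exemplars.
#' @param min_norm_score normalized-score threshold in (0, 1].
#' @inheritParams pairwise_align
#' @return list with `kept`, `rejected` (with `reason` and `norm_score`).
#' @export
reference_screen <- function(records, references, min_norm_score = 0.3,
                             matrix = NULL, gap_open = 10, gap_extend = 0.5) {
  if (is.null(references) || nrow(references) == 0)
    stop("empty reference set")
  if (is.null(matrix)) matrix <- gonnet250()
  scores <- vapply(seq_len(nrow(records)), function(i)
    reference_norm_score(records$residues[i], references, matrix,
                         gap_open, gap_extend, stop_at = min_norm_score),
    numeric(1))
  ok <- scores >= min_norm_score
  kept <- records[ok, , drop = FALSE]
  rejected <- records[!ok, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reason <- "below reference screen threshold"
    rejected$norm_score <- scores[!ok]
  }
  rownames(kept) <- rownames(rejected) <- NULL
  class(kept) <- c("seq_records", "data.frame")
  list(kept = kept, rejected = rejected, scores = scores)
}

# global-alignment identity: matches / aligned columns (dual-gap columns
# cannot occur in a pairwise alignment)
pair_identity <- function(a, b, matrix, gap_open, gap_extend) {
  pairwise_align(a, b, matrix, gap_open, gap_extend, "global")$identity
}

#' Remove near-duplicate sequences
#'
#' Greedy sweep in descending length order (ties by id): a record is
#' removed if its global-alignment identity to any already-kept record
#' reaches `threshold`, so each near-duplicate group retains its longest
#' representative. With `within_species = TRUE` only records with the same
#' organism are compared.
#'
#' @param records a [seq_records] data frame.
#' @param threshold identity threshold in (0, 1]; default 0.95.
#' @param within_species compare only within the same organism.
#' @inheritParams pairwise_align
#' @return list with `kept`, `removed_pairs` (removed id, kept id,
#'   identity).
#' @export
dedup_by_identity <- function(records, threshold = 0.95,
                              within_species = TRUE, matrix = NULL,
                              gap_open = 10, gap_extend = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  if (is.null(matrix)) matrix <- gonnet250()
  if (nrow(records) == 0)
    return(list(kept = records,
                removed_pairs = data.frame(removed = character(),
                                           kept = character(),
                                           identity = numeric())))
  ord <- order(-records$length, records$id)
  kept_idx <- integer()
  removed <- data.frame(removed = character(), kept = character(),
                        identity = numeric(), stringsAsFactors = FALSE)
  for (i in ord) {
    dup_of <- NA_integer_
    ident <- NA_real_
    for (k in kept_idx) {
      if (within_species &&
          !identical(records$organism[i], records$organism[k])) next
      v <- pair_identity(records$residues[i], records$residues[k],
                         matrix, gap_open, gap_extend)
      if (v >= threshold) { dup_of <- k; ident <- v; break }
    }
    if (is.na(dup_of)) {
      kept_idx <- c(kept_idx, i)
    } else {
      removed <- rbind(removed,
                       data.frame(removed = records$id[i],
                                  kept = records$id[dup_of],
                                  identity = ident,
                                  stringsAsFactors = FALSE))
    }
  }
  kept <- records[sort(kept_idx), , drop = FALSE]
  rownames(kept) <- NULL
  class(kept) <- c("seq_records", "data.frame")
  list(kept = kept, removed_pairs = removed)
}

#' Three-stage curation pipeline
#'
#' Fixed order: keyword filter, reference local-alignment screen,
#' identity deduplication. Every removed record carries exactly one
#' rejection reason (its first failing stage) and the report counts
#' reconcile exactly with the input.
#'
#' @inheritParams filter_by_keywords
#' @inheritParams reference_screen
#' @inheritParams dedup_by_identity
#' @return list of class `curation_result`: `records` (retained),
#'   `report` (counts), `rejections` (id, stage, reason).
#' @export
curate <- function(records, references, exclude_patterns = DEFAULT_EXCLUDE,
                   flag_patterns = character(), min_norm_score = 0.3,
                   threshold = 0.95, within_species = TRUE, matrix = NULL,
                   gap_open = 10, gap_extend = 0.5) {
  s1 <- filter_by_keywords(records, exclude_patterns, flag_patterns)
  s2 <- reference_screen(s1$kept, references, min_norm_score, matrix,
                         gap_open, gap_extend)
  s3 <- dedup_by_identity(s2$kept, threshold, within_species, matrix,
                          gap_open, gap_extend)
  rejections <- rbind(
    if (nrow(s1$rejected))
      data.frame(id = s1$rejected$id, stage = "keyword",
                 reason = s1$rejected$reason, stringsAsFactors = FALSE),
    if (nrow(s2$rejected))
      data.frame(id = s2$rejected$id, stage = "reference_screen",
                 reason = sprintf("norm score %.3f < threshold",
                                  s2$rejected$norm_score),
                 stringsAsFactors = FALSE),
    if (nrow(s3$removed_pairs))
      data.frame(id = s3$removed_pairs$removed, stage = "dedup",
                 reason = sprintf("identity %.3f to %s",
                                  s3$removed_pairs$identity,
                                  s3$removed_pairs$kept),
                 stringsAsFactors = FALSE))
  if (is.null(rejections))
    rejections <- data.frame(id = character(), stage = character(),
                             reason = character(), stringsAsFactors = FALSE)
  report <- list(n_input = nrow(records),
                 n_removed_by_keyword = nrow(s1$rejected),
                 n_removed_by_reference_screen = nrow(s2$rejected),
                 n_removed_as_duplicates = nrow(s3$removed_pairs),
                 n_retained = nrow(s3$kept))
  stopifnot(report$n_input == report$n_retained +
              report$n_removed_by_keyword +
              report$n_removed_by_reference_screen +
              report$n_removed_as_duplicates)
  structure(list(records = s3$kept, report = report,
                 rejections = rejections),
            class = "curation_result")
}

#' @export
print.curation_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0("curation: %d input -> %d retained ",
                     "(%d keyword, %d reference screen, %d duplicates removed)\n"),
              r$n_input, r$n_retained, r$n_removed_by_keyword,
              r$n_removed_by_reference_screen, r$n_removed_as_duplicates))
  invisible(x)
}
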