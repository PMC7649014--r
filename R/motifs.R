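#' Compile a motif pattern string
#'
#' Grammar (PROSITE-like): uppercase residues are fixed positions; `X` is a
#' wildcard matching any single residue (including an input `X` ambiguity
#' character); `[FY]` is a residue class; `x(m,n)` is a gap range matching
#' between m and n arbitrary residues; `-` may separate elements. Fixed
#' positions and classes are *not* satisfied by an input `X`.
#'
#' @param pattern_string e.g. `"CXNGGXC"`, `"CXCXXG[FY]XG"`,
#'   `"C-x(2,14)-C"`.
#' @param label optional source label (`"A"`, `"B"`, ...).
#' @return an object of class `motif_pattern`.
#' @export
compile_motif <- function(pattern_string, label = "custom") {
  s <- pattern_string
  elements <- list()
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "-") { i <- i + 1L; next }
    if (ch == "X") {
      elements[[length(elements) + 1L]] <- list(type = "wild")
      i <- i + 1L
    } else if (ch == "x") {
      rest <- substr(s, i, n)
      m <- regmatches(rest, regexec("^x\\((\\d+),(\\d+)\\)", rest))[[1]]
      if (!length(m))
        stop(sprintf("malformed gap range at column %d of '%s'", i, s))
      lo <- as.integer(m[2]); hi <- as.integer(m[3])
      if (lo > hi)
        stop(sprintf("gap range min > max at column %d of '%s'", i, s))
      elements[[length(elements) + 1L]] <- list(type = "range", min = lo,
                                                max = hi)
      i <- i + nchar(m[1])
    } else if (ch == "[") {
      close <- regexpr("]", substr(s, i, n), fixed = TRUE)
      if (close < 0)
        stop(sprintf("unterminated class at column %d of '%s'", i, s))
      body <- substr(s, i + 1L, i + close - 2L)
      if (!nzchar(body) || grepl(sprintf("[^%s]", paste(AA20, collapse = "")), body))
        stop(sprintf("malformed class at column %d of '%s'", i, s))
      elements[[length(elements) + 1L]] <-
        list(type = "class", residues = strsplit(body, "")[[1]])
      i <- i + close
    } else if (ch %in% AA20) {
      elements[[length(elements) + 1L]] <- list(type = "fixed", residue = ch)
      i <- i + 1L
    } else {
      stop(sprintf("unexpected character '%s' at column %d of '%s'", ch, i, s))
    }
  }
  if (!length(elements)) stop("empty motif pattern")
  structure(list(elements = elements, label = label, source = pattern_string),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("motif pattern %s: %s (%d elements)\n", x$label, x$source,
              length(x$elements)))
  invisible(x)
}

# regex translation; gap ranges are matched minimally (lazy), which is the
# scanning policy that parses tandem repeats unit by unit
motif_regex <- function(pattern) {
  paste(vapply(pattern$elements, function(e) {
    switch(e$type,
           fixed = e$residue,
           wild = ".",
           class = paste0("[", paste(e$residues, collapse = ""), "]"),
           range = sprintf(".{%d,%d}?", e$min, e$max))
  }, character(1)), collapse = "")
}

motif_length_range <- function(pattern) {
  lens <- vapply(pattern$elements, function(e)
    if (e$type == "range") c(e$min, e$max) else c(1L, 1L), numeric(2))
  c(sum(lens[1, ]), sum(lens[2, ]))
}

#' Scan a sequence for motif occurrences
#'
#' Matches are located left to right. With `allow_overlaps = TRUE` every
#' starting position is examined (one, minimally-expanded, match per
#' start); otherwise matches are non-overlapping, each next search
#' resuming after the previous match.
#'
#' @param record a [seq_records] row (or plain residue string).
#' @param pattern a [compile_motif()] pattern (or pattern string).
#' @param allow_overlaps report overlapping hits?
#' @return data frame of hits: `id`, `label`, `start`, `end` (1-based,
#'   inclusive), `match`.
#' @export
scan_motif <- function(record, pattern, allow_overlaps = TRUE) {
  if (is.character(pattern)) pattern <- compile_motif(pattern)
  if (is.character(record)) {
    id <- "seq"; seqs <- record
  } else {
    id <- record$id; seqs <- record$residues
  }
  stopifnot(length(seqs) == 1L)
  rx <- paste0("(?=(", motif_regex(pattern), "))")
  m <- gregexpr(rx, seqs, perl = TRUE)[[1]]
  empty <- data.frame(id = character(), label = character(),
                      start = integer(), end = integer(),
                      match = character(), stringsAsFactors = FALSE)
  if (m[1] == -1) return(empty)
  starts <- as.integer(attr(m, "capture.start")[, 1])
  lens <- as.integer(attr(m, "capture.length")[, 1])
  if (!allow_overlaps) {
    keep <- logical(length(starts))
    last_end <- 0L
    for (i in seq_along(starts)) {
      if (starts[i] > last_end) {
        keep[i] <- TRUE
        last_end <- starts[i] + lens[i] - 1L
      }
    }
    starts <- starts[keep]; lens <- lens[keep]
  }
  data.frame(id = id, label = pattern$label, start = starts,
             end = starts + lens - 1L,
             match = substring(seqs, starts, starts + lens - 1L),
             stringsAsFactors = FALSE)
}

#' Built-in conserved Notch-family motif patterns
#'
#' Motifs A (`CXNGGXC`) and B (`CXCXXG[FY]XG`) are the conserved EGF-internal
#' patterns; C, D and E are configurable placeholders for the additional
#' family motifs whose exact residues are published only as figure images -
#' they are marked experimental and meant to be overridden.
#'
#' @return named list of [compile_motif()] patterns.
#' @export
notch_motifs <- function() {
  pats <- list(
    A = compile_motif("CXNGGXC", "A"),
    B = compile_motif("CXCXXG[FY]XG", "B"),
    C = compile_motif("NXGSXXN", "C"),
    D = compile_motif("WNXGGXW", "D"),
    E = compile_motif("PXPXXTE", "E")
  )
  for (l in c("C", "D", "E")) attr(pats[[l]], "experimental") <- TRUE
  pats
}

#' The EGF-like repeat cysteine-spacing grammar
#'
#' Six cysteines with the inter-cysteine spacing bounds used by
#' [find_egf_repeats()]. Bounds accept the canonical synthetic unit and
#' typical EGF spacings.
#'
#' @return the pattern string.
#' @export
egf_grammar <- function() "C-x(2,14)-C-x(1,10)-C-x(1,6)-C-x(2,14)-C-x(1,8)-C"

#' Locate EGF-like repeats by cysteine spacing
#'
#' Non-overlapping, left-to-right matches of the six-cysteine spacing
#' grammar [egf_grammar()]. Each repeat records its six cysteine positions;
#' the canonical disulfide pairing is reported as (1-3, 2-4, 5-6).
#'
#' @param record a [seq_records] row or residue string.
#' @return data frame: `id`, `kind`, `start`, `end`, `cys` (comma-separated
#'   six cysteine positions), `disulfides`, `is_calcium_binding` (NA until
#'   classified).
#' @export
find_egf_repeats <- function(record) {
  pat <- compile_motif(egf_grammar(), "EGF")
  hits <- scan_motif(record, pat, allow_overlaps = FALSE)
  if (!nrow(hits))
    return(data.frame(id = character(), kind = character(),
                      start = integer(), end = integer(), cys = character(),
                      disulfides = character(),
                      is_calcium_binding = logical(),
                      stringsAsFactors = FALSE))
  seqs <- if (is.character(record)) record else record$residues
  cys_rx <- "^(C)(.{2,14}?)(C)(.{1,10}?)(C)(.{1,6}?)(C)(.{2,14}?)(C)(.{1,8}?)(C)$"
  cys <- vapply(seq_len(nrow(hits)), function(i) {
    frag <- hits$match[i]
    m <- regexec(cys_rx, frag)[[1]]
    st <- as.integer(m[-1])                  # group starts within fragment
    pos <- hits$start[i] - 1L + st[c(1, 3, 5, 7, 9, 11)]
    paste(pos, collapse = ",")
  }, character(1))
  data.frame(id = hits$id, kind = "EGF", start = hits$start, end = hits$end,
             cys = cys, disulfides = "1-3,2-4,5-6",
             is_calcium_binding = NA,
             stringsAsFactors = FALSE)
}

#' Classify an EGF-like repeat as calcium-binding
#'
#' A repeat is called calcium-binding when the five residues preceding its
#' first cysteine contain the surrogate consensus `[DN]-x-[DN]-[EQ]`
#' (aspartate/asparagine-rich flank). Repeats with fewer than 4 flanking
#' residues are called `FALSE`.
#'
#' @param record the [seq_records] row or string the repeat came from.
#' @param rep_row one row of [find_egf_repeats()] output.
#' @return logical flag.
#' @export
classify_cbEGF <- function(record, rep_row) {
  seqs <- if (is.character(record)) record else record$residues
  first_cys <- as.integer(strsplit(rep_row$cys, ",")[[1]][1])
  if (first_cys <= 4L) return(FALSE)
  flank <- substr(seqs, max(1L, first_cys - 5L), first_cys - 1L)
  grepl("[DN].[DN][EQ]", flank)
}

#' Digital calcium-binding signature of a sequence
#'
#' EGF-like repeats are called N- to C-terminal; each contributes `1` if
#' calcium-binding ([classify_cbEGF()]) else `0`.
#'
#' @param record a [seq_records] row or residue string.
#' @return a bit string (possibly empty).
#' @export
digital_signature <- function(record) {
  reps <- find_egf_repeats(record)
  if (!nrow(reps)) return("")
  bits <- vapply(seq_len(nrow(reps)), function(i)
    classify_cbEGF(record, reps[i, ]), logical(1))
  paste(as.integer(bits), collapse = "")
}

#' Discover conserved motifs from an alignment
#'
#' Each column is symbolized from its conservation profile: a fixed residue
#' when the modal gap-excluded frequency reaches `invariant_tau`; a
#' two-residue class when the top-2 cumulative frequency reaches
#' `class_tau` (and the column is not invariant); otherwise a wildcard.
#' Columns gappier than 50% are wildcards. Reported patterns are the
#' maximal windows of at least `min_len` columns that start and end on a
#' non-wildcard column and contain no wildcard run longer than
#' `max_wildcard_run`.
#'
#' @param msa a [protein_msa].
#' @param invariant_tau modal-frequency threshold for a fixed position.
#' @param class_tau top-2 cumulative threshold for a residue class.
#' @param min_len minimum window length.
#' @param max_wildcard_run longest tolerated internal wildcard run.
#' @return list of [compile_motif()] patterns, each with attributes
#'   `start_col`/`end_col` giving the alignment window.
#' @export
discover_conserved_motifs <- function(msa, invariant_tau = 0.95,
                                      class_tau = 0.95, min_len = 7,
                                      max_wildcard_run = 2) {
  stopifnot(invariant_tau > 0.5, invariant_tau <= 1,
            class_tau > 0.5, class_tau <= 1)
  prof <- conservation_profile(msa)
  sym <- vapply(seq_len(nrow(prof)), function(j) {
    p <- prof[j, ]
    if (is.na(p$modal) || p$gap_fraction > 0.5 || p$modal == "X") return("X")
    if (p$modal_freq >= invariant_tau) return(p$modal)
    if (p$top2_freq >= class_tau && nchar(p$top2) == 2) {
      cls <- sort(strsplit(p$top2, "")[[1]])
      return(paste0("[", cls[1], cls[2], "]"))
    }
    "X"
  }, character(1))
  is_wild <- sym == "X"
  # split at wildcard runs longer than max_wildcard_run
  run <- rle(is_wild)
  breaks <- rep(run$values & run$lengths > max_wildcard_run, run$lengths)
  # fragment index increments at the start of every break block
  frag <- cumsum(breaks & !c(FALSE, breaks[-length(breaks)]))
  frag[breaks] <- NA
  out <- list()
  for (f in unique(frag[!is.na(frag)])) {
    cols <- which(!is.na(frag) & frag == f)
    nw <- cols[!is_wild[cols]]
    if (!length(nw)) next
    cols <- seq(min(nw), max(nw))
    if (length(cols) < min_len) next
    pat <- paste(sym[cols], collapse = "")
    mp <- compile_motif(pat, "discovered")
    attr(mp, "start_col") <- min(cols)
    attr(mp, "end_col") <- max(cols)
    out[[length(out) + 1L]] <- mp
  }
  out
}
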