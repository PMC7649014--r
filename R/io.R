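#' Construct a set of sequence records
#'
#' A sequence record set is a plain `data.frame` with one row per protein:
#' columns `id` (accession), `description`, `organism`, `residues`
#' (uppercase, gap-free, 20-letter alphabet plus `X`), `length` and `flags`
#' (semicolon-separated noise markers, `""` if none).
#'
#' @param id character vector of unique accessions.
#' @param residues character vector of amino-acid strings.
#' @param description free-text descriptions.
#' @param organism species names (may be empty strings).
#' @param flags noise markers, semicolon-separated.
#' @return a `data.frame` of class `seq_records`.
#' @export
seq_records <- function(id, residues, description = "", organism = "",
                        flags = "") {
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (length(id) == 0L) {
    out <- data.frame(id = character(), description = character(),
                      organism = character(), residues = character(),
                      length = integer(), flags = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("seq_records", "data.frame")
    return(out)
  }
  if (anyDuplicated(id))
    stop("duplicate sequence id: ", id[duplicated(id)][1])
  bad <- regexpr(sprintf("[^%s]", paste(AAX, collapse = "")), residues)
  if (any(bad > 0)) {
    w <- which(bad > 0)[1]
    stop(sprintf("record '%s' has a non-amino-acid character at position %d",
                 id[w], bad[w]))
  }
  out <- data.frame(id = id,
                    description = rep_len(as.character(description), length(id)),
                    organism = rep_len(as.character(organism), length(id)),
                    residues = residues,
                    length = nchar(residues),
                    flags = rep_len(as.character(flags), length(id)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("seq_records", "data.frame")
  out
}

#' Parse an NCBI-style FASTA defline
#'
#' The accession is the first whitespace token, the organism is the content
#' of the *last* bracketed `[...]` group when present (NCBI convention), and
#' the description is everything else.
#'
#' @param raw_header header text without the leading `>`.
#' @return a list with `raw`, `accession`, `description`, `organism`.
#' @export
parse_defline <- function(raw_header) {
  raw_header <- trimws(raw_header)
  if (!nzchar(raw_header)) stop("empty FASTA header")
  accession <- sub("\\s.*$", "", raw_header)
  rest <- trimws(sub("^\\S+\\s*", "", raw_header))
  organism <- ""
  m <- gregexpr("\\[([^][]*)\\]", rest)[[1]]
  if (m[1] != -1) {
    k <- length(m)
    start <- m[k]
    len <- attr(m, "match.length")[k]
    organism <- substr(rest, start + 1L, start + len - 2L)
    rest <- trimws(paste0(substr(rest, 1L, start - 1L),
                          substr(rest, start + len, nchar(rest))))
  }
  list(raw = raw_header, accession = accession, description = rest,
       organism = organism)
}

format_defline <- function(id, description, organism) {
  h <- id
  if (nzchar(description)) h <- paste(h, description)
  if (nzchar(organism)) h <- paste0(h, " [", organism, "]")
  h
}

#' Read a protein FASTA file
#'
#' Residues are uppercased and a single terminal `*` stop is stripped.
#' Deflines are parsed into accession / description / organism.
#'
#' @param path path to a FASTA file.
#' @return a [seq_records] data frame, one row per entry, in file order.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("malformed FASTA (no leading '>'): ", path)
  grp <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  seqs <- seqs[as.character(seq_along(headers))]
  seqs[is.na(seqs)] <- ""
  seqs <- toupper(gsub("\\s", "", unname(seqs)))
  seqs <- sub("\\*$", "", seqs)
  parsed <- lapply(headers, parse_defline)
  seq_records(id = vapply(parsed, `[[`, "", "accession"),
              residues = seqs,
              description = vapply(parsed, `[[`, "", "description"),
              organism = vapply(parsed, `[[`, "", "organism"))
}

#' Write sequence records to FASTA
#'
#' @param records a [seq_records] data frame.
#' @param path output path.
#' @param wrap line width for sequence wrapping.
#' @export
write_fasta <- function(records, path, wrap = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", format_defline(records$id[i],
                                          records$description[i],
                                          records$organism[i])), con)
    s <- records$residues[i]
    starts <- seq(1L, max(nchar(s), 1L), by = wrap)
    writeLines(substring(s, starts, pmin(starts + wrap - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a gapped (aligned) FASTA file as a multiple alignment
#'
#' @param path path to an aligned FASTA file (`-` gaps).
#' @return a [protein_msa].
#' @export
read_alignment_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty alignment file: ", path)
  hdr <- grepl("^>", lines)
  grp <- cumsum(hdr)
  ids <- vapply(sub("^>", "", lines[hdr]),
                function(h) parse_defline(h)$accession, character(1))
  rows <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  protein_msa(unname(ids), unname(rows[as.character(seq_along(ids))]))
}

quote_newick_label <- function(x) {
  needs <- grepl("[][ \t():;,']", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Write an ultrametric tree in Newick format
#'
#' Branch lengths are parent height minus child height; bootstrap supports,
#' when present and requested, are written as internal-node labels. Labels
#' containing spaces or Newick metacharacters are quoted.
#'
#' @param tree an [upgma()] tree.
#' @param path output path; `NULL` returns the Newick string.
#' @param with_supports write per-node bootstrap supports as labels.
#' @export
write_newick <- function(tree, path = NULL, with_supports = FALSE) {
  stopifnot(inherits(tree, "upgma_tree"))
  n <- length(tree$labels)
  if (n < 2) stop("tree must have at least 2 leaves")
  if (anyDuplicated(tree$labels)) stop("duplicate leaf labels")
  hts <- tree$node_height
  labs <- quote_newick_label(tree$labels)
  sup <- tree$support
  fmt <- function(x) sprintf("%.10g", x)
  render <- function(k, is_root = FALSE) {
    # k: negative = leaf index, positive = merge index
    if (k < 0) {
      list(text = labs[-k], h = 0)
    } else {
      l <- render(tree$merge[k, 1])
      r <- render(tree$merge[k, 2])
      h <- hts[k]
      if (h < l$h - 1e-12 || h < r$h - 1e-12)
        stop("non-ultrametric heights: child above parent")
      lab <- if (!is_root && with_supports && !is.null(sup) &&
                 !is.na(sup[k])) fmt(sup[k]) else ""
      list(text = paste0("(", l$text, ":", fmt(h - l$h), ",",
                         r$text, ":", fmt(h - r$h), ")", lab),
           h = h)
    }
  }
  txt <- paste0(render(nrow(tree$merge), is_root = TRUE)$text, ";")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Write an alignment in Clustal-like format for human inspection
#'
#' @param msa a [protein_msa] alignment.
#' @param path output path.
#' @param width block width.
#' @export
write_clustal <- function(msa, path, width = 60) {
  stopifnot(inherits(msa, "protein_msa"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("CLUSTAL-like multiple sequence alignment (notchfam)", ""), con)
  nc <- msa_ncol(msa)
  ids <- formatC(msa$ids, width = max(nchar(msa$ids)) + 2, flag = "-")
  for (s in seq(1L, nc, by = width)) {
    e <- min(s + width - 1L, nc)
    writeLines(paste0(ids, substring(msa$rows, s, e)), con)
    writeLines("", con)
  }
  invisible(path)
}
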