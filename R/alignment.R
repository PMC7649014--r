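#' Multiple alignment container
#'
#' @param ids row identifiers.
#' @param rows equal-length gapped residue strings (`-` gaps).
#' @return an object of class `protein_msa`.
#' @export
protein_msa <- function(ids, rows) {
  ids <- as.character(ids)
  rows <- as.character(rows)
  stopifnot(length(ids) == length(rows))
  if (length(rows) && length(unique(nchar(rows))) != 1L)
    stop("alignment rows differ in length")
  structure(list(ids = ids, rows = setNames(rows, ids)),
            class = "protein_msa")
}

#' @export
print.protein_msa <- function(x, ...) {
  cat(sprintf("protein_msa: %d sequences x %d columns\n",
              length(x$ids), msa_ncol(x)))
  invisible(x)
}

#' Number of alignment columns
#' @param msa a [protein_msa].
#' @export
msa_ncol <- function(msa) if (length(msa$rows)) nchar(msa$rows[[1]]) else 0L

#' Alignment as a character matrix (rows = sequences)
#' @param x a [protein_msa].
#' @param ... unused.
#' @export
as.matrix.protein_msa <- function(x, ...) {
  m <- do.call(rbind, strsplit(unname(x$rows), ""))
  rownames(m) <- x$ids
  m
}

degap <- function(x) gsub("-", "", x, fixed = TRUE)

msa_codes <- function(msa) {
  m <- as.matrix(msa)
  codes <- match(m, AAX)          # gaps -> NA
  dim(codes) <- dim(m)
  rownames(codes) <- msa$ids
  codes
}

# turn an alignment path (index vectors with 0 = gap) into gapped strings
path_to_strings <- function(a, b, ai, bi) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  ga <- ifelse(ai == 0L, "-", ca[pmax(ai, 1L)])
  gb <- ifelse(bi == 0L, "-", cb[pmax(bi, 1L)])
  list(a = paste(ga, collapse = ""), b = paste(gb, collapse = ""))
}

#' Optimal pairwise alignment with affine gap penalties
#'
#' Dynamic-programming alignment under a substitution matrix (default the
#' Gonnet-250 family matrix) with affine gap penalties: a gap of length L
#' costs `gap_open + gap_extend * L`. Traceback ties are resolved
#' diagonal > up > left, so the result is deterministic.
#'
#' @param a,b amino-acid strings (may contain `X`, which scores 0).
#' @param matrix substitution matrix; defaults to [gonnet250()].
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @param mode `"global"` (Needleman-Wunsch) or `"local"` (Smith-Waterman).
#' @return a list of class `pairwise_alignment` with `aligned_a`,
#'   `aligned_b`, `score` and `identity` (matches / aligned columns).
#' @export
pairwise_align <- function(a, b, matrix = NULL, gap_open = 10,
                           gap_extend = 0.5, mode = c("global", "local")) {
  mode <- match.arg(mode)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  if (is.null(matrix)) matrix <- gonnet250()
  res <- align_pair_cpp(encode_residues(a), encode_residues(b), matrix,
                        gap_open, gap_extend, mode == "local")
  g <- path_to_strings(a, b, res$ai, res$bi)
  ca <- strsplit(g$a, "")[[1]]
  cb <- strsplit(g$b, "")[[1]]
  ncols <- length(ca)
  ident <- if (ncols) sum(ca == cb & ca != "-") / ncols else 0
  structure(list(aligned_a = g$a, aligned_b = g$b, score = res$score,
                 identity = ident, ai = res$ai, bi = res$bi, mode = mode),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("%s pairwise alignment, score %.2f, identity %.3f\n",
              x$mode, x$score, x$identity))
  cat(x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Pairwise difference distance
#'
#' Globally aligns two sequences and returns the fraction of mismatching
#' columns among columns where neither sequence is gapped (p-distance).
#'
#' @inheritParams pairwise_align
#' @return a number in `[0, 1]`.
#' @export
pairwise_distance <- function(a, b, matrix = NULL, gap_open = 10,
                              gap_extend = 0.5) {
  al <- pairwise_align(a, b, matrix, gap_open, gap_extend, "global")
  ca <- strsplit(al$aligned_a, "")[[1]]
  cb <- strsplit(al$aligned_b, "")[[1]]
  comp <- ca != "-" & cb != "-"
  if (!any(comp)) stop("no comparable (ungapped) columns between the pair")
  sum(ca[comp] != cb[comp]) / sum(comp)
}

#' Pairwise p-distance matrix of unaligned sequences
#'
#' Used for the progressive-alignment guide tree ("differences between each
#' pair of sequences" after Gonnet-scored pairwise alignment).
#'
#' @param records a [seq_records] data frame.
#' @inheritParams pairwise_align
#' @return a [dist_matrix] of kind `p_distance`.
#' @export
guide_distances <- function(records, matrix = NULL, gap_open = 10,
                            gap_extend = 0.5) {
  n <- nrow(records)
  m <- matrix(0, n, n, dimnames = list(records$id, records$id))
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        d <- pairwise_distance(records$residues[i], records$residues[j],
                               matrix, gap_open, gap_extend)
        m[i, j] <- d
        m[j, i] <- d
      }
    }
  }
  dist_matrix(m, kind = "p_distance")
}

#' Neighbour-joining guide tree
#'
#' Standard NJ on a pairwise distance matrix; negative branch lengths are
#' clamped to zero and the unrooted tree is midpoint-rooted so that it can
#' order profile merges in the progressive alignment.
#'
#' @param dm a [dist_matrix] (or plain symmetric matrix with dimnames).
#' @return a rooted `phylo` tree (ape).
#' @export
nj_guide_tree <- function(dm) {
  m <- if (inherits(dm, "dist_matrix")) dm$matrix else as.matrix(dm)
  if (any(is.na(m)) || any(!is.finite(m))) stop("NaN/non-finite distances")
  if (any(m < 0)) stop("negative distances")
  n <- nrow(m)
  if (n < 2) stop("need at least 2 taxa")
  labs <- rownames(m)
  if (n == 2) {
    txt <- sprintf("(%s:%g,%s:%g);", labs[1], m[1, 2] / 2,
                   labs[2], m[1, 2] / 2)
    return(ape::read.tree(text = txt))
  }
  tr <- ape::nj(stats::as.dist(m))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr <- phangorn::midpoint(tr)
  # midpoint() may leave a multichotomy; force binary for profile merging
  tr <- ape::multi2di(tr, random = FALSE)
  tr
}

#' Progressive multiple sequence alignment
#'
#' Post-order profile-profile alignment over a rooted guide tree. Profile
#' columns are scored by the frequency-weighted average substitution score;
#' gaps, once inserted, are never removed. Row order equals input order.
#'
#' @param records a [seq_records] data frame.
#' @param guide_tree rooted `phylo`; when `NULL`, built with
#'   [guide_distances()] + [nj_guide_tree()].
#' @inheritParams pairwise_align
#' @return a [protein_msa].
#' @export
progressive_msa <- function(records, guide_tree = NULL, matrix = NULL,
                            gap_open = 10, gap_extend = 0.5) {
  if (nrow(records) < 1) stop("no sequences to align")
  if (is.null(matrix)) matrix <- gonnet250()
  core <- matrix[AA20, AA20]
  if (nrow(records) == 1)
    return(protein_msa(records$id, records$residues))
  if (is.null(guide_tree))
    guide_tree <- nj_guide_tree(guide_distances(records, matrix,
                                                gap_open, gap_extend))
  if (!setequal(guide_tree$tip.label, records$id))
    stop("guide tree leaves do not match record ids")
  codes <- lapply(records$residues, encode_residues)
  names(codes) <- records$id

  align_node <- function(node) {
    ntip <- length(guide_tree$tip.label)
    if (node <= ntip) {
      id <- guide_tree$tip.label[node]
      return(list(ids = id,
                  aln = matrix(codes[[id]], nrow = 1)))
    }
    kids <- guide_tree$edge[guide_tree$edge[, 1] == node, 2]
    acc <- align_node(kids[1])
    for (k in kids[-1]) {
      nxt <- align_node(k)
      pa <- profile_from_codes_cpp(acc$aln, 20L)
      pb <- profile_from_codes_cpp(nxt$aln, 20L)
      res <- align_profile_cpp(pa, pb, core, gap_open, gap_extend)
      na <- ncol(acc$aln); nb <- ncol(nxt$aln)
      left <- matrix(NA_integer_, nrow(acc$aln), length(res$ai))
      left[, res$ai != 0L] <- acc$aln[, res$ai[res$ai != 0L], drop = FALSE]
      right <- matrix(NA_integer_, nrow(nxt$aln), length(res$bi))
      right[, res$bi != 0L] <- nxt$aln[, res$bi[res$bi != 0L], drop = FALSE]
      acc <- list(ids = c(acc$ids, nxt$ids), aln = rbind(left, right))
    }
    acc
  }
  root <- length(guide_tree$tip.label) + 1L
  res <- align_node(root)
  rows <- apply(res$aln, 1, function(r) {
    r2 <- ifelse(is.na(r), "-", AAX[r])
    paste(r2, collapse = "")
  })
  ord <- match(records$id, res$ids)
  msa <- protein_msa(records$id, rows[ord])
  attr(msa, "guide_tree") <- guide_tree
  msa
}

#' One-call alignment of a record set
#'
#' Convenience wrapper: Gonnet pairwise p-distances, NJ guide tree, then
#' progressive profile alignment.
#'
#' @inheritParams progressive_msa
#' @export
align_sequences <- function(records, matrix = NULL, gap_open = 10,
                            gap_extend = 0.5) {
  dm <- guide_distances(records, matrix, gap_open, gap_extend)
  tr <- if (nrow(records) >= 2) nj_guide_tree(dm) else NULL
  msa <- progressive_msa(records, tr, matrix, gap_open, gap_extend)
  attr(msa, "guide_distances") <- dm
  msa
}

#' Per-column conservation profile of an alignment
#'
#' For each column: the modal (gap-excluded) residue and its frequency, the
#' top-2 residues with their cumulative frequency, and the gap fraction.
#' Ties are broken alphabetically. All-gap columns carry `NA` residues.
#'
#' @param msa a [protein_msa].
#' @return a data frame with one row per column.
#' @export
conservation_profile <- function(msa) {
  m <- as.matrix(msa)
  if (!nrow(m)) stop("empty alignment")
  nr <- nrow(m)
  res <- lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    gaps <- col == "-"
    resd <- col[!gaps]
    if (!length(resd)) {
      return(data.frame(column = j, modal = NA_character_, modal_freq = NA_real_,
                        top2 = NA_character_, top2_freq = NA_real_,
                        gap_fraction = 1, stringsAsFactors = FALSE))
    }
    tab <- table(resd)
    tab <- tab[order(-tab, names(tab))]   # frequency desc, alphabetical ties
    freq <- as.numeric(tab) / length(resd)
    top2 <- paste(names(tab)[seq_len(min(2, length(tab)))], collapse = "")
    data.frame(column = j, modal = names(tab)[1], modal_freq = freq[1],
               top2 = top2, top2_freq = sum(freq[seq_len(min(2, length(tab)))]),
               gap_fraction = mean(gaps), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Majority consensus sequence of an alignment
#'
#' Columns whose gap fraction exceeds `gap_rule_threshold` are omitted;
#' otherwise the modal gap-excluded residue is emitted, ties broken
#' alphabetically.
#'
#' @param msa a [protein_msa].
#' @param gap_rule_threshold columns gappier than this are dropped.
#' @return a consensus amino-acid string.
#' @export
consensus <- function(msa, gap_rule_threshold = 0.5) {
  prof <- conservation_profile(msa)
  keep <- prof$gap_fraction <= gap_rule_threshold & !is.na(prof$modal)
  paste(prof$modal[keep], collapse = "")
}
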