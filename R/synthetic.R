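# ---- planted domain templates -------------------------------------------
#
# All templates are synthetic. Cysteines appear only where planted (EGF and
# LNR positions): the generator treats the disulfide cysteine skeleton as a
# structural invariant and never introduces C anywhere else, so the
# cysteine-spacing repeat caller's ground truth stays exact.

# canonical EGF-like unit: satisfies the 6-Cys spacing grammar and embeds
# Motif A (cols 1-7) and Motif B (cols 11-19)
EGF_SKELETON <- "CANGGECIDSCRCPPGFTGARSCEVC"
EGF_FIXED <- c(1L, 3L, 4L, 5L, 7L, 11L, 13L, 16L, 19L, 23L, 26L)
EGF_VAR <- c(2L, 6L, 8L, 9L, 10L, 12L, 14L, 15L, 18L, 20L, 21L, 22L, 24L, 25L)
EGF_FY <- 17L
EGF_CYS <- c(1L, 7L, 11L, 13L, 23L, 26L)

LNR_TEMPLATE <- paste0("C", "QLSTGWHKDNAPFYVRIE", "C", "GDWTLHKAPNSRFYVEQIG", "C")
LNR_CYS <- c(1L, 20L, 40L)
NOD_TEMPLATE <- strrep("DLGTNHWERSAPVKFYQIML", 4)          # 80 aa, C-free
TM_TEMPLATE <- "LVLLAVGLVIFLILLGVGAMVAGRR"                  # 25 aa
RAM_TEMPLATE <- strrep("KRQHMSDNEWTAPGVLYIFE", 3)           # 60 aa
ANK_TEMPLATE <- "GHTPLHLAARNGHEKVVQLLLDSGADVNAKTKA"         # 33 aa
MOTIFD_TEMPLATE <- "WNDGGRW"                                 # matches WNXGGXW
MOTIFD_VAR <- c(3L, 6L)

ALPHA_NO_C <- setdiff(AA20, "C")                 # linkers, substitutions
ALPHA_FLANK <- setdiff(AA20, c("C", "D", "N"))   # non-cb EGF flanks

cb_plan_bits <- function(n_egf) {
  if (n_egf == 0) return("")
  paste(ifelse(seq_len(n_egf) %% 4 == 0, "0", "1"), collapse = "")
}

#' Canonical roster of Notch-like architecture specifications
#'
#' The eight default clade specifications used by the synthetic benchmark:
#' Notch-like proteins of bacteria (~110 aa, one EGF-like unit plus the
#' Motif-D block), plants (~400 aa), protists (~600 aa), invertebrates
#' (~2,700 aa) and the four chordate paralogs Notch1 (2,627 aa, 36 EGF,
#' 3 LNR, 7 ANK), Notch2 (2,471 aa), Notch3 (2,321 aa) and Notch4
#' (2,059 aa, fewer EGF). Lengths are monotone Notch1 > 2 > 3 > 4.
#' `divergence` is each clade's planted divergence from the shared domain
#' templates; `cb_plan` is the planted calcium-binding bit plan over EGF
#' units.
#'
#' @return a data frame with one row per clade.
#' @export
canonical_roster <- function() {
  r <- data.frame(
    clade = c("bacteria", "plants", "protist", "invertebrate",
              "Notch1", "Notch2", "Notch3", "Notch4"),
    abbr = c("BAC", "PLA", "PRO", "INV", "N1", "N2", "N3", "N4"),
    target_length = c(110L, 400L, 600L, 2700L, 2627L, 2471L, 2321L, 2059L),
    n_egf = c(1L, 3L, 5L, 36L, 36L, 36L, 34L, 29L),
    n_lnr = c(0L, 0L, 1L, 3L, 3L, 3L, 3L, 3L),
    has_nod = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    n_ank = c(0L, 0L, 0L, 7L, 7L, 7L, 7L, 7L),
    has_motif_d = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    divergence = c(0.28, 0.25, 0.22, 0.19, 0.13, 0.10, 0.10, 0.16),
    genus = c("Bacillus", "Arabidopsis", "Plasmodium", "Drosophila",
              "Homo", "Mus", "Gallus", "Danio"),
    description = c("notch-like protein", "notch family protein",
                    "notch family protein", "notch receptor",
                    "notch receptor 1", "notch receptor 2",
                    "notch receptor 3", "notch receptor 4"),
    stringsAsFactors = FALSE)
  r$cb_plan <- vapply(r$n_egf, cb_plan_bits, character(1))
  r
}

#' Scale a roster down for desk-scale experiments
#'
#' Shrinks target lengths and repeat counts proportionally (at least one
#' EGF unit is always kept; the NOD/TM/RAM block is dropped below scale
#' 0.5). Planted motif structure is unchanged, so motif-recovery behaviour
#' is preserved at a fraction of the cost.
#'
#' @param roster a [canonical_roster()]-shaped data frame.
#' @param scale multiplicative factor in (0, 1].
#' @export
scale_roster <- function(roster, scale) {
  stopifnot(scale > 0, scale <= 1)
  r <- roster
  r$n_egf <- pmax(1L, as.integer(round(r$n_egf * scale)))
  r$n_lnr <- ifelse(r$n_lnr > 0, pmax(1L, as.integer(round(r$n_lnr * scale))),
                    0L)
  r$n_ank <- as.integer(round(r$n_ank * scale))
  if (scale < 0.5) r$has_nod <- FALSE
  r$cb_plan <- vapply(r$n_egf, cb_plan_bits, character(1))
  fixed <- vapply(seq_len(nrow(r)), function(i)
    plan_fixed_length(r[i, ]), numeric(1))
  r$target_length <- pmax(as.integer(fixed + pmax(30, round(60 * scale))),
                          as.integer(round(r$target_length * scale)))
  r
}

# segment plan for a spec; kinds: linker, flank, egf, motifd, lnr, nod,
# tm, ram, ank, tail
plan_segments <- function(spec) {
  segs <- list(list(kind = "linker", len = 15L))
  for (i in seq_len(spec$n_egf)) {
    segs <- c(segs, list(list(kind = "flank", len = 5L, unit = i,
                              cb = substr(spec$cb_plan, i, i) == "1"),
                         list(kind = "egf", len = 26L, unit = i,
                              cb = substr(spec$cb_plan, i, i) == "1")))
  }
  if (isTRUE(spec$has_motif_d))
    segs <- c(segs, list(list(kind = "linker", len = 6L),
                         list(kind = "motifd", len = 7L)))
  for (i in seq_len(spec$n_lnr))
    segs <- c(segs, list(list(kind = "linker", len = 8L),
                         list(kind = "lnr", len = 40L, unit = i)))
  if (isTRUE(spec$has_nod))
    segs <- c(segs, list(list(kind = "linker", len = 10L),
                         list(kind = "nod", len = 80L),
                         list(kind = "linker", len = 10L),
                         list(kind = "tm", len = 25L),
                         list(kind = "linker", len = 5L),
                         list(kind = "ram", len = 60L)))
  for (i in seq_len(spec$n_ank)) {
    if (i > 1) segs <- c(segs, list(list(kind = "linker", len = 4L)))
    segs <- c(segs, list(list(kind = "ank", len = 33L, unit = i)))
  }
  segs
}

plan_fixed_length <- function(spec) {
  sum(vapply(plan_segments(spec), `[[`, 0L, "len"))
}

#' Build a clade ancestor sequence with planted domain architecture
#'
#' Deterministic given the seed. EGF units instantiate the canonical
#' six-cysteine skeleton (embedding Motifs A and B); calcium-binding units
#' carry the `[DN]-x-[DN]-[EQ]` flank; LNR/NOD/TM/RAM/ANK and the Motif-D
#' block are fixed synthetic templates; linkers are drawn from a uniform
#' cysteine-free background.
#'
#' @param spec one row of a [canonical_roster()]-shaped data frame.
#' @param seed RNG seed.
#' @param background_tail optional shared background string for the
#'   C-terminal tail linker: clades built over the same background are
#'   homologous end to end (as gene-duplication paralogs are), so their
#'   pairwise distances reflect the planted divergence rates rather than
#'   random-linker noise. `NULL` draws an independent tail.
#' @return an object of class `notch_ancestor`: `record` ([seq_records]
#'   row), `segments` (with coordinates), `domains` (planted domain
#'   intervals), position classes (`egf_fixed`, `egf_var`, `egf_fy`,
#'   `flank`, `template_mut`, `template_cys`, `linker`), `necd_end`,
#'   `cb_plan`, `spec`.
#' @export
make_ancestor <- function(spec, seed = 1, background_tail = NULL) {
  spec <- as.list(spec)
  segs <- plan_segments(spec)
  fixed <- sum(vapply(segs, `[[`, 0L, "len"))
  tail_len <- spec$target_length - fixed
  if (tail_len < 0)
    stop(sprintf("target length %d too small for the domain plan (%d aa)",
                 spec$target_length, fixed))
  if (tail_len > 0) segs <- c(segs, list(list(kind = "tail", len = tail_len)))
  set.seed(seed)
  pieces <- lapply(segs, function(sg) {
    if (sg$kind == "tail" && !is.null(background_tail)) {
      if (nchar(background_tail) < sg$len)
        stop("background tail shorter than the tail segment")
      return(strsplit(substr(background_tail, 1, sg$len), "")[[1]])
    }
    switch(sg$kind,
      linker = ,
      tail = sample(ALPHA_NO_C, sg$len, replace = TRUE),
      flank = {
        if (isTRUE(sg$cb)) {
          core <- c(sample(c("D", "N"), 1), sample(ALPHA_FLANK, 1),
                    sample(c("D", "N"), 1), sample(c("E", "Q"), 1))
          if (sample(2, 1) == 1) c(core, sample(ALPHA_FLANK, 1))
          else c(sample(ALPHA_FLANK, 1), core)
        } else sample(ALPHA_FLANK, 5, replace = TRUE)
      },
      egf = strsplit(EGF_SKELETON, "")[[1]],
      motifd = strsplit(MOTIFD_TEMPLATE, "")[[1]],
      lnr = strsplit(LNR_TEMPLATE, "")[[1]],
      nod = strsplit(NOD_TEMPLATE, "")[[1]],
      tm = strsplit(TM_TEMPLATE, "")[[1]],
      ram = strsplit(RAM_TEMPLATE, "")[[1]],
      ank = strsplit(ANK_TEMPLATE, "")[[1]])
  })
  lens <- lengths(pieces)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  segdf <- data.frame(kind = vapply(segs, `[[`, "", "kind"),
                      start = starts, end = ends,
                      unit = vapply(segs, function(s)
                        if (is.null(s$unit)) NA_integer_ else s$unit, 0L),
                      cb = vapply(segs, function(s)
                        if (is.null(s$cb)) NA else s$cb, NA),
                      stringsAsFactors = FALSE)
  residues <- paste(unlist(pieces), collapse = "")
  pos <- list(egf_fixed = integer(), egf_var = integer(), egf_fy = integer(),
              flank = integer(), template_mut = integer(),
              template_cys = integer(), linker = integer())
  for (i in seq_len(nrow(segdf))) {
    s <- segdf$start[i]
    off <- function(x) s - 1L + x
    k <- segdf$kind[i]
    if (k == "egf") {
      pos$egf_fixed <- c(pos$egf_fixed, off(EGF_FIXED))
      pos$egf_var <- c(pos$egf_var, off(EGF_VAR))
      pos$egf_fy <- c(pos$egf_fy, off(EGF_FY))
    } else if (k == "flank") {
      pos$flank <- c(pos$flank, off(seq_len(5L)))
    } else if (k == "lnr") {
      pos$template_cys <- c(pos$template_cys, off(LNR_CYS))
      pos$template_mut <- c(pos$template_mut,
                            off(setdiff(seq_len(40L), LNR_CYS)))
    } else if (k == "motifd") {
      pos$template_mut <- c(pos$template_mut, off(MOTIFD_VAR))
    } else if (k %in% c("nod", "tm", "ram", "ank")) {
      pos$template_mut <- c(pos$template_mut,
                            off(seq_len(segdf$end[i] - s + 1L)))
    } else {
      pos$linker <- c(pos$linker, off(seq_len(segdf$end[i] - s + 1L)))
    }
  }
  dom <- segdf[!segdf$kind %in% c("linker", "flank", "tail"), , drop = FALSE]
  rownames(dom) <- NULL
  necd_end <- if (any(segdf$kind == "lnr")) {
    max(segdf$end[segdf$kind == "lnr"])
  } else if (any(segdf$kind == "motifd")) {
    max(segdf$end[segdf$kind == "motifd"])
  } else {
    max(segdf$end[segdf$kind == "egf"])
  }
  record <- seq_records(id = paste0("ANC_", spec$abbr), residues = residues,
                        description = "notch family ancestor, synthetic",
                        organism = "")
  structure(list(record = record, segments = segdf, domains = dom,
                 positions = pos, necd_end = necd_end,
                 cb_plan = spec$cb_plan, spec = spec, seed = seed),
            class = "notch_ancestor")
}

mutate_positions <- function(chars, idx, alphabet) {
  for (i in idx) {
    choices <- setdiff(alphabet, chars[i])
    chars[i] <- choices[sample.int(length(choices), 1)]
  }
  chars
}

#' Derive a diverged clade ancestor from a base ancestor
#'
#' Applies the planted between-clade divergence: designated EGF variable
#' columns are redrawn uniformly (cysteine-free alphabet), the F/Y column
#' of each unit is redrawn from \{F, Y\}, and template positions (and
#' linkers) mutate independently at the given rate. The cysteine skeleton,
#' flank windows and all planted coordinates are untouched.
#'
#' @param ancestor a [make_ancestor()] object.
#' @param rate clade divergence rate in `[0, 0.5)`.
#' @param seed RNG seed.
#' @return a `notch_ancestor` with mutated residues.
#' @export
derive_clade_ancestor <- function(ancestor, rate, seed = 1) {
  stopifnot(rate >= 0, rate < 0.5)
  set.seed(seed)
  chars <- strsplit(ancestor$record$residues, "")[[1]]
  p <- ancestor$positions
  chars[p$egf_var] <- sample(ALPHA_NO_C, length(p$egf_var), replace = TRUE)
  chars[p$egf_fy] <- sample(c("F", "Y"), length(p$egf_fy), replace = TRUE)
  mut_idx <- c(p$template_mut, p$linker)
  hit <- mut_idx[runif(length(mut_idx)) < rate]
  chars <- mutate_positions(chars, hit, ALPHA_NO_C)
  out <- ancestor
  out$record$residues <- paste(chars, collapse = "")
  out
}

default_protected <- function(ancestor) {
  p <- ancestor$positions
  sort(c(p$egf_fixed, p$egf_fy, p$flank, p$template_cys))
}

apply_indels <- function(chars, rate) {
  n_ev <- rbinom(1, length(chars), rate)
  for (e in seq_len(n_ev)) {
    if (length(chars) < 4) break
    pos <- sample.int(length(chars), 1)
    ilen <- min(rgeom(1, 0.5) + 1L, 5L)
    if (sample(2, 1) == 1) {  # deletion
      del <- pos:min(pos + ilen - 1L, length(chars) - 1L)
      if (length(del) < length(chars)) chars <- chars[-del]
    } else {                  # insertion
      ins <- sample(ALPHA_NO_C, ilen, replace = TRUE)
      chars <- append(chars, ins, after = pos)
    }
  }
  chars
}

#' Evolve a clade of member sequences from an ancestor
#'
#' Members accumulate i.i.d. substitutions at unprotected positions
#' (uniform cysteine-free replacement, never the original residue) and
#' geometric-length indels restricted to linker/tail segments, so planted
#' domain coordinates stay exact in the returned truth.
#'
#' @param ancestor a `notch_ancestor` (usually from
#'   [derive_clade_ancestor()]).
#' @param n_members number of member sequences.
#' @param sub_rate per-position substitution probability in `[0, 0.5)`.
#' @param indel_rate per-linker-position indel event probability.
#' @param protected_columns positions never substituted; default: EGF
#'   skeleton, F/Y columns, flank windows, LNR cysteines.
#' @param seed RNG seed.
#' @param id_prefix,organisms,description metadata for the emitted records.
#' @return list: `records` ([seq_records]), `domains` (per-member planted
#'   intervals, with member ids), `ancestor`.
#' @export
evolve_clade <- function(ancestor, n_members, sub_rate = 0.01,
                         indel_rate = 0.002, protected_columns = NULL,
                         seed = 1, id_prefix = "M", organisms = NULL,
                         description = "notch family member, synthetic") {
  stopifnot(sub_rate >= 0, sub_rate < 0.5, indel_rate >= 0, indel_rate < 0.5)
  if (is.null(protected_columns)) protected_columns <- default_protected(ancestor)
  if (is.null(organisms))
    organisms <- paste0("Synthetica sp", seq_len(n_members))
  chars0 <- strsplit(ancestor$record$residues, "")[[1]]
  segdf <- ancestor$segments
  prot <- rep(FALSE, length(chars0))
  prot[protected_columns] <- TRUE
  set.seed(seed)
  ids <- sprintf("%s%02d", id_prefix, seq_len(n_members))
  seqs <- character(n_members)
  dom_list <- vector("list", n_members)
  for (m in seq_len(n_members)) {
    pieces <- vector("list", nrow(segdf))
    for (i in seq_len(nrow(segdf))) {
      rng <- segdf$start[i]:segdf$end[i]
      seg <- chars0[rng]
      elig <- which(!prot[rng])
      if (length(elig) && sub_rate > 0) {
        hit <- elig[runif(length(elig)) < sub_rate]
        seg <- mutate_positions(seg, hit, ALPHA_NO_C)
      }
      if (segdf$kind[i] %in% c("linker", "tail") && indel_rate > 0)
        seg <- apply_indels(seg, indel_rate)
      pieces[[i]] <- seg
    }
    lens <- lengths(pieces)
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    sdf <- segdf
    sdf$start <- starts
    sdf$end <- ends
    seqs[m] <- paste(unlist(pieces), collapse = "")
    dom <- sdf[!sdf$kind %in% c("linker", "flank", "tail"), , drop = FALSE]
    dom$id <- ids[m]
    rownames(dom) <- NULL
    dom_list[[m]] <- dom
  }
  records <- seq_records(id = ids, residues = seqs,
                         description = description,
                         organism = organisms[seq_len(n_members)])
  list(records = records, domains = do.call(rbind, dom_list),
       ancestor = ancestor)
}

shuffle_residues <- function(residues) {
  paste(sample(strsplit(residues, "")[[1]]), collapse = "")
}

#' Generate the synthetic Notch benchmark with planted ground truth
#'
#' Emits per-clade member sequences (between-clade divergence well above
#' within-clade), noise records (shuffled sequences titled strawberry
#' notch / hypothetical / predicted / low quality / synthetic construct,
#' plus truncated "partial" copies), near-duplicate records (>= 96%
#' identity, shorter than their source, same organism), and two planted
#' outgroup homologs (GLP-1-like and LIN-12-like) with NCBI-style
#' deflines. The truth table records every record's clade and role.
#'
#' @param roster a [canonical_roster()]-shaped data frame.
#' @param members_per_clade clean members per clade.
#' @param noise_fraction noise records as a fraction of clean records.
#' @param duplicate_fraction near-duplicates as a fraction of clean
#'   records.
#' @param seed master seed; all stages derive sub-seeds from it.
#' @param sub_rate,indel_rate within-clade evolution rates.
#' @return an object of class `notch_benchmark`: `records`, `truth`
#'   (id, clade, role, duplicate_of, length), `references` (the clade
#'   ancestor exemplars), `ancestors`, `member_domains`, `params`.
#' @export
make_benchmark <- function(roster = canonical_roster(), members_per_clade = 6,
                           noise_fraction = 0.15, duplicate_fraction = 0.1,
                           seed = 1, sub_rate = 0.01, indel_rate = 0.002) {
  stopifnot(noise_fraction >= 0, noise_fraction < 1,
            duplicate_fraction >= 0, duplicate_fraction < 1)
  seed <- as.integer(seed) %% 1000000L
  # shared background tail: clades are homologous over their C-terminal
  # linker, so between-clade distance follows the planted rate ladder
  set.seed(seed + 3L)
  tail_pool <- paste(sample(ALPHA_NO_C, max(roster$target_length),
                            replace = TRUE), collapse = "")
  ancestors <- list()
  rec_list <- list()
  truth_list <- list()
  dom_list <- list()
  ref_list <- list()
  for (c in seq_len(nrow(roster))) {
    spec <- roster[c, ]
    base <- make_ancestor(spec, seed + 101L * c, background_tail = tail_pool)
    clade_anc <- derive_clade_ancestor(base, spec$divergence,
                                       seed + 101L * c + 50L)
    ev <- evolve_clade(clade_anc, members_per_clade, sub_rate, indel_rate,
                       seed = seed + 101L * c + 70L,
                       id_prefix = paste0("SYN_", spec$abbr, "_"),
                       organisms = paste0(spec$genus, " sp",
                                          seq_len(members_per_clade)),
                       description = spec$description)
    ancestors[[spec$clade]] <- clade_anc
    rec_list[[spec$clade]] <- ev$records
    dom_list[[spec$clade]] <- ev$domains
    truth_list[[spec$clade]] <-
      data.frame(id = ev$records$id, clade = spec$clade, role = "clean",
                 duplicate_of = NA_character_, length = ev$records$length,
                 stringsAsFactors = FALSE)
    ref <- clade_anc$record
    ref$id <- paste0("REF_", spec$abbr)
    ref$description <- "notch family reference exemplar, synthetic"
    ref$organism <- paste(spec$genus, "reference")
    ref_list[[spec$clade]] <- ref
    if (spec$clade == "invertebrate" || c == which.max(roster$divergence))
      inv_base <- base
    if (spec$clade == "invertebrate") inv_base <- base
  }
  clean <- do.call(rbind, rec_list)
  class(clean) <- c("seq_records", "data.frame")
  n_clean <- nrow(clean)

  # near-duplicates: light substitutions + slight C-terminal truncation
  set.seed(seed + 7L)
  n_dup <- ceiling(duplicate_fraction * n_clean)
  dup_src <- sample.int(n_clean, n_dup)
  dup_rec <- list()
  dup_truth <- list()
  for (k in seq_along(dup_src)) {
    i <- dup_src[k]
    chars <- strsplit(clean$residues[i], "")[[1]]
    L <- length(chars)
    nsub <- max(1L, round(0.01 * L))
    ntr <- max(1L, round(0.01 * L))
    hit <- sample.int(L - ntr, nsub)
    chars <- mutate_positions(chars, hit, ALPHA_NO_C)
    res <- paste(chars[seq_len(L - ntr)], collapse = "")
    dup_rec[[k]] <- seq_records(id = paste0(clean$id[i], "d"),
                                residues = res,
                                description = clean$description[i],
                                organism = clean$organism[i])
    dup_truth[[k]] <- data.frame(id = paste0(clean$id[i], "d"),
                                 clade = NA_character_, role = "duplicate",
                                 duplicate_of = clean$id[i],
                                 length = nchar(res), stringsAsFactors = FALSE)
  }

  # noise: headers that the keyword filter must reject
  set.seed(seed + 11L)
  n_noise <- ceiling(noise_fraction * n_clean)
  noise_desc <- c("strawberry notch homolog 1",
                  "hypothetical protein LOC%d",
                  "notch receptor, partial",
                  "PREDICTED: notch-like protein",
                  "low quality protein: notch homolog",
                  "synthetic construct notch fragment")
  noise_rec <- list()
  noise_truth <- list()
  for (k in seq_len(n_noise)) {
    i <- sample.int(n_clean, 1)
    type <- ((k - 1L) %% length(noise_desc)) + 1L
    desc <- gsub("%d", as.character(100000L + k), noise_desc[type],
                 fixed = TRUE)
    res <- if (type == 3L) {
      substr(clean$residues[i], 1L, max(30L, floor(0.4 * clean$length[i])))
    } else {
      shuffle_residues(clean$residues[i])
    }
    noise_rec[[k]] <- seq_records(id = sprintf("NOISE%02d", k),
                                  residues = res, description = desc,
                                  organism = clean$organism[i])
    noise_truth[[k]] <- data.frame(id = sprintf("NOISE%02d", k),
                                   clade = NA_character_, role = "noise",
                                   duplicate_of = NA_character_,
                                   length = nchar(res),
                                   stringsAsFactors = FALSE)
  }

  # planted outgroup homologs, diverged above all paralog clades
  og1 <- derive_clade_ancestor(inv_base, 0.35, seed + 91L)
  og2 <- derive_clade_ancestor(inv_base, 0.35, seed + 92L)
  outg <- seq_records(id = c("GLP1LIKE", "LIN12LIKE"),
                      residues = c(og1$record$residues, og2$record$residues),
                      description = c("notch-related receptor glp-1-like",
                                      "notch-related receptor lin-12-like"),
                      organism = "Caenorhabditis elegans")
  outg_truth <- data.frame(id = outg$id, clade = "outgroup",
                           role = "outgroup", duplicate_of = NA_character_,
                           length = outg$length, stringsAsFactors = FALSE)

  records <- rbind(clean,
                   if (length(dup_rec)) do.call(rbind, dup_rec),
                   if (length(noise_rec)) do.call(rbind, noise_rec),
                   outg)
  class(records) <- c("seq_records", "data.frame")
  truth <- rbind(do.call(rbind, truth_list),
                 if (length(dup_truth)) do.call(rbind, dup_truth),
                 if (length(noise_truth)) do.call(rbind, noise_truth),
                 outg_truth)
  rownames(records) <- rownames(truth) <- NULL
  references <- do.call(rbind, ref_list)
  class(references) <- c("seq_records", "data.frame")
  rownames(references) <- NULL
  structure(list(records = records, truth = truth, references = references,
                 ancestors = ancestors,
                 member_domains = do.call(rbind, dom_list),
                 params = list(members_per_clade = members_per_clade,
                               noise_fraction = noise_fraction,
                               duplicate_fraction = duplicate_fraction,
                               seed = seed, sub_rate = sub_rate,
                               indel_rate = indel_rate)),
            class = "notch_benchmark")
}

#' @export
print.notch_benchmark <- function(x, ...) {
  cat(sprintf("notch_benchmark: %d records (%s), seed %d\n",
              nrow(x$records),
              paste(sprintf("%d %s", table(x$truth$role),
                            names(table(x$truth$role))), collapse = ", "),
              x$params$seed))
  invisible(x)
}
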