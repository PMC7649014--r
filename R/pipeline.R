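PIPELINE_DEFAULTS <- list(
  identity = 0.95,          # duplicate-removal identity threshold
  min_score = 0.3,          # reference-screen normalized score
  within_species = TRUE,
  gap_open = 10,
  gap_extend = 0.5,
  distance = "jc_protein",  # clustering distance kind
  clamp = FALSE,            # clamp saturated JC pairs instead of erroring
  bootstrap = 100,
  gap_rule = 0.5,           # consensus gap rule
  invariant_tau = 0.95,
  class_tau = 0.95,
  min_len = 7,
  max_wildcard_run = 2,
  seed = 1,
  members_per_clade = 6,
  noise_fraction = 0.15,
  duplicate_fraction = 0.1,
  sub_rate = 0.01,
  indel_rate = 0.002
)

#' Pipeline configuration
#'
#' All stage parameters with their defaults (identity 0.95, bootstrap 100,
#' Gonnet gap penalties 10/0.5, conservation thresholds 0.95). Unknown
#' keys are rejected.
#'
#' @param ... overrides of the defaults.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(PIPELINE_DEFAULTS))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(PIPELINE_DEFAULTS, over)
  structure(cfg, class = "pipeline_config")
}

config_lines <- function(cfg) {
  vapply(names(cfg), function(k)
    paste0(k, "=", format(cfg[[k]], scientific = FALSE)), character(1))
}

#' Serialize / read a pipeline configuration
#' @param cfg a [pipeline_config()].
#' @param path flat `key=value` file path.
#' @export
write_config <- function(cfg, path) {
  writeLines(config_lines(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- lapply(kv, function(x) {
    v <- x[2]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else if (v %in% c("TRUE", "FALSE")) as.logical(v) else v
  })
  do.call(pipeline_config, setNames(vals, vapply(kv, `[`, "", 1)))
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  write_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}

write_tsv_artifact <- function(df, path, hash, extra = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#config_hash=", hash), paste0("#", extra)[nzchar(extra)]),
             con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage %s: %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the end-to-end Notch family pipeline
#'
#' simulate (optional) -> curate -> guide-tree progressive alignment ->
#' protein-JC UPGMA -> auto-threshold clusters -> per-cluster consensus ->
#' bootstrapped consensus phylogeny (outgroups join here) -> motif scans,
#' EGF/digital-signature annotation and conservation-based motif
#' discovery. All artifacts are written with stable filenames; reruns with
#' the same config are bit-identical.
#'
#' @param config a [pipeline_config()].
#' @param input a [seq_records] data frame, or `NULL` to simulate the
#'   default synthetic benchmark.
#' @param references exemplar [seq_records] for the curation screen
#'   (defaults to the benchmark's planted references when simulating).
#' @param outgroup_ids ids set aside from clustering and added at the
#'   consensus-phylogeny stage (defaults to the benchmark's planted
#'   outgroups when simulating).
#' @param roster architecture roster used when simulating; defaults to
#'   [canonical_roster()].
#' @param out_dir output directory for artifacts (`NULL`: nothing
#'   written).
#' @return an invisible list with all intermediate objects (`benchmark`,
#'   `curation`, `msa`, `distances`, `tree`, `clustering`, `consensus`,
#'   `specialized_tree`, `motif_hits`, `egf`, `signatures`, `discovered`,
#'   `report`).
#' @export
run_pipeline <- function(config = pipeline_config(), input = NULL,
                         references = NULL, outgroup_ids = NULL,
                         roster = canonical_roster(), out_dir = NULL) {
  cfg <- config
  hash <- config_hash(cfg)
  benchmark <- NULL
  if (is.null(input)) {
    benchmark <- run_stage("simulate",
      make_benchmark(roster = roster,
                     members_per_clade = cfg$members_per_clade,
                     noise_fraction = cfg$noise_fraction,
                     duplicate_fraction = cfg$duplicate_fraction,
                     seed = cfg$seed, sub_rate = cfg$sub_rate,
                     indel_rate = cfg$indel_rate))
    input <- benchmark$records
    if (is.null(references)) references <- benchmark$references
    if (is.null(outgroup_ids))
      outgroup_ids <- benchmark$truth$id[benchmark$truth$role == "outgroup"]
  }
  cur <- run_stage("curate",
    curate(input, references, min_norm_score = cfg$min_score,
           threshold = cfg$identity, within_species = cfg$within_species,
           gap_open = cfg$gap_open, gap_extend = cfg$gap_extend))
  retained <- cur$records
  if (nrow(retained) == 0) stop("stage curate: no sequences retained")
  core <- retained[!retained$id %in% outgroup_ids, , drop = FALSE]
  class(core) <- c("seq_records", "data.frame")
  outg <- retained[retained$id %in% outgroup_ids, , drop = FALSE]
  class(outg) <- c("seq_records", "data.frame")
  if (nrow(core) < 3) stop("stage align: fewer than 3 core sequences")

  msa <- run_stage("align",
    align_sequences(core, gap_open = cfg$gap_open,
                    gap_extend = cfg$gap_extend))
  dm <- run_stage("distances",
    msa_distance_matrix(msa, cfg$distance, clamp = cfg$clamp))
  tree <- run_stage("tree", upgma(dm))
  thr <- run_stage("cut", auto_threshold(tree))
  clustering <- run_stage("cut", cut_tree(tree, thr))

  cl_ids <- split(names(clustering$assignments), clustering$assignments)
  names(cl_ids) <- paste0("C", names(cl_ids))
  member_msas <- lapply(cl_ids, function(ids) subset_msa(msa, ids))
  spec_tree <- run_stage("consensus_phylogeny",
    specialized_phylogeny(cl_ids, member_msas,
                          extra_sequences = if (nrow(outg)) outg,
                          n_replicates = cfg$bootstrap, seed = cfg$seed,
                          gap_rule_threshold = cfg$gap_rule,
                          clamp = cfg$clamp))

  pats <- notch_motifs()[c("A", "B")]
  motif_hits <- run_stage("motifs", do.call(rbind, unlist(lapply(
    seq_len(nrow(retained)), function(i) lapply(pats, function(p)
      scan_motif(retained[i, ], p))), recursive = FALSE)))
  egf <- run_stage("motifs", do.call(rbind, lapply(
    seq_len(nrow(retained)), function(i) find_egf_repeats(retained[i, ]))))
  signatures <- run_stage("motifs", data.frame(
    id = retained$id,
    signature = vapply(seq_len(nrow(retained)), function(i)
      digital_signature(retained[i, ]), character(1)),
    stringsAsFactors = FALSE))
  discovered <- run_stage("motifs",
    discover_conserved_motifs(msa, cfg$invariant_tau, cfg$class_tau,
                              cfg$min_len, cfg$max_wildcard_run))

  res <- list(config = cfg, config_hash = hash, benchmark = benchmark,
              curation = cur, core = core, outgroups = outg, msa = msa,
              distances = dm, tree = tree, threshold = thr,
              clustering = clustering, cluster_ids = cl_ids,
              member_msas = member_msas, specialized_tree = spec_tree,
              motif_hits = motif_hits, egf = egf, signatures = signatures,
              discovered = discovered)
  res$report <- summarize_run(res)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    write_config(cfg, p("config.txt"))
    write_fasta(retained, p("curated.fasta"))
    write_tsv_artifact(cur$rejections, p("rejects.tsv"), hash)
    write_fasta(msa_as_records(msa), p("msa.afa"))
    write_clustal(msa, p("msa.clustal"))
    dmat <- as.data.frame(dm$matrix)
    dmat <- cbind(id = rownames(dmat), dmat)
    write_tsv_artifact(dmat, p("distances.tsv"), hash, dm$kind)
    write_newick(tree, p("upgma_tree.nwk"))
    cl_df <- data.frame(id = names(clustering$assignments),
                        cluster = paste0("C", clustering$assignments))
    write_tsv_artifact(cl_df, p("clusters.tsv"), hash,
                       sprintf("threshold=%.6g", thr))
    write_fasta(attr(spec_tree, "consensus_records"), p("consensus.fasta"))
    write_newick(spec_tree, p("specialized_tree.nwk"), with_supports = TRUE)
    write_tsv_artifact(motif_hits, p("motif_hits.tsv"), hash)
    write_tsv_artifact(egf, p("egf_annotations.tsv"), hash)
    write_tsv_artifact(signatures, p("signatures.tsv"), hash)
    disc_df <- data.frame(pattern = vapply(discovered, `[[`, "", "source"),
                          start_col = vapply(discovered, attr, 0L, "start_col"),
                          end_col = vapply(discovered, attr, 0L, "end_col"))
    write_tsv_artifact(disc_df, p("discovered_motifs.tsv"), hash)
    write_tsv_artifact(res$report$clusters, p("report.tsv"), hash)
    writeLines(res$report$text, p("summary.txt"))
  }
  invisible(res)
}

subset_msa <- function(msa, ids) {
  rows <- msa$rows[ids]
  m <- do.call(rbind, strsplit(unname(rows), ""))
  keep <- colSums(m != "-") > 0
  protein_msa(ids, apply(m[, keep, drop = FALSE], 1, paste, collapse = ""))
}

msa_as_records <- function(msa) {
  df <- data.frame(id = msa$ids, description = "", organism = "",
                   residues = unname(msa$rows),
                   length = nchar(unname(msa$rows)), flags = "",
                   stringsAsFactors = FALSE)
  class(df) <- c("seq_records", "data.frame")
  df
}

#' Summarize a pipeline run
#'
#' Per-cluster report (member count, organisms, consensus length,
#' representative motifs found) plus a text summary with composition
#' percentages and length ranges.
#'
#' @param run the result list of [run_pipeline()].
#' @return list with `clusters` (data frame) and `text`.
#' @export
summarize_run <- function(run) {
  if (is.null(run$clustering)) stop("missing clustering artifact")
  cl_ids <- run$cluster_ids
  cons <- attr(run$specialized_tree, "consensus_records")
  clusters <- do.call(rbind, lapply(names(cl_ids), function(cl) {
    ids <- cl_ids[[cl]]
    orgs <- sort(unique(run$core$organism[run$core$id %in% ids]))
    hits <- run$motif_hits[run$motif_hits$id %in% ids, , drop = FALSE]
    data.frame(cluster = cl, n_members = length(ids),
               organisms = paste(orgs, collapse = ";"),
               consensus_length = cons$length[match(cl, cons$id)],
               motifs = paste(sort(unique(hits$label)), collapse = ";"),
               min_length = min(run$core$length[run$core$id %in% ids]),
               max_length = max(run$core$length[run$core$id %in% ids]),
               stringsAsFactors = FALSE)
  }))
  clusters <- clusters[clusters$n_members > 0, , drop = FALSE]
  pct <- round(100 * clusters$n_members / sum(clusters$n_members), 1)
  text <- c(sprintf("%d sequences in %d clusters (threshold %.4g)",
                    sum(clusters$n_members), nrow(clusters), run$threshold),
            sprintf("  %s: %d members (%.1f%%), lengths %d-%d",
                    clusters$cluster, clusters$n_members, pct,
                    clusters$min_length, clusters$max_length))
  list(clusters = clusters, text = text)
}
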