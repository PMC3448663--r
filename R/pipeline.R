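# End-to-end orchestration: FASTA in, feature/classification tables, trimmed
# alignment, bootstrapped NJ tree and a run log out. Outputs are a pure
# function of (input bytes, config, seed): no timestamps, fixed number
# formatting, all randomness derived from the config seed.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full classification pipeline
#'
#' Stages: read FASTA; build a feature vector and group label per protein;
#' write the feature table and classification TSV; center-star MSA with
#' gap-fraction trimming (written as aligned FASTA plus kept-column TSV);
#' when at least three sequences are present, Poisson-corrected distances,
#' NJ tree and bootstrap supports written as Newick; and a run log recording
#' the full configuration. Errors are reported with the failing stage name.
#'
#' @param config A [run_config()].
#' @param fasta_path Input protein FASTA.
#' @param out_dir Output directory (created if needed).
#' @param context_table_path Optional context-annotation TSV for sublabeling.
#' @return Invisibly, a summary list: `n_records`, `counts` (table of compact
#'   labels), and `files` (paths written).
#' @export
run_pipeline <- function(config, fasta_path, out_dir,
                         context_table_path = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  records <- .stage("read", read_fasta(fasta_path))
  profile <- .stage("profile",
                    read_anchor_profile(config$anchor_profile_path))
  scoring <- blosum62_scheme(config$gap_open, config$gap_extend)

  fvs <- .stage("features", lapply(records, build_feature_vector,
                                   profile = profile, scoring = scoring,
                                   siroheme_min_anchors = config$siroheme_min_anchors,
                                   peripheral_min_anchors = config$peripheral_min_anchors,
                                   core_threshold = config$min_core_score))
  labels <- .stage("classify", {
    l <- lapply(fvs, classify_protein)
    names(l) <- vapply(records, `[[`, character(1), "id")
    if (!is.null(context_table_path)) {
      l <- apply_context_labels(l, read_context_table(context_table_path))
    }
    l
  })

  files <- c(feature_table = file.path(out_dir, "feature_table.tsv"),
             classification = file.path(out_dir, "classification.tsv"),
             alignment = file.path(out_dir, "alignment_trimmed.fasta"),
             kept_columns = file.path(out_dir, "kept_columns.tsv"),
             tree = file.path(out_dir, "tree.nwk"),
             log = file.path(out_dir, "run_log.yaml"))

  .stage("tables", {
    write_feature_table(records, fvs, unname(labels), files[["feature_table"]])
    cls <- data.frame(
      id = names(labels),
      label = vapply(labels, format_group_label, character(1)),
      family = vapply(labels, `[[`, character(1), "family"),
      group = vapply(labels, `[[`, character(1), "group"),
      subgroup = vapply(labels, `[[`, character(1), "subgroup"),
      arch_class = vapply(labels, `[[`, character(1), "arch_class"),
      sublabel = vapply(labels, `[[`, character(1), "sublabel"),
      flags = vapply(labels, function(g) paste(g$flags, collapse = ";"),
                     character(1)),
      stringsAsFactors = FALSE)
    write.table(cls, files[["classification"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  })

  tree_built <- FALSE
  if (length(records) >= 2L) {
    msa <- .stage("msa", center_star_msa(records, scoring))
    trimmed <- .stage("trim", trim_columns(msa, config$max_gap_fraction))
    .stage("msa_out", {
      write_msa_fasta(trimmed, files[["alignment"]])
      kept <- attr(trimmed, "kept_columns")
      write.table(data.frame(new_column = seq_along(kept),
                             original_column = kept),
                  files[["kept_columns"]], sep = "\t", quote = FALSE,
                  row.names = FALSE)
    })
    if (length(records) >= 3L && trimmed$n_col >= 1L) {
      tree <- .stage("tree", bootstrap_support(trimmed,
                                               n_replicates = config$bootstrap_n,
                                               seed = config$seed + 1L,
                                               correction = "poisson"))
      .stage("tree_out", write_newick(tree, files[["tree"]]))
      tree_built <- TRUE
    }
  }

  .stage("log", yaml::write_yaml(
    list(package = "siroclass",
         config = unclass(config),
         n_records = length(records),
         tree_built = tree_built),
    files[["log"]]))

  counts <- table(vapply(labels, format_group_label, character(1)))
  invisible(list(n_records = length(records), counts = counts,
                 files = files))
}
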