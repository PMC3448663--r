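#' Create a protein record
#'
#' The unit flowing through the pipeline: one named amino-acid sequence with
#' an optional organism tag.
#'
#' @param id Non-empty identifier, unique within a dataset.
#' @param sequence Amino-acid sequence over the 20 standard residues plus
#'   `X`; stored uppercase.
#' @param organism Organism string; may be empty.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, organism = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) < 1L) {
    stop("sequence of record '", id, "' is empty")
  }
  bad <- regexpr(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), sequence)
  if (bad > 0L) {
    stop("record '", id, "' has a non-amino-acid character '",
         substr(sequence, bad, bad), "' at position ", bad)
  }
  structure(list(id = id, organism = organism, sequence = sequence),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa)%s\n", x$id, nchar(x$sequence),
              if (nzchar(x$organism)) paste0(" [", x$organism, "]") else ""))
  invisible(x)
}

#' Read a protein FASTA file
#'
#' The first whitespace-delimited token of each header becomes the record id;
#' if the description ends in a bracketed suffix (`[Genus species]`) it is
#' taken as the organism tag. Sequences are uppercased on ingest.
#'
#' @param path Path to a FASTA file.
#' @return A list of [protein_record()] objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  orgs <- vapply(headers, function(h) {
    m <- regmatches(h, regexpr("\\[[^][]*\\]$", h))
    if (length(m)) substr(m, 2L, nchar(m) - 1L) else ""
  }, character(1), USE.NAMES = FALSE)
  seqs <- as.character(set)
  recs <- mapply(protein_record, id = ids, sequence = seqs, organism = orgs,
                 SIMPLIFY = FALSE)
  unname(recs)
}

#' Write protein records to FASTA
#'
#' Headers are normalized to `>id` or `>id [organism]`; sequences are wrapped
#' at 60 columns. Round-tripping through [read_fasta()] preserves sequence
#' content exactly.
#'
#' @param records List of [protein_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  lines <- unlist(lapply(records, function(r) {
    header <- if (nzchar(r$organism)) {
      sprintf(">%s [%s]", r$id, r$organism)
    } else {
      paste0(">", r$id)
    }
    n <- nchar(r$sequence)
    starts <- seq(1L, n, by = 60L)
    c(header, substring(r$sequence, starts, pmin(starts + 59L, n)))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Assemble a run configuration
#'
#' Holds every tunable of the pipeline; all randomness flows from the single
#' `seed`, which is recorded in every output.
#'
#' @param anchor_profile_path Path to an anchor-profile YAML, or `NULL` for
#'   the packaged default.
#' @param min_core_score Minimum self-normalized alignment score (0..1) for
#'   calling the FrhB core present.
#' @param gap_open,gap_extend Affine gap penalties (both `<= 0`,
#'   `gap_open <= gap_extend`).
#' @param max_gap_fraction Columns with a gap fraction above this are trimmed.
#' @param bootstrap_n Number of bootstrap replicates for branch support.
#' @param seed Integer master seed.
#' @param siroheme_min_anchors,peripheral_min_anchors How many of the four
#'   cysteine anchors (1..4) must be occupied to call the site present.
#' @return An object of class `run_config`.
#' @export
run_config <- function(anchor_profile_path = NULL,
                       min_core_score = 0.5,
                       gap_open = -11, gap_extend = -1,
                       max_gap_fraction = 0.5,
                       bootstrap_n = 100L,
                       seed = 1L,
                       siroheme_min_anchors = 4L,
                       peripheral_min_anchors = 4L) {
  stopifnot(min_core_score >= 0, min_core_score <= 1,
            gap_open <= gap_extend, gap_extend <= 0,
            max_gap_fraction >= 0, max_gap_fraction <= 1,
            bootstrap_n >= 1L,
            siroheme_min_anchors %in% 1:4, peripheral_min_anchors %in% 1:4)
  structure(list(anchor_profile_path = anchor_profile_path,
                 min_core_score = min_core_score,
                 gap_open = gap_open, gap_extend = gap_extend,
                 max_gap_fraction = max_gap_fraction,
                 bootstrap_n = as.integer(bootstrap_n),
                 seed = as.integer(seed),
                 siroheme_min_anchors = as.integer(siroheme_min_anchors),
                 peripheral_min_anchors = as.integer(peripheral_min_anchors)),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Path to a YAML (or JSON, a YAML subset) file whose keys match
#'   the arguments of [run_config()].
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, vals)
}

#' Write the per-protein feature/classification table
#'
#' One TSV row per protein: id, organism, each signature as 0/1, the
#' sulfite-binding residue pattern (e.g. `"1011"`), the group label fields
#' and any flags, in a fixed column order.
#'
#' @param records List of [protein_record()] objects.
#' @param feature_vectors List of feature vectors from
#'   [build_feature_vector()], parallel to `records`.
#' @param labels List of group labels from [classify_protein()], parallel to
#'   `records`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(records, feature_vectors, labels, path) {
  if (length(records) != length(feature_vectors) ||
      length(records) != length(labels)) {
    stop("records, feature_vectors and labels must have equal length")
  }
  df <- feature_table(records, feature_vectors, labels)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the feature/classification table as a data frame
#'
#' @inheritParams write_feature_table
#' @return A data frame with one row per protein.
#' @export
feature_table <- function(records, feature_vectors, labels) {
  as01 <- function(x) as.integer(isTRUE(x))
  rows <- lapply(seq_along(records), function(i) {
    r <- records[[i]]; fv <- feature_vectors[[i]]; gl <- labels[[i]]
    data.frame(
      id = r$id,
      organism = r$organism,
      siroheme_site = as01(fv$siroheme_site),
      peripheral_cluster = as01(fv$peripheral_cluster),
      additional_cluster = as01(fv$additional_cluster),
      sb_pattern = paste(as.integer(fv$sb_present), collapse = ""),
      frh_core = as01(fv$frh_core),
      ferredoxin_n_count = fv$ferredoxin_n_count,
      ferredoxin_c_count = fv$ferredoxin_c_count,
      fusion_order_ok = as01(fv$fusion_order_ok),
      family = gl$family,
      group = gl$group,
      subgroup = gl$subgroup,
      arch_class = gl$arch_class,
      sublabel = gl$sublabel,
      flags = paste(gl$flags, collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  if (length(rows) == 0L) {
    data.frame(id = character(), organism = character(),
               siroheme_site = integer(), peripheral_cluster = integer(),
               additional_cluster = integer(), sb_pattern = character(),
               frh_core = integer(), ferredoxin_n_count = integer(),
               ferredoxin_c_count = integer(), fusion_order_ok = integer(),
               family = character(), group = character(),
               subgroup = character(), arch_class = character(),
               sublabel = character(), flags = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
}
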