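# Signature detection: anchor-column mapping of the siroheme-[Fe4-S4] and
# peripheral cysteines and the four sulfite-binding Arg/Lys positions onto a
# query via global alignment, ferredoxin-motif scanning, and FrhB-core
# detection by normalized alignment score.

#' Read an anchor profile
#'
#' An anchor profile packages the reference sequences and anchor coordinates
#' that define what "signature present" means: a DsrB-like reference with
#' four siroheme-site cysteines, four peripheral-cluster cysteines and four
#' sulfite-binding Arg/Lys positions, an FrhB-core reference, and the
#' cysteine-spacing pattern of a ferredoxin-type [Fe4-S4] motif.
#'
#' @param path Path to a profile YAML; `NULL` loads the packaged default.
#' @return An object of class `anchor_profile`.
#' @export
read_anchor_profile <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "anchor_profile.yaml",
                        package = "siroclass", mustWork = TRUE)
  }
  y <- yaml::read_yaml(path)
  dir <- dirname(path)
  dsr <- read_fasta(file.path(dir, y$dsr_reference_fasta))[[1]]
  frh <- read_fasta(file.path(dir, y$frh_reference_fasta))[[1]]
  sites <- do.call(rbind, lapply(y$anchor_sites, function(s) {
    data.frame(site_id = s$site_id, feature_tag = s$feature_tag,
               ref_position = as.integer(s$ref_position),
               allowed_residues = paste(s$allowed_residues, collapse = ""),
               stringsAsFactors = FALSE)
  }))
  stopifnot(all(sites$ref_position >= 1L),
            all(sites$ref_position <= nchar(dsr$sequence)))
  fam <- sub("_?(C?[0-9])$", "", sites$feature_tag)
  counts <- table(fam)
  if (!all(counts == 4L)) {
    stop("anchor profile must define exactly four sites per feature family")
  }
  sb <- sites[grepl("^SB", sites$feature_tag), ]
  sb <- sb[order(sb$feature_tag), ]
  if (is.unsorted(sb$ref_position, strictly = TRUE)) {
    stop("SB anchor sites must be ordered SB1 < SB2 < SB3 < SB4 by position")
  }
  gaps <- do.call(rbind, y$ferredoxin_motif$gaps)
  structure(list(version = y$version,
                 dsr_reference = dsr,
                 frh_reference = frh,
                 anchor_sites = sites,
                 ferredoxin_gaps = gaps,
                 core_score_threshold = y$core_score_threshold,
                 additional_motif_ref_positions =
                   as.integer(y$additional_motif_ref_positions)),
            class = "anchor_profile")
}

#' Packaged default anchor profile
#' @return An `anchor_profile` (see [read_anchor_profile()]).
#' @export
default_anchor_profile <- function() read_anchor_profile(NULL)

#' @export
print.anchor_profile <- function(x, ...) {
  cat(sprintf("<anchor_profile> v%s: %d anchor sites on %s (%d aa), core %s (%d aa)\n",
              x$version, nrow(x$anchor_sites), x$dsr_reference$id,
              nchar(x$dsr_reference$sequence), x$frh_reference$id,
              nchar(x$frh_reference$sequence)))
  invisible(x)
}

#' Map anchor sites onto a query protein
#'
#' Globally aligns the profile's DsrB-like reference to the query and reports,
#' for each anchor site, the query position and residue aligned to the
#' anchor's reference position. A site is occupied iff that residue is one of
#' the site's allowed residues; a site aligned to a gap is unoccupied.
#'
#' @param query A [protein_record()] or sequence string.
#' @param profile An [read_anchor_profile()] result.
#' @param scoring A [scoring_scheme()] (default BLOSUM62).
#' @return A data frame with columns `site_id`, `feature_tag`,
#'   `ref_position`, `query_position` (`NA` if gapped), `residue` (`"-"` if
#'   gapped) and `occupied`.
#' @export
map_anchor_sites <- function(query, profile, scoring = blosum62_scheme()) {
  pa <- global_align(profile$dsr_reference, query, scoring)
  qs <- .seq_of(query)
  sites <- profile$anchor_sites
  qpos <- pa$ref_to_query_map[sites$ref_position]
  residue <- ifelse(is.na(qpos), GAP_CHAR,
                    substring(qs, qpos, qpos))
  occupied <- mapply(function(res, allowed) {
    !identical(res, GAP_CHAR) && grepl(res, allowed, fixed = TRUE)
  }, residue, sites$allowed_residues)
  out <- sites
  out$query_position <- qpos
  out$residue <- residue
  out$occupied <- unname(occupied)
  attr(out, "alignment") <- pa
  out
}

#' Scan for ferredoxin-type cysteine motifs
#'
#' Finds non-overlapping, left-greedy matches of the cysteine-spacing pattern
#' (default C-x(2)-C-x(2)-C-x(3)-C, the canonical bacterial-ferredoxin
#' spacing) within a window of the sequence.
#'
#' @param sequence A [protein_record()] or sequence string.
#' @param window Length-2 integer vector, 1-based inclusive; default the
#'   whole sequence.
#' @param gaps 3x2 matrix of `[min, max]` residue counts between consecutive
#'   cysteines.
#' @return A data frame of 1-based motif `start`/`end` positions (absolute
#'   coordinates in the full sequence), zero rows when none found.
#' @export
detect_ferredoxin_motifs <- function(sequence,
                                     window = NULL,
                                     gaps = matrix(c(2, 2, 2, 2, 3, 3),
                                                   nrow = 3, byrow = TRUE)) {
  s <- .seq_of(sequence)
  n <- nchar(s)
  if (is.null(window)) window <- c(1L, n)
  stopifnot(length(window) == 2L, window[1] >= 1L, window[2] <= n)
  if (window[1] > window[2]) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  sub <- substr(s, window[1], window[2])
  pat <- paste0("C", paste(sprintf(".{%d,%d}C", gaps[, 1], gaps[, 2]),
                           collapse = ""))
  m <- gregexpr(pat, sub, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  start <- as.integer(m) + window[1] - 1L
  end <- start + attr(m, "match.length") - 1L
  data.frame(start = start, end = end)
}

#' Detect the FrhB core in a query protein
#'
#' Globally aligns the profile's FrhB-core reference to the query; the core
#' is called present when the alignment score, normalized by the reference's
#' self-alignment score, reaches the profile's threshold. The core interval
#' is the query span aligned to the reference.
#'
#' @inheritParams map_anchor_sites
#' @param threshold Optional override of the profile's
#'   `core_score_threshold`.
#' @return A list: `present`, `interval` (1-based inclusive query span, `NA`s
#'   when no reference position is aligned), `score` (normalized).
#' @export
detect_frh_core <- function(query, profile, scoring = blosum62_scheme(),
                            threshold = NULL) {
  if (is.null(threshold)) threshold <- profile$core_score_threshold
  ref <- profile$frh_reference
  self_score <- global_align(ref, ref, scoring)$score
  pa <- global_align(ref, query, scoring)
  norm <- pa$score / self_score
  mapped <- pa$ref_to_query_map[!is.na(pa$ref_to_query_map)]
  interval <- if (length(mapped)) range(mapped) else c(NA_integer_, NA_integer_)
  list(present = is.finite(norm) && norm >= threshold,
       interval = as.integer(interval),
       score = norm)
}

#' Build the full feature vector for a query protein
#'
#' Runs anchor mapping, ferredoxin-motif scanning and FrhB-core detection and
#' summarizes them into the per-protein signature summary consumed by the
#' classifier:
#' * `siroheme_site` / `peripheral_cluster`: present iff at least
#'   `siroheme_min_anchors` / `peripheral_min_anchors` of the four cysteine
#'   anchors are occupied (default all four).
#' * `additional_cluster`: present iff at least one ferredoxin motif lies in
#'   the window strictly after the mapped peripheral anchor block.
#' * `sb_present`: occupancy of the four sulfite-binding Arg/Lys anchors,
#'   SB1..SB4 counted from the N-terminus.
#' * `frh_core`, `core_interval`, and ferredoxin-motif counts strictly
#'   N-terminal (`ferredoxin_n_count`) and C-terminal (`ferredoxin_c_count`)
#'   of the core (`NA` when no core).
#' * `fusion_order_ok`: `TRUE` iff the core is present, the siroheme site is
#'   present, and the core interval ends before the first siroheme anchor in
#'   query coordinates (the chimeric Fsr architecture).
#'
#' @inheritParams map_anchor_sites
#' @param siroheme_min_anchors,peripheral_min_anchors Integers 1..4.
#' @param core_threshold Optional override of the profile's core-score
#'   threshold.
#' @return An object of class `feature_vector`.
#' @export
build_feature_vector <- function(query, profile,
                                 scoring = blosum62_scheme(),
                                 siroheme_min_anchors = 4L,
                                 peripheral_min_anchors = 4L,
                                 core_threshold = NULL) {
  stopifnot(siroheme_min_anchors %in% 1:4, peripheral_min_anchors %in% 1:4)
  qs <- .seq_of(query)
  sites <- map_anchor_sites(query, profile, scoring)
  tagfam <- sub("_?C?[0-9]$", "", sites$feature_tag)
  siro <- sites[tagfam == "SIROHEME", ]
  peri <- sites[tagfam == "PERIPHERAL", ]
  sb <- sites[tagfam == "SB", ]
  sb <- sb[order(sb$feature_tag), ]

  siroheme_site <- sum(siro$occupied) >= siroheme_min_anchors
  peripheral_cluster <- sum(peri$occupied) >= peripheral_min_anchors

  # additional (**) cluster: ferredoxin motif strictly after the mapped
  # peripheral anchor block; without a mapped block boundary there is no
  # evidence window and the feature is absent.
  peri_q <- peri$query_position
  add_window_start <- if (any(!is.na(peri_q))) max(peri_q, na.rm = TRUE) + 1L else NA_integer_
  additional_cluster <- FALSE
  if (!is.na(add_window_start) && add_window_start <= nchar(qs)) {
    motifs <- detect_ferredoxin_motifs(qs,
                                       window = c(add_window_start, nchar(qs)),
                                       gaps = profile$ferredoxin_gaps)
    additional_cluster <- nrow(motifs) >= 1L
  }

  core <- detect_frh_core(query, profile, scoring, threshold = core_threshold)
  if (core$present) {
    all_motifs <- detect_ferredoxin_motifs(qs, gaps = profile$ferredoxin_gaps)
    n_count <- sum(all_motifs$end < core$interval[1])
    c_count <- sum(all_motifs$start > core$interval[2])
  } else {
    n_count <- NA_integer_
    c_count <- NA_integer_
  }

  first_siro_q <- suppressWarnings(min(siro$query_position, na.rm = TRUE))
  fusion_order_ok <- isTRUE(core$present) && isTRUE(siroheme_site) &&
    is.finite(first_siro_q) && !any(is.na(core$interval)) &&
    core$interval[2] < first_siro_q

  structure(list(siroheme_site = siroheme_site,
                 peripheral_cluster = peripheral_cluster,
                 additional_cluster = additional_cluster,
                 sb_present = setNames(sb$occupied,
                                       c("SB1", "SB2", "SB3", "SB4")),
                 frh_core = core$present,
                 core_interval = core$interval,
                 core_score = core$score,
                 ferredoxin_n_count = as.integer(n_count),
                 ferredoxin_c_count = as.integer(c_count),
                 fusion_order_ok = fusion_order_ok),
            class = "feature_vector")
}

#' Construct a feature vector directly
#'
#' Mainly for rule-table exploration and tests: bypasses detection and builds
#' the summary object from stated values.
#'
#' @param siroheme_site,peripheral_cluster,additional_cluster Logicals.
#' @param sb_present Logical vector of length 4 (SB1..SB4).
#' @param frh_core Logical.
#' @param ferredoxin_n_count,ferredoxin_c_count Integer counts (`NA` when no
#'   core).
#' @param fusion_order_ok Logical.
#' @param core_interval Optional 1-based core span.
#' @return A `feature_vector`.
#' @export
feature_vector <- function(siroheme_site = FALSE,
                           peripheral_cluster = FALSE,
                           additional_cluster = FALSE,
                           sb_present = c(FALSE, FALSE, FALSE, FALSE),
                           frh_core = FALSE,
                           ferredoxin_n_count = NA_integer_,
                           ferredoxin_c_count = NA_integer_,
                           fusion_order_ok = FALSE,
                           core_interval = c(NA_integer_, NA_integer_)) {
  stopifnot(length(sb_present) == 4L)
  structure(list(siroheme_site = isTRUE(siroheme_site),
                 peripheral_cluster = isTRUE(peripheral_cluster),
                 additional_cluster = isTRUE(additional_cluster),
                 sb_present = setNames(as.logical(sb_present),
                                       c("SB1", "SB2", "SB3", "SB4")),
                 frh_core = isTRUE(frh_core),
                 core_interval = as.integer(core_interval),
                 core_score = NA_real_,
                 ferredoxin_n_count = as.integer(ferredoxin_n_count),
                 ferredoxin_c_count = as.integer(ferredoxin_c_count),
                 fusion_order_ok = isTRUE(fusion_order_ok)),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf(
    "<feature_vector> siroheme=%s peripheral=%s additional=%s sb=%s core=%s n/c=%s/%s order=%s\n",
    x$siroheme_site, x$peripheral_cluster, x$additional_cluster,
    paste(as.integer(x$sb_present), collapse = ""), x$frh_core,
    x$ferredoxin_n_count, x$ferredoxin_c_count, x$fusion_order_ok))
  invisible(x)
}
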