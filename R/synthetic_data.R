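# Labeled synthetic protein families with planted or ablated signatures.
# Templates start from the packaged anchor references; signatures are ablated
# by substitution (Cys -> Ala at cluster sites, Arg/Lys -> Ala at
# sulfite-binding sites) so that coordinates stay fixed across labels, and
# architectures (ferredoxin extensions, FrhB core, chimeric fusion) are built
# by concatenation. Noise is an independent per-site substitution process
# with optional short indels, with planted truth tracked throughout.

# ferredoxin-type motif block used for extensions: two canonical-spacing
# motifs separated by a short cysteine-free spacer
.EXT_MOTIF <- "CAACPPCAAAC"
.EXT_SPACER <- "GSTNV"
.EXT_BLOCK <- paste0(.EXT_MOTIF, .EXT_SPACER, .EXT_MOTIF)
.LINKER_NC <- "GSGSGS"      # between extension block and core
.LINKER_CD <- "GSTAGSTAGS"  # between core and Dsr-like region in the chimera

#' The twelve concrete Dsr-LP labels
#' @return Character vector `"Ia"` .. `"IIId"`.
#' @export
dsrlp_labels <- function() {
  as.vector(t(outer(c("I", "II", "III"), c("a", "b", "c", "d"), paste0)))
}

#' The closed label set of the synthetic generator
#' @return Character vector of all 17 labels the generator can plant.
#' @export
synthetic_labels <- function() {
  c(dsrlp_labels(), "FSR", "FRHB_LIKE", "FPOF_FAMILY", "FDHB_LIKE",
    "UNCLASSIFIED")
}

.site_positions <- function(profile, tag_prefix) {
  s <- profile$anchor_sites
  s <- s[startsWith(s$feature_tag, tag_prefix), ]
  s <- s[order(s$feature_tag), ]
  setNames(s$ref_position, s$feature_tag)
}

#' Build a labeled template sequence
#'
#' Constructs the archetypal sequence for a label together with its planted
#' feature vector and the anchor coordinates (site anchors plus motif
#' cysteines) in template coordinates. For the `UNCLASSIFIED` label a random
#' signature-free sequence is drawn from the current RNG stream.
#'
#' @param label One of [synthetic_labels()].
#' @param profile An [read_anchor_profile()] result.
#' @return A list: `record` ([protein_record()]), `feature_vector` (the
#'   label's defining [feature_vector()]), `anchors` (named integer vector of
#'   1-based anchor positions).
#' @export
build_template <- function(label, profile) {
  label <- match.arg(label, synthetic_labels())
  dsr <- profile$dsr_reference$sequence
  frh <- profile$frh_reference$sequence
  siro_pos <- .site_positions(profile, "SIROHEME")
  peri_pos <- .site_positions(profile, "PERIPHERAL")
  sb_pos <- .site_positions(profile, "SB")
  add_pos <- setNames(profile$additional_motif_ref_positions,
                      paste0("ADDITIONAL_C", seq_along(
                        profile$additional_motif_ref_positions)))

  if (label == "UNCLASSIFIED") {
    seq <- paste(sample(setdiff(AA_ALPHABET, c("C", "X")), 250,
                        replace = TRUE), collapse = "")
    return(list(record = protein_record("UNCLASSIFIED_template", seq,
                                        organism = "synthetic"),
                feature_vector = feature_vector(),
                anchors = integer(0)))
  }

  if (label %in% dsrlp_labels()) {
    group <- sub("[a-d]$", "", label)
    subgroup <- sub("^I+", "", label)
    chars <- strsplit(dsr, "")[[1]]
    if (group == "I") chars[peri_pos] <- "A"
    if (group %in% c("I", "II")) chars[add_pos] <- "A"
    sb_present <- rep(TRUE, 4L)
    if (subgroup != "d") {
      idx <- match(subgroup, c("a", "b", "c"))
      chars[sb_pos[idx]] <- "A"
      sb_present[idx] <- FALSE
    }
    fv <- feature_vector(siroheme_site = TRUE,
                         peripheral_cluster = group != "I",
                         additional_cluster = group == "III",
                         sb_present = sb_present)
    anchors <- c(siro_pos, peri_pos, sb_pos, add_pos)
    return(list(record = protein_record(paste0(label, "_template"),
                                        paste(chars, collapse = ""),
                                        organism = "synthetic"),
                feature_vector = fv, anchors = anchors))
  }

  # FrhB-core architectures and the chimeric Fsr
  frh_len <- nchar(frh)
  ext_cys <- as.integer(gregexpr("C", .EXT_BLOCK, fixed = TRUE)[[1]])
  if (label == "FRHB_LIKE") {
    seq <- frh
    core <- c(1L, frh_len)
    anchors <- integer(0)
    fv <- feature_vector(frh_core = TRUE, ferredoxin_n_count = 0L,
                         ferredoxin_c_count = 0L, core_interval = core)
  } else if (label == "FPOF_FAMILY") {
    pre <- paste0(.EXT_BLOCK, .LINKER_NC)
    seq <- paste0(pre, frh)
    core <- nchar(pre) + c(1L, frh_len)
    anchors <- setNames(ext_cys, paste0("EXT_C", seq_along(ext_cys)))
    fv <- feature_vector(frh_core = TRUE, ferredoxin_n_count = 2L,
                         ferredoxin_c_count = 0L, core_interval = core)
  } else if (label == "FDHB_LIKE") {
    seq <- paste0(frh, .LINKER_NC, .EXT_BLOCK)
    core <- c(1L, frh_len)
    off <- frh_len + nchar(.LINKER_NC)
    anchors <- setNames(ext_cys + off, paste0("EXT_C", seq_along(ext_cys)))
    fv <- feature_vector(frh_core = TRUE, ferredoxin_n_count = 0L,
                         ferredoxin_c_count = 2L, core_interval = core)
  } else { # FSR: [2 ferredoxin motifs][FrhB core][linker][group IIId region]
    pre <- paste0(.EXT_BLOCK, .LINKER_NC)
    off_dsr <- nchar(pre) + frh_len + nchar(.LINKER_CD)
    seq <- paste0(pre, frh, .LINKER_CD, dsr)
    core <- nchar(pre) + c(1L, frh_len)
    anchors <- c(setNames(ext_cys, paste0("EXT_C", seq_along(ext_cys))),
                 siro_pos + off_dsr, peri_pos + off_dsr, sb_pos + off_dsr,
                 add_pos + off_dsr)
    # the Dsr-region additional motif sits C-terminal of the core, so the
    # chimera's planted C-side motif count is 1
    fv <- feature_vector(siroheme_site = TRUE, peripheral_cluster = TRUE,
                         additional_cluster = TRUE,
                         sb_present = rep(TRUE, 4L),
                         frh_core = TRUE, ferredoxin_n_count = 2L,
                         ferredoxin_c_count = 1L, fusion_order_ok = TRUE,
                         core_interval = core)
  }
  list(record = protein_record(paste0(label, "_template"), seq,
                               organism = "synthetic"),
       feature_vector = fv, anchors = anchors)
}

#' Mutate a sequence with planted-truth bookkeeping
#'
#' Applies independent per-site substitutions (to a uniformly random
#' different residue) at rate `mu` outside anchor positions and `anchor_mu`
#' at anchor positions, then `rpois(1, indel_rate)` indels of length 1-3
#' placed uniformly; by default indels avoid anchor positions and their +/-2
#' neighborhoods so planted truth stays well-defined, and anchor coordinates
#' are re-indexed across insertions and deletions. Draws from the current RNG
#' stream unless `seed` is given.
#'
#' @param record A [protein_record()].
#' @param anchors Named integer vector of anchor positions.
#' @param mu,anchor_mu Per-site substitution probabilities in `[0, 1)`.
#' @param indel_rate Expected number of indels per sequence.
#' @param seed Optional integer seed.
#' @param avoid_anchors If `FALSE` (adversarial mode), indels may hit anchor
#'   neighborhoods; anchors deleted outright are dropped from the returned
#'   coordinates.
#' @return A list: `record` (mutated), `anchors` (re-indexed).
#' @export
mutate_record <- function(record, anchors, mu, anchor_mu = 0,
                          indel_rate = 0, seed = NULL,
                          avoid_anchors = TRUE) {
  stopifnot(mu >= 0, mu < 1, anchor_mu >= 0, anchor_mu < 1, indel_rate >= 0)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  chars <- strsplit(record$sequence, "")[[1]]
  n <- length(chars)
  residues <- setdiff(AA_ALPHABET, "X")
  rate <- rep(mu, n)
  rate[anchors[anchors <= n]] <- anchor_mu
  hit <- which(runif(n) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(residues, chars[i]), 1L)
  }

  n_indels <- rpois(1L, indel_rate)
  for (k in seq_len(n_indels)) {
    n_cur <- length(chars)
    len <- sample.int(3L, 1L)
    insertion <- runif(1) < 0.5
    blocked <- rep(FALSE, n_cur)
    if (avoid_anchors && length(anchors)) {
      nb <- unique(unlist(lapply(anchors, function(p) (p - 2L):(p + 2L))))
      nb <- nb[nb >= 1L & nb <= n_cur]
      blocked[nb] <- TRUE
    }
    if (insertion) {
      # insertion point after position p (p = 0 .. n); avoid splitting a
      # blocked neighborhood
      ok <- which(!(blocked | c(blocked[-1], FALSE)))
      if (!length(ok)) next
      p <- sample(c(0L, ok), 1L)
      ins <- sample(residues, len, replace = TRUE)
      chars <- append(chars, ins, after = p)
      anchors <- ifelse(anchors > p, anchors + len, anchors)
    } else {
      if (n_cur <= len + 1L) next
      starts <- seq_len(n_cur - len + 1L)
      ok <- starts[vapply(starts, function(s) !any(blocked[s:(s + len - 1L)]),
                          logical(1))]
      if (!length(ok)) next
      p <- if (length(ok) == 1L) ok else sample(ok, 1L)
      span <- p:(p + len - 1L)
      chars <- chars[-span]
      anchors <- anchors[!(anchors %in% span)]
      anchors <- ifelse(anchors > p + len - 1L, anchors - len, anchors)
    }
  }
  list(record = protein_record(record$id, paste(chars, collapse = ""),
                               organism = record$organism),
       anchors = anchors)
}

#' Specify one synthetic family
#'
#' @param label One of [synthetic_labels()].
#' @param n_sequences Positive integer.
#' @param mu Per-site substitution probability outside anchors, in `[0, 1)`.
#' @param anchor_mu Per-site substitution probability at anchors (default 0).
#' @param indel_rate Expected indels per sequence.
#' @param seed Integer seed for this family.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(label, n_sequences, mu = 0, anchor_mu = 0,
                           indel_rate = 0, seed = 1L) {
  label <- match.arg(label, synthetic_labels())
  stopifnot(n_sequences >= 1L, mu >= 0, mu < 1, anchor_mu >= 0,
            anchor_mu < 1, indel_rate >= 0)
  structure(list(label = label, n_sequences = as.integer(n_sequences),
                 mu = mu, anchor_mu = anchor_mu, indel_rate = indel_rate,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a labeled synthetic dataset
#'
#' Concatenates one family per spec. Ids are `"<label>_<k>"` with `k`
#' counting globally per label, so collisions are impossible even when specs
#' repeat a label. Deterministic given the specs' seeds.
#'
#' @param specs List of [synthetic_spec()] objects.
#' @param profile An [read_anchor_profile()] result.
#' @return An object of class `labeled_dataset`: `records` (list of
#'   [protein_record()]) and `truth` (named list per id with `label`,
#'   `feature_vector`, `anchors`).
#' @export
generate_dataset <- function(specs, profile) {
  if (length(specs) == 0L) stop("need at least one synthetic_spec")
  stopifnot(all(vapply(specs, inherits, logical(1), "synthetic_spec")))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  records <- list()
  truth <- list()
  label_counter <- integer(0)
  for (spec in specs) {
    set.seed(spec$seed)
    tmpl <- build_template(spec$label, profile)
    for (k in seq_len(spec$n_sequences)) {
      prev <- if (spec$label %in% names(label_counter))
        label_counter[[spec$label]] else 0L
      label_counter[spec$label] <- prev + 1L
      id <- sprintf("%s_%d", spec$label, prev + 1L)
      base <- protein_record(id, tmpl$record$sequence,
                             organism = tmpl$record$organism)
      mut <- mutate_record(base, tmpl$anchors, mu = spec$mu,
                           anchor_mu = spec$anchor_mu,
                           indel_rate = spec$indel_rate)
      records[[id]] <- mut$record
      truth[[id]] <- list(label = spec$label,
                          feature_vector = tmpl$feature_vector,
                          anchors = mut$anchors)
    }
  }
  structure(list(records = unname(records), truth = truth),
            class = "labeled_dataset")
}

#' Write the ground-truth table of a synthetic dataset
#'
#' @param dataset A [generate_dataset()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(dataset, path) {
  rows <- lapply(dataset$records, function(r) {
    tr <- dataset$truth[[r$id]]
    fv <- tr$feature_vector
    data.frame(id = r$id, label = tr$label,
               siroheme_site = as.integer(fv$siroheme_site),
               peripheral_cluster = as.integer(fv$peripheral_cluster),
               additional_cluster = as.integer(fv$additional_cluster),
               sb_pattern = paste(as.integer(fv$sb_present), collapse = ""),
               frh_core = as.integer(fv$frh_core),
               ferredoxin_n_count = fv$ferredoxin_n_count,
               ferredoxin_c_count = fv$ferredoxin_c_count,
               fusion_order_ok = as.integer(fv$fusion_order_ok),
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
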