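# Rule engine turning a feature vector into a label: Dsr-LP groups I/II/III
# with subgroups a-d defined by the missing sulfite-binding residue, the
# fused Fsr chimera, and FrhB-core domain-architecture classes.

DSRLP_GROUPS <- c("I", "II", "III")
DSRLP_SUBGROUPS <- c("a", "b", "c", "d")
ARCH_CLASSES <- c("FRHB_LIKE", "FPOF_FAMILY", "FDHB_LIKE")

#' Construct a group label
#'
#' @param family One of `DSR_LP`, `FSR`, `FSRN_FAMILY`, `UNCLASSIFIED`.
#' @param group Dsr-LP group `I`/`II`/`III` or `"none"`.
#' @param subgroup `a`-`d` or `"none"`.
#' @param arch_class Architecture class (`FRHB_LIKE`, `FPOF_FAMILY`,
#'   `FDHB_LIKE`) or `"none"`.
#' @param sublabel Context-refined sublabel (e.g. `"FGltS(I)-alpha"`), or
#'   `""`.
#' @param flags Character vector of anomaly flags.
#' @return An object of class `group_label`.
#' @export
group_label <- function(family = "UNCLASSIFIED", group = "none",
                        subgroup = "none", arch_class = "none",
                        sublabel = "", flags = character(0)) {
  family <- match.arg(family, c("DSR_LP", "FSR", "FSRN_FAMILY", "UNCLASSIFIED"))
  stopifnot(group %in% c(DSRLP_GROUPS, "none"),
            subgroup %in% c(DSRLP_SUBGROUPS, "none"),
            arch_class %in% c(ARCH_CLASSES, "none"))
  if (!family %in% c("DSR_LP", "FSR") && (group != "none" || subgroup != "none")) {
    stop("group/subgroup may only be set for DSR_LP or FSR families")
  }
  if (!family %in% c("FSRN_FAMILY", "FSR") && arch_class != "none") {
    stop("arch_class may only be set for FSRN_FAMILY or FSR families")
  }
  structure(list(family = family, group = group, subgroup = subgroup,
                 arch_class = arch_class, sublabel = sublabel,
                 flags = sort(unique(flags))),
            class = "group_label")
}

#' @export
print.group_label <- function(x, ...) {
  cat("<group_label>", format_group_label(x),
      if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ";"), "]") else "",
      "\n", sep = "")
  invisible(x)
}

#' Compact string form of a group label
#'
#' `"IIId"` for a Dsr-LP, `"FSR"` for the chimera, the architecture class for
#' an FrhB-core protein, `"UNCLASSIFIED"` otherwise.
#'
#' @param gl A [group_label()].
#' @return A single string.
#' @export
format_group_label <- function(gl) {
  switch(gl$family,
         DSR_LP = paste0(gl$group,
                         if (gl$subgroup != "none") gl$subgroup else ""),
         FSR = "FSR",
         FSRN_FAMILY = gl$arch_class,
         UNCLASSIFIED = "UNCLASSIFIED")
}

.sb_subgroup <- function(sb) {
  # sb: logical 4-vector SB1..SB4. Subgroups are defined only by which of
  # SB1-SB3 is missing; SB4 is invariably conserved in natural sequences.
  flags <- character(0)
  n <- sum(sb)
  subgroup <- "none"
  if (!sb[4]) flags <- c(flags, "MISSING_SB4")
  if (n < 3L) flags <- c(flags, "LOW_SB_COUNT")
  if (sb[4] && n >= 3L) {
    subgroup <- if (all(sb)) "d"
    else if (!sb[1]) "a"
    else if (!sb[2]) "b"
    else "c"
  }
  list(subgroup = subgroup, flags = flags)
}

#' Classify a feature vector as a Dsr-LP group/subgroup
#'
#' Rule table: no siroheme site, no Dsr-LP. Otherwise the group is set by the
#' peripheral (P) and additional (A) [Fe4-S4] clusters -- (P=F,A=F) group I;
#' (P=T,A=F) group II; (P=T,A=T) group III; the unobserved combination
#' (P=F,A=T) falls back to group I with an anomaly flag. The subgroup is the
#' position of the missing sulfite-binding Arg/Lys residue: all four present
#' is `d`, missing the 1st/2nd/3rd is `a`/`b`/`c`; a missing 4th residue or
#' fewer than three residues yields no subgroup, with a flag. Total: every
#' feature vector receives exactly one label.
#'
#' @param fv A [feature_vector()].
#' @return A [group_label()].
#' @export
classify_dsrlp <- function(fv) {
  if (!isTRUE(fv$siroheme_site)) {
    return(group_label("UNCLASSIFIED"))
  }
  flags <- character(0)
  if (fv$peripheral_cluster && fv$additional_cluster) {
    group <- "III"
  } else if (fv$peripheral_cluster) {
    group <- "II"
  } else if (fv$additional_cluster) {
    group <- "I"
    flags <- c(flags, "ANOMALOUS_ADDITIONAL_WITHOUT_PERIPHERAL")
  } else {
    group <- "I"
  }
  sbr <- .sb_subgroup(fv$sb_present)
  group_label("DSR_LP", group = group, subgroup = sbr$subgroup,
              flags = c(flags, sbr$flags))
}

#' Classify a feature vector as an FrhB-core architecture
#'
#' No FrhB core, unclassified. A bare core is `FRHB_LIKE`; a core with at
#' least two ferredoxin motifs N-terminal and none C-terminal is
#' `FPOF_FAMILY` (the Fsr-N / FpoF / FqoF architecture); the mirror image is
#' `FDHB_LIKE`. Any other extension pattern is unclassified with the observed
#' counts recorded as a flag.
#'
#' @param fv A [feature_vector()].
#' @return A [group_label()].
#' @export
classify_fsrn <- function(fv) {
  if (!isTRUE(fv$frh_core)) {
    return(group_label("UNCLASSIFIED"))
  }
  n <- fv$ferredoxin_n_count
  c_ <- fv$ferredoxin_c_count
  if (n == 0L && c_ == 0L) {
    group_label("FSRN_FAMILY", arch_class = "FRHB_LIKE")
  } else if (n >= 2L && c_ == 0L) {
    group_label("FSRN_FAMILY", arch_class = "FPOF_FAMILY")
  } else if (c_ >= 2L && n == 0L) {
    group_label("FSRN_FAMILY", arch_class = "FDHB_LIKE")
  } else {
    group_label("UNCLASSIFIED",
                flags = sprintf("FERREDOXIN_COUNTS_N%d_C%d", n, c_))
  }
}

#' Classify a protein from its full feature vector
#'
#' A protein carrying both the FrhB core and the siroheme site in the fused
#' N-to-C order is the chimeric Fsr: its Dsr-LP group/subgroup comes from the
#' C-terminal (Dsr-like) features and its architecture class from the
#' N-terminal ferredoxin extensions. A core-plus-siroheme protein in the
#' reversed order is unclassified with a flag, as no such architecture is
#' known. Otherwise a siroheme-bearing protein is classified as a Dsr-LP and
#' a core-bearing protein by its architecture.
#'
#' @param fv A [feature_vector()].
#' @return A [group_label()].
#' @export
classify_protein <- function(fv) {
  if (isTRUE(fv$frh_core) && isTRUE(fv$siroheme_site)) {
    if (!isTRUE(fv$fusion_order_ok)) {
      return(group_label("UNCLASSIFIED", flags = "FUSION_ORDER_VIOLATION"))
    }
    dsr <- classify_dsrlp(fv)
    n <- fv$ferredoxin_n_count
    arch <- if (n >= 2L) "FPOF_FAMILY" else if (n == 0L) "FRHB_LIKE" else "none"
    flags <- dsr$flags
    if (arch == "none") flags <- c(flags, sprintf("FERREDOXIN_N_COUNT_%d", n))
    return(group_label("FSR", group = dsr$group, subgroup = dsr$subgroup,
                       arch_class = arch, flags = flags))
  }
  if (isTRUE(fv$siroheme_site)) return(classify_dsrlp(fv))
  if (isTRUE(fv$frh_core)) return(classify_fsrn(fv))
  group_label("UNCLASSIFIED")
}

#' Refine architecture labels with genomic-context annotations
#'
#' Members of the FpoF-family architecture gain the sublabel
#' `"FGltS(I)-alpha"` when encoded adjacent to a glutamate synthase subunit
#' and `"aFsr-beta"` when adjacent to an assimilatory-type sulfite reductase;
#' FdhB-like members adjacent to a glutamate synthase gain
#' `"FGltS(II)-alpha"`. Proteins without a context row are unchanged; unknown
#' tags raise a warning, not an error.
#'
#' @param labels Named list of [group_label()] objects, keyed by protein id.
#' @param context_table Data frame with columns `id` and `tag`; recognized
#'   tags are `glutamate_synthase_adjacent` and `aSir_adjacent`.
#' @return The relabeled named list.
#' @export
apply_context_labels <- function(labels, context_table) {
  stopifnot(is.list(labels), !is.null(names(labels)),
            all(c("id", "tag") %in% names(context_table)))
  known <- c("glutamate_synthase_adjacent", "aSir_adjacent")
  for (k in seq_len(nrow(context_table))) {
    id <- context_table$id[k]
    tag <- context_table$tag[k]
    if (!tag %in% known) {
      warning("unknown context tag '", tag, "' for id '", id, "'")
      next
    }
    if (!id %in% names(labels)) next
    gl <- labels[[id]]
    if (gl$arch_class == "FPOF_FAMILY") {
      gl$sublabel <- if (tag == "glutamate_synthase_adjacent")
        "FGltS(I)-alpha" else "aFsr-beta"
    } else if (gl$arch_class == "FDHB_LIKE" &&
               tag == "glutamate_synthase_adjacent") {
      gl$sublabel <- "FGltS(II)-alpha"
    }
    labels[[id]] <- gl
  }
  labels
}

#' Read a genomic-context annotation table
#'
#' @param path Two-column TSV (`id`, `tag`), with header.
#' @return A data frame.
#' @export
read_context_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "tag") %in% names(df))) {
    stop("context table must have columns 'id' and 'tag'")
  }
  df
}
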