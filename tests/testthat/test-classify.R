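# Expected Dsr-LP label for one cell of the feature space, written as a
# direct transcription of the group/subgroup definitions, independent of the
# package's rule engine.
expected_dsrlp <- function(S, P, A, sb) {
  if (!S) return(list(family = "UNCLASSIFIED", group = "none",
                      subgroup = "none"))
  group <- if (P && A) "III" else if (P) "II" else "I"
  pattern <- paste(as.integer(sb), collapse = "")
  subgroup <- switch(pattern, "1111" = "d", "0111" = "a", "1011" = "b",
                     "1101" = "c", "none")
  list(family = "DSR_LP", group = group, subgroup = subgroup)
}

test_that("the Dsr-LP rule engine is total and exact on all 128 cells", {
  sb_cells <- expand.grid(rep(list(c(FALSE, TRUE)), 4))
  n_concrete <- 0L
  for (S in c(FALSE, TRUE)) for (P in c(FALSE, TRUE)) for (A in c(FALSE, TRUE)) {
    for (r in seq_len(nrow(sb_cells))) {
      sb <- unlist(sb_cells[r, ])
      fv <- feature_vector(siroheme_site = S, peripheral_cluster = P,
                           additional_cluster = A, sb_present = sb)
      gl <- classify_dsrlp(fv)
      exp <- expected_dsrlp(S, P, A, sb)
      expect_equal(gl$family, exp$family)
      expect_equal(gl$group, exp$group)
      expect_equal(gl$subgroup, exp$subgroup)
      if (S) {
        if (!sb[4]) expect_true("MISSING_SB4" %in% gl$flags)
        if (sum(sb) < 3) expect_true("LOW_SB_COUNT" %in% gl$flags)
        if (!P && A) {
          expect_true("ANOMALOUS_ADDITIONAL_WITHOUT_PERIPHERAL" %in% gl$flags)
        }
        if (gl$subgroup != "none") n_concrete <- n_concrete + 1L
      }
    }
  }
  # cells with a concrete subgroup: siroheme present, one of the 4 defined
  # SB patterns, any of the 4 (P, A) combinations
  expect_equal(n_concrete, 16L)
})

test_that("named rule-table examples classify as stated", {
  lab <- function(S, P, A, sb) {
    format_group_label(classify_dsrlp(feature_vector(
      siroheme_site = S, peripheral_cluster = P, additional_cluster = A,
      sb_present = sb)))
  }
  expect_equal(lab(TRUE, FALSE, FALSE, c(FALSE, TRUE, TRUE, TRUE)), "Ia")
  expect_equal(lab(TRUE, TRUE, TRUE, c(TRUE, TRUE, TRUE, TRUE)), "IIId")
  expect_equal(lab(FALSE, TRUE, TRUE, c(TRUE, TRUE, TRUE, TRUE)),
               "UNCLASSIFIED")
  expect_equal(lab(TRUE, TRUE, FALSE, c(TRUE, TRUE, TRUE, TRUE)), "IId")
  gl <- classify_dsrlp(feature_vector(siroheme_site = TRUE,
                                      sb_present = c(TRUE, TRUE, TRUE, FALSE)))
  expect_equal(gl$group, "I")
  expect_equal(gl$subgroup, "none")
  expect_true("MISSING_SB4" %in% gl$flags)
})

test_that("architecture classes follow the core/extension rules", {
  mk <- function(core, n, c_) {
    feature_vector(frh_core = core, ferredoxin_n_count = n,
                   ferredoxin_c_count = c_)
  }
  expect_equal(classify_fsrn(mk(TRUE, 0L, 0L))$arch_class, "FRHB_LIKE")
  expect_equal(classify_fsrn(mk(TRUE, 2L, 0L))$arch_class, "FPOF_FAMILY")
  expect_equal(classify_fsrn(mk(TRUE, 3L, 0L))$arch_class, "FPOF_FAMILY")
  expect_equal(classify_fsrn(mk(TRUE, 0L, 2L))$arch_class, "FDHB_LIKE")
  expect_equal(classify_fsrn(mk(FALSE, 0L, 0L))$family, "UNCLASSIFIED")
  odd <- classify_fsrn(mk(TRUE, 2L, 2L))
  expect_equal(odd$family, "UNCLASSIFIED")
  expect_true(any(grepl("FERREDOXIN_COUNTS_N2_C2", odd$flags)))
})

test_that("the chimera rule joins C-terminal group and N-terminal class", {
  fsr_fv <- feature_vector(siroheme_site = TRUE, peripheral_cluster = TRUE,
                           additional_cluster = TRUE,
                           sb_present = rep(TRUE, 4),
                           frh_core = TRUE, ferredoxin_n_count = 2L,
                           ferredoxin_c_count = 1L, fusion_order_ok = TRUE)
  gl <- classify_protein(fsr_fv)
  expect_equal(gl$family, "FSR")
  expect_equal(gl$group, "III")
  expect_equal(gl$subgroup, "d")
  expect_equal(gl$arch_class, "FPOF_FAMILY")

  # reversed fusion order is not a known architecture
  rev_fv <- fsr_fv
  rev_fv$fusion_order_ok <- FALSE
  gl2 <- classify_protein(rev_fv)
  expect_equal(gl2$family, "UNCLASSIFIED")
  expect_true("FUSION_ORDER_VIOLATION" %in% gl2$flags)

  # dispatch without the core falls through to the Dsr-LP engine
  dsr_fv <- feature_vector(siroheme_site = TRUE,
                           sb_present = c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(format_group_label(classify_protein(dsr_fv)), "Ia")
  expect_equal(classify_protein(feature_vector())$family, "UNCLASSIFIED")
})

test_that("context annotations refine architecture sublabels", {
  labels <- list(
    p1 = group_label("FSRN_FAMILY", arch_class = "FPOF_FAMILY"),
    p2 = group_label("FSRN_FAMILY", arch_class = "FPOF_FAMILY"),
    p3 = group_label("FSRN_FAMILY", arch_class = "FDHB_LIKE"),
    p4 = group_label("FSRN_FAMILY", arch_class = "FPOF_FAMILY"))
  ctx <- data.frame(
    id = c("p1", "p2", "p3", "ghost"),
    tag = c("glutamate_synthase_adjacent", "aSir_adjacent",
            "glutamate_synthase_adjacent", "glutamate_synthase_adjacent"))
  out <- apply_context_labels(labels, ctx)
  expect_equal(out$p1$sublabel, "FGltS(I)-alpha")
  expect_equal(out$p2$sublabel, "aFsr-beta")
  expect_equal(out$p3$sublabel, "FGltS(II)-alpha")
  expect_equal(out$p4$sublabel, "")  # no context row: unchanged
  expect_warning(
    apply_context_labels(labels, data.frame(id = "p1", tag = "mystery")),
    "unknown context tag")
})
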