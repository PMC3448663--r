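prof <- test_profile()
b62 <- test_scoring()

test_that("anchor mapping on the reference itself occupies every site", {
  occ <- map_anchor_sites(prof$dsr_reference, prof, b62)
  expect_true(all(occ$occupied))
  expect_equal(occ$query_position, occ$ref_position)
})

test_that("a planted SB2 ablation leaves only that site unoccupied", {
  chars <- strsplit(prof$dsr_reference$sequence, "")[[1]]
  sb2 <- prof$anchor_sites$ref_position[prof$anchor_sites$feature_tag == "SB2"]
  chars[sb2] <- "A"
  q <- protein_record("ablated", paste(chars, collapse = ""))
  occ <- map_anchor_sites(q, prof, b62)
  expect_false(occ$occupied[occ$feature_tag == "SB2"])
  expect_true(all(occ$occupied[occ$feature_tag != "SB2"]))
})

test_that("anchor mapping absorbs insertions; occupancy is indel-robust", {
  ref <- prof$dsr_reference$sequence
  sb1 <- prof$anchor_sites$ref_position[prof$anchor_sites$feature_tag == "SB1"]
  # 3 residues inserted before SB1: all sites still occupied, map shifts +3
  q <- paste0(substr(ref, 1, sb1 - 10), "WWW", substr(ref, sb1 - 9, nchar(ref)))
  occ <- map_anchor_sites(protein_record("ins3", q), prof, b62)
  expect_true(all(occ$occupied))
  expect_equal(occ$query_position, occ$ref_position + 3L)

  # seeded random insertions of <= 10 residues outside anchor neighborhoods
  tmpl <- build_template("IIId", prof)
  set.seed(404)
  for (k in 1:5) {
    mut <- mutate_record(tmpl$record, tmpl$anchors, mu = 0,
                         indel_rate = 3)
    occ <- map_anchor_sites(mut$record, prof, b62)
    expect_true(all(occ$occupied), info = paste("replicate", k))
  }
})

test_that("ferredoxin motif scan finds planted, non-overlapping matches", {
  hits <- detect_ferredoxin_motifs("CAACPPCAAAC")
  expect_equal(hits$start, 1L)
  expect_equal(hits$end, 11L)

  expect_equal(nrow(detect_ferredoxin_motifs("AAAA")), 0L)

  two <- paste0("CAACPPCAAAC", "WWWWW", "CAACPPCAAAC")
  hits2 <- detect_ferredoxin_motifs(two)
  expect_equal(nrow(hits2), 2L)
  expect_true(hits2$start[2] > hits2$end[1])

  # window restricts the scan
  expect_equal(nrow(detect_ferredoxin_motifs(two, window = c(12L, 16L))), 0L)
})

test_that("FrhB core detection is self-normalized and rejects shuffles", {
  core <- detect_frh_core(prof$frh_reference, prof, b62)
  expect_true(core$present)
  expect_equal(core$score, 1.0)
  expect_equal(core$interval, c(1L, nchar(prof$frh_reference$sequence)))

  # empirical null: same-composition shuffles score below threshold
  chars <- strsplit(prof$frh_reference$sequence, "")[[1]]
  set.seed(505)
  for (k in 1:20) {
    shuf <- paste(sample(chars), collapse = "")
    res <- detect_frh_core(protein_record("shuf", shuf), prof, b62)
    expect_false(res$present, info = paste("shuffle", k))
  }

  # ferredoxin block before the core shifts the interval past the block
  pre <- "CAACPPCAAACGSTNVCAACPPCAAACGSGSGS"
  q <- protein_record("ext", paste0(pre, prof$frh_reference$sequence))
  res <- detect_frh_core(q, prof, b62)
  expect_true(res$present)
  expect_equal(res$interval[1], nchar(pre) + 1L)
})

test_that("feature vectors reproduce planted truth at zero noise", {
  for (lab in c("IIId", "Ia", "FSR")) {
    tmpl <- build_template(lab, prof)
    fv <- build_feature_vector(tmpl$record, prof, b62)
    expect_true(fv_matches_truth(fv, tmpl$feature_vector), info = lab)
  }
  fsr <- build_feature_vector(build_template("FSR", prof)$record, prof, b62)
  expect_true(fsr$frh_core)
  expect_equal(fsr$ferredoxin_n_count, 2L)
  expect_true(fsr$fusion_order_ok)
  expect_true(fsr$siroheme_site)
})

test_that("anchor noise only degrades features, never restores ablated ones", {
  # a group I template has all peripheral + additional cysteines replaced by
  # Ala; anchor-level mutation must not spuriously recreate those clusters
  tmpl <- build_template("Ia", prof)
  set.seed(606)
  flips <- 0L
  for (k in 1:10) {
    mut <- mutate_record(tmpl$record, tmpl$anchors, mu = 0, anchor_mu = 0.3)
    fv <- build_feature_vector(mut$record, prof, b62)
    expect_false(fv$peripheral_cluster, info = paste("replicate", k))
    if (!fv$siroheme_site) flips <- flips + 1L
  }
  # high anchor noise should knock out the (strict, 4-of-4) siroheme call in
  # most replicates: degradation is toward absence
  expect_gt(flips, 5L)
})
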