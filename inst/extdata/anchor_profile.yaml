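# Packaged anchor profile, version 1.
#
# The two reference sequences are SYNTHETIC composites (see the [synthetic]
# tag in their FASTA headers): DSR_REF is a DsrB-like scaffold carrying every
# classifier signature at fixed, versioned coordinates; FRH_REF is a
# cysteine-free FrhB-core scaffold, so ferredoxin-motif counts on a query can
# only come from genuine N-/C-terminal extensions, never from the core itself.
# Real-sequence use requires only swapping this profile for one whose
# reference is a curated natural DsrB / FrhB sequence.
#
# Note on the siroheme site: some natural DsrB sequences couple the [Fe4-S4]
# center to siroheme through a non-conserved cysteine outside the four
# canonical anchors. That position is deliberately NOT an anchor site here and
# never counts toward siroheme-site presence.
version: 1
dsr_reference_fasta: anchor_dsr_reference.fasta
frh_reference_fasta: anchor_frh_reference.fasta
core_score_threshold: 0.5
anchor_sites:
  - {site_id: siroheme_c1, feature_tag: SIROHEME_C1, ref_position: 150, allowed_residues: [C]}
  - {site_id: siroheme_c2, feature_tag: SIROHEME_C2, ref_position: 156, allowed_residues: [C]}
  - {site_id: siroheme_c3, feature_tag: SIROHEME_C3, ref_position: 170, allowed_residues: [C]}
  - {site_id: siroheme_c4, feature_tag: SIROHEME_C4, ref_position: 176, allowed_residues: [C]}
  - {site_id: peripheral_c1, feature_tag: PERIPHERAL_C1, ref_position: 210, allowed_residues: [C]}
  - {site_id: peripheral_c2, feature_tag: PERIPHERAL_C2, ref_position: 216, allowed_residues: [C]}
  - {site_id: peripheral_c3, feature_tag: PERIPHERAL_C3, ref_position: 219, allowed_residues: [C]}
  - {site_id: peripheral_c4, feature_tag: PERIPHERAL_C4, ref_position: 225, allowed_residues: [C]}
  - {site_id: sb1, feature_tag: SB1, ref_position: 40, allowed_residues: [R, K]}
  - {site_id: sb2, feature_tag: SB2, ref_position: 80, allowed_residues: [R, K]}
  - {site_id: sb3, feature_tag: SB3, ref_position: 130, allowed_residues: [R, K]}
  - {site_id: sb4, feature_tag: SB4, ref_position: 190, allowed_residues: [R, K]}
# Bacterial-ferredoxin cysteine spacing C-x(2)-C-x(2)-C-x(3)-C; each entry is
# the [min, max] number of arbitrary residues between consecutive cysteines.
ferredoxin_motif:
  gaps: [[2, 2], [2, 2], [3, 3]]
# Cysteines of the additional (**) ferredoxin-type [Fe4-S4] motif carried by
# DSR_REF; the synthetic-data generator ablates these for group I/II labels.
additional_motif_ref_positions: [240, 243, 246, 250]
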