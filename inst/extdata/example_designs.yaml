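# Example assay-design configuration for the packaged FGFR2 model.
# Intervals are 1-based closed genomic coordinates (hg19 labels).
ba_fish_example:
  type: ba_fish
  probe5: {chrom: chr10, start: 123359972, end: 123409972}
  probe3: {chrom: chr10, start: 123185844, end: 123235844}
  resolution_bp: 1000000
dual_fish_bicc1:
  type: dual_fish
  partner_gene: BICC1
  partner_probe: {chrom: chr10, start: 60195000, end: 60230000}
  driver_probe: {chrom: chr10, start: 123237844, end: 123357972}
imbalance_default:
  type: imbalance
  exons_5p: ["1", "2", "3", "4", "5", "6", "7", "8"]
  exons_3p: ["17", "18"]
  ratio_threshold: 0.5
amplicon_panel:
  type: amplicon
  driver_primers: ["17", "18"]
  partner_primers:
    CCDC6: ["1", "2"]
    BICC1: ["2", "3"]
    TACC2: ["2", "3"]
    ATE1: ["2", "12"]
spe_panel:
  type: spe
  driver_primers: ["2", "5", "8", "17", "18"]
  design_isoform: NM_000141.4
hyca_dna_intron17:
  type: hyca
  level: DNA
  probes:
    - {chrom: chr10, start: 123265784, end: 123275462}
hyca_rna_all_exons:
  type: hyca
  level: RNA
  captured_exons:
    FGFR2: ["1", "2", "3", "4", "5", "6", "7", "8", "9", "10", "11", "12",
            "13", "14", "15", "16", "17", "18", "C3"]
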