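# Synthetic nine-strain, three-locus panel mirroring the Hydra
# strain-typing design. Allele values are repeat unit counts (one list per
# genomic copy; two entries per copy = heterozygous). Flank filler DNA is
# synthesised deterministically from flank_seed, so the templates are a
# pure function of this file; the run seed only drives stutter, mosaicism
# and primer-site disruption draws. Synthetic flanks are not the genomic
# flanks, so amplicon sizes match the published gel sizes only where the
# flank lengths were chosen to do so (218 bp at ms-c25145 in the
# AEP/H. oligactis strains; 104/118 bp at ms-DMTF1).
name: paper_like_panel
flank_seed: 20200928
resolution_bp: 2
stutter:
  p_minus: 0.1
  p_plus: 0.05
  n_molecules: 1000
  mosaic_allele_rate: 0.0
loci:
  ms-c25145:
    motif: TG
    forward: GGAAGAGACAGATTCCCAAT
    reverse: AATGCTCTTTCCTCACAGTC
    left_len: 110
    right_len: 80
    # 16 bp segment of the upstream flank deleted in the
    # H. vulgaris-Pallas strains (flank_deletion: true below)
    flank_insert: TAGTCAAAGTAGTACA
  ms-AIP:
    motif: AT
    forward: CGAGACAGCGTTTTCAAG
    reverse: CCACTCTTCCATTCTAACCA
    left_len: 90
    right_len: 83
  ms-DMTF1:
    motif: AT
    forward: ATCGATTTAACTGCTGAAGG
    reverse: AACCAAATCACAGATTTAAAATAA
    left_len: 50
    right_len: 42
strains:
  Hm-105:
    ms-c25145:
      alleles: [[6, 13], [17, 17]]   # duplicated locus: twice two alleles
      flank_deletion: true
    ms-AIP:
      alleles: [[13, 13]]
    ms-DMTF1:
      alleles: [[10, 10]]
      primer_site_intact: false
  Basel1:
    ms-c25145:
      alleles: [[7, 13]]
      flank_deletion: true
    ms-AIP:
      alleles: [[11, 11]]
      left_extra: 3                  # A-rich flank insertion
    ms-DMTF1:
      alleles: [[10, 10]]
      primer_site_intact: false
  Basel2:
    ms-c25145:
      alleles: [[8, 8]]
      flank_deletion: true
    ms-AIP:
      alleles: [[13, 13]]
      left_extra: 6
    ms-DMTF1:
      alleles: [[10, 10]]
      primer_site_intact: false
  reg-16:
    ms-c25145:
      alleles: [[8, 8]]
      flank_deletion: true
      primer_site_intact: false      # degraded template: no product
    ms-AIP:
      alleles: [[11, 11]]
      left_extra: 3
    ms-DMTF1:
      alleles: [[10, 10]]
      primer_site_intact: false
  AEP1:
    ms-c25145:
      alleles: [[14, 14]]
    ms-AIP:
      alleles: [[16, 16]]
      left_extra: -4                 # shorter A-rich region in H. vulgaris-NA
    ms-DMTF1:
      alleles: [[6, 13]]
  AEP2:
    ms-c25145:
      alleles: [[14, 14]]
    ms-AIP:
      alleles: [[16, 22]]
      left_extra: -4
    ms-DMTF1:
      alleles: [[6, 13]]
  Ho_CS:
    ms-c25145:
      alleles: [[14, 14]]
    ms-AIP:
      alleles: [[11, 11]]
      primer_site_intact: false
    ms-DMTF1:
      alleles: [[10, 10]]
      primer_site_intact: false
  Ho_CR:
    ms-c25145:
      alleles: [[14, 14]]
    ms-AIP:
      alleles: [[11, 11]]
      primer_site_intact: false
    ms-DMTF1:
      alleles: [[10, 10]]
      primer_site_intact: false
  Nicolet:
    ms-c25145:
      alleles: [[10, 10]]
      primer_site_intact: false
    ms-AIP:
      alleles: [[10, 10]]
      primer_site_intact: false
    ms-DMTF1:
      alleles: [[10, 10]]
      primer_site_intact: false
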