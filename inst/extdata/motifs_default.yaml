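# Default NB-ARC / TIR motif definitions for NLR subfamily classification.
#
# Pattern symbols: uppercase letter = that residue; 'h' = any hydrophobic
# residue (set below); 'x' = any residue. Discriminant positions (1-based)
# must match exactly and are never relaxed; they carry the subfamily
# signal. Non-discriminant positions tolerate up to max_mismatch
# substitutions.
#
# The RNL RNBS-D (CFLDLGxFP), the RNL QHD and the CNL2 VHD variants are
# fixed text-anchored consensus strings; the remaining variants are
# curated transcriptions built around the discriminant residues that
# separate the subfamilies (a conserved cysteine at position 5, 6 or 7
# after the conserved D4 of RNBS-D in CNL, CNL2 and TNL respectively,
# versus G6 and C1 in RNL; M1/V1/Q1 in the MHD variants). CNL2 carries no
# scannable RNBS-A variant (its RNBS-A is polymorphic); no TNL-specific
# MHD variant exists because TNLs share the hydrophobic-M1 form with
# CNLs. TIR1-TIR5 are carried for reporting only and take no part in the
# NB-ARC chain.
hydrophobic: AVLIMFWY
max_mismatch: 1
spacing:
  min: 20
  max: 180
motifs:
  - name: PLOOP
    pattern: GxxGxGKTT
    discriminant: [6, 7, 8]
    subfamily: SHARED
  - name: KIN2
    pattern: hhhhDDVW
    discriminant: [5, 6, 8]
    subfamily: SHARED
  - name: KIN3
    pattern: GSxhhhTTR
    discriminant: [1, 2]
    subfamily: SHARED
  - name: RNBS_C
    pattern: LSYxxLPxhLK
    discriminant: [1, 2, 3]
    subfamily: SHARED
  - name: GLPL
    pattern: GLPLAL
    discriminant: [1, 2, 3, 4]
    subfamily: SHARED
  - name: RNBS_A_CNL
    pattern: FDhxAWVCVSQ
    discriminant: [2, 6, 8]
    subfamily: CNL
  - name: RNBS_A_RNL
    pattern: FDhxAWVTVSE
    discriminant: [2, 6, 8]
    subfamily: RNL
  - name: RNBS_A_TNL
    pattern: FLENhREhS
    discriminant: [3, 4, 6]
    subfamily: TNL
  - name: RNBS_D_CNL
    pattern: hFLDCWxLP
    discriminant: [4, 5, 6]
    subfamily: CNL
  - name: RNBS_D_CNL2
    pattern: xFLDLCxFP
    discriminant: [4, 6]
    subfamily: CNL2
  - name: RNBS_D_RNL
    pattern: CFLDLGxFP
    discriminant: [1, 4, 6]
    subfamily: RNL
  - name: RNBS_D_TNL
    pattern: xFLDLxChP
    discriminant: [4, 7]
    subfamily: TNL
  - name: MHD_CNL
    pattern: MHD
    discriminant: [1, 2, 3]
    subfamily: CNL
  - name: MHD_CNL2
    pattern: VHD
    discriminant: [1, 2, 3]
    subfamily: CNL2
  - name: MHD_RNL
    pattern: QHD
    discriminant: [1, 2, 3]
    subfamily: RNL
  - name: TIR1
    pattern: FDVFLSFRG
    discriminant: [1, 4]
    subfamily: SHARED
  - name: TIR2
    pattern: PVFYxVDPS
    discriminant: [6, 7]
    subfamily: SHARED
  - name: TIR3
    pattern: YASSxWCLxEL
    discriminant: [6, 7]
    subfamily: SHARED
  - name: TIR4
    pattern: LxKWRxALxE
    discriminant: [4, 5]
    subfamily: SHARED
  - name: TIR5
    pattern: WRxALxEAAx
    discriminant: [1, 2]
    subfamily: SHARED
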