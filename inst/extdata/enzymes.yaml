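# Shipped restriction-enzyme catalog (public REBASE recognition data).
# cut_offset: cut position from the motif start, top strand; Type IIS
# downstream cutters (AcuI, MmeI) carry motif length + downstream distance.
- name: AcuI
  recognition: CTGAAG
  cut_offset: 22      # CTGAAG(16/14)
- name: AluI
  recognition: AGCT
  cut_offset: 2       # AG^CT
- name: ApoI
  recognition: RAATTY
  cut_offset: 1       # R^AATTY
- name: Hpy188I
  recognition: TCNGA
  cut_offset: 3       # TCN^GA
- name: MmeI
  recognition: TCCRAC
  cut_offset: 26      # TCCRAC(20/18)
- name: MseI
  recognition: TTAA
  cut_offset: 1       # T^TAA
- name: MspI
  recognition: CCGG
  cut_offset: 1       # C^CGG
- name: SwaI
  recognition: ATTTAAAT
  cut_offset: 4       # ATTT^AAAT
- name: TaqI
  recognition: TCGA
  cut_offset: 1       # T^CGA
- name: Tsp45I
  recognition: GTSAC
  cut_offset: 0       # ^GTSAC
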