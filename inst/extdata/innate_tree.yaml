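nodes:
  Cells:
    parent: All
    gate:
      kind: threshold1d
      channels:
      - Beads
      side:
      - below
      threshold: 4.0
      fallback_percentile: 0.95
      min_peak_frac: 0.05
  Size:
    parent: Cells
    gate:
      kind: threshold1d
      channels:
      - FSC-A
      side:
      - above
      fallback_percentile: 0.05
      min_peak_frac: 0.05
  Singlets:
    parent: Size
    gate:
      kind: polygon
      channels:
      - FSC-A
      - FSC-H
      vertices:
      - - 0.0
        - -3000.0
      - - 262144.0
        - 83886.08
      - - 262144.0
        - 196608.0
      - - 0.0
        - 3000.0
      fallback_percentile: 0.95
      min_peak_frac: 0.05
  Live:
    parent: Singlets
    gate:
      kind: threshold1d
      channels:
      - Viability
      side:
      - below
      fallback_percentile: 0.995
      min_peak_frac: 0.01
  Leukocytes:
    parent: Live
    gate:
      kind: threshold1d
      channels:
      - CD45
      side:
      - above
      threshold: 2.0
      fallback_percentile: 0.95
      min_peak_frac: 0.05
  Granulocytes:
    parent: Leukocytes
    gate:
      kind: threshold1d
      channels:
      - CD66
      side:
      - above
      fallback_percentile: 0.95
      min_peak_frac: 0.05
  NonGranulocytes:
    parent: Leukocytes
    gate:
      kind: threshold1d
      channels:
      - CD66
      side:
      - below
      fallback_percentile: 0.95
      min_peak_frac: 0.05
  MatureNeutrophils:
    parent: Granulocytes
    gate:
      kind: rect2d
      channels:
      - CD11b
      - CD16
      side:
      - above
      - above
      fallback_percentile: 0.95
      min_peak_frac: 0.05
  ImmatureNeutrophils1:
    parent: Granulocytes
    gate:
      kind: rect2d
      channels:
      - CD11b
      - CD16
      side:
      - below
      - below
      fallback_percentile: 0.95
      min_peak_frac: 0.05
  ImmatureNeutrophils2:
    parent: Granulocytes
    gate:
      kind: rect2d
      channels:
      - CD11b
      - CD16
      side:
      - below
      - above
      fallback_percentile: 0.95
      min_peak_frac: 0.05
  CD11bposCD16negGranulocytes:
    parent: Granulocytes
    gate:
      kind: rect2d
      channels:
      - CD11b
      - CD16
      side:
      - above
      - below
      fallback_percentile: 0.95
      min_peak_frac: 0.05
  Monocytes:
    parent: NonGranulocytes
    gate:
      kind: rect2d
      channels:
      - HLADR
      - CD14
      side:
      - above
      - above
      fallback_percentile: 0.95
      min_peak_frac: 0.05
  HLADRposCD14neg:
    parent: NonGranulocytes
    gate:
      kind: rect2d
      channels:
      - HLADR
      - CD14
      side:
      - above
      - below
      fallback_percentile: 0.95
      min_peak_frac: 0.05
  HLADRnegCD14neg:
    parent: NonGranulocytes
    gate:
      kind: rect2d
      channels:
      - HLADR
      - CD14
      side:
      - below
      - below
      fallback_percentile: 0.95
      min_peak_frac: 0.05
  NKcells:
    parent: HLADRnegCD14neg
    gate:
      kind: rect2d
      channels:
      - CD56
      - CD16
      side:
      - above
      - above
      fallback_percentile: 0.95
      min_peak_frac: 0.05
  Lymphocytes:
    parent: HLADRnegCD14neg
    gate:
      kind: rect2d
      channels:
      - CD56
      - CD16
      side:
      - below
      - below
      fallback_percentile: 0.95
      min_peak_frac: 0.05
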