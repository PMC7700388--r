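roles:
  lipid_P:
    resnames: DOP
    names: P
  amphiphile:
    resnames:
    - DOP
    - CHL
  ca_marker:
    names: CA
  hvr_motif:
    resnums:
    - 180
    - 181
    - 182
    - 183
    - 184
    names:
    - 'N'
    - CA
    - C
    - O
  far_group:
    resnames: FAR
  gtp_group:
    resnames: GTP
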