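# Selection rules for a CHARMM-named all-atom system: DOPC/DOPS bilayer with
# cholesterol, protein chain with standard residue numbering, farnesyl
# (resname FAR here; adjust to the topology, e.g. CYF for farnesyl-cysteine)
# and bound GTP.
roles:
  lipid_P:
    resnames: [DOPC, DOPS]
    names: [P]
  amphiphile:
    resnames: [DOPC, DOPS, CHL1]
    names: [P, O3]      # one marker atom per amphiphile
  ca_marker:
    names: [CA]
  hvr_motif:
    resnums: [180, 181, 182, 183, 184]
    names: [N, CA, C, O]
  far_group:
    resnames: [FAR]
  gtp_group:
    resnames: [GTP]
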