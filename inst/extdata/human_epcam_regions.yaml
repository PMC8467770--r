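# Example region definitions for the human EpCAM reference system, in the
# author 1-based sequence numbering of the extracellular region:
#   loop  — the thyroglobulin (TY) loop
#   siteA — the TYD binding site
#   siteB — the CTD binding site
regions:
  loop: 78-98
  siteA: 109-115
  siteB: 219-225
  numbering: author 1-based sequence numbering
analysis:
  center_cutoffs: [6.5, 8.0, 12.0]
  atom_contact_cutoff: 4.5
  min_contact_residues: 3
  bootstrap_replicates: 10000
  ci_level: 0.95
  seed: 1
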