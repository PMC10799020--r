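# Demo patch/FRAP cohort: eight conditions emulating a two-partner
# crosslinking x ligand design. Group-level ground truths use published-range
# mobile fractions; D in the few x 10^-2 um^2/s range typical of
# transmembrane receptors.
beam:
  w: 0.77            # Gaussian spot e^-2 radius, um
  K: 3               # ~68% bleach depth
  t_max: 120         # post-bleach follow-up, s
  dt_post: 0.4       # sampling interval, s
  n_pre: 10
  monitor_interval: 0.4
noise:
  sigma0: 0.02
  scheme: signal-scaled
cell_cv: 0.15        # between-cell CV of D and R_f
conditions:
  - {condition: NRP1_ENG_free,        crosslinked: false, ligand: none,   D: 0.025, R_f: 0.64, n_cells: 30}
  - {condition: NRP1_ENG_CL,          crosslinked: true,  ligand: none,   D: 0.025, R_f: 0.39, n_cells: 30}
  - {condition: NRP1_ENG_CL_VEGFA,    crosslinked: true,  ligand: VEGF-A, D: 0.025, R_f: 0.26, n_cells: 30}
  - {condition: VEGFR2_ENG_free,      crosslinked: false, ligand: none,   D: 0.030, R_f: 0.62, n_cells: 30}
  - {condition: VEGFR2_ENG_CL,        crosslinked: true,  ligand: none,   D: 0.030, R_f: 0.42, n_cells: 30}
  - {condition: NRP1_VEGFR2_free,     crosslinked: false, ligand: none,   D: 0.025, R_f: 0.56, n_cells: 30}
  - {condition: NRP1_VEGFR2_CL,       crosslinked: true,  ligand: none,   D: 0.025, R_f: 0.34, n_cells: 30}
  - {condition: NRP1_VEGFR2_CL_ENG,   crosslinked: true,  ligand: none,   D: 0.025, R_f: 0.18, n_cells: 30}
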