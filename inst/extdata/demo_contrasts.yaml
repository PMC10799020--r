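# Contrasts over the demo cohort: crosslink contrasts yield interaction
# calls and complex fractions; the ligand contrast tests a VEGF-A effect.
- {name: NRP1_with_ENG,        free: NRP1_ENG_free,    crosslinked: NRP1_ENG_CL}
- {name: VEGFR2_with_ENG,      free: VEGFR2_ENG_free,  crosslinked: VEGFR2_ENG_CL}
- {name: NRP1_with_VEGFR2,     free: NRP1_VEGFR2_free, crosslinked: NRP1_VEGFR2_CL}
- {name: NRP1_VEGFR2_plus_ENG, free: NRP1_VEGFR2_free, crosslinked: NRP1_VEGFR2_CL_ENG}
- {name: VEGFA_on_NRP1_ENG_CL, type: ligand, base: NRP1_ENG_CL, ligand: NRP1_ENG_CL_VEGFA}
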