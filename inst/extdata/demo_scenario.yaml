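# Small demonstration scenario: a 2x2 methylome design on a 300 kb
# chromosome with nine planted age-DMRs, plus feeding and MIAMI simulations.
seed: 1
tissue_mode: gastrocnemius
design:
  n_per_group: 3
  chrom_lengths:
    chr1: 300000
  cpg_spacing_mean: 100
  coverage_mean: 15
effects:
  n_age_hyper: 6
  n_age_hypo: 3
feeding:
  n_per_state: 5
miami:
  n_probes: 500
  frac_hyper: 0.1
  frac_hypo: 0.1
  noise_sd: 0.1
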