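# End-to-end pipeline on synthetic data emulating the Tawharanui
# reintroduction: 21 + 4 founders, 9 breeding seasons.  The model block
# fixes the reduced model (no sex/translocation/banding-age effects, no
# year effects on resighting or fecundity); the two fits differ only in
# whether fecundity is density dependent.  MCMC settings are kept modest so
# the whole run finishes in about a minute.
seed: 20070301
out: outputs/tawharanui_synthetic
simulate:
  preset: tawharanui
  n_years: 9
  density_dependent: false
model:
  sex_on_adult: false
  translocation_effect: false
  banding_age_effect: false
  density_on_juvenile: false
  year_re_on_resighting: false
  year_re_on_fecundity: false
mcmc:
  iterations: 4000
  burn_in: 1000
  chains: 2
  thin: 4
fits:
  - {name: U_noDD, prior_mode: uninformative, density_on_fecundity: false}
  - {name: U_DD, prior_mode: uninformative, density_on_fecundity: true}
sequential:
  kmax: 3
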