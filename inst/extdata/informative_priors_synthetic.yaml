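# SYNTHETIC PLACEHOLDER informative prior set.
#
# The published data-derived predictive distributions for these four
# parameters live in a supplement that is not shipped with this package.
# These stand-in values were calibrated once so that the prior-only finite
# rate of increase is about 1.08 with a 95% interval of roughly
# (0.76, 1.66), the documented prior-predictive behaviour for a peninsular
# reintroduction site (lower apparent juvenile survival than island sites).
# They are NOT the published priors; replace this file with the real ones
# for inference on real data.
mean_fecundity:          # fledglings per female per year, prior on log f
  family: normal
  scale: log
  par1: 1.3083328196501788   # log(3.7)
  par2: 0.33
sigma_female:            # SD of female effect on log fecundity (>= 0)
  family: normal
  scale: natural
  par1: 0.30
  par2: 0.10
adult_survival:          # annual adult survival, prior on logit scale
  family: normal
  scale: logit
  par1: 1.1526795099383855   # qlogis(0.76)
  par2: 0.38
juvenile_survival:       # apparent juvenile survival, prior on logit scale
  family: normal
  scale: logit
  par1: -1.6946138176447566  # qlogis(0.155)
  par2: 0.65
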