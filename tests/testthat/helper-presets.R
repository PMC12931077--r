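# Shared generating parameters for the recovery tests: the published
# construct presets plus small helpers.

kv101_act <- function(gamma = 1) preset_params("kv10.1", gamma)$act
kv102_act <- function(gamma = 1) preset_params("kv10.2", gamma)$act
coexpr_preset <- function() preset_params("coexpression")

grid_mV <- seq(-120, 30, 10)

# Monte-Carlo tetramer-assembly oracle: sample n channels with i.i.d.
# Bernoulli(p_s) subunits, assign each channel its composition Boltzmann
# (all-mutant channels conduct nothing), average the per-channel current.
mc_mixture_current <- function(act, mix, v, n = 1e6) {
  m <- stats::rbinom(n, 4, mix$p_s)
  po <- ifelse(m == 4, 0,
               boltzmann_open_fraction(v, vn_of_composition(pmin(m, 3),
                                                            act$v_n,
                                                            mix$v_ns),
                                       act$k_n))
  i <- act$gamma * (v - act$e_rev) * po
  list(mean = mean(i), se = stats::sd(i) / sqrt(n))
}
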