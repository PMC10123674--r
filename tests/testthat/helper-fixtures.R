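# Shared fixtures: small thermograms and parameter sets built in code.

lysozyme_eq <- function() equilibrium_params(dH0 = 107, t_m = 335, cp_step = 2.27)
lysozyme_stat <- function() stat_params(dE0 = 110, t_m = 335, cv = 1.05)
lysozyme_zb <- function() {
  zimm_bragg_params(h0 = 0.91, cv_res = 0.007, sigma = 5e-7, n_res = 129,
                    t_m = 335)
}

flat_thermogram <- function(t_from = 300, t_to = 310, step = 0.1, cp = 1) {
  tt <- seq(t_from, t_to, by = step)
  as_thermogram(data.frame(temperature = tt, cp = cp))
}

noise_free_scenario <- function(name, seed = 1L) {
  sp <- scenario(name, seed = seed)
  sp$noise_sd <- 0
  sp
}
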