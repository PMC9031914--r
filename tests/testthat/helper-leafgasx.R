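# shared fixtures: default parameter sets and noiseless protocol specs
p_default <- function(...) fvcb_params(...)

spec_quiet <- function(seed = 1L, ...) {
  sim_spec(noise_sd_A = 0, noise_sd_F = 0, seed = seed, ...)
}

# effective Michaelis constant at the parameters' oxygen level
km_of <- function(p) p$Kc * (1 + p$O / p$Ko)

# independent scalar evaluation of the J(PAR) quadratic via polyroot
j_quadratic_oracle <- function(par, alphaJ, thetaJ, Jmax) {
  aI <- alphaJ * par
  roots <- polyroot(c(aI * Jmax, -(aI + Jmax), thetaJ))
  min(Re(roots))
}
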