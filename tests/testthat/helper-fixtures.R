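# Shared in-code fixtures: random but valid profiles, stages and emission
# matrices, all seeded by the caller.

random_phase_profile <- function(seed) {
  set.seed(seed)
  m <- matrix(stats::rexp(34), 17L, 2L)
  phase_profile(m / sum(m))
}

random_stage <- function(seed, eta_range = c(-3, 0.9)) {
  set.seed(seed)
  apcd_stage("rand",
             matrix(stats::runif(34, eta_range[1], eta_range[2]), 17L, 2L))
}

random_congener_masses <- function(seed, scale = 10) {
  set.seed(seed)
  stats::setNames(stats::rexp(17) * scale, congener_names())
}

# single-year pulse emission matrix (g), one row
pulse_emissions <- function(year, masses) {
  m <- matrix(masses, nrow = 1L,
              dimnames = list(year, congener_names()))
  m
}

uniform_half_lives <- function(value = 20) {
  stats::setNames(rep(value, 17L), congener_names())
}
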