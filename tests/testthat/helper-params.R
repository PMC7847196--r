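# Shared fixtures: parameter sets and small simulated studies, all built in
# code at test time.

pdx_params <- function() {
  read_params_yaml(system.file("extdata", "pdx_params_synthetic.yaml",
                               package = "xenopower"))
}

cdx_params <- function() {
  read_params_yaml(system.file("extdata", "cdx_params_synthetic.yaml",
                               package = "xenopower"))
}

# the small parameter set used by the frozen Monte-Carlo oracle values
oracle_params <- function(sigma3 = 0.05) {
  growth_params(mu1 = 0, mu2 = log(0.1), sigma1 = 0.1, sigma2 = 0.2,
                sigma3 = sigma3)
}

# two-animal hand study: control 100 -> 500 mm^3, treated 100 -> 300 mm^3,
# doubled per arm so the t-test precondition (n >= 2) holds where needed
hand_study <- function(n_copies = 1) {
  mk <- function(id, arm, v14) {
    animal_trajectory(id, arm, c(0, 14), c(100, v14))
  }
  animals <- list()
  for (k in seq_len(n_copies)) {
    animals <- c(animals, list(mk(sprintf("C%d", k), "control", 500),
                               mk(sprintf("T%d", k), "treated", 300)))
  }
  study_table("hand", animals, horizon = 14)
}
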