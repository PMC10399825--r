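# Shared fixtures: an average subject (study-mean measurements) and one
# cached synthetic trial so that several test files can reuse it.
FS <- 10000 / 9

average_subject <- function() {
  anthropometry(L_ac_ecl = 0.358, L_ecm_psu = 0.27, L_ecm_palm = 0.30,
                body_mass = 78.7, sex = "male",
                F_hand_max_flex = 202.6, F_hand_max_ext = 167.0)
}

average_fixed <- derive_fixed_parameters(average_subject())

cached_trial <- local({
  trial <- NULL
  function() {
    if (is.null(trial)) trial <<- make_trial(synthetic_trial_spec(seed = 42L))
    trial
  }
})

# matrix of zero excitations for forward-dynamics tests
zero_excitation <- function(n) matrix(0, nrow = n, ncol = 4)
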