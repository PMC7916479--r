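# Shared fixtures, built lazily and cached for the whole run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

fix_layout <- function() cached("layout", function() speller_layout())

# A clean profile: no noise, no alpha background, no trial jitter.
noiseless_profile <- function(seed = 5, ...) {
  subject_profile(subject_seed = seed,
                  noise_scale = c(wet = 0, dry = 0),
                  alpha_scale = 0, amplitude_jitter = 0, ...)
}

# Noiseless 3-block wet+dry session at 250 Hz (identity-check fixture;
# 3 blocks so leave-one-block-out TRCA keeps 2 training trials per class).
fix_clean_session <- function() cached("clean_session", function() {
  simulate_subject(fix_layout(), noiseless_profile(), n_blocks = 3,
                   electrodes = c("wet", "dry"), sampling_rate = 250)
})

fix_clean_record <- function() cached("clean_record", function() {
  session_to_record(fix_clean_session())
})

# Default-noise 3-block wet+dry session at 250 Hz (realistic fixture used for
# the qualitative-ordering and transfer tests).
fix_noisy_record <- function() cached("noisy_record", function() {
  sess <- simulate_subject(fix_layout(), subject_profile(subject_seed = 11),
                           n_blocks = 3, electrodes = c("wet", "dry"),
                           sampling_rate = 250)
  session_to_record(sess)
})

# Full-protocol session: 10 blocks, both electrodes, 1000 Hz acquisition.
fix_full_record <- function() cached("full_record", function() {
  sess <- simulate_subject(fix_layout(), subject_profile(subject_seed = 1),
                           n_blocks = 10, electrodes = c("wet", "dry"),
                           sampling_rate = 1000)
  list(session = sess, record = session_to_record(sess))
})

# Pure-noise epochs (no evoked response): 10 blocks x 12 trials, wet.
fix_noise_only_epochs <- function() cached("noise_only_epochs", function() {
  prof <- subject_profile(subject_seed = 3,
                          amplitudes_wet = rep(0, 4),
                          amplitudes_dry = rep(0, 4))
  sess <- simulate_subject(fix_layout(), prof, n_blocks = 10,
                           electrodes = "wet", sampling_rate = 250)
  record_to_epochs(session_to_record(sess), "wet")
})
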