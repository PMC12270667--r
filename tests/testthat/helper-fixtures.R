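# Shared fixtures: small noiseless sessions and a default screen/pRF.

default_screen <- function(ppd = 20) screen_geometry(8, 4.5, ppd)

# pRF with no surround suppression (pure Gaussian activation)
prf_no_norm <- function(...) {
  prf_params(x = 0, y = 0, sigma1 = 0.7, sigma2 = 1.4,
             amp_act = 1, amp_norm = 0, b = 0, d = 1, ...)
}

noiseless_config <- function(...) {
  session_config(noise_sd = 0, drift_amp = 0, ...)
}

# Single-condition noiseless session plus its 20-point evoked profile
noiseless_profile <- function(condition, seed = 11, gm_size = 7,
                              truth_params = list()) {
  cfg <- noiseless_config(conditions = condition, gm_size = gm_size,
                          truth_params = truth_params)
  paradigms <- lapply(1:2, function(v)
    build_paradigm(v, seed = seed, conditions = condition))
  sess <- generate_session(paradigms, config = cfg, seed = seed)
  runs <- preprocess_session(sess)
  es <- epoch_and_average(runs, tr = cfg$tr)
  m20 <- select_gm_and_regrid(es$means[[condition]], runs[[1]]$gm_bounds)
  list(session = sess, runs = runs, epochs = es, m20 = m20)
}
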