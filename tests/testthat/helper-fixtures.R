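# shared fixtures, all generated in code

tiny_device <- function(a_p = 30, a_d = -40) {
  device_params(g_min = 100, g_max = 170.3, p_max = 100, a_p = a_p, a_d = a_d)
}

# a small, well-separated 2-odorant / 2-channel profile for cheap tests
tiny_profile <- function() {
  m <- matrix(c(150, 110,
                112, 148), 2, 2,
              dimnames = list(c("chA", "chB"), c("o1", "o2")))
  affinity_profile(m, noise_sd = 1, baseline_gmax = c(100, 100), ref_ppm = 3)
}

single_sets <- function(seed = 5L) {
  suppressWarnings(build_datasets(default_affinity_profile(),
                                  default_classes("single"), seed = seed))
}

mixed_sets <- function(seed = 5L) {
  suppressWarnings(build_datasets(default_affinity_profile(),
                                  default_classes("mixed"),
                                  n_train = 2194L, n_infer = 366L, seed = seed))
}
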