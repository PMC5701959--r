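# shared small objects for fast module tests; built once per test run
small_params <- function(nt = 30L) acquisition_params(n_timepoints = nt)

# cached 32^3 phantom and noiseless series (cheap but not free)
.test_cache <- new.env(parent = emptyenv())

test_phantom <- function() {
  if (is.null(.test_cache$ph)) .test_cache$ph <- build_phantom(c(32, 32, 32),
                                                               seed = 7)
  .test_cache$ph
}

test_series <- function() {
  if (is.null(.test_cache$ser)) {
    ph <- test_phantom()
    pr <- small_params()
    bl <- simulate_blood_curve(pr)
    .test_cache$bl <- bl
    .test_cache$ser <- simulate_series(ph, bl, pr, noise_sd = 0, seed = 7)
  }
  .test_cache$ser
}

test_blood <- function() {
  test_series()
  .test_cache$bl
}
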