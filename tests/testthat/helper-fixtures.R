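# Shared fixtures, built lazily and cached for the whole test run. The
# reduced-fidelity isochromat grid (15 x 101) keeps dictionary builds at
# test scale; accuracy-critical simulator tests use the full default grid.

.fixtures <- new.env(parent = emptyenv())

.cached <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

reduced_grid <- function() isochromat_grid(n_readout = 15, n_slice = 101)

reduced_dict <- function() .cached("reduced_dict", function() {
  build_dictionary(tse_protocol(), reduced_grid(), pulse_model())
})

reduced_fine_dict <- function() .cached("reduced_fine_dict", function() {
  interpolate_dictionary(reduced_dict())
})

# noiseless phantom plus forward-simulated series shared by round-trip tests
noiseless_phantom <- function() .cached("noiseless_phantom", function() {
  make_phantom(phantom_spec(shape = c(96, 96), noise_snr = Inf), seed = 5)
})

noiseless_ir <- function() .cached("noiseless_ir", function() {
  simulate_ir_series(noiseless_phantom(), seed = 6)
})

noiseless_tse <- function() .cached("noiseless_tse", function() {
  simulate_tse_series(noiseless_phantom(), grid = reduced_grid(), seed = 6)
})

# default-shape (160 x 160) noiseless phantom for the round-trip criteria
default_phantom <- function() .cached("default_phantom", function() {
  make_phantom(phantom_spec(noise_snr = Inf), seed = 5)
})

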