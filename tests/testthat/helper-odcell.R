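# shared fixtures built in code

# a clean single-rod image spec with deterministic dimensions
single_rod_spec <- function(length_um = 3.0, width_um = 1.26, seed = 1L) {
  image_spec(n_cells = 1L, shape = c(128L, 128L),
             length_dist = c(length_um, 0), width_dist = c(width_um, 0),
             seed = seed)
}

# rounds like the measurement tables do (half away from zero, 1 decimal)
round1 <- function(x) floor(x * 10 + 0.5) / 10

# printed reference values used across tests (frozen from the embedded table)
REF_N_GLUCOSE <- 11.1e8   # cells/ml/OD
REF_VTOT_GLUCOSE <- 3.6   # ul/ml/OD
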