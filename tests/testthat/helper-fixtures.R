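# Shared, lazily built fixtures. Pipeline runs cost seconds each, so
# expensive objects are built once per test session and reused.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

surrogate_of <- function(kind) {
  cached(paste0("surrogate_", kind),
         function() make_surrogate(surrogate_spec(kind, seed = 3)))
}

# a complete noisy, misaligned femur pipeline run reused by several tests
noisy_femur_run <- function() {
  cached("noisy_femur_run", function() {
    base <- surrogate_of("femur")
    pair <- make_pair(base, asymmetry_spec(noise_sd = 0.3,
                                           misalign_rot_deg = 15,
                                           misalign_trans_mm = 10),
                      seed = 7)
    list(pair = pair,
         cs = run_pair(pair$left, pair$right, "femur",
                       default_config(seed = 5)))
  })
}

# a clean (no bump, no noise) but misaligned pair of a given bone, run
# through the full pipeline: the null-symmetry case
null_run <- function(bone) {
  cached(paste0("null_run_", bone), function() {
    base <- surrogate_of(bone)
    pair <- make_pair(base, asymmetry_spec(misalign_rot_deg = 15,
                                           misalign_trans_mm = 10),
                      seed = 9)
    list(pair = pair,
         cs = run_pair(pair$left, pair$right, bone, default_config(seed = 5)))
  })
}

# small unit sphere mesh for geometric oracles
unit_sphere <- function(level = 3L) {
  cached(paste0("sphere_", level),
         function() osteosym:::icosphere(level))
}
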