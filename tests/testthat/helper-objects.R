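# Shared, lazily built fixtures (scene construction and transport runs are
# the expensive parts; build each once per session).
.fixtures <- new.env(parent = emptyenv())

.cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

test_spectrum <- function(kvp = 28) {
  .cached(paste0("spec", kvp), generate_spectrum(tube_setting(kvp = kvp)))
}

test_scene_cc <- function() {
  .cached("scene_cc", build_scene(breast_spec(5.6), view = "CC"))
}

test_scene_mlo <- function() {
  .cached("scene_mlo", build_scene(breast_spec(5.6), view = "MLO"))
}

# moderate-statistics CC tally reused by transport/dosimetry tests
test_tally_cc <- function() {
  .cached("tally_cc",
          run_transport(test_scene_cc(), test_spectrum(), 2e5, rng_seed = 42))
}

test_tally_mlo <- function() {
  .cached("tally_mlo",
          run_transport(test_scene_mlo(), test_spectrum(), 2e5, rng_seed = 43))
}

test_protocol_table <- function() {
  .cached("odt", {
    proto <- exposure_protocol(kvp = 28)
    normalize_tallies(list(CC = test_tally_cc(), MLO = test_tally_mlo()),
                      proto, test_scene_cc())
  })
}
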