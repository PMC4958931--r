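# The scaled-down emergent-structure study: a 30 x 30 lattice with three
# 10-row digits run through the full experimental track (15 cycles per
# phase, default parameters, membrane noise on, receptive-field maps at
# phase ends).  Computed once per test run and shared by every test that
# scores the emergent map.
.study_cache <- new.env(parent = emptyenv())

study_spec <- function() lattice_spec(30, 7, c(10, 10, 10))

study_track <- function() {
  if (is.null(.study_cache$track)) {
    set.seed(101)
    net <- somatonet(study_spec())
    .study_cache$track <- run_track(net, "experimental", n_cycles = 15,
                                    rf_every = 15)
  }
  .study_cache$track
}
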