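test_that("cycles present every patch once and advance the schedule", {
  net <- somatonet(tiny_spec(), seed = 5)
  pats <- enumerate_patches(net$spec, 3, 3)
  expect_equal(nrow(pats), 3L * (3L - 3L + 1L) * (9L - 3L + 1L))  # 21
  set.seed(5)
  net2 <- run_cycle(net, pats)
  expect_equal(net2$cycle, 1L)
  expect_equal(net2$beta_w, net$beta_w * 0.99)
  # determinism: same seed, same cycle
  set.seed(5)
  net3 <- run_cycle(net, pats)
  expect_identical(net2$weights, net3$weights)
})

test_that("phases gate plasticity off during mapping and log every cycle", {
  net <- somatonet(tiny_spec(), seed = 6)
  set.seed(6)
  ph <- run_phase(net, phase_spec("baseline", n_cycles = 2, patch_h = 3,
                                  patch_w = 3, rf_every = 1))
  expect_equal(nrow(ph$log), 2L)
  expect_equal(ph$log$trials, c(21L, 21L))
  expect_equal(names(ph$rf_maps), c("1", "2"))
  expect_s3_class(ph$rf_maps[[1]], "rf_map")
  expect_equal(ph$net$cycle, 2L)
  expect_equal(ph$net$history$trials, 42L)
  # a zero-cycle phase changes nothing and derives no maps
  ph0 <- run_phase(net, phase_spec("baseline", n_cycles = 0, patch_h = 3,
                                   patch_w = 3))
  expect_identical(ph0$net$weights, net$weights)
  expect_equal(length(ph0$rf_maps), 0L)
  # optional per-cycle weight checkpoints
  set.seed(6)
  phc <- run_phase(net, phase_spec("baseline", 2, 3, 3, rf_every = 0),
                   checkpoint_weights = TRUE)
  expect_equal(names(phc$checkpoints), c("1", "2"))
  expect_identical(phc$checkpoints[["2"]], phc$net$weights)
})

test_that("receptive-field mapping is weight-neutral within a phase", {
  net <- somatonet(tiny_spec(), seed = 7)
  set.seed(7)
  a <- run_phase(net, phase_spec("baseline", 1, 3, 3, rf_every = 1))
  set.seed(7)
  b <- run_phase(net, phase_spec("baseline", 1, 3, 3, rf_every = 0))
  # identical weights whether or not a map was derived after the cycle:
  # probe trials never adapt or renormalize weights
  expect_identical(a$net$weights, b$net$weights)
})

test_that("syndactyly phases fuse D1-D2 and release restores the baseline set", {
  expect_equal(phase_spec("syndactyly")$boundary_mode, "fuse_d1_d2")
  expect_equal(phase_spec("release")$boundary_mode, "respect_all")
  expect_equal(phase_spec("uniform_control")$boundary_mode, "uniform")
  s <- tiny_spec()
  expect_equal(nrow(enumerate_patches(s, 3, 3, "fuse_d1_d2")),
               (6L - 3L + 1L) * 7L + 7L)          # fused band + D3
})

test_that("tracks chain phases and keep stimulation counts matched on D3", {
  net <- somatonet(tiny_spec(), seed = 8,
                   neuron = neuron_params(noise_amp = 0))
  tr <- run_track(net, "both", n_cycles = 1, rf_every = 0,
                  patch_h = 3, patch_w = 3, seed = 8)
  expect_setequal(names(tr$phases),
                  c("baseline", "syndactyly", "release",
                    "control_1", "control_2"))
  # the control branch starts from the baseline-refined network
  expect_identical(tr$phases$baseline$net$history$phase, "baseline")
  expect_equal(nrow(tr$manifest), 5L)
  # D3 receives identical per-cycle placements on both branches
  n_d3 <- function(mode) sum(enumerate_patches(tiny_spec(), 3, 3,
                                               mode)$digit == "D3")
  expect_equal(n_d3("respect_all"), n_d3("fuse_d1_d2"))
  # reproducibility end to end
  tr2 <- run_track(somatonet(tiny_spec(), seed = 8,
                             neuron = neuron_params(noise_amp = 0)),
                   "both", n_cycles = 1, rf_every = 0,
                   patch_h = 3, patch_w = 3, seed = 8)
  expect_identical(tr$phases$release$net$weights,
                   tr2$phases$release$net$weights)
  expect_identical(tr$phases$control_2$net$weights,
                   tr2$phases$control_2$net$weights)
})

test_that("the adaptation step resets per phase by default and can continue", {
  net <- somatonet(tiny_spec(), seed = 9)
  set.seed(9)
  ph1 <- run_phase(net, phase_spec("baseline", 2, 3, 3, rf_every = 0))
  expect_equal(ph1$net$beta_w, 0.00025 * 0.99^2)
  set.seed(9)
  ph2 <- run_phase(ph1$net, phase_spec("syndactyly", 1, 3, 3, rf_every = 0))
  expect_equal(ph2$net$beta_w, 0.00025 * 0.99)   # reset, then one decay
  cont <- plasticity_params(beta_reset = FALSE)
  netc <- somatonet(tiny_spec(), plasticity = cont, seed = 9)
  set.seed(9)
  phc <- run_phase(netc, phase_spec("baseline", 2, 3, 3, rf_every = 0))
  set.seed(9)
  phc2 <- run_phase(phc$net, phase_spec("syndactyly", 1, 3, 3, rf_every = 0))
  expect_equal(phc2$net$beta_w, 0.00025 * 0.99^3)
})

test_that("report tallies patches per digit and manifest totals", {
  net <- somatonet(tiny_spec(), seed = 10,
                   neuron = neuron_params(noise_amp = 0))
  tr <- run_track(net, "experimental", n_cycles = 1, rf_every = 1,
                  patch_h = 3, patch_w = 3, seed = 10)
  rep <- report(tr)
  expect_equal(sum(rep$manifest$trials), 21L + 35L + 21L)
  base_counts <- rep$patch_counts[rep$patch_counts$phase == "baseline", ]
  expect_equal(sort(base_counts$patches_per_cycle), c(7L, 7L, 7L))
  expect_true(all(c("band_widths", "border_centroids") %in% names(rep)))
})
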