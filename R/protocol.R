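#' Experimental phase specification
#'
#' A phase is a fixed number of stimulation cycles under one boundary
#' condition.  One cycle presents every admissible patch placement exactly
#' once, in seeded random order, with plasticity on and trial-end
#' normalization; the adaptation step `beta_w` decays once per completed
#' cycle.  Receptive-field maps (plasticity gated off) are derived after
#' each `rf_every`-th cycle.
#'
#' Phase kinds map to boundary modes: `baseline`, `release` and
#' `baseline_control` stimulate within digits (`respect_all`); `syndactyly`
#' ignores the D1--D2 boundary (`fuse_d1_d2`); `uniform_control` lets patches
#' range over the whole lattice.  `release` is identical in stimulation to
#' `baseline` -- the distinction is that it is applied to a syndactyly-refined
#' network.
#'
#' @param kind phase kind (see Details).
#' @param n_cycles number of stimulation cycles.
#' @param patch_h,patch_w stimulus patch extent in nodes.
#' @param rf_every derive a receptive-field map after every `rf_every`-th
#'   cycle (1 = after each cycle, matching the reference protocol; 0 = none).
#' @return Object of class `phase_spec`.
#' @export
phase_spec <- function(kind = c("baseline", "syndactyly", "release",
                                "baseline_control", "uniform_control"),
                       n_cycles = 15L, patch_h = 7L, patch_w = 7L,
                       rf_every = 1L) {
  kind <- match.arg(kind)
  if (n_cycles < 0L) stop("n_cycles must be nonnegative")
  boundary_mode <- switch(kind,
                          syndactyly = "fuse_d1_d2",
                          uniform_control = "uniform",
                          "respect_all")
  structure(list(kind = kind, n_cycles = as.integer(n_cycles),
                 patch_h = as.integer(patch_h), patch_w = as.integer(patch_w),
                 boundary_mode = boundary_mode,
                 rf_every = as.integer(rf_every)),
            class = "phase_spec")
}

#' Run one stimulation cycle
#'
#' Presents every enumerated patch exactly once in a random order drawn from
#' the current RNG stream, with plasticity on; weights are normalized at the
#' end of every trial and the adaptation step decays once at cycle end.
#'
#' @param net a `somatonet`.
#' @param patches patch placements from [enumerate_patches()]; defaults to
#'   the baseline enumeration for the network's lattice.
#' @param shuffle present patches in random order (the protocol); `FALSE`
#'   presents them in enumeration order.
#' @return The updated network (completed-cycle counter advanced, `beta_w`
#'   decayed).
#' @export
run_cycle <- function(net, patches = enumerate_patches(net$spec),
                      shuffle = TRUE) {
  ord <- if (shuffle) sample.int(nrow(patches)) else seq_len(nrow(patches))
  stims <- cbind(patches$row[ord] - 1L, patches$col[ord] - 1L,
                 patches$height[ord], patches$width[ord])
  storage.mode(stims) <- "integer"
  res <- run_block(net, stims, net$trial$stim_mag, renormalize = TRUE,
                   gate = TRUE)
  net <- update_weights(net, res$weights)
  net$beta_w <- decay_beta(net$beta_w, 1L, net$plasticity$alpha_beta)
  net$cycle <- net$cycle + 1L
  net
}

#' Run one experimental phase
#'
#' Runs `n_cycles` stimulation cycles under the phase's boundary condition.
#' After each `rf_every`-th cycle plasticity is gated off, the full
#' receptive-field mapping procedure is executed (one probe trial per input
#' node) and a receptive-field map is derived; probing never alters the
#' weights.  By default the adaptation step is reset to `beta_w0` at phase
#' start (each phase runs a fresh schedule); see [plasticity_params()].
#'
#' @param net a `somatonet`.
#' @param phase a [phase_spec()].
#' @param checkpoint_weights if `TRUE`, keep a snapshot of the full weight
#'   array after every cycle (in `checkpoints`); off by default since a
#'   45 x 45 snapshot is ~3 MB per cycle.
#' @param verbose print per-cycle progress.
#' @return List of class `somato_phase`: the updated `net`, `rf_maps` (named
#'   by completed-cycle count), a per-cycle `log` data frame, and optionally
#'   per-cycle weight `checkpoints`.
#' @export
run_phase <- function(net, phase, checkpoint_weights = FALSE,
                      verbose = FALSE) {
  stopifnot(inherits(phase, "phase_spec"))
  if (net$plasticity$beta_reset) net$beta_w <- net$plasticity$beta_w0
  patches <- enumerate_patches(net$spec, phase$patch_h, phase$patch_w,
                               phase$boundary_mode)
  rf_maps <- list()
  checkpoints <- list()
  log <- data.frame(cycle = integer(), trials = integer(), beta_w = numeric())
  for (k in seq_len(phase$n_cycles)) {
    beta_used <- net$beta_w
    net <- run_cycle(net, patches)
    log <- rbind(log, data.frame(cycle = net$cycle, trials = nrow(patches),
                                 beta_w = beta_used))
    if (phase$rf_every > 0L && k %% phase$rf_every == 0L) {
      tensor <- probe_map(net)
      rf_maps[[as.character(net$cycle)]] <- rf_map(tensor)
    }
    if (checkpoint_weights)
      checkpoints[[as.character(net$cycle)]] <- net$weights
    if (verbose)
      message(sprintf("[%s] cycle %d/%d (%d trials, beta_w %.3g)",
                      phase$kind, k, phase$n_cycles, nrow(patches), beta_used))
  }
  net$history <- rbind(net$history,
                       data.frame(phase = phase$kind, cycles = phase$n_cycles,
                                  trials = phase$n_cycles * nrow(patches)))
  out <- list(net = net, rf_maps = rf_maps, log = log, phase = phase)
  if (checkpoint_weights) out$checkpoints <- checkpoints
  structure(out, class = "somato_phase")
}

#' Run an experimental or control track
#'
#' The experimental track evolves one network through baseline refinement,
#' simulated digital syndactyly (D1--D2 fused), and syndactyly release.  The
#' control track subjects the same baseline-refined network to two further
#' complete baseline refinements instead, so that the control digit D3 (and
#' all regions far from the D1--D2 border) receives exactly the same number
#' of stimulation trials on both tracks.  `track = "both"` runs the shared
#' baseline once and branches, as in the reference protocol.
#'
#' @param net a freshly initialized `somatonet` (or any starting network).
#' @param track `"experimental"`, `"control"`, or `"both"`.
#' @param n_cycles cycles per phase.
#' @param rf_every receptive-field mapping cadence within each phase
#'   (see [phase_spec()]).
#' @param patch_h,patch_w stimulus patch extent.
#' @param seed optional seed for the whole run (one RNG stream; permutations
#'   and membrane noise are drawn from it in a fixed order, so runs are
#'   replayable).
#' @param verbose print progress.
#' @return Object of class `somato_track`: list with `track`, `phases` (a
#'   named list of [run_phase()] results), and a `manifest` data frame.
#'   For `track = "both"`, `phases` holds the shared `baseline` plus
#'   `syndactyly`, `release`, `control_1`, `control_2`.
#' @export
run_track <- function(net, track = c("experimental", "control", "both"),
                      n_cycles = 15L, rf_every = 0L,
                      patch_h = 7L, patch_w = 7L, seed = NULL,
                      verbose = FALSE) {
  track <- match.arg(track)
  force(net)   # evaluate before seeding: construction may consume the RNG
  if (!is.null(seed)) set.seed(seed)
  ph <- function(kind) phase_spec(kind, n_cycles, patch_h, patch_w, rf_every)
  phases <- list()
  base <- run_phase(net, ph("baseline"), verbose)
  phases$baseline <- base
  if (track %in% c("experimental", "both")) {
    syn <- run_phase(base$net, ph("syndactyly"), verbose)
    rel <- run_phase(syn$net, ph("release"), verbose)
    phases$syndactyly <- syn
    phases$release <- rel
  }
  if (track %in% c("control", "both")) {
    c1 <- run_phase(base$net, ph("baseline_control"), verbose)
    c2 <- run_phase(c1$net, ph("baseline_control"), verbose)
    phases$control_1 <- c1
    phases$control_2 <- c2
  }
  manifest <- do.call(rbind, lapply(names(phases), function(nm) {
    lg <- phases[[nm]]$log
    if (nrow(lg)) cbind(phase = nm, lg) else NULL
  }))
  structure(list(track = track, phases = phases, manifest = manifest,
                 n_cycles = n_cycles, seed = seed),
            class = "somato_track")
}

#' @export
print.somato_track <- function(x, ...) {
  cat(sprintf("Somatotopic %s track: %s\n", x$track,
              paste(names(x$phases), collapse = " -> ")))
  tot <- sum(x$manifest$trials)
  cat(sprintf("  %d cycles/phase, %d stimulation trials total\n",
              x$n_cycles, tot))
  invisible(x)
}

#' Protocol accounting tables
#'
#' Summarizes a run: trials per phase and cycle, patch counts per digit per
#' cycle, and -- when receptive-field maps were derived -- the divergence
#' band widths and border-exclusion counts of the final map of each phase.
#'
#' @param track a [run_track()] result.
#' @return Named list of data frames.
#' @export
report <- function(track) {
  stopifnot(inherits(track, "somato_track"))
  spec <- track$phases[[1L]]$net$spec
  counts <- do.call(rbind, lapply(names(track$phases), function(nm) {
    phs <- track$phases[[nm]]$phase
    pats <- enumerate_patches(spec, phs$patch_h, phs$patch_w,
                              phs$boundary_mode)
    tab <- as.data.frame(table(pats$digit), stringsAsFactors = FALSE)
    names(tab) <- c("digit", "patches_per_cycle")
    cbind(phase = nm, tab)
  }))
  out <- list(manifest = track$manifest, patch_counts = counts)
  maps <- lapply(track$phases, function(p) {
    if (length(p$rf_maps)) p$rf_maps[[length(p$rf_maps)]] else NULL
  })
  maps <- Filter(Negate(is.null), maps)
  if (length(maps)) {
    out$band_widths <- do.call(rbind, lapply(names(maps), function(nm)
      cbind(phase = nm, divergence_band_width(maps[[nm]], spec))))
    out$border_centroids <- do.call(rbind, lapply(names(maps), function(nm) {
      bc <- centroid_border_cells(maps[[nm]], spec)
      data.frame(phase = nm, boundary = bc$boundary,
                 n_border_centroids = bc$n)
    }))
  }
  out
}
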