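#' Construct a somatotopic network
#'
#' Builds the full model: paired `N` x `N` input and cortical lattices, the
#' four masked connection-weight sets (`ES`, `EE`, `EI`, `IE`) initialized
#' i.i.d. uniform and immediately normalized to their postsynaptic resource
#' levels, and the neuron/plasticity/trial parameter sets.  There is no
#' spatial preconditioning: all structure seen after refinement is emergent.
#'
#' The returned object is a plain list; all protocol functions
#' ([run_trial()], [run_cycle()], [run_phase()], [run_track()]) are
#' functional and return an updated copy.
#'
#' @param spec a [lattice_spec()].
#' @param neuron a [neuron_params()].
#' @param plasticity a [plasticity_params()].
#' @param trial a [trial_spec()].
#' @param seed optional integer seed set before drawing initial weights.
#' @return Object of class `somatonet` with elements `spec`, `neuron`,
#'   `plasticity`, `trial`, `weights` (numeric array `N^2` cells x `M^2`
#'   offsets x 4 types), `beta_w` (current adaptation step), `cycle` (count
#'   of completed cycles) and `history` (per-phase log).
#' @examples
#' net <- somatonet(lattice_spec(9, 3, c(3, 3, 3)), seed = 1)
#' summary(net)
#' @export
somatonet <- function(spec, neuron = neuron_params(),
                      plasticity = plasticity_params(),
                      trial = trial_spec(), seed = NULL) {
  stopifnot(inherits(spec, "lattice_spec"), inherits(neuron, "neuron_params"),
            inherits(plasticity, "plasticity_params"),
            inherits(trial, "trial_spec"))
  if (!is.null(seed)) set.seed(seed)
  structure(
    list(spec = spec, neuron = neuron, plasticity = plasticity, trial = trial,
         weights = init_weights(spec, plasticity$resources),
         beta_w = plasticity$beta_w0, cycle = 0L,
         history = data.frame(phase = character(), cycles = integer(),
                              trials = integer())),
    class = "somatonet")
}

#' Initialize connection weights
#'
#' Draws one uniform value per structurally present connection (the clipped
#' `M` x `M` mask of each cell, all four types) and normalizes each cell's
#' incoming weights of each type to the type's resource mean.  The uniform
#' range is immaterial: normalization makes the result scale-invariant.
#'
#' @param spec a [lattice_spec()].
#' @param resources per-type resource levels (see [plasticity_params()]).
#' @return Numeric array `N^2` x `M^2` x 4 with dimnames on the type axis;
#'   structurally absent slots (mask clipped at the edge) are exactly zero.
#' @export
init_weights <- function(spec, resources = plasticity_params()$resources) {
  info <- .cpp_topology(spec$N, spec$M)
  mask <- as.numeric(info$mask)               # N^2 x M^2
  w <- runif(length(mask) * 4L) * rep(mask, 4L)
  w <- .cpp_normalize_weights(w, spec$N, spec$M, unname(resources[CONN_TYPES]))
  dim(w) <- c(spec$N^2, spec$M^2, 4L)
  dimnames(w) <- list(NULL, NULL, CONN_TYPES)
  w
}

#' Normalize incoming weights to their resource levels
#'
#' Multiplicative per-(cell, type) rescaling so that the mean incoming weight
#' over each cell's actual (edge-clipped) fan-in equals the type's resource
#' level; relative proportions among a cell's inputs are preserved, and the
#' operation is idempotent.  Applied automatically at the end of every
#' plasticity-on trial.
#'
#' @param weights weight array as in [init_weights()], or a `somatonet`.
#' @param spec the [lattice_spec()] (ignored when `weights` is a network).
#' @param resources per-type resource levels.
#' @return Normalized copy of the weights (or network).
#' @export
normalize_weights <- function(weights, spec = NULL,
                              resources = plasticity_params()$resources) {
  if (inherits(weights, "somatonet")) {
    net <- weights
    net$weights[] <- .cpp_normalize_weights(
      as.numeric(net$weights), net$spec$N, net$spec$M,
      unname(net$plasticity$resources[CONN_TYPES]))
    return(net)
  }
  d <- dim(weights)
  out <- .cpp_normalize_weights(as.numeric(weights), spec$N, spec$M,
                                unname(resources[CONN_TYPES]))
  dim(out) <- d
  dimnames(out) <- dimnames(weights)
  out
}

#' @export
print.somatonet <- function(x, ...) {
  cat(sprintf("Somatotopic network: %d x %d columns (%d cells), %d x %d masks\n",
              x$spec$N, x$spec$N, 2L * x$spec$N^2, x$spec$M, x$spec$M))
  cat(sprintf("  completed cycles: %d; current beta_w: %g; mode: %s\n",
              x$cycle, x$beta_w, x$neuron$mode))
  if (nrow(x$history))
    cat("  phases run:", paste(x$history$phase, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
summary.somatonet <- function(object, ...) {
  w <- object$weights
  info <- .cpp_topology(object$spec$N, object$spec$M)
  fan <- info$fan_in
  means <- vapply(CONN_TYPES, function(t)
    mean(rowSums(w[, , t]) / fan), numeric(1))
  out <- list(spec = object$spec, cycle = object$cycle,
              beta_w = object$beta_w, mean_incoming = means,
              history = object$history)
  class(out) <- "summary.somatonet"
  out
}

#' @export
print.summary.somatonet <- function(x, ...) {
  print(x$spec)
  cat(sprintf("Completed cycles: %d (beta_w now %g)\n", x$cycle, x$beta_w))
  cat("Mean incoming weight per cell (should equal the type resources):\n")
  print(round(x$mean_incoming, 6))
  if (nrow(x$history)) { cat("History:\n"); print(x$history) }
  invisible(x)
}

#' Incoming weight pattern of one cell
#'
#' The spatial pattern of a cell's incoming weights of one type, as an
#' `M` x `M` matrix centered on the cell (rows/cols of the matrix follow the
#' lattice; entries outside the lattice are `NA`).  This is the per-column
#' weight display used to inspect how afferent and lateral weights
#' redistribute across refinement and syndactyly.
#'
#' @param net a `somatonet`.
#' @param row,col 1-based coordinates of the postsynaptic cell.
#' @param type connection type.
#' @return `M` x `M` numeric matrix; `[HM+1, HM+1]` is the self/center slot.
#' @export
incoming_weights <- function(net, row, col, type = c("ES", "EE", "EI", "IE")) {
  type <- match.arg(type)
  spec <- net$spec
  HM <- spec$M %/% 2L
  i <- cell_index(spec, row, col) + 1L
  out <- matrix(NA_real_, spec$M, spec$M)
  for (o in seq_len(spec$M^2)) {
    dr <- (o - 1L) %% spec$M - HM
    dc <- (o - 1L) %/% spec$M - HM
    if (row + dr >= 1L && row + dr <= spec$N &&
        col + dc >= 1L && col + dc <= spec$N)
      out[dr + HM + 1L, dc + HM + 1L] <- net$weights[i, o, type]
  }
  out
}

#' Long-form weight table
#'
#' @param net a `somatonet`.
#' @param type optional subset of connection types.
#' @return Data frame `post_row`, `post_col`, `pre_row`, `pre_col`, `type`,
#'   `weight`, one row per structurally present connection.
#' @export
weight_table <- function(net, type = CONN_TYPES) {
  spec <- net$spec
  HM <- spec$M %/% 2L
  NC <- spec$N^2
  post_row <- rep_len((seq_len(NC) - 1L) %% spec$N + 1L, NC)
  post_col <- rep_len((seq_len(NC) - 1L) %/% spec$N + 1L, NC)
  out <- list()
  for (tp in type) {
    for (o in seq_len(spec$M^2)) {
      dr <- (o - 1L) %% spec$M - HM
      dc <- (o - 1L) %/% spec$M - HM
      pr <- post_row + dr; pc <- post_col + dc
      ok <- pr >= 1L & pr <= spec$N & pc >= 1L & pc <= spec$N
      if (!any(ok)) next
      out[[length(out) + 1L]] <- data.frame(
        post_row = post_row[ok], post_col = post_col[ok],
        pre_row = pr[ok], pre_col = pc[ok], type = tp,
        weight = net$weights[ok, o, tp])
    }
  }
  do.call(rbind, out)
}

# internal: marshal parameters for the kernel
kernel_npar <- function(net) {
  nm <- net$neuron; tr <- net$trial
  steps_per_ms <- 0.001 / nm$h
  list(h = nm$h, tau_m = nm$tau_m, beta_m = nm$beta_m,
       noise_amp = nm$noise_amp,
       mode = if (nm$mode == "rk4") 1L else 0L,
       total_steps = as.integer(round(tr$total_ms * steps_per_ms)),
       pre_steps = as.integer(round(tr$prestim_ms * steps_per_ms)),
       stim_steps = as.integer(round(tr$stim_ms * steps_per_ms)),
       settle_steps = as.integer(round(tr$settle_ms * steps_per_ms)))
}

kernel_alpha_w <- function(net) 1 - net$neuron$h / net$plasticity$tau_w

# internal: run a block of trials through the kernel, returning the raw list
run_block <- function(net, stims, stim_mag, renormalize, gate,
                      record_probe = FALSE, record_cells = integer()) {
  res <- .cpp_run_block(
    as.numeric(net$weights), net$spec$N, net$spec$M, stims,
    stim_mag, renormalize, kernel_npar(net),
    kernel_alpha_w(net), net$beta_w,
    unname(net$plasticity$resources[CONN_TYPES]),
    gate, TRUE, record_probe, as.integer(record_cells))
  res
}

# internal: fold kernel weights back into the network
update_weights <- function(net, wvec) {
  net$weights[] <- wvec
  net
}

#' Run a single stimulation trial
#'
#' Runs one trial: the network state is reset, the stimulus drives the given
#' input patch (or single probe node) during the stimulus window, and, when
#' plasticity is on, weights adapt at every step and are normalized at trial
#' end.  Optionally records the membrane potential and firing-rate time
#' series of designated cortical columns together with their topographically
#' matching input node.
#'
#' @param net a `somatonet`.
#' @param patch length-2 vector `(row, col)` of the patch origin, with patch
#'   size taken from `height`/`width`; for a probe use `height = width = 1`
#'   and `probe = TRUE`.
#' @param height,width patch extent in nodes.
#' @param probe if `TRUE` the stimulus is a receptive-field probe: magnitude
#'   1.0 on a single node, no vector renormalization, plasticity forced off.
#' @param plasticity_on gate for weight adaptation (ignored for probes).
#' @param record_cells optional data frame / matrix of 1-based `(row, col)`
#'   cortical coordinates whose time series should be recorded.
#' @return List with the updated `net` and, if requested, `series`: a data
#'   frame per recorded cell with `time_ms`, `v_s`, `r_s`, `v_e`, `r_e`,
#'   `v_i`, `r_i`.
#' @export
run_trial <- function(net, patch, height = 7L, width = 7L, probe = FALSE,
                      plasticity_on = TRUE, record_cells = NULL) {
  if (probe) { height <- 1L; width <- 1L; plasticity_on <- FALSE }
  stims <- matrix(as.integer(c(patch[1L] - 1L, patch[2L] - 1L,
                               height, width)), 1L)
  cells <- integer()
  if (!is.null(record_cells)) {
    record_cells <- as.matrix(record_cells)
    cells <- cell_index(net$spec, record_cells[, 1L], record_cells[, 2L])
  }
  mag <- if (probe) 1.0 else net$trial$stim_mag
  res <- run_block(net, stims, mag, renormalize = !probe,
                   gate = isTRUE(plasticity_on), record_cells = cells)
  net <- update_weights(net, res$weights)
  out <- list(net = net)
  if (length(cells)) {
    ts <- res$series[[1L]]
    h_ms <- net$neuron$h * 1000
    out$series <- lapply(seq_along(cells), function(k) {
      cols <- (k - 1L) * 6L + 1:6
      d <- as.data.frame(ts[, cols])
      names(d) <- c("v_s", "r_s", "v_e", "r_e", "v_i", "r_i")
      cbind(time_ms = seq_len(nrow(d)) * h_ms, d)
    })
    names(out$series) <- paste0("cell_", record_cells[, 1L], "_",
                                record_cells[, 2L])
  }
  out
}

#' Advance the network state by one integration step
#'
#' Reference single-step update, in R, of the coupled S/E/I dynamics: the
#' fan-in-averaged synaptic drive is computed from the current rates, each
#' membrane potential leaks and receives its per-step drive (forward Euler,
#' or the collapsed fourth-order Runge--Kutta leak factor), optional
#' uniform noise is added, and rates are refreshed.  Used for exposition
#' and for validating the compiled kernel; protocol functions use the
#' kernel.
#'
#' @param state list with numeric vectors `v_s`, `v_e`, `v_i` of length `N^2`.
#' @param net a `somatonet` providing weights and parameters.
#' @param drive external drive vector for the S layer (length `N^2`).
#' @param noise if `TRUE`, add uniform noise using the current RNG stream
#'   (order: S, then E, then I units).
#' @return Updated state list, with rates `r_s`, `r_e`, `r_i` refreshed.
#' @export
step_network <- function(state, net, drive = 0, noise = FALSE) {
  spec <- net$spec
  info <- .cpp_topology(spec$N, spec$M)
  NC <- spec$N^2
  drive <- rep_len(drive, NC)
  rs <- firing_rate(state$v_s, net$neuron$beta_m)
  re <- firing_rate(state$v_e, net$neuron$beta_m)
  ri <- firing_rate(state$v_i, net$neuron$beta_m)
  accE <- numeric(NC); accI <- numeric(NC)
  M <- spec$M; HM <- M %/% 2L
  pre_rate <- function(r, dr, dc) {
    m <- matrix(0, spec$N, spec$N)
    rr <- max(1L, 1L - dr):min(spec$N, spec$N - dr)
    cc <- max(1L, 1L - dc):min(spec$N, spec$N - dc)
    m[rr, cc] <- matrix(r, spec$N, spec$N)[rr + dr, cc + dc]
    as.numeric(m)
  }
  for (o in seq_len(M^2)) {
    dr <- (o - 1L) %% M - HM; dc <- (o - 1L) %/% M - HM
    accE <- accE + net$weights[, o, "ES"] * pre_rate(rs, dr, dc) +
      net$weights[, o, "EE"] * pre_rate(re, dr, dc) -
      net$weights[, o, "EI"] * pre_rate(ri, dr, dc)
    accI <- accI + net$weights[, o, "IE"] * pre_rate(re, dr, dc)
  }
  accE <- accE / info$fan_in; accI <- accI / info$fan_in
  a <- net$neuron$h / net$neuron$tau_m
  P <- if (net$neuron$mode == "rk4")
    1 - a + a^2 / 2 - a^3 / 6 + a^4 / 24 else 1 - a
  QD <- (1 - P) / a    # euler: exactly one unit of drive per step
  state$v_e <- P * state$v_e + QD * accE
  state$v_i <- P * state$v_i + QD * accI
  state$v_s <- P * state$v_s + QD * drive
  if (noise && net$neuron$noise_amp > 0) {
    amp <- net$neuron$noise_amp
    state$v_s <- state$v_s + runif(NC, -amp, amp)
    state$v_e <- state$v_e + runif(NC, -amp, amp)
    state$v_i <- state$v_i + runif(NC, -amp, amp)
  }
  state$r_s <- firing_rate(state$v_s, net$neuron$beta_m)
  state$r_e <- firing_rate(state$v_e, net$neuron$beta_m)
  state$r_i <- firing_rate(state$v_i, net$neuron$beta_m)
  state
}
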