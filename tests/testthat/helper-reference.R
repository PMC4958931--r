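# Shared fixtures and independent reference implementations.

# small lattices used throughout the unit tests
tiny_spec <- function() lattice_spec(9L, 3L, c(3L, 3L, 3L))
mini_spec <- function() lattice_spec(5L, 3L, c(2L, 3L))

quiet_net <- function(spec = tiny_spec(), seed = 7, mode = "rk4",
                      noise = 0) {
  somatonet(spec,
            neuron = neuron_params(noise_amp = noise, mode = mode),
            seed = seed)
}

# Literal reference implementation of one trial, in plain R: per step the
# fan-in-averaged drive is computed from current rates, the covariance rule
# is applied (gate on), and the membrane relaxation is integrated either by
# the forward-Euler map or by an explicit four-stage Runge-Kutta on
# f(v) = (I - v)/tau with the drive held fixed over the step.  Noise-free,
# independent of the compiled kernel.
reference_trial <- function(net, patch_row, patch_col, height, width,
                            gate = TRUE, probe = FALSE,
                            record_cell = NULL) {
  spec <- net$spec
  N <- spec$N; M <- spec$M; HM <- M %/% 2L; NC <- N^2; NO <- M^2
  info <- somatomap:::.cpp_topology(N, M)
  fan <- info$fan_in
  mask <- info$mask
  w <- net$weights
  nm <- net$neuron
  a <- nm$h / nm$tau_m
  alpha_w <- 1 - nm$h / net$plasticity$tau_w
  beta_w <- net$beta_w
  R <- unname(net$plasticity$resources[c("ES", "EE", "EI", "IE")])

  tr <- net$trial
  total <- tr$total_ms; pre <- tr$prestim_ms; stim_ms <- tr$stim_ms
  if (probe) { height <- 1L; width <- 1L }
  drive <- matrix(0, N, N)
  drive[patch_row:(patch_row + height - 1L),
        patch_col:(patch_col + width - 1L)] <-
    if (probe) 1.0 else tr$stim_mag / sqrt(height * width)
  drive <- as.numeric(drive)

  shift_rate <- function(r, dr, dc) {
    m <- matrix(0, N, N); rm <- matrix(r, N, N)
    rr <- max(1L, 1L - dr):min(N, N - dr)
    cc <- max(1L, 1L - dc):min(N, N - dc)
    m[rr, cc] <- rm[rr + dr, cc + dc]
    as.numeric(m)
  }
  # dv/dt = -v/tau_m + I/h, drive I frozen over the step; Euler reproduces
  # the discrete network map v(t+1) = alpha_m v(t) + I(t)
  advance <- function(v, I) {
    if (nm$mode == "euler") return((1 - a) * v + I)
    k1 <- -v / nm$tau_m + I / nm$h
    k2 <- -(v + nm$h / 2 * k1) / nm$tau_m + I / nm$h
    k3 <- -(v + nm$h / 2 * k2) / nm$tau_m + I / nm$h
    k4 <- -(v + nm$h * k3) / nm$tau_m + I / nm$h
    v + nm$h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }

  vS <- vE <- vI <- numeric(NC)
  rec <- NULL
  if (!is.null(record_cell))
    rec <- matrix(NA_real_, total, 6)
  settle <- tr$settle_ms
  for (st in seq_len(settle + total)) {
    stim_on <- st > settle + pre && st <= settle + pre + stim_ms
    in_trial <- st > settle
    rs <- firing_rate(vS, nm$beta_m)
    re <- firing_rate(vE, nm$beta_m)
    ri <- firing_rate(vI, nm$beta_m)
    accE <- numeric(NC); accI <- numeric(NC)
    pres <- vector("list", NO)
    for (o in seq_len(NO)) {
      dr <- (o - 1L) %% M - HM; dc <- (o - 1L) %/% M - HM
      ps <- shift_rate(rs, dr, dc); pe <- shift_rate(re, dr, dc)
      pi_ <- shift_rate(ri, dr, dc)
      accE <- accE + w[, o, "ES"] * ps + w[, o, "EE"] * pe -
        w[, o, "EI"] * pi_
      accI <- accI + w[, o, "IE"] * pe
      pres[[o]] <- list(ps = ps, pe = pe, pi = pi_)
    }
    if (gate && in_trial) {
      for (o in seq_len(NO)) {
        mk <- mask[, o]
        w[, o, "ES"] <- alpha_w * w[, o, "ES"] + mk * beta_w * re * pres[[o]]$ps
        w[, o, "EE"] <- alpha_w * w[, o, "EE"] + mk * beta_w * re * pres[[o]]$pe
        w[, o, "EI"] <- alpha_w * w[, o, "EI"] + mk * beta_w * re * pres[[o]]$pi
        w[, o, "IE"] <- alpha_w * w[, o, "IE"] + mk * beta_w * ri * pres[[o]]$pe
      }
    }
    vE <- advance(vE, accE / fan)
    vI <- advance(vI, accI / fan)
    vS <- advance(vS, if (stim_on) drive else numeric(NC))
    if (!is.null(record_cell) && in_trial) {
      i <- somatomap:::cell_index(net$spec, record_cell[1], record_cell[2]) + 1L
      rec[st - settle, ] <- c(vS[i], firing_rate(vS, nm$beta_m)[i],
                              vE[i], firing_rate(vE, nm$beta_m)[i],
                              vI[i], firing_rate(vI, nm$beta_m)[i])
    }
  }
  if (gate) {
    for (t in seq_along(R)) {
      sums <- rowSums(w[, , t])
      w[, , t] <- w[, , t] * (R[t] * fan / sums)
    }
  }
  list(weights = w, series = rec)
}

# brute-force patch enumeration oracle: every placement of an h x w patch
# wholly inside the lattice and inside one (possibly fused) digit band
brute_force_patches <- function(spec, h, w, mode = "respect_all") {
  bands <- digit_bands(spec)
  if (mode == "fuse_d1_d2")
    bands <- rbind(data.frame(digit = "D1+2", first = bands$first[1],
                              last = bands$last[2]),
                   bands[-(1:2), ])
  out <- NULL
  for (r in 1:(spec$N - h + 1)) for (cc in 1:(spec$N - w + 1)) {
    for (b in seq_len(nrow(bands))) {
      if (r >= bands$first[b] && r + h - 1 <= bands$last[b])
        out <- rbind(out, data.frame(row = r, col = cc, digit = bands$digit[b]))
    }
  }
  out
}
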