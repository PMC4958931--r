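#' Probe every input node and record cortical responses
#'
#' First step of the two-step receptive-field mapping procedure: one probe
#' trial per input-layer node (`N^2` trials, magnitude 1.0 on a single node,
#' no renormalization), with plasticity gated off, recording for every
#' cortical E and I cell the mean pre-stimulus rate, the mean
#' stimulus-period rate and the peak rate of each trial.  Probing never
#' alters the network.
#'
#' @param net a `somatonet`.
#' @return Object of class `probe_tensor`: matrices `e_pre`, `e_stim`,
#'   `e_peak`, `i_pre`, `i_stim`, `i_peak`, each `N^2` cells by `N^2` probes
#'   (probe `j` stimulates the input node at row `(j-1) %% N + 1`, column
#'   `(j-1) %/% N + 1`), plus the lattice spec and the completed-cycle count.
#' @export
probe_map <- function(net) {
  NC <- net$spec$N^2
  i0 <- seq_len(NC) - 1L
  stims <- cbind(i0 %% net$spec$N, i0 %/% net$spec$N, 1L, 1L)
  storage.mode(stims) <- "integer"
  res <- run_block(net, stims, stim_mag = 1.0, renormalize = FALSE,
                   gate = FALSE, record_probe = TRUE)
  structure(c(res$probe, list(spec = net$spec, cycle = net$cycle)),
            class = "probe_tensor")
}

#' @export
print.probe_tensor <- function(x, ...) {
  cat(sprintf("Probe response tensor: %d probes x %d cells x 2 cell types (cycle %d)\n",
              ncol(x$e_stim), nrow(x$e_stim), x$cycle))
  invisible(x)
}

# 1-based probe id -> lattice coordinates (kernel cell order)
probe_coords <- function(spec, id = seq_len(spec$N^2)) {
  data.frame(row = (id - 1L) %% spec$N + 1L,
             col = (id - 1L) %/% spec$N + 1L)
}

# connected components of a node set under 8-connectivity, by vectorized BFS
count_components <- function(rr, cc) {
  n <- length(rr)
  if (n == 0L) return(0L)
  key <- rr * 100000L + cc
  nb <- c(-100001L, -100000L, -99999L, -1L, 1L, 99999L, 100000L, 100001L)
  remaining <- rep(TRUE, n)
  comp <- 0L
  while (any(remaining)) {
    comp <- comp + 1L
    seed <- which.max(remaining)
    frontier <- key[seed]
    remaining[seed] <- FALSE
    repeat {
      cand <- unique(as.vector(outer(frontier, nb, `+`)))
      hit <- which(remaining)[key[remaining] %in% cand]
      if (!length(hit)) break
      frontier <- key[hit]
      remaining[hit] <- FALSE
    }
  }
  comp
}

#' Derive receptive fields for all cortical cells
#'
#' Second step of receptive-field mapping.  A cell's receptive field is the
#' set of input nodes whose probe drives the cell's response above
#' `threshold` times the maximum response observed in that cell across all
#' probes; the response statistic is the mean stimulus-period firing rate
#' (default) or the peak rate.  Response magnitude is the maximum over
#' probes of the ratio of mean stimulus-period to mean pre-stimulus rate.
#' Position and orientation are the sample mean and (maximum-likelihood)
#' covariance of the member node coordinates; modality counts the
#' 8-connected components of the member set, and `digit_span` the number of
#' digit bands it touches.
#'
#' @param tensor a [probe_map()] result.
#' @param threshold receptive-field threshold as a fraction of the cell's
#'   maximum response.
#' @param statistic `"stim_mean"` or `"peak"`.
#' @param weighted if `TRUE`, centroid and covariance are response-weighted
#'   instead of unweighted sample moments (non-default variant).
#' @param modality if `TRUE` (default) count connected components per cell.
#' @return Object of class `rf_map`: a data frame with one row per cell and
#'   type (`type`, `row`, `col`, `id`, `centroid_row`, `centroid_col`,
#'   `area`, `magnitude`, `cov_rr`, `cov_rc`, `cov_cc`, `n_modes`,
#'   `digit_span`), with the per-cell member sets, spec, cycle and options
#'   as attributes.
#' @export
rf_map <- function(tensor, threshold = 0.5,
                   statistic = c("stim_mean", "peak"),
                   weighted = FALSE, modality = TRUE) {
  statistic <- match.arg(statistic)
  spec <- tensor$spec
  pc <- probe_coords(spec)
  digit_per_probe <- digit_of_row(spec, pc$row)
  cells <- probe_coords(spec)     # same ordering for cortical cells
  out <- list(); members <- list()
  for (ty in c("E", "I")) {
    resp <- if (ty == "E") {
      if (statistic == "stim_mean") tensor$e_stim else tensor$e_peak
    } else {
      if (statistic == "stim_mean") tensor$i_stim else tensor$i_peak
    }
    pre <- if (ty == "E") tensor$e_pre else tensor$i_pre
    stim <- if (ty == "E") tensor$e_stim else tensor$i_stim
    mx <- apply(resp, 1L, max)
    if (any(mx <= 0))
      stop(sprintf("empty receptive field: %s cell(s) %s responded to no probe",
                   ty, paste(head(which(mx <= 0)), collapse = ", ")))
    L <- resp > mx * threshold
    n <- rowSums(L)
    if (weighted) {
      wsum <- rowSums(resp * L)
      cr <- as.numeric((resp * L) %*% pc$row) / wsum
      cc <- as.numeric((resp * L) %*% pc$col) / wsum
      srr <- as.numeric((resp * L) %*% pc$row^2) / wsum - cr^2
      scc <- as.numeric((resp * L) %*% pc$col^2) / wsum - cc^2
      src <- as.numeric((resp * L) %*% (pc$row * pc$col)) / wsum - cr * cc
    } else {
      cr <- as.numeric(L %*% pc$row) / n
      cc <- as.numeric(L %*% pc$col) / n
      srr <- as.numeric(L %*% pc$row^2) / n - cr^2
      scc <- as.numeric(L %*% pc$col^2) / n - cc^2
      src <- as.numeric(L %*% (pc$row * pc$col)) / n - cr * cc
    }
    magnitude <- apply(stim / pre, 1L, max)
    mem <- apply(L, 1L, which, simplify = FALSE)
    n_modes <- if (modality) {
      vapply(mem, function(id)
        count_components(pc$row[id], pc$col[id]), integer(1))
    } else rep(NA_integer_, length(mem))
    digit_span <- vapply(mem, function(id)
      length(unique(digit_per_probe[id])), integer(1))
    out[[ty]] <- data.frame(
      type = ty, row = cells$row, col = cells$col,
      id = column_id(spec, cells$row, cells$col),
      centroid_row = cr, centroid_col = cc, area = n,
      magnitude = magnitude, cov_rr = srr, cov_rc = src, cov_cc = scc,
      n_modes = n_modes, digit_span = digit_span)
    members[[ty]] <- mem
  }
  df <- rbind(out$E, out$I)
  attr(df, "members") <- members
  attr(df, "spec") <- spec
  attr(df, "cycle") <- tensor$cycle
  attr(df, "threshold") <- threshold
  attr(df, "statistic") <- statistic
  class(df) <- c("rf_map", "data.frame")
  df
}

#' Receptive-field member nodes of one cell
#'
#' @param map an [rf_map()].
#' @param row,col cortical cell coordinates (1-based).
#' @param type `"E"` or `"I"`.
#' @return Integer vector of member probe ids (use [probe_coords()] on the
#'   map's spec for coordinates).
#' @export
rf_members <- function(map, row, col, type = c("E", "I")) {
  type <- match.arg(type)
  spec <- attr(map, "spec")
  attr(map, "members")[[type]][[cell_index(spec, row, col) + 1L]]
}

#' Receptive-field centroid and orientation of one cell
#'
#' The centroid is the sample mean of the member node coordinates; the
#' orientation is the 2 x 2 sample covariance with its 50%-level Gaussian
#' ellipse (the display convention: a multi-peaked receptive field shows as
#' a single large ellipse, so always check `n_modes`).
#'
#' @inheritParams rf_members
#' @return For `rf_centroid`, numeric `(row, col)`.  For `rf_orientation`, a
#'   list: `cov` (2 x 2), `angle` (radians, major axis from the row axis),
#'   `axes` (50%-level semi-axes, in nodes), and `degenerate` (`TRUE` for
#'   singleton or collinear member sets).
#' @export
rf_centroid <- function(map, row, col, type = c("E", "I")) {
  type <- match.arg(type)
  r <- map[map$type == type & map$row == row & map$col == col, ]
  c(row = r$centroid_row, col = r$centroid_col)
}

#' @rdname rf_centroid
#' @export
rf_orientation <- function(map, row, col, type = c("E", "I")) {
  type <- match.arg(type)
  r <- map[map$type == type & map$row == row & map$col == col, ]
  cv <- matrix(c(r$cov_rr, r$cov_rc, r$cov_rc, r$cov_cc), 2L)
  eg <- eigen(cv, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  k <- stats::qchisq(0.5, df = 2)      # 50% level of the fitted Gaussian
  list(cov = cv, angle = atan2(eg$vectors[2L, 1L], eg$vectors[1L, 1L]),
       axes = sqrt(k * lam), degenerate = any(lam < .Machine$double.eps))
}

#' Jaccard overlap of two receptive fields
#'
#' @param a,b integer vectors of member probe ids (see [rf_members()]).
#' @return `|intersection| / |union|` in `[0, 1]`.
#' @export
rf_overlap <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(NA_real_)
  length(intersect(a, b)) / u
}

#' Intracolumnar excitatory--inhibitory centroid divergence
#'
#' Euclidean distance on the input lattice between the E-cell and I-cell
#' receptive-field centroids of the same cortical column.  Immediate lattice
#' neighbors are 1 unit apart orthogonally and `sqrt(2) ~ 1.414` diagonally;
#' divergence greater than two diagonal units (2.828) marks the divergent,
#' border-straddling columns.
#'
#' @param map an [rf_map()].
#' @return Data frame `row`, `col`, `divergence`, one row per column.
#' @export
rf_divergence <- function(map) {
  e <- map[map$type == "E", ]
  i <- map[map$type == "I", ]
  stopifnot(all(e$id == i$id))
  data.frame(row = e$row, col = e$col,
             divergence = sqrt((e$centroid_row - i$centroid_row)^2 +
                               (e$centroid_col - i$centroid_col)^2))
}

#' Width of the divergent band at each digit boundary
#'
#' For each representational boundary and each side, counts the consecutive
#' boundary-adjacent cortical rows containing at least one column whose E--I
#' centroid divergence exceeds `threshold` (default two diagonal units).
#' Columns within `edge_exclude` nodes of the lateral lattice edges are
#' ignored, since planar-boundary edge effects are confined to the outermost
#' nodes.
#'
#' @param map an [rf_map()] (or a precomputed [rf_divergence()] data frame).
#' @param spec the [lattice_spec()]; defaults to the map's.
#' @param threshold divergence threshold in lattice units.
#' @param edge_exclude number of columns to ignore at each lateral edge.
#' @return Data frame `boundary`, `side`, `width` (rows), with the divergent
#'   columns as attribute `divergent`.
#' @export
divergence_band_width <- function(map, spec = attr(map, "spec"),
                                  threshold = 2 * sqrt(2), edge_exclude = 3L) {
  div <- if (inherits(map, "rf_map")) rf_divergence(map) else map
  interior <- div$col > edge_exclude & div$col <= spec$N - edge_exclude
  dcells <- div[interior & div$divergence > threshold, ]
  rows_with <- unique(dcells$row)
  bands <- digit_bands(spec)
  out <- list()
  for (b in seq_len(nrow(bands) - 1L)) {
    rb <- bands$last[b]
    lab <- paste0(bands$digit[b], "-", bands$digit[b + 1L])
    wlo <- 0L
    while (rb - wlo >= bands$first[b] && (rb - wlo) %in% rows_with)
      wlo <- wlo + 1L
    whi <- 0L
    while (rb + 1L + whi <= bands$last[b + 1L] && (rb + 1L + whi) %in% rows_with)
      whi <- whi + 1L
    out[[length(out) + 1L]] <- data.frame(
      boundary = lab, side = c(bands$digit[b], bands$digit[b + 1L]),
      width = c(wlo, whi))
  }
  out <- do.call(rbind, out)
  attr(out, "divergent") <- dcells
  out
}

#' Width of the double-digit inhibitory band at each digit boundary
#'
#' The complementary band measure based on receptive-field extent rather
#' than centroid divergence: for each boundary and side, the number of
#' consecutive boundary-adjacent cortical rows in which the majority of
#' interior columns have an inhibitory receptive field spanning two digit
#' bands.  Excitatory cells are single-digit after refinement, so the
#' double-digit band is an inhibitory signature of the representational
#' discontinuity.
#'
#' @param map an [rf_map()].
#' @param spec the [lattice_spec()]; defaults to the map's.
#' @param type cell type to score (inhibitory by default).
#' @param frac fraction of a row's interior columns that must be
#'   double-digit for the row to count.
#' @param edge_exclude columns ignored at each lateral edge.
#' @return Data frame `boundary`, `side`, `width` (rows), with all
#'   qualifying rows as attribute `rows`.
#' @export
double_digit_band <- function(map, spec = attr(map, "spec"), type = "I",
                              frac = 0.5, edge_exclude = 3L) {
  d <- map[map$type == type, ]
  d <- d[d$col > edge_exclude & d$col <= spec$N - edge_exclude, ]
  prop <- tapply(d$digit_span >= 2L, d$row, mean)
  rows_with <- as.integer(names(prop))[prop > frac]
  bands <- digit_bands(spec)
  out <- list()
  for (b in seq_len(nrow(bands) - 1L)) {
    rb <- bands$last[b]
    wlo <- 0L
    while (rb - wlo >= bands$first[b] && (rb - wlo) %in% rows_with)
      wlo <- wlo + 1L
    whi <- 0L
    while (rb + 1L + whi <= bands$last[b + 1L] && (rb + 1L + whi) %in% rows_with)
      whi <- whi + 1L
    out[[length(out) + 1L]] <- data.frame(
      boundary = paste0(bands$digit[b], "-", bands$digit[b + 1L]),
      side = c(bands$digit[b], bands$digit[b + 1L]),
      width = c(wlo, whi))
  }
  out <- do.call(rbind, out)
  attr(out, "rows") <- rows_with
  out
}

#' Centroids on border-adjacent rows
#'
#' Identifies cortical cells (of one type) whose receptive-field centroid
#' falls on one of the two input-lattice rows immediately flanking a digit
#' boundary (nearest-node assignment).  In a baseline-refined map there are
#' no such excitatory centroids away from the lattice edges; under
#' syndactyly the fused D1--D2 border is populated again.
#'
#' @param map an [rf_map()].
#' @param spec the [lattice_spec()]; defaults to the map's.
#' @param type cell type.
#' @param edge_exclude columns ignored at each lateral edge.
#' @return List with `boundary` labels, counts `n`, and the offending
#'   `cells` data frame.
#' @export
centroid_border_cells <- function(map, spec = attr(map, "spec"), type = "E",
                                  edge_exclude = 3L) {
  d <- map[map$type == type, ]
  interior <- d$col > edge_exclude & d$col <= spec$N - edge_exclude
  d <- d[interior, ]
  near_row <- floor(d$centroid_row + 0.5)
  bands <- digit_bands(spec)
  labs <- character(0); ns <- integer(0); cells <- list()
  for (b in seq_len(nrow(bands) - 1L)) {
    rb <- bands$last[b]
    hit <- near_row == rb | near_row == rb + 1L
    labs <- c(labs, paste0(bands$digit[b], "-", bands$digit[b + 1L]))
    ns <- c(ns, sum(hit))
    cells[[length(cells) + 1L]] <- d[hit, c("row", "col", "centroid_row",
                                            "centroid_col")]
  }
  list(boundary = labs, n = ns, cells = do.call(rbind, cells))
}

#' Receptive-field profile along a recording track
#'
#' Summarizes receptive fields along a longitudinal (fixed cortical row) or
#' cross-digit (fixed cortical column) recording track, including the
#' Jaccard overlap between successive recorded sites.
#'
#' @param map an [rf_map()].
#' @param row,col fix exactly one of the two to select the track.
#' @param type cell type.
#' @param every record every `every`-th site along the track.
#' @return Data frame of per-site summaries ordered along the track, with
#'   `overlap_prev`, the overlap with the previously recorded site.
#' @export
track_profile <- function(map, row = NULL, col = NULL, type = c("E", "I"),
                          every = 1L) {
  type <- match.arg(type)
  if (is.null(row) == is.null(col))
    stop("fix exactly one of row (longitudinal track) or col (cross-digit track)")
  d <- map[map$type == type, ]
  d <- d[if (!is.null(row)) d$row == row else d$col == col, ]
  d <- d[order(if (!is.null(row)) d$col else d$row), ]
  d <- d[seq(1L, nrow(d), by = every), ]
  mem <- attr(map, "members")[[type]]
  spec <- attr(map, "spec")
  ids <- cell_index(spec, d$row, d$col) + 1L
  ov <- c(NA_real_, vapply(seq_len(nrow(d) - 1L), function(k)
    rf_overlap(mem[[ids[k]]], mem[[ids[k + 1L]]]), numeric(1)))
  d$overlap_prev <- ov
  rownames(d) <- NULL
  d
}

#' Orientation-preservation score of the map
#'
#' A simple numerical measure of topographic order: the fraction of
#' laterally adjacent same-type column pairs whose receptive-field centroid
#' displacement preserves the lattice orientation (centroid column strictly
#' increasing left to right; centroid row strictly increasing top to
#' bottom).  A perfect one-to-one topographic map scores 1.
#'
#' @param map an [rf_map()].
#' @param type cell type.
#' @return Scalar in `[0, 1]`.
#' @export
topographic_order <- function(map, type = c("E", "I")) {
  type <- match.arg(type)
  spec <- attr(map, "spec")
  d <- map[map$type == type, ]
  CR <- matrix(NA_real_, spec$N, spec$N)
  CC <- matrix(NA_real_, spec$N, spec$N)
  CR[cbind(d$row, d$col)] <- d$centroid_row
  CC[cbind(d$row, d$col)] <- d$centroid_col
  horiz <- CC[, -1L] > CC[, -spec$N]
  vert <- CR[-1L, ] > CR[-spec$N, ]
  mean(c(horiz, vert))
}
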