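# synthetic probe tensors let every derived measure be checked against
# hand-computed values
fake_tensor <- function(spec, e_stim, i_stim = e_stim,
                        e_pre = NULL, i_pre = NULL) {
  NC <- spec$N^2
  if (is.null(e_pre)) e_pre <- matrix(1, NC, NC)
  if (is.null(i_pre)) i_pre <- matrix(1, NC, NC)
  structure(list(e_pre = e_pre, e_stim = e_stim, e_peak = e_stim,
                 i_pre = i_pre, i_stim = i_stim, i_peak = i_stim,
                 spec = spec, cycle = 0L),
            class = "probe_tensor")
}

pid <- function(spec, r, c) (c - 1L) * spec$N + r

test_that("membership thresholds at half the per-cell maximum", {
  s <- tiny_spec(); NC <- 81
  resp <- matrix(0.1, NC, NC)
  resp[1, ] <- 0.001
  resp[1, pid(s, 1, 1)] <- 1.0
  resp[1, pid(s, 2, 1)] <- 0.6
  resp[1, pid(s, 3, 1)] <- 0.4
  m <- rf_map(fake_tensor(s, resp), modality = FALSE)
  mem <- rf_members(m, 1, 1, "E")
  expect_setequal(mem, c(pid(s, 1, 1), pid(s, 2, 1)))  # 0.6 > 0.5, 0.4 < 0.5
  # uniform responses: every probe clears half of the maximum
  expect_equal(m$area[m$type == "E"][2], NC)
  # single responsive probe: area 1, degenerate orientation
  resp[2, ] <- 0; resp[2, pid(s, 5, 6)] <- 0.8
  m2 <- rf_map(fake_tensor(s, resp), modality = FALSE)
  r2 <- m2[m2$type == "E", ][2, ]
  expect_equal(r2$area, 1L)
  expect_equal(c(r2$centroid_row, r2$centroid_col), c(5, 6))
  expect_true(rf_orientation(m2, 2, 1, "E")$degenerate)  # cell index 2 = (2, 1)
})

test_that("all-zero responses raise an empty receptive field error", {
  s <- tiny_spec()
  resp <- matrix(1, 81, 81)
  resp[5, ] <- 0
  expect_error(rf_map(fake_tensor(s, resp)), "empty receptive field")
})

test_that("centroid and covariance are the sample moments of the member set", {
  s <- tiny_spec(); NC <- 81
  resp <- matrix(0, NC, NC)
  # symmetric 3 x 3 block centered at (5, 5) for every cell
  blk <- as.vector(outer(4:6, 4:6, function(r, c) pid(s, r, c)))
  resp[, blk] <- 1
  m <- rf_map(fake_tensor(s, resp), modality = FALSE)
  expect_equal(m$centroid_row, rep(5, 2 * NC))
  expect_equal(m$centroid_col, rep(5, 2 * NC))
  # MLE covariance of a uniform 3 x 3 block: 2/3 on the diagonal, 0 off
  expect_equal(m$cov_rr, rep(2 / 3, 2 * NC), tolerance = 1e-12)
  expect_equal(m$cov_cc, rep(2 / 3, 2 * NC), tolerance = 1e-12)
  expect_equal(m$cov_rc, rep(0, 2 * NC), tolerance = 1e-12)
  o <- rf_orientation(m, 3, 3, "E")
  expect_true(all(eigen(o$cov)$values >= 0))
  # two-point member set {(1,1),(3,3)}: centroid at the midpoint
  resp2 <- matrix(0, NC, NC)
  resp2[, c(pid(s, 1, 1), pid(s, 3, 3))] <- 1
  m2 <- rf_map(fake_tensor(s, resp2), modality = FALSE)
  expect_equal(m2$centroid_row[1], 2)
  expect_equal(m2$centroid_col[1], 2)
})

test_that("raising the threshold never enlarges a receptive field", {
  s <- tiny_spec()
  set.seed(4)
  resp <- matrix(runif(81 * 81), 81, 81)
  areas <- sapply(c(0.3, 0.5, 0.7, 0.9), function(th)
    rf_map(fake_tensor(s, resp), threshold = th, modality = FALSE)$area)
  expect_true(all(diff(t(areas)) <= 0))
})

test_that("translating all responses translates every centroid", {
  s <- tiny_spec(); NC <- 81
  place <- function(r0, c0) {
    resp <- matrix(0, NC, NC)
    blk <- as.vector(outer(r0:(r0 + 1), c0:(c0 + 1),
                           function(r, c) pid(s, r, c)))
    resp[, blk] <- 1
    resp
  }
  m1 <- rf_map(fake_tensor(s, place(2, 3)), modality = FALSE)
  m2 <- rf_map(fake_tensor(s, place(3, 5)), modality = FALSE)
  expect_equal(m2$centroid_row - m1$centroid_row, rep(1, 2 * NC))
  expect_equal(m2$centroid_col - m1$centroid_col, rep(2, 2 * NC))
})

test_that("divergence is the Euclidean centroid distance within a column", {
  s <- lattice_spec(15, 3, c(5, 5, 5)); NC <- 225
  e <- matrix(0, NC, NC); i <- matrix(0, NC, NC)
  e[, pid(s, 10, 10)] <- 1            # all E centroids at (10, 10)
  i[, pid(s, 10, 13)] <- 1            # all I centroids at (10, 13)
  m <- rf_map(fake_tensor(s, e, i), modality = FALSE)
  d <- rf_divergence(m)
  expect_equal(d$divergence, rep(3, NC))
  i2 <- matrix(0, NC, NC); i2[, pid(s, 11, 11)] <- 1
  d2 <- rf_divergence(rf_map(fake_tensor(s, e, i2), modality = FALSE))
  expect_equal(d2$divergence, rep(sqrt(2), NC), tolerance = 1e-12)
  expect_equal(round(d2$divergence[1], 3), 1.414)
  d0 <- rf_divergence(rf_map(fake_tensor(s, e, e), modality = FALSE))
  expect_equal(d0$divergence, rep(0, NC))
  # with zero divergence everywhere the band width is zero at every boundary
  bw <- divergence_band_width(rf_map(fake_tensor(s, e, e), modality = FALSE))
  expect_equal(bw$width, rep(0L, 4))
  expect_equal(bw$boundary, c("D1-D2", "D1-D2", "D2-D3", "D2-D3"))
})

test_that("divergent rows straddling a boundary are measured per side", {
  s <- lattice_spec(15, 3, c(5, 5, 5)); NC <- 225
  e <- matrix(0, NC, NC)
  e[, pid(s, 8, 8)] <- 1
  i <- e
  # columns in rows 5 and 6 (flanking the D1-D2 boundary) get divergent I RFs
  div_cells <- which(probe_coords(s)$row %in% c(5, 6))
  i[div_cells, ] <- 0
  i[div_cells, pid(s, 12, 8)] <- 1
  m <- rf_map(fake_tensor(s, e, i), modality = FALSE)
  bw <- divergence_band_width(m)
  expect_equal(bw$width[bw$boundary == "D1-D2"], c(1L, 1L))
  expect_equal(bw$width[bw$boundary == "D2-D3"], c(0L, 0L))
  dv <- attr(bw, "divergent")
  expect_setequal(unique(dv$row), c(5, 6))
})

test_that("centroids on border-adjacent rows are detected and edge columns excluded", {
  s <- lattice_spec(15, 3, c(5, 5, 5)); NC <- 225
  e <- matrix(0, NC, NC)
  e[, pid(s, 8, 8)] <- 1                       # far from any boundary
  cellA <- somatomap:::cell_index(s, 2, 8) + 1L  # interior column
  cellB <- somatomap:::cell_index(s, 2, 2) + 1L  # lateral edge column
  e[c(cellA, cellB), ] <- 0
  e[c(cellA, cellB), pid(s, 5, 8)] <- 1        # centroid on boundary row 5
  m <- rf_map(fake_tensor(s, e), modality = FALSE)
  bc <- centroid_border_cells(m, s)
  expect_equal(bc$n[bc$boundary == "D1-D2"], 1L)   # edge column not counted
  expect_equal(bc$n[bc$boundary == "D2-D3"], 0L)
  expect_equal(bc$cells$row, 2)
  expect_equal(bc$cells$col, 8)
})

test_that("overlap is the Jaccard index of member sets", {
  expect_equal(rf_overlap(1:4, 1:4), 1)
  expect_equal(rf_overlap(1:4, 5:8), 0)
  expect_equal(rf_overlap(1:4, 3:6), 1 / 3)
})

test_that("a one-to-one map has maximal orientation-preservation score", {
  s <- tiny_spec()
  m <- rf_map(fake_tensor(s, diag(81)), modality = FALSE)
  expect_equal(topographic_order(m, "E"), 1)
  expect_equal(topographic_order(m, "I"), 1)
  # scrambled centroids score below a topographic map
  set.seed(8)
  scram <- diag(81)[sample(81), ]
  expect_lt(topographic_order(rf_map(fake_tensor(s, scram),
                                     modality = FALSE), "E"), 0.8)
})

test_that("modality counts 8-connected components and digit span counts bands", {
  s <- tiny_spec(); NC <- 81
  resp <- matrix(0, NC, NC)
  blob1 <- as.vector(outer(1:2, 1:2, function(r, c) pid(s, r, c)))
  blob2 <- as.vector(outer(7:8, 6:7, function(r, c) pid(s, r, c)))
  resp[, c(blob1, blob2)] <- 1
  m <- rf_map(fake_tensor(s, resp))
  expect_equal(m$n_modes, rep(2L, 2 * NC))     # bimodal, double-digit
  expect_equal(m$digit_span, rep(2L, 2 * NC))  # rows 1-2 in D1, 7-8 in D3
  # diagonal contact counts as connected
  resp2 <- matrix(0, NC, NC)
  resp2[, c(pid(s, 1, 1), pid(s, 2, 2), pid(s, 3, 3))] <- 1
  expect_equal(rf_map(fake_tensor(s, resp2))$n_modes[1], 1L)
})

test_that("track profiles order sites and report successive overlap", {
  s <- tiny_spec(); NC <- 81
  resp <- matrix(0, NC, NC)
  blk <- function(r, c) as.vector(outer(max(1, r - 1):min(9, r + 1),
                                        max(1, c - 1):min(9, c + 1),
                                        function(rr, cc) pid(s, rr, cc)))
  for (i in seq_len(NC)) {
    co <- probe_coords(s, i)
    resp[i, blk(co$row, co$col)] <- 1    # RF centered on own position
  }
  m <- rf_map(fake_tensor(s, resp), modality = FALSE)
  prof <- track_profile(m, row = 5, type = "E")
  expect_equal(prof$col, 1:9)
  expect_true(is.na(prof$overlap_prev[1]))
  expect_true(all(prof$overlap_prev[-1] > 0))
  # overlap decays monotonically with distance along the track
  memA <- rf_members(m, 5, 2, "E")
  ov <- sapply(3:7, function(cc) rf_overlap(memA, rf_members(m, 5, cc, "E")))
  expect_true(all(diff(ov) <= 0))
})

test_that("probing a network returns a complete tensor and never alters it", {
  net <- quiet_net(seed = 31)
  before <- net$weights
  pt <- probe_map(net)
  expect_identical(net$weights, before)
  expect_equal(dim(pt$e_stim), c(81L, 81L))
  expect_equal(dim(pt$i_peak), c(81L, 81L))
  # noise-free probing is reproducible
  pt2 <- probe_map(net)
  expect_identical(pt$e_stim, pt2$e_stim)
  # uncoupled cortex: stimulus-period rates equal pre-stimulus rates
  net0 <- net; net0$weights[] <- 0
  pt0 <- probe_map(net0)
  expect_equal(pt0$e_stim, pt0$e_pre, tolerance = 1e-12)
  expect_equal(rf_map(pt0, modality = FALSE)$magnitude, rep(1, 162),
               tolerance = 1e-12)
})
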