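#' Lattice and digit-partition specification
#'
#' Defines the paired square lattices of the model: an input (skin) layer and
#' a cortical layer, both `N` by `N`, with the input rows partitioned into
#' contiguous horizontal bands representing the digits of a model hand.  The
#' column axis is the proximal--distal (longitudinal) axis of the digits.
#' Connections are local: every postsynaptic cell sees a centered `M` by `M`
#' neighborhood, truncated (not wrapped) at the lattice edge.
#'
#' @param N side length of the square lattices (nodes).
#' @param M side of the local connection mask (odd, `M <= N`).
#' @param digit_rows integer vector of band heights (rows per digit), summing
#'   to `N`.  The default three 15-row bands with `N = 45` model a three-digit
#'   hand; digits are numbered D1, D2, ... from the top row down.
#' @return An object of class `lattice_spec`.
#' @examples
#' spec <- lattice_spec()                      # 45 x 45, three 15-row digits
#' small <- lattice_spec(30, 7, c(10, 10, 10)) # scaled-down control network
#' @export
lattice_spec <- function(N = 45L, M = 7L, digit_rows = NULL) {
  N <- as.integer(N); M <- as.integer(M)
  if (N < 1L) stop("N must be positive")
  if (M %% 2L == 0L) stop("mask side M must be odd")
  if (M > N) stop("mask side M must not exceed the lattice side N")
  if (is.null(digit_rows)) {
    if (N %% 3L != 0L)
      stop("supply digit_rows explicitly when N is not divisible by 3")
    digit_rows <- rep(N %/% 3L, 3L)
  }
  digit_rows <- as.integer(digit_rows)
  if (any(digit_rows < 1L) || sum(digit_rows) != N)
    stop("digit_rows must be positive and sum to N")
  structure(
    list(N = N, M = M, digit_rows = digit_rows,
         n_digits = length(digit_rows)),
    class = "lattice_spec")
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf("Lattice spec: %d x %d nodes, %d x %d local mask\n",
              x$N, x$N, x$M, x$M))
  b <- digit_bands(x)
  cat(sprintf("Digits: %s\n", paste(
    sprintf("%s rows %d-%d", b$digit, b$first, b$last), collapse = ", ")))
  invisible(x)
}

#' Digit band extents
#'
#' @param spec a [lattice_spec()].
#' @return Data frame with one row per digit: `digit` label, `first` and
#'   `last` row (1-based, inclusive).
#' @export
digit_bands <- function(spec) {
  last <- cumsum(spec$digit_rows)
  first <- c(1L, head(last, -1L) + 1L)
  data.frame(digit = paste0("D", seq_along(first)),
             first = first, last = last)
}

#' Digit membership of a lattice row
#' @param spec a [lattice_spec()].
#' @param row 1-based row index (vectorized).
#' @return Integer digit index per row.
#' @export
digit_of_row <- function(spec, row) {
  findInterval(row, c(1L, cumsum(spec$digit_rows) + 1L),
               rightmost.closed = FALSE)
}

#' Cortical column label
#'
#' Columns are conventionally labeled row-major: column id
#' `(row - 1) * N + col`.  With `N = 45` the label 648 is row 15, column 18 --
#' a column on the D1 side immediately adjacent to the D1--D2 border.
#'
#' @param spec a [lattice_spec()].
#' @param row,col 1-based lattice coordinates.
#' @return Integer column id.
#' @seealso [column_coord()] for the inverse.
#' @export
column_id <- function(spec, row, col) (row - 1L) * spec$N + col

#' @rdname column_id
#' @param id column id as returned by [column_id()].
#' @return For `column_coord`, a data frame with `row` and `col`.
#' @export
column_coord <- function(spec, id) {
  data.frame(row = (id - 1L) %/% spec$N + 1L,
             col = (id - 1L) %% spec$N + 1L)
}

# internal: 0-based column-major cell index used by the kernel
cell_index <- function(spec, row, col) (row - 1L) + spec$N * (col - 1L)

#' Build a connection topology
#'
#' Enumerates, for one connection type, the presynaptic sources of every
#' postsynaptic cell: the centered `M` by `M` neighborhood clipped at the
#' lattice edge (planar boundary conditions).  All four types (`ES`, `EE`,
#' `EI`, `IE`) share the same geometry; excitatory cells connect to
#' themselves (the center offset is part of `EE`), inhibitory cells have no
#' self-connection because no I-to-I type exists.  Each (postsynaptic,
#' presynaptic) pair occurs at most once.
#'
#' @param spec a [lattice_spec()].
#' @param type connection type, one of `"ES"`, `"EE"`, `"EI"`, `"IE"`.
#' @return An object of class `conn_topology` with the offset table, the
#'   validity mask and the per-cell fan-in.
#' @examples
#' tp <- build_topology(lattice_spec(), "ES")
#' tp$fan_in[1, 1]    # corner cell: ((M+1)/2)^2 = 16
#' tp$fan_in[23, 23]  # interior cell: M^2 = 49
#' @export
build_topology <- function(spec, type = c("ES", "EE", "EI", "IE")) {
  type <- match.arg(type)
  info <- .cpp_topology(spec$N, spec$M)
  fan <- matrix(info$fan_in, spec$N, spec$N)
  structure(
    list(spec = spec, type = type,
         offsets = data.frame(dr = info$dr, dc = info$dc),
         mask = info$mask,      # (N^2 cells) x (M^2 offsets), column-major cells
         fan_in = fan),
    class = "conn_topology")
}

#' @export
print.conn_topology <- function(x, ...) {
  cat(sprintf("%s topology on %d x %d lattice, %d x %d mask; fan-in %d-%d\n",
              x$type, x$spec$N, x$spec$N, x$spec$M, x$spec$M,
              min(x$fan_in), max(x$fan_in)))
  invisible(x)
}

#' Presynaptic sources of one cell
#'
#' @param topology a [build_topology()] result.
#' @param row,col 1-based postsynaptic cell coordinates.
#' @return Data frame of presynaptic `row`, `col` (1-based), one per source.
#' @export
presynaptic_sources <- function(topology, row, col) {
  off <- topology$offsets
  pr <- row + off$dr
  pc <- col + off$dc
  ok <- pr >= 1L & pr <= topology$spec$N & pc >= 1L & pc <= topology$spec$N
  data.frame(row = pr[ok], col = pc[ok])
}

#' Enumerate stimulus patches
#'
#' Lists every admissible placement of a `patch_h` by `patch_w` rectangular
#' stimulus on the input lattice, one placement per trial.  Placements
#' respect digit boundaries: a patch must lie wholly inside one digit band
#' (or inside the fused D1+D2 band under simulated syndactyly, or anywhere on
#' the lattice for the uniform-stimulation control).
#'
#' @param spec a [lattice_spec()].
#' @param patch_h,patch_w patch height and width in nodes.
#' @param boundary_mode `"respect_all"` (baseline), `"fuse_d1_d2"`
#'   (syndactyly: the D1--D2 boundary is ignored, all others respected), or
#'   `"uniform"` (patches range over the whole lattice; control condition).
#' @return Data frame of class `stimulus_patches`: 1-based `row`, `col` of
#'   the patch origin (top-left), `height`, `width`, and the `digit` label of
#'   the band the patch belongs to.
#' @examples
#' nrow(enumerate_patches(lattice_spec()))           # 1053 = 3 * 351
#' nrow(enumerate_patches(lattice_spec(), boundary_mode = "fuse_d1_d2")) # 1287
#' @export
enumerate_patches <- function(spec, patch_h = 7L, patch_w = 7L,
                              boundary_mode = c("respect_all", "fuse_d1_d2",
                                                "uniform")) {
  boundary_mode <- match.arg(boundary_mode)
  patch_h <- as.integer(patch_h); patch_w <- as.integer(patch_w)
  if (patch_h < 1L || patch_w < 1L) stop("patch dimensions must be positive")
  if (patch_w > spec$N) stop("patch wider than the lattice")
  bands <- digit_bands(spec)
  if (boundary_mode == "fuse_d1_d2") {
    if (spec$n_digits < 2L) stop("fuse_d1_d2 requires at least two digits")
    bands <- rbind(
      data.frame(digit = "D1+2", first = bands$first[1L],
                 last = bands$last[2L]),
      bands[-(1:2), , drop = FALSE])
  } else if (boundary_mode == "uniform") {
    bands <- data.frame(digit = "all", first = 1L, last = spec$N)
  }
  out <- lapply(seq_len(nrow(bands)), function(b) {
    rows <- bands$last[b] - bands$first[b] + 1L
    if (patch_h > rows)
      stop(sprintf("patch height %d exceeds the %d-row band %s",
                   patch_h, rows, bands$digit[b]))
    origins <- expand.grid(
      row = seq.int(bands$first[b], bands$last[b] - patch_h + 1L),
      col = seq_len(spec$N - patch_w + 1L))
    data.frame(row = origins$row, col = origins$col,
               height = patch_h, width = patch_w, digit = bands$digit[b])
  })
  out <- do.call(rbind, out)
  attr(out, "spec") <- spec
  attr(out, "boundary_mode") <- boundary_mode
  class(out) <- c("stimulus_patches", "data.frame")
  out
}

#' Per-node stimulation count map
#'
#' Counts, for every input-layer node, how many enumerated patch placements
#' cover it in one cycle.  Within a digit the count profile is highest along
#' the band midline and falls off toward band edges; same-height digits have
#' identical profiles up to row translation.
#'
#' @param patches a [enumerate_patches()] result.
#' @param spec the [lattice_spec()]; defaults to the one the patches carry.
#' @return `N` by `N` integer matrix of counts.
#' @export
stimulation_count_map <- function(patches, spec = attr(patches, "spec")) {
  counts <- matrix(0L, spec$N, spec$N)
  for (k in seq_len(nrow(patches))) {
    r <- patches$row[k]; c <- patches$col[k]
    rr <- r:(r + patches$height[k] - 1L)
    cc <- c:(c + patches$width[k] - 1L)
    counts[rr, cc] <- counts[rr, cc] + 1L
  }
  counts
}
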