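#' Build a rectangular trapping grid
#'
#' Constructs a regular lattice of trap locations in planar metric
#' coordinates, the layout used by grid-based small-mammal live-trapping
#' studies.  The origin (0, 0) is the south-west trap; trap identifiers are
#' assigned row-major from the SW corner.
#'
#' @param nx,ny Number of trap columns and rows (positive integers).
#' @param spacing Distance between adjacent traps along rows and columns,
#'   in metres.
#' @param detector Detector behaviour, `"multi_catch"` (several animals can
#'   share a trap within an occasion) or `"single_catch"` (a Sherman-style
#'   trap closed by its first capture).
#'
#' @return A tibble of class `trap_array` with columns `trap_id`, `x`, `y`
#'   and attributes recording the lattice dimensions, spacing and detector
#'   kind.
#' @examples
#' traps <- build_grid(10, 10, 9.43)
#' nrow(traps)
#' @export
build_grid <- function(nx, ny, spacing, detector = c("multi_catch", "single_catch")) {
  detector <- match.arg(detector)
  if (!is_count(nx) || !is_count(ny)) {
    stop("`nx` and `ny` must be positive integers", call. = FALSE)
  }
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0) {
    stop("`spacing` must be a single positive number of metres", call. = FALSE)
  }
  grid <- tidyr::expand_grid(row = seq_len(ny) - 1L, col = seq_len(nx) - 1L)
  traps <- tibble::tibble(
    trap_id = sprintf("T%03d", seq_len(nrow(grid))),
    x = grid$col * spacing,
    y = grid$row * spacing
  )
  new_trap_array(traps, detector = detector)
}

#' @keywords internal
new_trap_array <- function(df, detector = "multi_catch") {
  stopifnot(all(c("trap_id", "x", "y") %in% names(df)))
  df <- tibble::as_tibble(df[, c("trap_id", "x", "y")])
  df$trap_id <- as.character(df$trap_id)
  if (anyDuplicated(df$trap_id)) stop("trap ids must be unique", call. = FALSE)
  if (nrow(df) < 1L) stop("a trap array needs at least one trap", call. = FALSE)
  if (!all(is.finite(df$x)) || !all(is.finite(df$y))) {
    stop("trap coordinates must be finite", call. = FALSE)
  }
  structure(df, detector = detector,
            class = c("trap_array", class(tibble::tibble())))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

#' Detector kind of a trap array
#' @param traps A `trap_array`.
#' @return `"multi_catch"` or `"single_catch"`.
#' @export
detector_kind <- function(traps) {
  attr(traps, "detector") %||% "multi_catch"
}

# Recover (row, col) lattice indices from coordinates; errors if the traps do
# not sit on a complete or checkerboard-thinned rectangular lattice.
lattice_index <- function(traps, require_full = TRUE) {
  xs <- sort(unique(round(traps$x, 9)))
  ys <- sort(unique(round(traps$y, 9)))
  step <- function(v) if (length(v) > 1) diff(v) else numeric(0)
  dx <- step(xs); dy <- step(ys)
  sp <- c(dx, dy)
  if (length(sp) > 0 && max(abs(sp - sp[1])) > 1e-6) {
    stop("traps do not form a regular rectangular lattice", call. = FALSE)
  }
  spacing <- if (length(sp)) sp[1] else NA_real_
  col <- match(round(traps$x, 9), xs) - 1L
  row <- match(round(traps$y, 9), ys) - 1L
  if (require_full && nrow(traps) != length(xs) * length(ys)) {
    stop("traps do not form a complete rectangular lattice", call. = FALSE)
  }
  list(row = row, col = col, nx = length(xs), ny = length(ys), spacing = spacing)
}

#' Thin a grid to half density in a checkerboard pattern
#'
#' Removes every other trap from a rectangular lattice, leaving the
#' "five-dice" pattern used for half-density trapping designs.  The
#' south-west corner trap is always retained, so the surviving traps are
#' those whose row + column parity matches the SW corner.
#'
#' @param traps A `trap_array` forming a complete rectangular lattice.
#' @return A `trap_array` with roughly half the traps; original trap ids and
#'   coordinates are preserved.
#' @examples
#' half <- checkerboard_halve(build_grid(10, 10, 9.43))
#' nrow(half)                       # 50
#' mean_nearest_trap_distance(half) # 13.34 m
#' @export
checkerboard_halve <- function(traps) {
  idx <- lattice_index(traps)
  keep <- (idx$row + idx$col) %% 2L == 0L
  out <- traps[keep, , drop = FALSE]
  new_trap_array(out, detector = detector_kind(traps))
}

#' Extract a contiguous square sub-grid
#'
#' Reduced-area trapping designs drop whole rows and columns of an N x N
#' grid.  The position of the retained n x n block is set by `anchor`; the
#' five choices cover the centre and the four corners, so spatial bias of a
#' given placement can be assessed.
#'
#' @param traps A `trap_array` forming a complete N x N lattice.
#' @param n Side length (in traps) of the sub-grid, `n <= N`.
#' @param anchor One of `"NW"`, `"NE"`, `"SW"`, `"SE"`, `"center"`.
#' @return A `trap_array` of `n * n` traps with unchanged coordinates.
#' @examples
#' sub <- subgrid(build_grid(10, 10, 9.43), 7, "NW")
#' nrow(sub) # 49
#' @export
subgrid <- function(traps, n, anchor = c("NW", "NE", "SW", "SE", "center")) {
  anchor <- match.arg(anchor)
  idx <- lattice_index(traps)
  if (idx$nx != idx$ny) stop("`subgrid()` expects a square N x N lattice", call. = FALSE)
  N <- idx$nx
  if (!is_count(n) || n > N) {
    stop("`n` must be a positive integer no larger than the lattice side", call. = FALSE)
  }
  off <- switch(anchor,
    SW = c(0L, 0L),
    SE = c(0L, N - n),
    NW = c(N - n, 0L),
    NE = c(N - n, N - n),
    center = c((N - n) %/% 2L, (N - n) %/% 2L)
  )
  keep <- idx$row >= off[1] & idx$row < off[1] + n &
          idx$col >= off[2] & idx$col < off[2] + n
  new_trap_array(traps[keep, , drop = FALSE], detector = detector_kind(traps))
}

#' Mean nearest-trap distance
#'
#' Mean over traps of the distance from each trap to its nearest neighbour —
#' the "mean trap spacing" summary used to describe thinned designs.
#'
#' @param traps A `trap_array` with at least two traps.
#' @return Distance in metres.
#' @export
mean_nearest_trap_distance <- function(traps) {
  if (nrow(traps) < 2L) {
    stop("nearest-trap spacing is undefined for fewer than two traps", call. = FALSE)
  }
  d <- as.matrix(stats::dist(cbind(traps$x, traps$y)))
  diag(d) <- Inf
  mean(apply(d, 1L, min))
}

#' Buffer width from the detection spatial scale
#'
#' The habitat mask must extend far enough beyond the traps that animals
#' with activity centres outside it are effectively undetectable; the usual
#' rule is a multiple of the detection scale sigma (4 sigma by default in
#' downstream helpers).
#'
#' @param sigma Detection spatial scale in metres.
#' @param multiplier Dimensionless multiple, at least 1.
#' @return Buffer width in metres.
#' @examples
#' buffer_from_sigma(12.5, 4) # 50
#' @export
buffer_from_sigma <- function(sigma, multiplier = 4) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("`sigma` must be a single positive number of metres", call. = FALSE)
  }
  if (!is.numeric(multiplier) || length(multiplier) != 1L || multiplier < 1) {
    stop("`multiplier` must be at least 1", call. = FALSE)
  }
  multiplier * sigma
}

#' Discretise the region around a trap array into a habitat mask
#'
#' The SECR likelihood integrates over possible activity centres; the mask
#' is a regular lattice of cell centres covering the trap bounding box
#' expanded by `buffer` on all sides.  Cells are squares of side
#' `mask_spacing`; the number of cells per side is the smallest count whose
#' total extent covers the buffered box, so the summed cell area can exceed
#' the box area by at most a sliver under one cell row per dimension.
#'
#' @param traps A `trap_array`.
#' @param buffer Buffer width in metres (non-negative).
#' @param mask_spacing Cell side in metres; defaults to `buffer / 10`
#'   (about 5 m for the standard 50 m buffer), fine enough that halving it
#'   moves density estimates by well under 1%.
#' @return A tibble of class `habitat_mask` with columns `x`, `y` and
#'   attributes `cell_area_ha`, `spacing`, `buffer` and `area_ha`.
#' @examples
#' mask <- build_mask(build_grid(10, 10, 9.43), buffer = 50)
#' attr(mask, "area_ha")
#' @export
build_mask <- function(traps, buffer, mask_spacing = NULL) {
  if (!is.numeric(buffer) || length(buffer) != 1L || buffer < 0) {
    stop("`buffer` must be a single non-negative number of metres", call. = FALSE)
  }
  if (is.null(mask_spacing)) {
    mask_spacing <- if (buffer > 0) buffer / 10 else 1
  }
  if (!is.numeric(mask_spacing) || length(mask_spacing) != 1L || mask_spacing <= 0) {
    stop("`mask_spacing` must be a single positive number of metres", call. = FALSE)
  }
  xr <- range(traps$x) + c(-buffer, buffer)
  yr <- range(traps$y) + c(-buffer, buffer)
  ncell <- function(extent) max(1L, ceiling(extent / mask_spacing - 1e-9))
  nx <- ncell(diff(xr)); ny <- ncell(diff(yr))
  # centre the covered span on the buffered box so the overhang is symmetric
  centres <- function(lo, extent, n) {
    start <- lo - (n * mask_spacing - extent) / 2
    start + (seq_len(n) - 0.5) * mask_spacing
  }
  pts <- tidyr::expand_grid(y = centres(yr[1], diff(yr), ny),
                            x = centres(xr[1], diff(xr), nx))
  mask <- tibble::tibble(x = pts$x, y = pts$y)
  cell_ha <- mask_spacing^2 / 1e4
  structure(mask,
            cell_area_ha = cell_ha,
            spacing = mask_spacing,
            buffer = buffer,
            area_ha = nrow(mask) * cell_ha,
            class = c("habitat_mask", class(tibble::tibble())))
}

#' Total area of a habitat mask in hectares
#' @param mask A `habitat_mask`.
#' @return Area in hectares (cell count times cell area).
#' @export
mask_area <- function(mask) {
  attr(mask, "area_ha") %||% (nrow(mask) * attr(mask, "cell_area_ha"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
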