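# Tile stitching with linear-ramp blending.

#' Linear ramp weights for an overlap region
#'
#' The incoming tile's weight at 0-based overlap position `i` is
#' `(i + 1) / (overlap + 1)`; the outgoing tile carries the complement.
#' Endpoints are strictly inside (0, 1) so every acquired pixel contributes.
#'
#' @param overlap Overlap width in pixels (>= 0); `0` returns an empty
#'   profile (plain abutment).
#' @return Numeric vector of incoming-tile weights.
#' @examples
#' linear_ramp_weights(3) # 0.25 0.50 0.75
#' @export
linear_ramp_weights <- function(overlap) {
  if (!is_scalar_number(overlap) || overlap < 0 || overlap != round(overlap)) {
    abort_invalid("`overlap` must be a non-negative integer.")
  }
  if (overlap == 0) return(numeric(0))
  seq_len(overlap) / (overlap + 1)
}

#' Regular tile grid layout
#'
#' Splits an image of dimension `image_dim` into a `grid[1] x grid[2]` grid
#' of equally sized tiles overlapping their neighbours by `overlap_px`
#' pixels. The geometry must be exact: `(dim + (k - 1) * overlap)` must be
#' divisible by `k` along each axis.
#'
#' @param image_dim Full-image dimension `c(rows, cols)`.
#' @param grid Tile grid `c(rows, cols)`.
#' @param overlap_px Overlap width in pixels (same on both axes).
#' @return An object of class `tile_layout`.
#' @export
tile_layout <- function(image_dim, grid = c(2, 2), overlap_px = 16) {
  if (length(image_dim) != 2 || length(grid) != 2) {
    abort_invalid("`image_dim` and `grid` must each have two entries.")
  }
  if (!is_scalar_number(overlap_px) || overlap_px < 0 ||
      overlap_px != round(overlap_px)) {
    abort_invalid("`overlap_px` must be a non-negative integer.")
  }
  tile_dim <- integer(2)
  for (a in 1:2) {
    k <- grid[a]
    if (k == 1 && overlap_px >= 0) {
      tile_dim[a] <- as.integer(image_dim[a])
      next
    }
    tot <- image_dim[a] + (k - 1) * overlap_px
    if (tot %% k != 0) {
      abort_invalid(sprintf(
        "axis %d: image size %d with %d tiles and overlap %d is not an exact grid.",
        a, image_dim[a], k, overlap_px))
    }
    tile_dim[a] <- as.integer(tot %/% k)
    if (tile_dim[a] <= overlap_px) {
      abort_invalid("tiles must be larger than the overlap.")
    }
  }
  starts <- function(a) {
    as.integer(1 + (seq_len(grid[a]) - 1) * (tile_dim[a] - overlap_px))
  }
  structure(
    list(image_dim = as.integer(image_dim), grid = as.integer(grid),
         tile_dim = tile_dim, overlap_px = as.integer(overlap_px),
         row_starts = starts(1), col_starts = starts(2)),
    class = "tile_layout"
  )
}

#' Split an image into tiles
#'
#' @param image Numeric matrix matching the layout's image dimension.
#' @param layout A [tile_layout()].
#' @return List of tile matrices in row-major tile order.
#' @export
split_tiles <- function(image, layout) {
  stopifnot(inherits(layout, "tile_layout"))
  if (!identical(dim(image), layout$image_dim)) {
    abort_invalid("image dimensions do not match the layout.")
  }
  tiles <- list()
  for (i in seq_along(layout$row_starts)) {
    for (j in seq_along(layout$col_starts)) {
      r0 <- layout$row_starts[i]; c0 <- layout$col_starts[j]
      tiles[[length(tiles) + 1L]] <-
        image[r0:(r0 + layout$tile_dim[1] - 1L),
              c0:(c0 + layout$tile_dim[2] - 1L), drop = FALSE]
    }
  }
  tiles
}

# Per-axis blending profile for tile index k of K tiles of width w with
# overlap o: ramp up on the left (unless first), ramp down on the right
# (unless last), 1 in the interior. Complementary ramps sum to 1 exactly.
axis_profile <- function(k, K, w, o) {
  prof <- rep(1, w)
  if (o > 0) {
    ramp <- linear_ramp_weights(o)
    if (k > 1) prof[seq_len(o)] <- ramp
    if (k < K) prof[(w - o + 1):w] <- rev(ramp)
  }
  prof
}

#' Stitch tiles with linear-ramp blending
#'
#' Reassembles the full image from a regular tile grid, blending overlap
#' regions with complementary linear ramps. Constant fields are preserved
#' exactly because the weights sum to one at every pixel.
#'
#' @param tiles List of tile matrices in row-major tile order.
#' @param layout A [tile_layout()].
#' @return The stitched matrix.
#' @export
stitch <- function(tiles, layout) {
  stopifnot(inherits(layout, "tile_layout"))
  if (length(tiles) != prod(layout$grid)) {
    abort_invalid("number of tiles does not match the layout grid.")
  }
  out <- matrix(0, layout$image_dim[1], layout$image_dim[2])
  idx <- 0L
  for (i in seq_along(layout$row_starts)) {
    pr <- axis_profile(i, layout$grid[1], layout$tile_dim[1], layout$overlap_px)
    for (j in seq_along(layout$col_starts)) {
      idx <- idx + 1L
      tile <- tiles[[idx]]
      if (!identical(dim(tile), layout$tile_dim)) {
        abort_invalid("tile dimensions do not match the layout.")
      }
      pc <- axis_profile(j, layout$grid[2], layout$tile_dim[2],
                         layout$overlap_px)
      w <- outer(pr, pc)
      r0 <- layout$row_starts[i]; c0 <- layout$col_starts[j]
      rows <- r0:(r0 + layout$tile_dim[1] - 1L)
      cols <- c0:(c0 + layout$tile_dim[2] - 1L)
      out[rows, cols] <- out[rows, cols] + w * tile
    }
  }
  out
}

#' Stitch wrapped differential-phase tiles
#'
#' Differential-phase tiles are blended on the complex phasor `exp(i * phi)`
#' and the angle re-taken, so the ramps never average across the +/- pi cut.
#'
#' @param tiles List of phase tiles (radians).
#' @param layout A [tile_layout()].
#' @return Stitched phase matrix in (-pi, pi].
#' @export
stitch_phase <- function(tiles, layout) {
  re <- stitch(lapply(tiles, cos), layout)
  im <- stitch(lapply(tiles, sin), layout)
  wrap_phase(atan2(im, re))
}
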