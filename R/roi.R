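# Rectangular regions of interest. 1-based, inclusive on both ends
# (rows run top-down, columns left-right), stored as length-4 integer
# vectors c(row1, row2, col1, col2).

#' Define a rectangular region of interest
#'
#' @param row1,row2 First and last row (1-based, inclusive).
#' @param col1,col2 First and last column (1-based, inclusive).
#' @return An integer vector of class `roi`.
#' @export
roi <- function(row1, row2, col1, col2) {
  r <- c(row1 = unname(row1), row2 = unname(row2),
         col1 = unname(col1), col2 = unname(col2))
  if (any(!is.finite(r)) || any(r != round(r)) || any(r < 1)) {
    abort_invalid("ROI bounds must be positive integers.")
  }
  if (r[["row2"]] < r[["row1"]] || r[["col2"]] < r[["col1"]]) {
    abort_invalid("ROI must satisfy row2 >= row1 and col2 >= col1.")
  }
  structure(as.integer(r), names = names(r), class = "roi")
}

as_roi <- function(x) {
  if (inherits(x, "roi")) return(x)
  if (is.numeric(x) && length(x) == 4L) return(roi(x[1], x[2], x[3], x[4]))
  abort_invalid("expected an ROI (length-4 vector row1, row2, col1, col2).")
}

roi_in_bounds <- function(r, dim) {
  r[1] >= 1L && r[3] >= 1L && r[2] <= dim[1] && r[4] <= dim[2]
}

roi_overlaps <- function(a, b) {
  a[1] <= b[2] && b[1] <= a[2] && a[3] <= b[4] && b[3] <= a[4]
}

roi_area <- function(r) {
  unname((r[2] - r[1] + 1L) * (r[4] - r[3] + 1L))
}

roi_values <- function(image, r) {
  image[r[1]:r[2], r[3]:r[4]]
}

# Shift an ROI by (drow, dcol).
roi_shift <- function(r, drow, dcol) {
  roi(r[1] + drow, r[2] + drow, r[3] + dcol, r[4] + dcol)
}

layout_roi <- function(layout_row, prefix) {
  roi(layout_row[[paste0(prefix, "_row1")]],
      layout_row[[paste0(prefix, "_row2")]],
      layout_row[[paste0(prefix, "_col1")]],
      layout_row[[paste0(prefix, "_col2")]])
}
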