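# Orientation classes and their ON-region geometry.
#
# Coordinate convention (fixed throughout the package): (row, col), row
# increases downward, column increases rightward. 45 degrees is the
# anti-diagonal (up-right to down-left), 135 degrees the main diagonal
# (up-left to down-right).

.ORIENTATIONS <- c(0L, 45L, 90L, 135L)

# Three ON-region offsets (dr, dc) relative to the receptive-field centre;
# the centre (0,0) belongs to every triple.
.ON_OFFSETS <- list(
  "0"   = cbind(dr = c(0L, 0L, 0L),   dc = c(-1L, 0L, 1L)),
  "45"  = cbind(dr = c(-1L, 0L, 1L),  dc = c(1L, 0L, -1L)),
  "90"  = cbind(dr = c(-1L, 0L, 1L),  dc = c(0L, 0L, 0L)),
  "135" = cbind(dr = c(-1L, 0L, 1L),  dc = c(-1L, 0L, 1L))
)

#' The four detectable orientation classes
#'
#' The artificial visual system discriminates four global orientations,
#' one per simple-cell type: 0 (horizontal), 45 (anti-diagonal),
#' 90 (vertical) and 135 (main diagonal) degrees.
#'
#' @return Integer vector `c(0L, 45L, 90L, 135L)`.
#' @export
#' @examples
#' orientations()
orientations <- function() .ORIENTATIONS

#' ON-region offsets of an orientation-selective simple cell
#'
#' Each simple cell has a 3x3 local receptive field whose excitatory (ON)
#' region is a 3-pixel line through the centre. This returns the three
#' (row, col) offsets, relative to the centre, that make up the ON region
#' for one orientation class. Rows increase downward, columns rightward,
#' so 45 degrees is the anti-diagonal triple and 135 the main diagonal.
#'
#' @param orientation One of 0, 45, 90, 135 (degrees).
#' @return A 3x2 integer matrix with columns `dr`, `dc`; the centre
#'   offset (0, 0) is always the middle row.
#' @export
#' @examples
#' orientation_offsets(45)
orientation_offsets <- function(orientation) {
  .ON_OFFSETS[[as_orientation(orientation)]]
}

# Validate and canonicalise an orientation to its character key.
as_orientation <- function(orientation) {
  key <- as.character(orientation)
  key <- sub("^([0-9]+)\\.0*$", "\\1", key)
  if (length(key) != 1L || !key %in% names(.ON_OFFSETS)) {
    stop("orientation must be one of 0, 45, 90, 135 (degrees), got: ",
         paste(orientation, collapse = ", "), call. = FALSE)
  }
  key
}
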