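#' Construct a binary image
#'
#' The input to the artificial visual system: an M x N grid of photoreceptor
#' states, 1 where the receptor receives light and 0 otherwise.
#'
#' @param x A matrix (or object coercible to one) whose entries are all 0 or 1.
#' @return An integer matrix of class `binary_image`.
#' @export
#' @examples
#' binary_image(rbind(c(0, 1, 0), c(1, 1, 1), c(0, 1, 0)))
binary_image <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop("a binary image must have at least one row and one column",
         call. = FALSE)
  }
  if (anyNA(x) || !all(x == 0L | x == 1L)) {
    stop("every pixel of a binary image must be exactly 0 or 1",
         call. = FALSE)
  }
  storage.mode(x) <- "integer"
  dimnames(x) <- NULL
  class(x) <- c("binary_image", class(matrix()))
  x
}

#' @rdname binary_image
#' @export
as_binary_image <- function(x) {
  if (is_binary_image(x)) x else binary_image(x)
}

#' @rdname binary_image
#' @export
is_binary_image <- function(x) inherits(x, "binary_image")

#' Number of lit pixels in a binary image
#'
#' @param image A [binary_image()] or 0/1 matrix.
#' @return Integer count of pixels equal to 1.
#' @export
lit_pixels <- function(image) sum(as_binary_image(image) == 1L)

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf("<binary_image: %d x %d, %d lit>\n", nrow(x), ncol(x),
              sum(x == 1L)))
  glyph <- ifelse(unclass(x) == 1L, "#", ".")
  apply(glyph, 1L, function(row) cat(paste(row, collapse = ""), "\n"))
  invisible(x)
}

#' @export
plot.binary_image <- function(x, ...) {
  m <- unclass(x)
  # image() draws column-major from the bottom; reorient so the plot matches
  # the printed grid (row 1 at the top).
  graphics::image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = c("white", "black"), axes = FALSE, asp = nrow(m) / ncol(m),
                  ...)
  invisible(x)
}
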