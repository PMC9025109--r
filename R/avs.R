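#' An artificial visual system for global orientation detection
#'
#' Constructs the feedforward model: for an M x N binary image, every pixel
#' is the centre of a 3x3 local receptive field watched by four
#' McCulloch-Pitts simple cells (one per orientation class). A simple cell
#' fires when the weighted sum of its three ON-region inputs reaches the
#' threshold `theta`; with unit weights and `theta = 2.5` this means all
#' three ON pixels are lit. Four complex cells each sum every
#' same-orientation simple-cell output over the whole image, and the most
#' activated complex cell labels the global orientation.
#'
#' The parameters exist so the threshold logic stays inspectable and
#' perturbable; the defaults are the model proper and are what every other
#' function in the package uses.
#'
#' @param theta Activation threshold of a simple cell (unitless).
#' @param weights Connection weights of the three ON-region inputs, in
#'   offset order (see [orientation_offsets()]). OFF-region weights are
#'   identically 0 and are not parameters.
#' @return An object of class `avs`.
#' @seealso [predict.avs()], [detect_orientation()], [scan_simple_cells()]
#' @export
#' @examples
#' m <- avs()
#' img <- binary_image(rbind(c(0, 0, 0), c(1, 1, 1), c(0, 0, 0)))
#' predict(m, img)
avs <- function(theta = 2.5, weights = c(1, 1, 1)) {
  stopifnot(is.numeric(theta), length(theta) == 1L, !is.na(theta),
            is.numeric(weights), length(weights) == 3L, !anyNA(weights),
            all(weights >= 0))
  structure(list(theta = as.numeric(theta), weights = as.numeric(weights)),
            class = "avs")
}

#' @export
print.avs <- function(x, ...) {
  cat("Artificial visual system (Hubel-Wiesel feedforward model)\n")
  cat(sprintf("  simple cells : 3x3 receptive field, ON weights (%s), theta = %g\n",
              paste(format(x$weights), collapse = ", "), x$theta))
  cat("  complex cells: one per orientation class (0, 45, 90, 135 deg),\n")
  cat("                 each summing all same-orientation simple cells\n")
  invisible(x)
}

#' @export
coef.avs <- function(object, ...) {
  c(w1 = object$weights[1L], w2 = object$weights[2L], w3 = object$weights[3L],
    theta = object$theta)
}

#' @export
summary.avs <- function(object, dim = c(32L, 32L), ...) {
  arch <- avs_architecture(dim, model = object)
  structure(list(model = object, dim = dim, architecture = arch),
            class = "summary.avs")
}

#' @export
print.summary.avs <- function(x, ...) {
  print(x$model)
  a <- x$architecture
  cat(sprintf("Instantiated for a %d x %d input:\n", x$dim[1L], x$dim[2L]))
  cat(sprintf("  local receptive fields : %d\n", a$receptive_fields))
  cat(sprintf("  simple cells           : %d\n", a$simple_cells))
  cat(sprintf("  complex cells          : %d\n", a$complex_cells))
  cat(sprintf("  spike-rate ceiling     : %d per complex cell\n",
              a$max_spike_rate))
  invisible(x)
}

#' Cell counts of the system instantiated for a given image size
#'
#' An M x N input is covered by M*N local receptive fields (one per pixel
#' centre), each inspected by four orientation-selective simple cells, all
#' pooled by four complex cells. Since each firing simple cell contributes
#' one spike to its complex cell, a complex cell's spike rate is at most
#' M*N.
#'
#' @param dim Image size `c(M, N)` in pixels.
#' @param model An [avs()] model (counts do not depend on its parameters).
#' @return A list with `receptive_fields`, `simple_cells`, `complex_cells`
#'   and `max_spike_rate`.
#' @export
#' @examples
#' avs_architecture(c(32, 32))
avs_architecture <- function(dim, model = avs()) {
  stopifnot(length(dim) == 2L, all(dim >= 1L))
  M <- as.integer(dim[1L]); N <- as.integer(dim[2L])
  list(receptive_fields = M * N,
       simple_cells = M * N * length(.ORIENTATIONS),
       complex_cells = length(.ORIENTATIONS),
       max_spike_rate = M * N)
}

# Shifted copy of a matrix: out[r, c] = x[r + dr, c + dc], zero where the
# source index leaves the matrix (out-of-image = no light stimulation).
shift_zero <- function(x, dr, dc) {
  M <- nrow(x); N <- ncol(x)
  out <- matrix(0L, M, N)
  r1 <- max(1L, 1L - dr); r2 <- min(M, M - dr)
  c1 <- max(1L, 1L - dc); c2 <- min(N, N - dc)
  if (r1 <= r2 && c1 <= c2) {
    out[r1:r2, c1:c2] <- x[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc)]
  }
  out
}

#' Response of a single simple cell
#'
#' Evaluates one orientation-selective simple cell centred at a given
#' pixel: the weighted sum of its three ON-region inputs is compared with
#' the threshold. ON-region pixels falling outside the image contribute 0
#' (no light stimulation); OFF-region pixels never affect the result.
#'
#' @param image A [binary_image()] or 0/1 matrix.
#' @param center Length-2 integer `(row, col)` of the receptive-field
#'   centre, 1-based.
#' @param orientation One of 0, 45, 90, 135.
#' @param model An [avs()] model.
#' @return `1L` if the cell fires, else `0L`.
#' @export
#' @examples
#' img <- matrix(0L, 5, 5); img[3, 2:4] <- 1L
#' simple_cell_response(img, c(3, 3), 0)   # horizontal triple lit -> fires
#' simple_cell_response(img, c(3, 3), 90)  # vertical triple unlit -> silent
simple_cell_response <- function(image, center, orientation, model = avs()) {
  img <- as_binary_image(image)
  stopifnot(length(center) == 2L)
  r <- as.integer(center[1L]); c <- as.integer(center[2L])
  if (r < 1L || r > nrow(img) || c < 1L || c > ncol(img)) {
    stop(sprintf("centre (%d, %d) lies outside the %d x %d image",
                 r, c, nrow(img), ncol(img)), call. = FALSE)
  }
  off <- orientation_offsets(orientation)
  s <- 0
  for (k in 1:3) {
    rr <- r + off[k, "dr"]; cc <- c + off[k, "dc"]
    x <- if (rr >= 1L && rr <= nrow(img) && cc >= 1L && cc <= ncol(img)) {
      img[rr, cc]
    } else 0L
    s <- s + model$weights[k] * x
  }
  if (s >= model$theta) 1L else 0L
}

#' Scan all simple cells over an image
#'
#' Evaluates every simple cell of the system: one per pixel (receptive-field
#' centre) per orientation class, i.e. M*N*4 cells for an M x N image.
#'
#' @inheritParams simple_cell_response
#' @return A named list of four 0/1 activation matrices (one per
#'   orientation, names `"0"`, `"45"`, `"90"`, `"135"`), class
#'   `simple_cell_maps`.
#' @export
#' @examples
#' img <- matrix(0L, 5, 5); img[3, ] <- 1L
#' scan_simple_cells(img)[["0"]]
scan_simple_cells <- function(image, model = avs()) {
  img <- unclass(as_binary_image(image))
  w <- model$weights
  maps <- lapply(.ON_OFFSETS, function(off) {
    s <- w[1L] * shift_zero(img, off[1L, "dr"], off[1L, "dc"]) +
         w[2L] * shift_zero(img, off[2L, "dr"], off[2L, "dc"]) +
         w[3L] * shift_zero(img, off[3L, "dr"], off[3L, "dc"])
    m <- matrix(as.integer(s >= model$theta), nrow(img), ncol(img))
    m
  })
  structure(maps, class = "simple_cell_maps")
}

#' Complex-cell spike rates
#'
#' Each complex cell sums the outputs of every simple cell of its
#' orientation; the sum is its spike rate (one spike per firing simple
#' cell). Accepts either an image or the activation maps from
#' [scan_simple_cells()].
#'
#' @param x A binary image, or a `simple_cell_maps` list of four equally
#'   sized activation matrices named by orientation.
#' @param model An [avs()] model (used only when `x` is an image).
#' @return Named integer vector of class `complex_response`: spike rates
#'   for orientations `"0"`, `"45"`, `"90"`, `"135"`.
#' @export
#' @examples
#' img <- matrix(0L, 7, 7); img[2:6, 2:6] <- 1L   # filled 5x5 square
#' complex_response(img)
complex_response <- function(x, model = avs()) {
  if (inherits(x, "simple_cell_maps") ||
      (is.list(x) && !is_binary_image(x))) {
    maps <- x
    if (!setequal(names(maps), names(.ON_OFFSETS))) {
      stop("activation maps must be named by the four orientations",
           call. = FALSE)
    }
    dims <- vapply(maps, function(m) dim(m), integer(2L))
    if (any(dims != dims[, 1L])) {
      stop("activation maps must all have identical dimensions",
           call. = FALSE)
    }
    maps <- maps[names(.ON_OFFSETS)]
  } else {
    maps <- scan_simple_cells(x, model)
  }
  z <- vapply(maps, function(m) as.integer(sum(m)), integer(1L))
  structure(z, class = "complex_response")
}

#' @export
print.complex_response <- function(x, ...) {
  cat("Complex-cell spike rates (spikes):\n")
  print(stats::setNames(as.integer(x), paste0(names(x), "°")))
  invisible(x)
}

#' Detect the global orientation of an object in a binary image
#'
#' Runs the full pipeline — simple-cell scan, complex-cell pooling,
#' winner-take-all — and reports the orientation of the maximally activated
#' complex cell. Ties are never broken silently: when two or more complex
#' cells share the maximal spike rate (e.g. a square activates the 0- and
#' 90-degree cells equally) or when no cell fires at all, the result is
#' flagged ambiguous and carries no label.
#'
#' @inheritParams simple_cell_response
#' @return An object of class `avs_detection` with elements `z` (the
#'   [complex_response()]), `winners` (orientations attaining the maximal
#'   nonzero spike rate; empty when nothing fires), `is_ambiguous`, and
#'   `label` (the winning orientation, or `NA` when ambiguous).
#' @export
#' @examples
#' img <- matrix(0L, 7, 7); img[4, 2:6] <- 1L
#' detect_orientation(img)
detect_orientation <- function(image, model = avs()) {
  z <- complex_response(image, model)
  mx <- max(z)
  winners <- if (mx > 0L) .ORIENTATIONS[as.integer(z) == mx] else integer(0L)
  ambiguous <- length(winners) != 1L
  structure(list(z = z,
                 winners = winners,
                 is_ambiguous = ambiguous,
                 label = if (ambiguous) NA_integer_ else winners),
            class = "avs_detection")
}

#' @export
print.avs_detection <- function(x, ...) {
  print(x$z)
  if (!x$is_ambiguous) {
    cat(sprintf("Detected orientation: %d°\n", x$label))
  } else if (length(x$winners) == 0L) {
    cat("No complex cell fired: no orientation detected.\n")
  } else {
    cat(sprintf("Ambiguous: orientations {%s} are equally most activated.\n",
                paste0(x$winners, "°", collapse = ", ")))
  }
  invisible(x)
}

#' Predict method for the artificial visual system
#'
#' @param object An [avs()] model.
#' @param newdata A binary image (or a list of them).
#' @param type `"detection"` for the full [detect_orientation()] result,
#'   `"label"` for just the orientation label (NA when ambiguous),
#'   `"response"` for the four complex-cell spike rates.
#' @param ... Unused.
#' @return See `type`; for a list of images, a list (or vector/matrix) of
#'   the corresponding results.
#' @export
predict.avs <- function(object, newdata,
                        type = c("detection", "label", "response"), ...) {
  type <- match.arg(type)
  one <- function(img) {
    switch(type,
           detection = detect_orientation(img, object),
           label = detect_orientation(img, object)$label,
           response = complex_response(img, object))
  }
  if (is.list(newdata) && !is_binary_image(newdata)) {
    out <- lapply(newdata, one)
    if (type == "label") out <- unlist(out)
    if (type == "response") out <- do.call(rbind, out)
    out
  } else {
    one(newdata)
  }
}

#' Spike record of the complex cells
#'
#' Replays the scan in row-major order over receptive-field centres and
#' records, per orientation, the sequence of simple-cell firing events
#' (each event is the centre coordinate of a firing cell). The length of a
#' record equals that complex cell's spike rate.
#'
#' @inheritParams simple_cell_response
#' @return Named list of four data frames with columns `row`, `col`, in
#'   scan order; class `spike_record`.
#' @export
#' @examples
#' img <- matrix(0L, 3, 7); img[2, 2:6] <- 1L
#' spike_record(img)[["0"]]
spike_record <- function(image, model = avs()) {
  maps <- scan_simple_cells(image, model)
  rec <- lapply(maps, function(m) {
    idx <- which(t(m) == 1L)  # transpose -> row-major over (row, col)
    N <- ncol(m)
    data.frame(row = (idx - 1L) %/% N + 1L,
               col = (idx - 1L) %% N + 1L)
  })
  structure(rec, class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  cat("Spike record (scan-ordered simple-cell firings):\n")
  for (o in names(x)) {
    cat(sprintf("  %3s°: %d spike(s)\n", o, nrow(x[[o]])))
  }
  invisible(x)
}
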