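# Generators for the evaluation inputs: ideal oriented objects, elongated
# blobs, pixel noise, morph sequences, and labelled datasets.

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Bounding box (rows, cols) of a rendered object.
object_bbox <- function(orientation, length, width) {
  switch(as_orientation(orientation),
         "0"   = c(width, length),
         "90"  = c(length, width),
         "45"  = c(length, length + width - 1L),
         "135" = c(length, length + width - 1L))
}

#' Specify an ideal oriented object
#'
#' An ideal object is a line (width 1), bar or rectangle with one definite
#' orientation among the four classes. For 0/90 degrees it renders as a
#' filled axis-aligned length x width rectangle; for 45/135 degrees as
#' `width` adjacent parallel diagonal runs of `length` pixels each (a
#' staircase bar). A definite orientation requires strict `length > width`;
#' squares — which the system genuinely cannot orient — are only allowed
#' with `allow_square = TRUE`.
#'
#' @param family One of `"line"`, `"bar"`, `"rectangle"` (synonyms differing
#'   only in width: a line has width 1) or `"blob"` (see [render_blob()]).
#' @param orientation One of 0, 45, 90, 135 (degrees): the long axis.
#' @param length Extent along the long axis, in pixels.
#' @param width Extent across it, in pixels (>= 1).
#' @param position `(row, col)` of the bounding box's top-left corner,
#'   1-based; `NULL` centres the object in the frame.
#' @param frame Image size `c(M, N)`.
#' @param allow_square Permit `length == width` (ambiguous by construction).
#' @return An object of class `object_spec`.
#' @export
#' @examples
#' object_spec("line", 0, length = 5)
object_spec <- function(family = c("line", "bar", "rectangle", "blob"),
                        orientation, length, width = 1L, position = NULL,
                        frame = c(32L, 32L), allow_square = FALSE) {
  family <- match.arg(family)
  orientation <- as.integer(as_orientation(orientation))
  L <- as.integer(length); W <- as.integer(width)
  stopifnot(L >= 1L, W >= 1L, base::length(frame) == 2L)
  frame <- as.integer(frame)
  if (L * W < 3L) {
    stop("an ideal object must have at least 3 lit pixels", call. = FALSE)
  }
  if (L < W || (L == W && !allow_square)) {
    stop("a definite orientation requires length > width ",
         "(use allow_square = TRUE for deliberately ambiguous squares)",
         call. = FALSE)
  }
  bbox <- object_bbox(orientation, L, W)
  if (any(bbox > frame)) {
    stop(sprintf("object footprint %d x %d does not fit a %d x %d frame",
                 bbox[1L], bbox[2L], frame[1L], frame[2L]), call. = FALSE)
  }
  if (is.null(position)) {
    position <- (frame - bbox) %/% 2L + 1L
  }
  position <- as.integer(position)
  if (any(position < 1L) || any(position + bbox - 1L > frame)) {
    stop("object at this position does not fit entirely inside the frame",
         call. = FALSE)
  }
  structure(list(family = family, orientation = orientation,
                 length = L, width = W, position = position, frame = frame,
                 allow_square = allow_square),
            class = "object_spec")
}

#' @export
print.object_spec <- function(x, ...) {
  cat(sprintf("<object_spec: %s, %d°, length %d x width %d, at (%d, %d) in %d x %d>\n",
              x$family, x$orientation, x$length, x$width,
              x$position[1L], x$position[2L], x$frame[1L], x$frame[2L]))
  invisible(x)
}

#' Render an ideal object into a binary image
#'
#' @param spec An [object_spec()].
#' @return A list with `image` (a [binary_image()]) and `mask` (0/1 matrix
#'   marking exactly the object pixels; here identical to the clean image).
#' @export
#' @examples
#' render_object(object_spec("bar", 135, length = 3, frame = c(7, 7)))$image
render_object <- function(spec) {
  stopifnot(inherits(spec, "object_spec"))
  M <- spec$frame[1L]; N <- spec$frame[2L]
  L <- spec$length; W <- spec$width
  r0 <- spec$position[1L]; c0 <- spec$position[2L]
  mask <- matrix(0L, M, N)
  o <- as.character(spec$orientation)
  if (o == "0") {
    mask[r0:(r0 + W - 1L), c0:(c0 + L - 1L)] <- 1L
  } else if (o == "90") {
    mask[r0:(r0 + L - 1L), c0:(c0 + W - 1L)] <- 1L
  } else {
    i <- rep(0:(L - 1L), times = W)
    k <- rep(0:(W - 1L), each = L)
    rows <- r0 + i
    cols <- if (o == "135") c0 + k + i else c0 + (L - 1L) - i + k
    mask[cbind(rows, cols)] <- 1L
  }
  list(image = binary_image(mask), mask = mask)
}

#' Add pixel noise to a binary image
#'
#' Two regimes. `"background"` noise lights `round(p * M * N)` distinct
#' pixels chosen uniformly among background (non-object) pixels; the object
#' itself is never altered. `"whole_image"` noise flips (0 -> 1, 1 -> 0)
#' `round(p * M * N)` distinct pixels chosen uniformly over the entire
#' frame, so it can erase object pixels and change the object's shape.
#' Sampling is without replacement.
#'
#' @param image A [binary_image()] or 0/1 matrix.
#' @param mask Object-pixel mask (required for `"background"`).
#' @param kind `"background"` or `"whole_image"`.
#' @param p Noise proportion in \[0, 1\], as a fraction of all M*N pixels.
#' @param seed Optional integer; when given, noise placement is drawn from
#'   a local RNG seeded with it and the caller's RNG state is untouched.
#' @return The noisy [binary_image()].
#' @export
#' @examples
#' obj <- render_object(object_spec("line", 0, length = 5))
#' noisy <- add_noise(obj$image, obj$mask, "background", p = 0.05, seed = 1)
#' lit_pixels(noisy) - lit_pixels(obj$image)  # exactly round(0.05 * 1024)
add_noise <- function(image, mask = NULL, kind = c("background", "whole_image"),
                      p, seed = NULL) {
  kind <- match.arg(kind)
  img <- as_binary_image(image)
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1)
  n <- round(p * nrow(img) * ncol(img))
  if (n == 0L) return(img)
  with_seed(seed, {
    if (kind == "background") {
      if (is.null(mask)) {
        stop("background noise requires the object-pixel mask", call. = FALSE)
      }
      stopifnot(all(dim(mask) == dim(img)))
      bg <- which(mask == 0L)
      if (n > length(bg)) {
        stop(sprintf("requested %d background noise pixels but only %d background pixels exist",
                     n, length(bg)), call. = FALSE)
      }
      img[bg[sample.int(length(bg), n)]] <- 1L
    } else {
      idx <- sample.int(nrow(img) * ncol(img), n)
      img[idx] <- 1L - img[idx]
    }
    binary_image(img)
  })
}

#' Sample a random ideal-object specification
#'
#' Draws shape and position uniformly among the feasible configurations:
#' either an exact lit-pixel count (`pixels`, a pixel-count stratum — the
#' factorisations length x width with strict length > width) or a minimum
#' count (`min_pixels`). `min_aspect` restricts to markedly elongated
#' objects (length / width >= min_aspect); position is uniform over all
#' placements keeping the object fully inside the frame. Uses the current
#' RNG stream.
#'
#' @param orientation One of 0, 45, 90, 135.
#' @param pixels Exact lit-pixel count, or `NULL`.
#' @param min_pixels Minimum lit-pixel count (used when `pixels` is `NULL`).
#' @param frame Image size `c(M, N)`.
#' @param min_aspect Minimum length/width ratio (1 = any strict `L > W`).
#' @param widths Candidate widths.
#' @return An [object_spec()].
#' @export
sample_object_spec <- function(orientation, pixels = NULL, min_pixels = 3L,
                               frame = c(32L, 32L), min_aspect = 1,
                               widths = 1:5) {
  frame <- as.integer(frame)
  fits <- function(L, W) all(object_bbox(orientation, L, W) <= frame)
  pairs <- list()
  if (!is.null(pixels)) {
    pixels <- as.integer(pixels)
    for (W in seq_len(floor(sqrt(pixels)))) {
      if (pixels %% W != 0L) next
      L <- pixels %/% W
      if (L > W && L / W >= min_aspect && fits(L, W)) {
        pairs[[base::length(pairs) + 1L]] <- c(L, W)
      }
    }
    if (base::length(pairs) == 0L) {
      stop(sprintf("no feasible shape with exactly %d lit pixels at %s°",
                   pixels, orientation), call. = FALSE)
    }
  } else {
    for (W in as.integer(widths)) {
      Lmin <- max(W + 1L, ceiling(min_pixels / W), ceiling(min_aspect * W))
      if (Lmin > max(frame)) next
      Lmax <- Lmin - 1L
      for (L in Lmin:max(frame)) {
        if (fits(L, W)) Lmax <- L else break
      }
      if (Lmax >= Lmin) {
        for (L in Lmin:Lmax) pairs[[base::length(pairs) + 1L]] <- c(L, W)
      }
    }
    if (base::length(pairs) == 0L) {
      stop(sprintf("no feasible shape with >= %d lit pixels at %s°",
                   min_pixels, orientation), call. = FALSE)
    }
  }
  lw <- pairs[[sample.int(base::length(pairs), 1L)]]
  bbox <- object_bbox(orientation, lw[1L], lw[2L])
  pos <- c(sample.int(frame[1L] - bbox[1L] + 1L, 1L),
           sample.int(frame[2L] - bbox[2L] + 1L, 1L))
  object_spec(family = if (lw[2L] == 1L) "line" else "bar",
              orientation = orientation, length = lw[1L], width = lw[2L],
              position = pos, frame = frame)
}

#' Build a labelled dataset of generated binary images
#'
#' Generates `n_per_class` images per orientation class, each an ideal
#' object of random feasible shape and position, optionally corrupted by
#' noise. The entire construction is driven by `seed` (each item also
#' records its own derived noise seed), so the same configuration and seed
#' reproduce the dataset bit-exactly.
#'
#' @param n_per_class Images per orientation class.
#' @param orientations Orientation classes to include.
#' @param pixels Exact lit-pixel count per object (a stratum), or `NULL`.
#' @param min_pixels Minimum lit-pixel count (when `pixels` is `NULL`).
#' @param frame Image size `c(M, N)`.
#' @param min_aspect Minimum length/width elongation of the objects.
#' @param widths Candidate object widths.
#' @param noise_kind `NULL` (clean), `"background"` or `"whole_image"`.
#' @param noise_p Noise proportion.
#' @param seed Master seed.
#' @return An object of class `avs_dataset`: a list with `items` (each
#'   holding `image`, `label`, `spec`, `mask`, `noise`) and `config`
#'   (provenance: every generation parameter plus the master seed).
#' @export
#' @examples
#' ds <- build_dataset(n_per_class = 2, pixels = 3, seed = 1)
#' length(ds$items)
build_dataset <- function(n_per_class = 10L,
                          orientations = c(0L, 45L, 90L, 135L),
                          pixels = NULL, min_pixels = 3L,
                          frame = c(32L, 32L), min_aspect = 1,
                          widths = 1:5,
                          noise_kind = NULL, noise_p = 0, seed = 1L) {
  stopifnot(n_per_class >= 0L)
  config <- list(n_per_class = n_per_class, orientations = orientations,
                 pixels = pixels, min_pixels = min_pixels, frame = frame,
                 min_aspect = min_aspect, widths = widths,
                 noise_kind = noise_kind, noise_p = noise_p, seed = seed)
  items <- with_seed(seed, {
    out <- vector("list", n_per_class * length(orientations))
    i <- 0L
    for (o in orientations) {
      for (k in seq_len(n_per_class)) {
        spec <- sample_object_spec(o, pixels = pixels,
                                   min_pixels = min_pixels, frame = frame,
                                   min_aspect = min_aspect, widths = widths)
        ro <- render_object(spec)
        noise <- NULL
        img <- ro$image
        # the per-item seed is drawn unconditionally so that clean and noisy
        # builds from the same master seed share identical object geometry
        noise_seed <- sample.int(.Machine$integer.max - 1L, 1L)
        if (!is.null(noise_kind) && noise_p > 0) {
          img <- add_noise(img, ro$mask, noise_kind, noise_p,
                           seed = noise_seed)
          noise <- list(kind = noise_kind, p = noise_p, seed = noise_seed)
        }
        i <- i + 1L
        out[[i]] <- list(image = img, label = as.integer(o), spec = spec,
                         mask = ro$mask, noise = noise)
      }
    }
    out
  })
  structure(list(items = items, config = config), class = "avs_dataset")
}

#' @export
print.avs_dataset <- function(x, ...) {
  n <- length(x$items)
  labels <- vapply(x$items, `[[`, integer(1L), "label")
  cat(sprintf("<avs_dataset: %d images (%s)>\n", n,
              paste(sprintf("%d x %d°", table(labels),
                            as.integer(names(table(labels)))),
                    collapse = ", ")))
  cfg <- x$config
  cat(sprintf("  frame %d x %d, %s, noise: %s, seed %s\n",
              cfg$frame[1L], cfg$frame[2L],
              if (!is.null(cfg$pixels)) sprintf("exactly %d lit pixels", cfg$pixels)
              else sprintf(">= %d lit pixels", cfg$min_pixels),
              if (is.null(cfg$noise_kind) || cfg$noise_p == 0) "none"
              else sprintf("%s p = %g", cfg$noise_kind, cfg$noise_p),
              format(cfg$seed)))
  invisible(x)
}

#' Grow an object step by step along one axis
#'
#' Reproduces the elongation-morph experiments: starting from an object
#' (possibly a square), the extent along the given axis grows by `by`
#' pixels per step, with the bounding box's top-left corner held fixed.
#' For 0/90-degree rectangles the axis may differ from the object's current
#' long axis (growing a 3x18 rectangle along 90 degrees turns it back into
#' a square); diagonal bars grow along their own orientation only.
#'
#' @param start An [object_spec()] (use `allow_square = TRUE` to start from
#'   a square).
#' @param axis Growth direction: 0, 45, 90 or 135 degrees.
#' @param steps Number of growth steps (the sequence has `steps + 1` images).
#' @param by Pixels added per step.
#' @return An object of class `morph_sequence`: lists `images` and `specs`
#'   in growth order.
#' @export
#' @examples
#' sq <- object_spec("rectangle", 0, length = 3, width = 3,
#'                   allow_square = TRUE)
#' ms <- morph_sequence(sq, axis = 0, steps = 15)   # 3x3 -> 3x18
#' length(ms$images)
morph_sequence <- function(start, axis, steps, by = 1L) {
  stopifnot(inherits(start, "object_spec"), steps >= 0L, by >= 1L)
  axis <- as.integer(as_orientation(axis))
  diagonal <- start$orientation %in% c(45L, 135L)
  if (diagonal && axis != start$orientation) {
    stop("diagonal bars can only grow along their own orientation",
         call. = FALSE)
  }
  if (!diagonal && !axis %in% c(0L, 90L)) {
    stop("axis-aligned objects grow along 0 or 90 degrees", call. = FALSE)
  }
  # Track axis-aligned objects as rows x cols so growth can cross the square.
  if (!diagonal) {
    hw <- object_bbox(start$orientation, start$length, start$width)
  }
  images <- vector("list", steps + 1L)
  specs <- vector("list", steps + 1L)
  for (s in 0:steps) {
    spec_s <- if (diagonal) {
      object_spec(start$family, start$orientation,
                  length = start$length + s * by, width = start$width,
                  position = start$position, frame = start$frame,
                  allow_square = TRUE)
    } else {
      h <- hw[1L] + if (axis == 90L) s * by else 0L
      w <- hw[2L] + if (axis == 0L) s * by else 0L
      if (w >= h) {
        object_spec(start$family, 0L, length = w, width = h,
                    position = start$position, frame = start$frame,
                    allow_square = TRUE)
      } else {
        object_spec(start$family, 90L, length = h, width = w,
                    position = start$position, frame = start$frame,
                    allow_square = TRUE)
      }
    }
    specs[[s + 1L]] <- spec_s
    images[[s + 1L]] <- render_object(spec_s)$image
  }
  structure(list(images = images, specs = specs, axis = axis, by = by),
            class = "morph_sequence")
}

#' Render a randomized elongated blob
#'
#' A procedural stand-in for natural elongated objects: a rasterized
#' ellipse with randomly jittered size and elongation and random position,
#' whose principal axis lies along the requested orientation class. The
#' object is connected and labelled by construction.
#'
#' @param elongation Minimum major/minor axis ratio (>= 2, so that the
#'   orientation is definite).
#' @param orientation One of 0, 45, 90, 135.
#' @param size Major-axis length in pixels (>= 12).
#' @param seed Optional seed for a local RNG.
#' @param frame Image size `c(M, N)`.
#' @return A list with `image` (a [binary_image()]), `mask`, and
#'   `orientation` (the ground-truth label).
#' @export
#' @examples
#' b <- render_blob(elongation = 3, orientation = 90, size = 14, seed = 1)
#' detect_orientation(b$image)$label
render_blob <- function(elongation = 2, orientation, size = 12L, seed = NULL,
                        frame = c(32L, 32L)) {
  stopifnot(elongation >= 2, size >= 12)
  orientation <- as.integer(as_orientation(orientation))
  frame <- as.integer(frame)
  with_seed(seed, {
    a <- size / 2
    e <- elongation * stats::runif(1L, 1, 1.25)
    b <- max(a / e, 1)
    theta <- orientation * pi / 180
    # Half-extents of the rotated ellipse along rows/cols (y points up, so
    # image rows use -y; extents are symmetric under the sign).
    half_c <- sqrt((a * cos(theta))^2 + (b * sin(theta))^2)
    half_r <- sqrt((a * sin(theta))^2 + (b * cos(theta))^2)
    if (2 * half_r + 1 > frame[1L] || 2 * half_c + 1 > frame[2L]) {
      stop("blob of this size does not fit the frame", call. = FALSE)
    }
    rc <- stats::runif(1L, 1 + half_r, frame[1L] - half_r)
    cc <- stats::runif(1L, 1 + half_c, frame[2L] - half_c)
    rows <- matrix(seq_len(frame[1L]), frame[1L], frame[2L])
    cols <- matrix(seq_len(frame[2L]), frame[1L], frame[2L], byrow = TRUE)
    dx <- cols - cc
    dy <- -(rows - rc)   # y increases upward in the angle convention
    u <- dx * cos(theta) + dy * sin(theta)
    v <- -dx * sin(theta) + dy * cos(theta)
    mask <- matrix(as.integer((u / a)^2 + (v / b)^2 <= 1),
                   frame[1L], frame[2L])
    if (sum(mask) < 3L) {
      stop("degenerate blob: fewer than 3 lit pixels", call. = FALSE)
    }
    list(image = binary_image(mask), mask = mask, orientation = orientation)
  })
}
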