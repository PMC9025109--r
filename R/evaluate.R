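# Evaluation harness: accuracy tables, noise sweeps, spike-rate curves.

#' Evaluate the system on a labelled dataset
#'
#' Runs orientation detection on every image and scores it against the
#' ground-truth label. A classification is correct iff the detection has a
#' unique winner equal to the truth; ambiguous outcomes (ties or no firing
#' cell) are tallied in their own confusion-matrix column and scored
#' incorrect.
#'
#' @param dataset An `avs_dataset` from [build_dataset()] or
#'   [read_dataset_dir()], or a plain list of `list(image =, label =)` items.
#' @param model An [avs()] model.
#' @return An object of class `avs_eval` with `overall_accuracy`,
#'   `per_class_accuracy`, `confusion` (true orientation x predicted
#'   orientation plus an `"ambiguous"` column), `n_items`, and `config`
#'   (the dataset's provenance, when present).
#' @export
#' @examples
#' ds <- build_dataset(n_per_class = 3, pixels = 8, seed = 7)
#' evaluate_dataset(ds)
evaluate_dataset <- function(dataset, model = avs()) {
  items <- if (inherits(dataset, "avs_dataset")) dataset$items else dataset
  if (length(items) == 0L) {
    stop("cannot evaluate an empty dataset", call. = FALSE)
  }
  classes <- as.character(.ORIENTATIONS)
  confusion <- matrix(0L, nrow = 4L, ncol = 5L,
                      dimnames = list(true = classes,
                                      predicted = c(classes, "ambiguous")))
  for (item in items) {
    det <- detect_orientation(item$image, model)
    truth <- as.character(item$label)
    pred <- if (det$is_ambiguous) "ambiguous" else as.character(det$label)
    confusion[truth, pred] <- confusion[truth, pred] + 1L
  }
  row_n <- rowSums(confusion)
  per_class <- ifelse(row_n > 0, diag(confusion[, classes]) / row_n, NA_real_)
  names(per_class) <- classes
  overall <- sum(diag(confusion[, classes])) / sum(confusion)
  structure(list(overall_accuracy = overall,
                 per_class_accuracy = per_class,
                 confusion = confusion,
                 n_items = sum(confusion),
                 config = if (inherits(dataset, "avs_dataset")) dataset$config),
            class = "avs_eval")
}

#' @export
print.avs_eval <- function(x, ...) {
  cat(sprintf("AVS evaluation on %d images\n", x$n_items))
  cat(sprintf("  overall accuracy : %.3f\n", x$overall_accuracy))
  cat("  per class        :",
      paste(sprintf("%s° %.3f", names(x$per_class_accuracy),
                    x$per_class_accuracy), collapse = "  "), "\n")
  cat("  confusion matrix (true x predicted):\n")
  print(x$confusion)
  invisible(x)
}

#' Accuracy under increasing noise
#'
#' Re-noises a clean base dataset at each requested proportion and noise
#' regime, evaluates each corrupted copy, and tabulates accuracy against
#' the noise level. Noise placement is derived deterministically from
#' `seed`, independently per (kind, proportion) cell; `p = 0` rows evaluate
#' the clean base itself.
#'
#' @param dataset A clean `avs_dataset` whose items carry object masks.
#' @param kinds Noise regimes to sweep.
#' @param proportions Sorted noise proportions in \[0, 1\].
#' @param model An [avs()] model.
#' @param seed Master seed for noise placement.
#' @return A data frame of class `avs_noise_sweep` with columns `kind`,
#'   `p`, `accuracy`, `correct`, `n`.
#' @export
#' @examples
#' ds <- build_dataset(n_per_class = 5, min_pixels = 32, min_aspect = 3,
#'                     seed = 2)
#' noise_sweep(ds, proportions = c(0, 0.05), seed = 3)
noise_sweep <- function(dataset, kinds = c("background", "whole_image"),
                        proportions, model = avs(), seed = 1L) {
  stopifnot(inherits(dataset, "avs_dataset"),
            all(proportions >= 0), all(proportions <= 1),
            !is.unsorted(proportions))
  kinds <- match.arg(kinds, several.ok = TRUE)
  rows <- list()
  for (ki in seq_along(kinds)) {
    for (p in proportions) {
      ev <- if (p == 0) {
        evaluate_dataset(dataset, model)
      } else {
        cell_seed <- (seed + 7919L * ki + round(100000 * p)) %%
          (.Machine$integer.max - 1L)
        noisy <- with_seed(cell_seed, lapply(dataset$items, function(item) {
          s <- sample.int(.Machine$integer.max - 1L, 1L)
          list(image = add_noise(item$image, item$mask, kinds[ki], p,
                                 seed = s),
               label = item$label)
        }))
        evaluate_dataset(noisy, model)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        kind = kinds[ki], p = p, accuracy = ev$overall_accuracy,
        correct = sum(diag(ev$confusion[, 1:4])), n = ev$n_items)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("avs_noise_sweep", "data.frame")
  out
}

#' @export
print.avs_noise_sweep <- function(x, ...) {
  cat("Recognition accuracy under noise:\n")
  wide <- stats::reshape(as.data.frame(x)[, c("kind", "p", "accuracy")],
                         idvar = "kind", timevar = "p", direction = "wide")
  names(wide) <- sub("^accuracy\\.", "p = ", names(wide))
  wide[-1L] <- lapply(wide[-1L], function(v) sprintf("%.3f", v))
  print(wide, row.names = FALSE)
  invisible(x)
}

#' Spike rates of one object rendered at each orientation
#'
#' Renders the same shape at 0, 45, 90 and 135 degrees (centred in the
#' frame) and records all four complex-cell spike rates per rendering —
#' the orientation-tuning experiment.
#'
#' @param length,width Shape of the object (pixels).
#' @param frame Image size `c(M, N)`.
#' @param model An [avs()] model.
#' @param allow_square Permit `length == width`.
#' @return A `spike_rate_curve`: `x` (the rendered orientations) and `z`
#'   (4 x 4 matrix of spike rates, one row per rendering, columns named by
#'   responding complex cell).
#' @export
#' @examples
#' orientation_sweep(length = 5)
orientation_sweep <- function(length, width = 1L, frame = c(32L, 32L),
                              model = avs(), allow_square = FALSE) {
  z <- t(vapply(.ORIENTATIONS, function(o) {
    img <- render_object(object_spec("bar", o, length = length, width = width,
                                     frame = frame,
                                     allow_square = allow_square))$image
    as.integer(complex_response(img, model))
  }, integer(4L)))
  dimnames(z) <- list(rendered = as.character(.ORIENTATIONS),
                      cell = as.character(.ORIENTATIONS))
  structure(list(x = .ORIENTATIONS, z = z), class = "spike_rate_curve")
}

#' Spike-rate curves along a morph sequence
#'
#' Evaluates the four complex-cell spike rates for every image of an
#' elongation-morph sequence, in sequence order.
#'
#' @param sequence A `morph_sequence` from [morph_sequence()], or a list of
#'   binary images.
#' @param model An [avs()] model.
#' @return A `spike_rate_curve`: `x` (step index) and `z` (steps x 4 matrix).
#' @export
#' @examples
#' sq <- object_spec("rectangle", 0, 3, 3, allow_square = TRUE)
#' morph_curves(morph_sequence(sq, axis = 0, steps = 15))
morph_curves <- function(sequence, model = avs()) {
  images <- if (inherits(sequence, "morph_sequence")) sequence$images
            else sequence
  if (length(images) == 0L) stop("empty sequence", call. = FALSE)
  z <- t(vapply(images, function(img) as.integer(complex_response(img, model)),
                integer(4L)))
  colnames(z) <- as.character(.ORIENTATIONS)
  structure(list(x = seq_along(images), z = z), class = "spike_rate_curve")
}

#' @export
print.spike_rate_curve <- function(x, ...) {
  cat("Complex-cell spike rates:\n")
  print(cbind(x = x$x, x$z))
  invisible(x)
}

#' @export
plot.spike_rate_curve <- function(x, xlab = "step", ylab = "spike rate",
                                  ...) {
  graphics::matplot(x$x, x$z, type = "b", pch = 1:4, lty = 1,
                    col = grDevices::hcl.colors(4L, "Dark 2"),
                    xlab = xlab, ylab = ylab, ...)
  graphics::legend("topleft", legend = paste0(colnames(x$z), "°"),
                   col = grDevices::hcl.colors(4L, "Dark 2"), pch = 1:4,
                   lty = 1, bty = "n")
  invisible(x)
}
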