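# Image and dataset I/O: PGM (P2/P5), PNG (grayscale), text grids, dataset
# directories with CSV manifests.
#
# Text-grid dialect: one image row per line, each a string of '0'/'1'
# characters (optional whitespace between them); blank lines ignored.

image_format_of <- function(path, format = NULL) {
  if (!is.null(format)) return(match.arg(format, c("pgm", "png", "text")))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         pgm = "pgm",
         png = "png",
         txt = , grid = , text = "text",
         stop("cannot infer image format from extension '", ext,
              "' (use pgm, png, txt)", call. = FALSE))
}

#' Read a binary image from file
#'
#' Supports PGM (both ASCII `P2` and binary `P5`), grayscale PNG, and the
#' plain text-grid format (lines of 0/1 characters). Any pixel value
#' greater than 0 maps to lit (1).
#'
#' @param path File path.
#' @param format `"pgm"`, `"png"` or `"text"`; inferred from the extension
#'   when `NULL`.
#' @return A [binary_image()].
#' @export
read_binary_image <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  switch(image_format_of(path, format),
         pgm = read_pgm(path),
         png = read_png_binary(path),
         text = read_text_grid(path))
}

#' Write a binary image to file
#'
#' Inverse of [read_binary_image()]; lit pixels are written as the format's
#' maximum value (PGM/PNG) or the character `1` (text grid). Round-trips
#' bit-exactly.
#'
#' @param image A [binary_image()] or 0/1 matrix.
#' @param path Destination path.
#' @param format `"pgm"` (ASCII `P2`), `"png"` or `"text"`; inferred from
#'   the extension when `NULL`.
#' @return `path`, invisibly.
#' @export
write_binary_image <- function(image, path, format = NULL) {
  img <- as_binary_image(image)
  switch(image_format_of(path, format),
         pgm = write_pgm(img, path),
         png = png::writePNG(unclass(img) * 1.0, path),
         text = writeLines(apply(unclass(img), 1L, paste, collapse = ""),
                           path))
  invisible(path)
}

read_text_grid <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- gsub("[[:space:]]", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty text grid: ", path, call. = FALSE)
  if (length(unique(nchar(lines))) != 1L) {
    stop("ragged text grid (rows of unequal width): ", path, call. = FALSE)
  }
  chars <- strsplit(lines, "")
  if (!all(unlist(chars) %in% c("0", "1"))) {
    stop("text grid may only contain 0 and 1: ", path, call. = FALSE)
  }
  binary_image(do.call(rbind, lapply(chars, as.integer)))
}

read_png_binary <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]  # grayscale expected; take one channel
  binary_image(matrix(as.integer(x > 0), nrow(x), ncol(x)))
}

# Minimal PGM reader: handles P2 (ASCII) and P5 (binary), '#' comments.
read_pgm <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  is_space <- function(b) b %in% as.raw(c(0x20, 0x09, 0x0a, 0x0d, 0x0b, 0x0c))
  pos <- 1L
  next_token <- function() {
    repeat {
      while (pos <= length(raw) && is_space(raw[pos])) pos <<- pos + 1L
      if (pos <= length(raw) && raw[pos] == as.raw(0x23)) {  # '#' comment
        while (pos <= length(raw) && raw[pos] != as.raw(0x0a)) pos <<- pos + 1L
      } else break
    }
    start <- pos
    while (pos <= length(raw) && !is_space(raw[pos])) pos <<- pos + 1L
    if (start > length(raw)) stop("truncated PGM: ", path, call. = FALSE)
    rawToChar(raw[start:(pos - 1L)])
  }
  magic <- next_token()
  if (!magic %in% c("P2", "P5")) {
    stop("not a PGM file (magic '", magic, "'): ", path, call. = FALSE)
  }
  width <- as.integer(next_token())
  height <- as.integer(next_token())
  maxval <- as.integer(next_token())
  if (anyNA(c(width, height, maxval)) || width < 1L || height < 1L) {
    stop("corrupt PGM header: ", path, call. = FALSE)
  }
  vals <- if (magic == "P2") {
    rest <- rawToChar(raw[pos:length(raw)])
    v <- suppressWarnings(as.integer(strsplit(trimws(rest), "[[:space:]]+")[[1]]))
    if (anyNA(v)) stop("corrupt PGM pixel data: ", path, call. = FALSE)
    v
  } else {
    pos <- pos + 1L  # single whitespace after maxval
    if (maxval > 255L) stop("16-bit P5 PGM not supported: ", path, call. = FALSE)
    if (length(raw) - pos + 1L < width * height) {
      stop("truncated P5 pixel data: ", path, call. = FALSE)
    }
    as.integer(raw[pos:(pos + width * height - 1L)])
  }
  if (length(vals) < width * height) {
    stop("PGM pixel data shorter than header promises: ", path, call. = FALSE)
  }
  binary_image(matrix(as.integer(vals[seq_len(width * height)] > 0L),
                      nrow = height, ncol = width, byrow = TRUE))
}

write_pgm <- function(image, path) {
  m <- unclass(image)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), "1"), con)
  writeLines(apply(m, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' Write a labelled dataset to a directory
#'
#' Exports every image plus a `manifest.csv` (filename, orientation label,
#' family, lit-pixel count, noise kind/proportion/seed) and a
#' `config.json` echoing the generation provenance.
#'
#' @param dataset An `avs_dataset`.
#' @param dir Output directory (created if missing).
#' @param format Image format, `"pgm"`, `"png"` or `"text"`.
#' @return `dir`, invisibly.
#' @export
write_dataset_dir <- function(dataset, dir, format = "pgm") {
  stopifnot(inherits(dataset, "avs_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- switch(format, pgm = "pgm", png = "png", text = "txt")
  items <- dataset$items
  manifest <- data.frame(
    file = sprintf("img%05d.%s", seq_along(items), ext),
    orientation = vapply(items, `[[`, integer(1L), "label"),
    family = vapply(items, function(it)
      if (is.null(it$spec)) NA_character_ else it$spec$family, character(1L)),
    lit_pixels = vapply(items, function(it) lit_pixels(it$image), integer(1L)),
    noise_kind = vapply(items, function(it)
      if (is.null(it$noise)) "none" else it$noise$kind, character(1L)),
    noise_p = vapply(items, function(it)
      if (is.null(it$noise)) 0 else it$noise$p, numeric(1L)),
    noise_seed = vapply(items, function(it)
      if (is.null(it$noise)) NA_integer_ else it$noise$seed, integer(1L)))
  for (i in seq_along(items)) {
    write_binary_image(items[[i]]$image, file.path(dir, manifest$file[i]),
                       format)
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  if (!is.null(dataset$config)) {
    jsonlite::write_json(dataset$config, file.path(dir, "config.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
  }
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset_dir()]
#'
#' @param dir Directory containing `manifest.csv` and the image files.
#' @return An `avs_dataset` whose items carry `image` and `label` (object
#'   specs and masks are not reconstructed from disk).
#' @export
read_dataset_dir <- function(dir) {
  manifest_path <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest_path)) {
    stop("no manifest.csv in ", dir, call. = FALSE)
  }
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  items <- lapply(seq_len(nrow(manifest)), function(i) {
    list(image = read_binary_image(file.path(dir, manifest$file[i])),
         label = as.integer(manifest$orientation[i]),
         spec = NULL, mask = NULL,
         noise = if (manifest$noise_kind[i] == "none") NULL else
           list(kind = manifest$noise_kind[i], p = manifest$noise_p[i],
                seed = manifest$noise_seed[i]))
  })
  config_path <- file.path(dir, "config.json")
  config <- if (file.exists(config_path)) {
    jsonlite::read_json(config_path, simplifyVector = TRUE)
  }
  structure(list(items = items, config = config), class = "avs_dataset")
}
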