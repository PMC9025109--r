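# Independent oracles, written directly from the model definition and kept
# free of the package's scanning code paths.

# ON-region offsets restated literally (row down, col right).
oracle_offsets <- list(
  "0"   = list(c(0, -1), c(0, 0), c(0, 1)),
  "45"  = list(c(-1, 1), c(0, 0), c(1, -1)),
  "90"  = list(c(-1, 0), c(0, 0), c(1, 0)),
  "135" = list(c(-1, -1), c(0, 0), c(1, 1))
)

# Brute-force re-evaluation of the threshold unit at every centre.
oracle_maps <- function(img, theta = 2.5, weights = c(1, 1, 1)) {
  img <- unclass(img)
  M <- nrow(img); N <- ncol(img)
  out <- list()
  for (o in names(oracle_offsets)) {
    m <- matrix(0L, M, N)
    for (r in seq_len(M)) {
      for (c in seq_len(N)) {
        s <- 0
        for (k in 1:3) {
          rr <- r + oracle_offsets[[o]][[k]][1]
          cc <- c + oracle_offsets[[o]][[k]][2]
          x <- if (rr >= 1 && rr <= M && cc >= 1 && cc <= N) img[rr, cc] else 0
          s <- s + weights[k] * x
        }
        m[r, c] <- as.integer(s >= theta)
      }
    }
    out[[o]] <- m
  }
  out
}

oracle_z <- function(img, ...) {
  vapply(oracle_maps(img, ...), sum, numeric(1))
}

# Closed-form complex response of a fully interior filled H-rows x W-cols
# axis-aligned rectangle.
rect_closed_form <- function(H, W) {
  c("0" = H * max(W - 2, 0), "45" = max(W - 2, 0) * max(H - 2, 0),
    "90" = W * max(H - 2, 0), "135" = max(W - 2, 0) * max(H - 2, 0))
}

# A frame with a filled rectangle whose top-left corner is at (r0, c0).
rect_image <- function(H, W, frame = c(32, 32), r0 = 2, c0 = 2) {
  img <- matrix(0L, frame[1], frame[2])
  img[r0:(r0 + H - 1), c0:(c0 + W - 1)] <- 1L
  img
}

random_binary_matrix <- function(M, N, density = 0.3) {
  matrix(as.integer(stats::runif(M * N) < density), M, N)
}
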