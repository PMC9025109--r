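# Simple cells, complex cells, whole-image scanning, orientation decision.

test_that("a simple cell fires iff its full ON triple is lit", {
  img <- matrix(0L, 5, 5)
  img[2, 1:3] <- 1L  # 0-based (2,1)..(2,3) of the worked example, 1-based here

  expect_identical(simple_cell_response(img, c(2, 2), 0), 1L)
  img2 <- img; img2[2, 1] <- 0L  # only two ON pixels lit: sum 2 < 2.5
  expect_identical(simple_cell_response(img2, c(2, 2), 0), 0L)
  expect_identical(simple_cell_response(matrix(0L, 4, 4), c(2, 2), 45), 0L)

  # OFF-region stimulation never changes the response
  img3 <- img; img3[1, 1:3] <- 1L; img3[3, 1:3] <- 1L
  expect_identical(simple_cell_response(img3, c(2, 2), 0), 1L)
})

test_that("receptive-field pixels beyond the image count as no stimulation", {
  img <- matrix(0L, 4, 6)
  img[1, 2:4] <- 1L  # 3-pixel line in the top row
  expect_identical(simple_cell_response(img, c(1, 3), 0), 1L)
  expect_identical(simple_cell_response(img, c(1, 3), 90), 0L)  # (-1,0) out
  expect_identical(simple_cell_response(img, c(1, 3), 45), 0L)
  expect_identical(simple_cell_response(img, c(1, 3), 135), 0L)
})

test_that("invalid centres and orientations are rejected", {
  img <- matrix(0L, 3, 3)
  expect_error(simple_cell_response(img, c(0, 1), 0), "outside")
  expect_error(simple_cell_response(img, c(2, 4), 0), "outside")
  expect_error(simple_cell_response(img, c(2, 2), 30), "orientation")
})

test_that("scanning evaluates one cell per pixel per orientation", {
  img <- matrix(0L, 7, 9)
  img[4, 3:7] <- 1L  # interior 1x5 horizontal line
  maps <- scan_simple_cells(img)
  expect_named(maps, c("0", "45", "90", "135"))
  expect_identical(sum(maps[["0"]]), 3L)
  expect_identical(which(maps[["0"]] == 1L), which(row(img) == 4 & col(img) %in% 4:6))
  for (o in c("45", "90", "135")) expect_identical(sum(maps[[o]]), 0L)

  zero <- scan_simple_cells(matrix(0L, 32, 32))
  expect_true(all(vapply(zero, sum, integer(1)) == 0L))

  # all-ones 3x3: the 0/90 triples stay in bounds along the middle column/row
  # (3 firing centres each); only the diagonal triples need the centre pixel
  ones <- scan_simple_cells(matrix(1L, 3, 3))
  expect_identical(vapply(ones, sum, integer(1)),
                   c("0" = 3L, "45" = 1L, "90" = 3L, "135" = 1L))
  for (o in names(ones)) expect_identical(ones[[o]][2, 2], 1L)
  expect_identical(unclass(scan_simple_cells(matrix(1L, 3, 3))[["45"]]),
                   oracle_maps(matrix(1L, 3, 3))[["45"]])
  # total cell count: M*N entries per orientation map, four maps
  expect_identical(sum(lengths(ones)), 3L * 3L * 4L)
})

test_that("an activated centre is always itself lit", {
  set.seed(11)
  for (i in 1:10) {
    img <- random_binary_matrix(9, 9, density = stats::runif(1, 0.2, 0.8))
    maps <- scan_simple_cells(img)
    for (o in names(maps)) {
      expect_true(all(img[maps[[o]] == 1L] == 1L))
    }
  }
})

test_that("complex cells sum their activation maps and validate input", {
  img <- rect_image(5, 5)  # filled interior 5x5 square in 32x32
  z <- complex_response(img)
  expect_identical(as.integer(z), c(15L, 9L, 15L, 9L))
  expect_named(z, c("0", "45", "90", "135"))

  z2 <- complex_response(rect_image(3, 18))
  expect_identical(as.integer(z2), c(48L, 16L, 18L, 16L))

  expect_identical(as.integer(complex_response(matrix(0L, 6, 6))), rep(0L, 4))

  maps <- scan_simple_cells(img)
  expect_identical(complex_response(maps), z)
  bad <- maps; bad[["90"]] <- bad[["90"]][1:10, 1:10]
  expect_error(complex_response(bad), "identical dimensions")
  expect_error(complex_response(unname(unclass(maps))), "named")
})

test_that("winner-take-all decision reports ties and silence as ambiguous", {
  line <- matrix(0L, 9, 9); line[5, 3:7] <- 1L
  d <- detect_orientation(line)
  expect_identical(d$label, 0L)
  expect_false(d$is_ambiguous)
  expect_identical(as.integer(d$z), c(3L, 0L, 0L, 0L))

  square <- detect_orientation(rect_image(5, 5))
  expect_true(square$is_ambiguous)
  expect_identical(square$winners, c(0L, 90L))
  expect_identical(square$label, NA_integer_)

  silent <- detect_orientation(matrix(0L, 8, 8))
  expect_true(silent$is_ambiguous)
  expect_length(silent$winners, 0)
})

test_that("predict methods expose detection, label and response views", {
  m <- avs()
  line <- matrix(0L, 9, 9); line[3:7, 5] <- 1L
  expect_identical(predict(m, line, type = "label"), 90L)
  expect_s3_class(predict(m, line), "avs_detection")
  expect_identical(predict(m, line, type = "response"),
                   complex_response(line))
  imgs <- list(line, t(line))
  expect_identical(predict(m, imgs, type = "label"), c(90L, 0L))
})

test_that("spike records replay the scan in row-major order", {
  img <- matrix(0L, 3, 7); img[2, 2:6] <- 1L
  rec <- spike_record(img)
  expect_identical(nrow(rec[["0"]]), 3L)
  expect_identical(rec[["0"]]$col, 3:5)
  expect_true(all(vapply(rec[c("45", "90", "135")], nrow, integer(1)) == 0L))

  empty <- spike_record(matrix(0L, 5, 5))
  expect_true(all(vapply(empty, nrow, integer(1)) == 0L))

  # record length is definitionally the complex cell's spike rate;
  # events are sorted row-major
  set.seed(21)
  for (i in 1:5) {
    img <- random_binary_matrix(10, 12, 0.5)
    rec <- spike_record(img)
    z <- complex_response(img)
    for (o in names(rec)) {
      expect_identical(nrow(rec[[o]]), as.integer(z[[o]]))
      key <- rec[[o]]$row * 1000L + rec[[o]]$col
      expect_false(is.unsorted(key))
    }
  }
})

test_that("scan agrees with brute-force re-evaluation on random images", {
  set.seed(101)
  for (i in 1:20) {
    M <- sample(1:12, 1); N <- sample(1:12, 1)
    img <- random_binary_matrix(M, N, stats::runif(1, 0.1, 0.9))
    maps <- scan_simple_cells(img)
    ref <- oracle_maps(img)
    for (o in names(ref)) expect_identical(unclass(maps[[o]]), ref[[o]])
  }
})

test_that("non-default threshold and weights flow through the scan", {
  # theta = 1.5 with unit weights: any two ON pixels suffice
  img <- matrix(0L, 5, 5); img[3, 3:4] <- 1L
  m <- avs(theta = 1.5)
  expect_identical(simple_cell_response(img, c(3, 3), 0, m), 1L)
  expect_identical(sum(scan_simple_cells(img, m)[["0"]]), 2L)
  expect_identical(as.integer(complex_response(img, m))[1], 2L)
  # centre weight alone can clear a low threshold
  m2 <- avs(theta = 0.5, weights = c(0, 1, 0))
  expect_identical(as.integer(complex_response(img, m2)),
                   rep(2L, 4))
  expect_error(avs(weights = c(1, -1, 1)))
})

test_that("rectangle responses follow the closed form for all 3..12 sizes", {
  for (H in 3:12) {
    for (W in 3:12) {
      img <- rect_image(H, W, frame = c(14, 14))
      expect_identical(as.numeric(complex_response(img)),
                       as.numeric(rect_closed_form(H, W)),
                       info = sprintf("H=%d W=%d", H, W))
    }
  }
})

test_that("complex cells are translation invariant for interior objects", {
  set.seed(33)
  base <- render_object(object_spec("bar", 45, length = 6, width = 2,
                                    position = c(2, 2), frame = c(20, 20)))
  z0 <- complex_response(base$image)
  for (shift in list(c(5, 3), c(0, 9), c(11, 0), c(8, 8))) {
    moved <- render_object(object_spec("bar", 45, length = 6, width = 2,
                                       position = c(2, 2) + shift,
                                       frame = c(20, 20)))
    expect_identical(complex_response(moved$image), z0)
  }
})

test_that("90-degree rotation swaps 0<->90 and 45<->135 responses", {
  rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])
  set.seed(44)
  for (i in 1:10) {
    img <- random_binary_matrix(10, 10, 0.4)
    z <- complex_response(img)
    zr <- complex_response(rot90(img))
    expect_identical(zr[["0"]], z[["90"]])
    expect_identical(zr[["90"]], z[["0"]])
    expect_identical(zr[["45"]], z[["135"]])
    expect_identical(zr[["135"]], z[["45"]])
    # transposition swaps 0<->90 and fixes both diagonals
    zt <- complex_response(t(img))
    expect_identical(zt[["0"]], z[["90"]])
    expect_identical(zt[["90"]], z[["0"]])
    expect_identical(zt[["45"]], z[["45"]])
    expect_identical(zt[["135"]], z[["135"]])
  }
})

test_that("lighting a pixel never decreases any spike rate", {
  set.seed(55)
  for (i in 1:10) {
    img <- random_binary_matrix(8, 8, 0.3)
    z <- as.integer(complex_response(img))
    dark <- which(img == 0L)
    px <- dark[sample.int(length(dark), 1)]
    img[px] <- 1L
    expect_true(all(as.integer(complex_response(img)) >= z))
  }
})

test_that("spike rates are bounded by the lit-pixel count", {
  set.seed(66)
  for (i in 1:10) {
    img <- random_binary_matrix(9, 11, stats::runif(1, 0.1, 0.95))
    z <- as.integer(complex_response(img))
    expect_true(all(z <= sum(img)))
    expect_true(all(z <= length(img)))
  }
})

test_that("architecture counts scale as M x N x 4 simple cells", {
  a <- avs_architecture(c(32, 32))
  expect_identical(a$receptive_fields, 1024L)
  expect_identical(a$simple_cells, 4096L)
  expect_identical(a$complex_cells, 4L)
  expect_identical(a$max_spike_rate, 1024L)
  b <- avs_architecture(c(5, 7))
  expect_identical(b$simple_cells, 140L)
})

test_that("model object prints and exposes its parameters", {
  m <- avs()
  expect_identical(unname(coef(m)), c(1, 1, 1, 2.5))
  expect_output(print(m), "theta = 2.5")
  expect_output(print(summary(m, dim = c(32, 32))), "4096")
})
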