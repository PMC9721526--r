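test_that("a constant field has a single essential component bar", {
  b <- compute_barcode(matrix(1, 8, 8))
  expect_equal(nrow(b), 1L)
  expect_equal(b$dim, 0L)
  expect_equal(b$birth, 1)
  expect_equal(b$death, 0)
  expect_true(b$essential)
})

test_that("the ring field yields the expected component and loop bars", {
  b <- compute_barcode(ring_field_5x5())
  expect_equal(nrow(b), 2L)
  d0 <- b[b$dim == 0L, ]; d1 <- b[b$dim == 1L, ]
  expect_equal(c(d0$birth, d0$death), c(0.9, 0))
  expect_true(d0$essential)
  expect_equal(c(d1$birth, d1$death), c(0.9, 0.1))
  # the loop dies when the interior pixel (3, 3) enters the filtration
  expect_equal(d1$death_cell, 13L)
  expect_equal(as.numeric(ring_field_5x5()[d1$birth_cell]), 0.9)
})

test_that("compute_barcode agrees with the brute-force reduction", {
  for (i in 1:15) {
    f <- rand_distinct_field(c(sample(2:6, 1), sample(2:6, 1)), seed = i)
    expect_equal(bar_multiset(compute_barcode(f)),
                 bar_multiset(reference_barcode_bruteforce(f)))
  }
  for (i in 16:20) {
    f <- rand_distinct_field(c(3L, 3L, 3L), seed = i)
    expect_equal(bar_multiset(compute_barcode(f)),
                 bar_multiset(reference_barcode_bruteforce(f)))
  }
})

test_that("bars alive at a threshold count the Betti numbers of B(p)", {
  for (i in 1:8) {
    f <- rand_distinct_field(c(5L, 5L), seed = 100 + i)
    b <- compute_barcode(f)
    for (p in as.numeric(f)) {
      for (k in 0:1)
        expect_equal(bars_alive(b, p, k), betti_at_threshold(f, p, k))
    }
  }
})

test_that("monotone relabelling maps bars through g with fixed critical cells", {
  f <- rand_distinct_field(c(6L, 6L), seed = 5)
  g <- function(x) x^2             # strictly increasing on [0, 1]
  # bar ranks can change (lengths scale unevenly); identify bars by their
  # critical cells, which must be preserved exactly
  canon <- function(b) b[order(b$dim, b$birth_cell), ]
  b1 <- canon(compute_barcode(f))
  b2 <- canon(compute_barcode(g(f)))
  expect_equal(b2$birth, g(b1$birth))
  # essential deaths are pinned at 0; finite deaths transform
  fin <- !b1$essential
  expect_equal(b2$death[fin], g(b1$death[fin]))
  expect_equal(b2$birth_cell, b1$birth_cell)
  expect_equal(b2$death_cell, b1$death_cell)
})

test_that("barcodes are bit-identical across repeated runs", {
  f <- rand_distinct_field(c(7L, 7L), seed = 6)
  expect_identical(compute_barcode(f), compute_barcode(f))
  # ties broken deterministically too
  ft <- round(f * 4) / 4
  expect_identical(compute_barcode(ft), compute_barcode(ft))
})

test_that("vertex connectivity joins diagonally touching pixels", {
  dg <- matrix(0, 3, 3); dg[1, 1] <- 1; dg[2, 2] <- 1
  expect_equal(betti_at_threshold(dg, 0.5, 0), 1L)
  b <- compute_barcode(dg)
  expect_equal(sum(b$dim == 0L), 1L)
})

test_that("a hollow voxel shell has one cavity", {
  sh <- array(0, c(4, 4, 4)); sh[1:3, 1:3, 1:3] <- 1; sh[2, 2, 2] <- 0
  expect_equal(betti_at_threshold(sh, 0.5, 0), 1L)
  expect_equal(betti_at_threshold(sh, 0.5, 1), 0L)
  expect_equal(betti_at_threshold(sh, 0.5, 2), 1L)
})

test_that("empty and invalid inputs error", {
  expect_error(compute_barcode(matrix(0.5, 2, 2), max_dim = 2), "max_dim")
  expect_error(betti_at_threshold(matrix(0.5, 2, 2), 0.5, 2), "dim")
  expect_error(reference_barcode_bruteforce(matrix(0.5, 30, 30)), "500")
})

test_that("barcode export round-trips through CSV and JSON", {
  b <- compute_barcode(ring_field_5x5())
  csv <- tempfile(fileext = ".csv"); json <- tempfile(fileext = ".json")
  write_barcode(b, csv); write_barcode(b, json)
  back <- utils::read.csv(csv)
  expect_equal(back$birth, b$birth)
  expect_equal(back$death, b$death)
  j <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(j$bars$birth, b$birth)
  expect_equal(j$shape, c(5L, 5L))
  unlink(c(csv, json))
})
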