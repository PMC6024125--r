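test_that("capture history validation enforces the detection invariants", {
  ind <- individuals("a", "female", "wild-born", "nestling", 1L)
  # no detection at first occasion
  expect_error(capture_history(matrix(c(0, 0, 1), 1, 3), ind),
               "no detection at its first occasion")
  # detection before first occasion
  det <- matrix(c(1, 1, 0), 1, 3)
  expect_error(capture_history(det, ind), "a.*before first occasion")
  expect_error(capture_history(matrix(c(0, 1, 2), 1, 3), ind),
               "0 or 1")
  expect_error(capture_history(matrix(c(0, 1, 1), 1, 3),
                               individuals("a", "female", "wild-born",
                                           "nestling", 5L)),
               "occasion range")
  expect_error(individuals("a", "feemale", "wild-born", "nestling", 0L),
               "invalid sex code")
  expect_error(capture_history(matrix(1, 1, 1),
                               individuals("a", "female", "wild-born",
                                           "nestling", 0L),
                               first_interval_fraction = 1.2),
               "first_interval_fraction")
})

test_that("fecundity and unbanded validation", {
  expect_error(fecundity_records("a", 1, -1, 10), "non-negative")
  expect_error(fecundity_records("a", 1, 2, 0), "density must be positive")
  expect_error(unbanded_counts(1, "male", -2), "non-negative")
  toy <- toy_dataset()
  expect_silent(validate_dataset(toy))
  bad <- toy
  bad$fecundity <- fecundity_records("ghost", 1, 2, 10)
  expect_error(validate_dataset(bad), "unknown females.*ghost")
  bad$fecundity <- fecundity_records("m01", 1, 2, 10)
  expect_error(validate_dataset(bad), "male individuals")
})

expect_same_dataset <- function(a, b) {
  expect_equal(unname(a$capture_history$detections),
               unname(b$capture_history$detections))
  expect_equal(a$capture_history$individuals, b$capture_history$individuals)
  expect_equal(a$capture_history$first_interval_fraction,
               b$capture_history$first_interval_fraction)
  expect_equal(as.data.frame(a$fecundity), as.data.frame(b$fecundity),
               ignore_attr = TRUE)
  expect_equal(as.data.frame(a$unbanded), as.data.frame(b$unbanded),
               ignore_attr = TRUE)
}

test_that("csv-bundle round trip is the identity, including edge cases", {
  toy <- toy_dataset()
  d <- tempfile()
  write_dataset(toy, d)
  back <- read_dataset(d, "csv-bundle")
  expect_same_dataset(toy, back)
  expect_equal(nrow(back$capture_history$detections), 3)
  expect_equal(ncol(back$capture_history$detections), 4)

  # empty fecundity table survives with header
  toy$fecundity <- fecundity_records()
  write_dataset(toy, d)
  expect_equal(nrow(read_dataset(d)$fecundity), 0)
})

test_that("round-trip identity holds across 100 random simulated datasets", {
  d <- tempfile()
  for (s in 1:100) {
    sim <- small_sim(seed = s, n_years = 3)
    write_dataset(sim, d)
    expect_same_dataset(sim, read_dataset(d))
  }
})

test_that("BUGS dump reader handles the classic dialect and rejects junk", {
  f <- tempfile(fileext = ".txt")
  # matrix written column-major, as R's structure(.Dim=) fills it
  writeLines(paste0(
    "list(y = structure(.Data = c(1,0,0, 0,1,1, 1,1,0, 0,1,0),",
    " .Dim = c(3, 4)),",
    " f = c(0, 1, 1), sex = c(2, 1, 3), origin = c(1, 1, 2),",
    " fif = 0.5)"), f)
  got <- read_dataset(f, "bugs-dump")
  toy <- toy_dataset()
  expect_equal(unname(got$capture_history$detections),
               unname(toy$capture_history$detections))
  expect_equal(got$capture_history$individuals$sex,
               toy$capture_history$individuals$sex)
  expect_equal(got$capture_history$first_interval_fraction, 0.5)

  writeLines("list(y = rnorm(3))", f)
  expect_error(read_dataset(f, "bugs-dump"), "unsupported construct")
  writeLines(c("list(y = c(1,2,", "oops((", "3))"), f)
  expect_error(read_dataset(f, "bugs-dump"), "malformed BUGS dump")
  writeLines("list(f = c(0, 1))", f)
  expect_error(read_dataset(f, "bugs-dump"), "lacks variable 'y'")
})
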