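test_that("inp records map to validated encounter histories", {
  f <- withr::local_tempfile(fileext = ".inp")
  writeLines(c("1011000000 1 1 3.40;",
               "0000100000 1 0;"), f)
  ds <- read_inp(f, study_calendar(2003, 10))
  h <- ds$histories
  expect_equal(nrow(h), 2L)
  expect_equal(h$mark_occasion, c(1L, 5L))
  expect_equal(h$mark_class, c("fledgling", "adult"))
  expect_equal(h$mass, c(3.40, NA))
  expect_equal(ds$detections[1, ], c(1L, 0L, 1L, 1L, rep(0L, 6)))
})

test_that("malformed inp lines are rejected with line numbers", {
  cal <- study_calendar(2003, 10)
  f <- withr::local_tempfile(fileext = ".inp")
  writeLines("101100000 1 1 3.40;", f)          # 9 characters
  expect_error(read_inp(f, cal), "line 1.*length")
  writeLines("10110000x0 1 1;", f)
  expect_error(read_inp(f, cal), "non-binary")
  writeLines("1011000000 1 0 3.40;", f)          # mass on an adult
  expect_error(read_inp(f, cal), "adult")
  writeLines("1011000000 1 1 heavy;", f)
  expect_error(read_inp(f, cal), "non-numeric mass")
})

test_that("write_inp / read_inp round-trips random datasets", {
  set.seed(42)
  T <- 8L
  n <- 100L
  det <- matrix(0L, n, T)
  mark <- sample.int(T, n, replace = TRUE)
  cls <- sample(c("fledgling", "adult"), n, replace = TRUE)
  for (i in seq_len(n)) {
    det[i, mark[i]] <- 1L
    if (mark[i] < T)
      det[i, (mark[i] + 1):T] <- rbinom(T - mark[i], 1, 0.3)
  }
  mass <- ifelse(cls == "fledgling", round(rnorm(n, 3.28, 0.3), 2), NA)
  ds <- cmr_dataset(study_calendar(2003, T),
                    data.frame(animal_id = sprintf("A%05d", seq_len(n)),
                               mark_occasion = mark, mark_class = cls,
                               mass = mass, stringsAsFactors = FALSE),
                    det)
  f1 <- withr::local_tempfile(fileext = ".inp")
  f2 <- withr::local_tempfile(fileext = ".inp")
  write_inp(ds, f1)
  ds2 <- read_inp(f1, ds$calendar)
  expect_equal(ds2$histories, ds$histories)
  expect_equal(unname(ds2$detections), unname(ds$detections))
  expect_equal(ds2$mass_standardizer$z, ds$mass_standardizer$z)
  write_inp(ds2, f2)
  expect_identical(readLines(f1), readLines(f2))   # write-read-write stable
})

test_that("empty dataset writes an empty file", {
  ds <- cmr_dataset(study_calendar(2003, 5),
                    data.frame(animal_id = character(),
                               mark_occasion = integer(),
                               mark_class = character(),
                               mass = numeric()),
                    matrix(integer(), 0, 5))
  f <- withr::local_tempfile(fileext = ".inp")
  write_inp(ds, f)
  expect_length(readLines(f), 0L)
})

test_that("standardize produces exact z-scores and round-trips", {
  s <- standardize(c(1, 2, 3))
  expect_equal(s$z, c(-1, 0, 1))
  expect_equal(s$center, 2)
  expect_equal(s$scale, 1)
  set.seed(5)
  for (rep in 1:20) {
    x <- rnorm(sample(5:40, 1), sd = runif(1, 0.1, 10))
    s <- standardize(x)
    expect_equal(mean(s$z), 0, tolerance = 1e-10)
    expect_equal(sd(s$z), 1, tolerance = 1e-10)
    expect_equal(destandardize(s), x, tolerance = 1e-12)
    # affine invariance: a + b x (b > 0) has the same z-scores
    a <- rnorm(1); b <- runif(1, 0.1, 5)
    expect_equal(standardize(a + b * x)$z, s$z, tolerance = 1e-9)
  }
  expect_error(standardize(rep(1, 5)), "constant")
  expect_error(standardize(3), "at least 2")
})

test_that("fledglings without mass are removed, others untouched", {
  ds <- tiny_dataset(c("1000", "1100", "1010", "0110", "0011"),
                     classes = c("fledgling", "fledgling", "fledgling",
                                 "adult", "adult"),
                     masses = c(3.1, NA, 3.5, NA, NA))
  out <- filter_missing_mass(ds)
  expect_equal(out$removed, 1L)
  expect_equal(n_animals(out$dataset), 4L)
  expect_equal(sum(out$dataset$histories$mark_class == "adult"), 2L)
  kept <- out$dataset$histories$animal_id
  expect_equal(out$dataset$detections,
               ds$detections[ds$histories$animal_id %in% kept, ])
  # no-op when nothing is missing
  expect_equal(filter_missing_mass(out$dataset)$removed, 0L)
})

test_that("masking 11 masses reproduces the study's removal count", {
  sim <- small_sim(seed = 31L, fledglings = 40L, adults = 10L)
  ds <- sim$dataset
  fidx <- which(ds$histories$mark_class == "fledgling")
  set.seed(8)
  ds$histories$mass[sample(fidx, 11)] <- NA
  expect_equal(filter_missing_mass(ds)$removed, 11L)
})

test_that("dataset validation catches structural violations", {
  expect_no_error(tiny_dataset(c("0100", "0100"), c("adult", "adult")))
  h <- data.frame(animal_id = c("a", "a"), mark_occasion = c(1L, 1L),
                  mark_class = "adult", mass = NA_real_)
  det <- rbind(c(1L, 0L), c(1L, 0L))
  expect_error(cmr_dataset(study_calendar(2003, 2), h, det), "duplicate")
  det2 <- rbind(c(1L, 1L, 0L))
  h2 <- data.frame(animal_id = "a", mark_occasion = 2L,
                   mark_class = "adult", mass = NA_real_)
  expect_error(cmr_dataset(study_calendar(2003, 3), h2, det2),
               "before marking")
})

test_that("year covariate tables align to the calendar", {
  cal <- study_calendar(2003, 10)
  tab <- tiny_year_covariates(10)
  f <- withr::local_tempfile(fileext = ".csv")
  write_year_covariates(tab, f)
  got <- read_year_covariates(f, cal)
  expect_equal(got$pred_pressure, tab$pred_pressure)
  expect_length(attr(got, "missing_covariates"), 0L)

  # shuffled rows are re-sorted by season
  write_year_covariates(tab[sample(10), ], f)
  expect_equal(read_year_covariates(f, cal)$lsst_lag1, tab$lsst_lag1)

  # a missing optional column is flagged, not fatal
  write_year_covariates(tab[, setdiff(names(tab), "sam_lag1")], f)
  expect_equal(attr(read_year_covariates(f, cal), "missing_covariates"),
               "sam_lag1")

  # wrong row count is structural
  write_year_covariates(tab[1:9, ], f)
  expect_error(read_year_covariates(f, cal), "9 rows")
})

test_that("annual covariates standardize over survival intervals", {
  tab <- tiny_year_covariates(10)
  ds <- tiny_dataset(c("1000000000", "0100000000"), c("adult", "adult"),
                     year_covariates = tab)
  s <- standardized_year_covariate(ds, "lsst_lag1")
  expect_equal(s$raw, tab$lsst_lag1[1:9])
  expect_equal(mean(s$z), 0, tolerance = 1e-12)
})
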