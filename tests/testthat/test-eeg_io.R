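test_that("recording roundtrips through the array container bit-exactly", {
  set.seed(1)
  rec <- recording(matrix(rnorm(8 * 1024), 8), paste0("ch", 1:8), 128,
                   subject_id = "s07", trial_id = "t03")
  path <- file.path(tempdir(), "rt.dat")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_identical(back$data, rec$data)
  expect_identical(back$channel_labels, rec$channel_labels)
  expect_identical(back$fs, rec$fs)
  expect_identical(back$subject_id, "s07")
  expect_identical(back$trial_id, "t03")
})

test_that("a 32-channel synthetic recording with 10-20 labels loads with n = 32", {
  set.seed(2)
  rec <- recording(matrix(rnorm(32 * 256), 32), standard_montage(32), 128)
  path <- file.path(tempdir(), "m32.dat")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(nrow(back$data), 32L)
  expect_true(all(c("Fp1", "Cz", "O2") %in% back$channel_labels))
})

test_that("duplicate channel labels are a format error naming the duplicate", {
  expect_error(recording(matrix(0, 2, 10), c("Cz", "Cz"), 128), "Cz")
  # a file whose sidecar carries duplicates must fail on read too
  rec <- recording(matrix(rnorm(20), 2), c("Cz", "Pz"), 128)
  path <- file.path(tempdir(), "dup.dat")
  write_recording(rec, path)
  sc <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sc$channel_labels <- c("Cz", "Cz")
  jsonlite::write_json(sc, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  expect_error(read_recording(path), "Cz")
})

test_that("non-finite samples are a validation error naming channel and index", {
  m <- matrix(0, 2, 5); m[2, 4] <- NaN
  err <- tryCatch(recording(m, c("C3", "C4"), 128), error = identity)
  expect_match(conditionMessage(err), "C4")
  expect_match(conditionMessage(err), "3")   # 0-based sample index
})

test_that("factor sequences roundtrip exactly with metadata and model id", {
  set.seed(3)
  fs <- factor_sequence(matrix(rnorm(3 * 500), 3), 128, subject_id = "s01",
                        trial_id = "t01", model_id = "vae_m3")
  path <- file.path(tempdir(), "fac.dat")
  write_factors(fs, path)
  back <- read_factors(path)
  expect_identical(back$factors, fs$factors)
  expect_identical(back$model_id, "vae_m3")
  expect_identical(back$fs, fs$fs)
})

test_that("a factors file containing NaN fails validation on read", {
  fs <- factor_sequence(matrix(1, 2, 4), 128)
  path <- file.path(tempdir(), "nan.dat")
  write_factors(fs, path)
  con <- file(path, "wb")
  writeBin(c(1, NaN, rep(1, 6)), con, size = 8L, endian = "little")
  close(con)
  expect_error(read_factors(path), "non-finite")
})

test_that("delimited containers preserve full floating precision", {
  set.seed(4)
  rec <- recording(matrix(rnorm(3 * 40), 3), c("F3", "Fz", "F4"), 256)
  path <- file.path(tempdir(), "tiny.tsv")
  write_recording(rec, path, format = "delimited")
  back <- read_recording(path, format = "delimited")
  expect_equal(back$data, rec$data, tolerance = 0)
})

test_that("label tables roundtrip and enforce key uniqueness", {
  lab <- trial_labels(c("s01", "s01"), c("t01", "t02"),
                      c("valence", "valence"), c(7, 3),
                      c("positive", "negative"))
  path <- file.path(tempdir(), "labels.tsv")
  write_labels(lab, path)
  back <- read_labels(path)
  expect_equal(back$klass, c("positive", "negative"))
  expect_error(trial_labels(c("s01", "s01"), c("t01", "t01"),
                            c("valence", "valence"), c(7, 7),
                            c("positive", "positive")),
               "unique")
})

test_that("EDF import reads back what the EDF writer stored", {
  set.seed(5)
  rec <- recording(matrix(rnorm(4 * 256), 4), c("C3", "C4", "O1", "O2"), 128)
  path <- file.path(tempdir(), "t.edf")
  eegfactors:::write_edf(rec, path)
  back <- read_recording(path, format = "edf")
  expect_identical(back$channel_labels, rec$channel_labels)
  expect_equal(back$fs, 128)
  # 16-bit quantization: agreement to ~1e-4 of the amplitude range
  expect_lt(max(abs(back$data - rec$data)), diff(range(rec$data)) * 1e-4)
})

test_that("readers preserve channel order as stored", {
  rec <- recording(rbind(1:10, 11:20, 21:30), c("Pz", "Cz", "Fz"), 100)
  path <- file.path(tempdir(), "ord.dat")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_identical(back$channel_labels, c("Pz", "Cz", "Fz"))
  expect_identical(back$data[1, ], as.numeric(1:10))
})
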