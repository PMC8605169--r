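test_that("read_iqc groups rows into one sorted series per key", {
  iqc <- read_iqc(iqc_fixture_small())
  expect_s3_class(iqc, "usigma_iqc")
  expect_equal(nrow(iqc), 4)  # 2 labs x 1 analyte x 2 levels
  expect_true(all(iqc$n == 3))
  expect_false(anyDuplicated(paste(iqc$lab, iqc$analyte, iqc$level)) > 0)

  # the unordered key comes back run-sorted, values following their runs
  a1 <- iqc[iqc$lab == "Lab A" & iqc$level == "level1", ]
  expect_equal(a1$run[[1]], c(1, 2, 3))
  expect_equal(a1$values[[1]], c(25.0, 25.2, 24.8))
})

test_that("read_iqc rejects bad files with named errors", {
  expect_error(read_iqc(write_iqc_fixture("Lab A,K,level1,1,-1.0")),
               "positive.*row.*1", ignore.case = TRUE)
  p <- tempfile(fileext = ".csv")
  writeLines(c("lab,analyte,run,value", "Lab A,K,1,10"), p)
  expect_error(read_iqc(p), "level")
  expect_error(read_iqc(write_iqc_fixture("Lab A,K,level1,1,10.0")),
               "at least 2")
})

test_that("read_iqc accepts a column dialect remap", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("site,analyte,level,run,value",
               "Lab A,K,level1,1,10", "Lab A,K,level1,2,11"), p)
  iqc <- read_iqc(p, dialect = c(lab = "site"))
  expect_equal(iqc$lab, "Lab A")
})

test_that("IQC round trip is lossless", {
  iqc <- read_iqc(iqc_fixture_small())
  p <- tempfile(fileext = ".csv")
  write_iqc(iqc, p)
  again <- read_iqc(p)
  expect_equal(as.data.frame(again), as.data.frame(iqc))
})

test_that("read_eqa validates replicate counts and target consistency", {
  eqa <- read_eqa(eqa_fixture_one_key())
  expect_equal(nrow(eqa), 1)
  expect_equal(eqa$n, 5)
  expect_equal(eqa$target, 10)

  # two targets for one key
  p <- write_eqa_fixture(c("Lab A,K,level1,1,10,10",
                           "Lab A,K,level1,2,10,11"))
  expect_error(read_eqa(p, strict_n = NULL), "inconsistent")

  # 3 replicates: rejected under strict_n = 5, accepted when relaxed
  p3 <- write_eqa_fixture(sprintf("Lab A,K,level1,%d,10.%d,10", 1:3, 1:3))
  expect_error(read_eqa(p3), "exactly 5")
  relaxed <- read_eqa(p3, strict_n = NULL)
  expect_equal(relaxed$n, 3)
})

test_that("EQA round trip is lossless", {
  eqa <- read_eqa(eqa_fixture_one_key())
  p <- tempfile(fileext = ".csv")
  write_eqa(eqa, p)
  expect_equal(as.data.frame(read_eqa(p)), as.data.frame(eqa))
})

test_that("builtin TEa table matches the national urinary goals", {
  goals <- load_tea_goals("china_eqa_2020")
  expect_equal(nrow(goals), 10)
  expect_equal(tea_for(goals, "Crea"), 17)
  expect_equal(tea_for(goals, "TP"), 44)
  expect_equal(tea_for(goals, "K"), 29)
  expect_equal(
    stats::setNames(goals$tea, goals$analyte),
    c(K = 29, Na = 26, Cl = 26, Ca = 31, P = 23, GLU = 20, Urea = 21,
      Crea = 17, TP = 44, mALB = 30)
  )
})

test_that("custom TEa files load and unknown analytes raise lookup errors", {
  p <- tempfile(fileext = ".json")
  writeLines('{"K": 25}', p)
  goals <- load_tea_goals(p)
  expect_equal(tea_for(goals, "K"), 25)
  expect_error(tea_for(goals, "Na"), "Na")

  bad <- tempfile(fileext = ".json")
  writeLines('{"K": 0}', bad)
  expect_error(load_tea_goals(bad), "K")
})
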