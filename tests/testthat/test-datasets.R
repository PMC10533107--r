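test_that("the 11 dataset specs are well-formed", {
  ids <- dataset_ids()
  expect_length(ids, 11L)
  expect_false("RHTD" %in% ids) # no reduced heat tonic dataset
  for (id in ids) {
    sp <- dataset_spec(id)
    expect_equal(sp$n_classes == 7L, sp$quality == "both")
  }
  expect_error(dataset_spec("XYZ"), "unknown dataset")
})

test_that("filtering keeps matching sequences with their preceding baseline run", {
  codes <- c(rep(0L, 4), rep(1L, 3), rep(0L, 4), rep(7L, 5), rep(0L, 2))
  ws <- toy_windows(codes)
  pd <- filter_windows(ws, "PD")
  expect_equal(pd$code, c(rep(0L, 4), rep(1L, 3)))
  # tonic spec keeps the tonic sequence and its attributed baseline instead
  td <- filter_windows(ws, "TD")
  expect_equal(td$code, c(rep(0L, 4), rep(7L, 5)))
})

test_that("filtering drops artifacts and respects quality filters", {
  codes <- c(0L, 0L, -10L, 1L, 1L, 0L, 4L, 4L, 0L)
  ws <- toy_windows(codes)
  hpd <- filter_windows(ws, "HPD")
  expect_equal(hpd$code, c(0L, 0L, 1L, 1L))
  expect_setequal(dataset_classes("HPD"), c("BL", "PH1", "PH2", "PH3"))
  epd <- filter_windows(ws, "EPD")
  expect_equal(epd$code, c(0L, 4L, 4L))
  expect_false(any(filter_windows(ws, "PD")$code %in% ARTIFACT_CODES))
})

test_that("filtering an empty set and refiltering are no-ops", {
  ws <- toy_windows(integer(0))
  expect_equal(n_windows(filter_windows(ws, "PD")), 0L)
  codes <- c(rep(0L, 6), rep(2L, 4), rep(0L, 3), rep(5L, 2))
  once <- filter_windows(toy_windows(codes), "PD")
  twice <- filter_windows(once, "PD")
  expect_identical(once$code, twice$code)
  expect_identical(once$x, twice$x)
})

test_that("reduction retains exactly m preceding baseline windows per sequence", {
  codes <- c(rep(0L, 12), rep(4L, 5))
  red <- reduce_no_pain(filter_windows(toy_windows(codes), "REPD"))
  expect_equal(red$code, c(rep(0L, 5), rep(4L, 5)))
  short <- c(rep(0L, 3), rep(4L, 5))
  red2 <- reduce_no_pain(filter_windows(toy_windows(short), "REPD"))
  expect_equal(red2$code, short) # cannot retain more than exist
})

test_that("reduction yields exactly 50% baseline when every run is long enough", {
  set.seed(1)
  codes <- unlist(lapply(1:10, function(k) {
    m <- sample(3:6, 1)
    c(rep(0L, m + sample(2:5, 1)), rep(sample(1:6, 1), m))
  }))
  red <- reduce_no_pain(filter_windows(toy_windows(codes), "RPD"))
  expect_equal(mean(red$code == 0L), 0.5)
})

test_that("reduction never removes pain windows and never grows the set", {
  set.seed(2)
  codes <- unlist(lapply(1:6, function(k)
    c(rep(0L, sample(1:8, 1)), rep(sample(1:6, 1), sample(2:6, 1)))))
  filt <- filter_windows(toy_windows(codes), "RPD")
  red <- reduce_no_pain(filt)
  expect_equal(sum(red$code != 0L), sum(filt$code != 0L))
  expect_lte(n_windows(red), n_windows(filt))
  expect_error(reduce_no_pain(filter_windows(toy_windows(codes), "PD")),
               "reduced")
})

test_that("label encoding follows the class ordering and intensity/3 targets", {
  codes <- c(0L, 1L, 2L, 3L, 4L, 5L, 6L)
  ws <- encode_labels(filter_windows(toy_windows(c(0L, codes[-1])), "PD"))
  expect_equal(ws$class_index[ws$code == 0L], 0L)
  expect_equal(ws$value[ws$code == 0L], 0)
  expect_equal(ws$class_index[ws$code == 5L], 5L) # electrical intensity 2
  expect_equal(ws$value[ws$code == 5L], 2 / 3)
  expect_equal(ws$class_index[ws$code == 3L], 3L)
  expect_equal(ws$value[ws$code == 3L], 1)
  # 4-class dataset collapses to BL + intensity
  hp <- encode_labels(filter_windows(toy_windows(c(0L, 1L, 2L, 3L)), "HPD"))
  expect_equal(hp$class_index, 0:3)
  expect_equal(hp$value, c(0, 1, 2, 3) / 3)
  expect_equal(dataset_classes("PD"),
               c("BL", "PH1", "PH2", "PH3", "PE1", "PE2", "PE3"))
})

test_that("class counts cover the spec's classes", {
  codes <- c(rep(0L, 4), rep(1L, 2), rep(5L, 3))
  ws <- encode_labels(filter_windows(toy_windows(codes), "PD"))
  cc <- class_counts(ws)
  expect_equal(sum(cc), n_windows(ws))
  expect_equal(unname(cc["PE2"]), 3L)
  expect_equal(unname(cc["PH3"]), 0L)
})
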