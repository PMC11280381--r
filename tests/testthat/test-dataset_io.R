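test_that("a CSV compound table is read back as-is", {
  df <- data.frame(id = c("a", "b", "c"), PSA = c(30.5, 45.2, 60.1),
                   DM = c(2.1, 3.3, 4.2), MW = c(400, 450, 470),
                   pIC50 = c(6.1, 6.5, 7.0))
  ds <- read_compound_table(write_toy_csv(df))
  expect_s3_class(ds, "qsar_dataset")
  expect_equal(ds$ids, c("a", "b", "c"))
  expect_equal(colnames(ds$descriptors), c("PSA", "DM", "MW"))
  expect_equal(unname(ds$descriptors[, "PSA"]), df$PSA)
  expect_equal(ds$pic50, df$pIC50)
})

test_that("malformed cells and duplicate ids are rejected with context", {
  df <- data.frame(id = c("a", "b"), PSA = c("30.5", "NA"), pIC50 = c(6, 7))
  expect_error(read_compound_table(write_toy_csv(df)),
               "row 2.*PSA", class = "qsar_parse_error")
  df2 <- data.frame(id = c("a", "a"), PSA = c(1, 2), pIC50 = c(6, 7))
  expect_error(read_compound_table(write_toy_csv(df2)),
               "duplicate", class = "qsar_validation_error")
})

test_that("IC50 converts to pIC50 on the molar scale", {
  expect_equal(ic50_to_pic50(1000, "nM"), 6)
  expect_equal(ic50_to_pic50(1, "M"), 0)
  expect_equal(ic50_to_pic50(1, "uM"), 6)
  expect_equal(ic50_to_pic50(1, "µM"), 6)  # micro sign accepted
  # hand arithmetic: -log10(5.5e-8) = 9 - log10(55)
  expect_equal(ic50_to_pic50(55, "nM"), 9 - log10(55), tolerance = 1e-12)
  expect_equal(round(ic50_to_pic50(55, "nM"), 4), 7.2596)
  expect_error(ic50_to_pic50(0, "nM"), class = "qsar_domain_error")
  expect_error(ic50_to_pic50(-5, "M"), class = "qsar_domain_error")
})

test_that("IC50 and pIC50 columns must agree under conversion", {
  df <- data.frame(id = c("a", "b"), PSA = c(1, 2),
                   IC50 = c(1000, 55), unit = c("nM", "nM"),
                   pIC50 = c(6, 7.259637))
  ds <- read_compound_table(write_toy_csv(df), ic50_col = "IC50", unit_col = "unit")
  expect_equal(ds$pic50[1], 6)
  df$pIC50[2] <- 7.5  # inconsistent with 55 nM
  expect_error(read_compound_table(write_toy_csv(df), ic50_col = "IC50",
                                   unit_col = "unit"),
               "disagree", class = "qsar_validation_error")
})

test_that("training records must carry an activity, candidates may not", {
  X <- matrix(1:4, 2, 2, dimnames = list(NULL, c("A", "B")))
  expect_error(qsar_dataset(X, pic50 = c(6, NA)), class = "qsar_validation_error")
  ds <- qsar_dataset(X, pic50 = c(6, NA), role = c("train", "candidate"))
  expect_equal(ds$role, c("train", "candidate"))
})

test_that("the split is seeded, sized by round-half-up, and partitions", {
  ds <- generate_dataset(default_paperlike_spec(seed = 3))
  sp <- split_dataset(ds, 0.8, seed = 11)
  expect_equal(sum(sp$role == "train"), 40)
  expect_equal(sum(sp$role == "test"), 10)
  expect_identical(sp, split_dataset(ds, 0.8, seed = 11))
  expect_false(identical(sp$role, split_dataset(ds, 0.8, seed = 12)$role))
  # empty test set under required external validation
  small <- qsar_dataset(matrix(rnorm(20), 10, 2,
                               dimnames = list(NULL, c("A", "B"))),
                        pic50 = rnorm(10))
  expect_error(split_dataset(small, 1.0), class = "qsar_config_error")
  expect_equal(sum(split_dataset(small, 1.0, require_test = FALSE)$role == "train"), 10)
})

test_that("split partitions exactly for many seeds and sizes", {
  for (i in 1:1000) {
    set.seed(i)
    n <- sample(5:60, 1)
    ds <- qsar_dataset(matrix(rnorm(2 * n), n, 2,
                              dimnames = list(NULL, c("A", "B"))),
                       pic50 = rnorm(n))
    fr <- runif(1, 0.3, 0.9)
    sp <- split_dataset(ds, fr, seed = i)
    n_train <- sum(sp$role == "train")
    expect_equal(n_train + sum(sp$role == "test"), n)
    expect_equal(n_train, floor(fr * n + 0.5))
  }
})

test_that("write/read round-trips numeric values to 12+ significant digits", {
  ds <- generate_dataset(default_paperlike_spec(seed = 5))
  path <- tempfile(fileext = ".csv")
  write_compound_table(ds, path)
  back <- read_compound_table(path, role_col = "role")
  expect_equal(back$descriptors, ds$descriptors, tolerance = 1e-12)
  expect_equal(back$pic50, ds$pic50, tolerance = 1e-12)
})

test_that("the candidate fixture matches its published descriptor rows", {
  cand <- load_fixture("table4_candidates")
  expect_equal(length(cand$ids), 11)
  expect_true(all(cand$role == "candidate"))
  m1 <- cand$descriptors["M1", ]
  expect_equal(unname(m1[c("PSA", "DM", "MW")]), c(27.690, 3.599, 476.510))
})
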