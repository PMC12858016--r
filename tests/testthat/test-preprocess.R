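test_that("abnormal coding matches the reference-range rule exactly", {
  expect_equal(encode_abnormal(15.2, 13.0, 17.0), 0.5)
  expect_equal(encode_abnormal(18.1, 13.0, 17.0), 1)
  expect_equal(encode_abnormal(12.9, 13.0, 17.0), 0)
  # boundaries are inside the closed reference range
  expect_equal(encode_abnormal(17.0, 13.0, 17.0), 0.5)
  expect_equal(encode_abnormal(13.0, 13.0, 17.0), 0.5)
  expect_equal(encode_abnormal(NA_real_, 13, 17), NA_real_)
  expect_error(encode_abnormal(1, 5, 5), "lower < upper")
})

test_that("coding is scale-equivariant through the reference range", {
  set.seed(1)
  for (i in 1:50) {
    v <- rnorm(1, 10, 5); lo <- runif(1, 5, 9); hi <- lo + runif(1, 1, 5)
    a <- runif(1, 0.1, 10)
    expect_identical(encode_abnormal(a * v, a * lo, a * hi),
                     encode_abnormal(v, lo, hi))
  }
})

coded_fixture <- function(values_by_item, n = 40, seed = 1) {
  set.seed(seed)
  purrr::imap_dfr(values_by_item, function(v, nm) {
    tibble::tibble(patient_id = "P1", time_index = seq_len(n), item = nm,
                   value = v)
  })
}

test_that("item selection ranks by abnormal count and drops correlated items", {
  set.seed(2)
  base <- sample(c(0, 0.5, 1), 40, replace = TRUE, prob = c(0.4, 0.2, 0.4))
  tbl <- coded_fixture(list(
    A = base,                                       # abnormal count high
    B = base,                                       # perfectly correlated twin
    C = sample(c(0, 0.5, 1), 40, TRUE, prob = c(0.1, 0.8, 0.1))
  ))
  kept <- suppressWarnings(select_lab_items(tbl, preprocess_config(n_lab_items = 50)))
  expect_true("A" %in% kept$item)     # A wins the tie with B lexicographically
  expect_false("B" %in% kept$item)    # r = 1 > 0.7
  expect_true("C" %in% kept$item)
  expect_equal(kept$item[1], "A")     # ordered by descending abnormal count
})

test_that("greedy correlation filter agrees with a brute-force audit", {
  set.seed(3)
  items <- purrr::map(1:10, function(i) {
    if (i <= 3) sample(c(0, 0.5, 1), 60, TRUE)
    else {
      # correlated copies of earlier items with flips
      src <- sample(1:3, 1)
      v <- sample(c(0, 0.5, 1), 60, TRUE)
      flip <- runif(60) < 0.6
      v
    }
  })
  names(items) <- sprintf("i%02d", 1:10)
  items$i04 <- items$i01; items$i05 <- items$i02   # exact duplicates
  tbl <- coded_fixture(items, n = 60)
  kept <- suppressWarnings(select_lab_items(tbl, preprocess_config(n_lab_items = 50)))$item
  wide <- tidyr::pivot_wider(tbl, id_cols = "time_index", names_from = "item",
                             values_from = "value")
  M <- as.matrix(wide[, -1])
  # every kept pair satisfies |r| <= 0.7
  for (a in kept) for (b in setdiff(kept, a)) {
    expect_lte(abs(cor(M[, a], M[, b])), 0.7)
  }
  # every dropped item violates the threshold against an earlier kept item
  counts <- colSums(M != 0.5)
  for (d in setdiff(names(items), kept)) {
    earlier <- kept[counts[kept] > counts[d] |
                      (counts[kept] == counts[d] & kept < d)]
    expect_true(any(abs(cor(M[, d], M[, earlier, drop = FALSE])) > 0.7))
  }
})

test_that("min-max normalization rescales to [0, 1] and flags degeneracy", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_warning(out <- minmax_normalize(c(5, 5)), "constant")
  expect_equal(out, c(0, 0))
  expect_error(minmax_normalize(c(NA_real_, NA_real_)), "all-missing")
  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(30); x[sample(30, 5)] <- NA
    y <- minmax_normalize(x)
    expect_equal(min(y, na.rm = TRUE), 0)
    expect_equal(max(y, na.rm = TRUE), 1)
    expect_identical(is.na(y), is.na(x))
  }
})

test_that("LOCF imputation forward-fills, back-fills the head, and is idempotent", {
  expect_equal(impute_locf(c(1, NA, NA, 4)), c(1, 1, 1, 4))
  expect_equal(impute_locf(c(NA, 2, NA)), c(2, 2, 2))
  expect_error(impute_locf(rep(NA_real_, 3)), "all-missing")
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(25); x[runif(25) < 0.5] <- NA
    if (all(is.na(x))) x[1] <- 0
    once <- impute_locf(x)
    expect_identical(impute_locf(once), once)
    expect_false(anyNA(once))
    expect_identical(once[!is.na(x)], x[!is.na(x)])
  }
})

raw_cohort_fixture <- function() {
  co <- generate_cohort(synth_config(n_patients = 8, n_items = 57,
                                     length_range = c(50, 60),
                                     missing_rate = 0.2, emission = "raw",
                                     seed = 9))
  list(obs = {
    long <- as_tibble(co)
    long$date <- as.character(as.Date("2006-01-01") + long$time_index - 1)
    long[, c("patient_id", "date", "item", "value")]
  },
  meta = co$meta,
  ranges = ehrstate:::synthetic_reference_ranges(50))
}

test_that("tensor assembly yields the full feature layout with valid masks", {
  fx <- raw_cohort_fixture()
  tn <- suppressWarnings(
    build_ehr_tensor(fx$obs, fx$meta, fx$ranges, preprocess_config()))
  expect_s3_class(tn, "ehr_tensor")
  expect_equal(as.vector(table(tn$features$category)[c(
    "anthropometric", "gender", "vital", "lab", "interval")]),
    c(2L, 1L, 4L, 50L, 1L))
  expect_equal(ncol(tn$x[[1]]), 58)   # 57 features + interval channel
  expect_equal(tn$features$feature[1:3], c("height", "weight", "gender"))
  expect_equal(utils::tail(tn$features$feature, 1), "delta_t")
  for (i in seq_along(tn$x)) {
    expect_true(all(tn$x[[i]] >= 0 & tn$x[[i]] <= 1, na.rm = TRUE))
    expect_identical(dim(tn$mask[[i]]), dim(tn$x[[i]]))
    expect_false(anyNA(tn$x_imp[[i]]))
    expect_true(all(is.na(tn$x[[i]][!tn$mask[[i]]])))
  }
  expect_true(all(tn$lengths >= 50 & tn$lengths <= 238))
  # no retained lab pair exceeds the correlation threshold (brute force)
  lab <- tn$features$feature[tn$features$category == "lab"]
  pooled <- do.call(rbind, lapply(tn$x, function(x) x[, lab]))
  cc <- suppressWarnings(cor(pooled, use = "pairwise.complete.obs"))
  diag(cc) <- 0
  expect_lte(max(abs(cc), na.rm = TRUE), 0.7)
})

test_that("length filtering excludes short patients and truncation keeps the tail", {
  fx <- raw_cohort_fixture()
  short_cfg <- preprocess_config(min_steps = 55, max_steps = 238)
  tn <- suppressWarnings(build_ehr_tensor(fx$obs, fx$meta, fx$ranges, short_cfg))
  n_days <- table(fx$obs$patient_id["" != fx$obs$patient_id])
  days_per_patient <- tapply(fx$obs$date, fx$obs$patient_id,
                             function(d) length(unique(d)))
  expect_setequal(tn$patient_id, names(days_per_patient)[days_per_patient >= 55])
  expect_equal(tn$report$n_dropped_short,
               sum(days_per_patient < 55))

  trunc_cfg <- preprocess_config(min_steps = 10, max_steps = 40)
  tn2 <- suppressWarnings(build_ehr_tensor(fx$obs, fx$meta, fx$ranges, trunc_cfg))
  expect_true(all(tn2$lengths == 40))
  # truncated rows are the most recent days: gender constant, but check a lab
  pid <- tn2$patient_id[1]
  pd <- dplyr::filter(fx$obs, patient_id == pid)
  last_days <- utils::tail(sort(unique(pd$date)), 40)
  coded <- dplyr::filter(pd, item == "lab01", date %in% last_days) |>
    dplyr::inner_join(fx$ranges, by = "item") |>
    dplyr::mutate(code = encode_abnormal(value, lower, upper))
  got <- tn2$x[[pid]][match(coded$date, last_days), "lab01"]
  expect_equal(unname(got), coded$code)
})

test_that("unknown item codes are skipped with a warning, not an error", {
  fx <- raw_cohort_fixture()
  obs <- dplyr::bind_rows(fx$obs,
                          tibble::tibble(patient_id = fx$obs$patient_id[1],
                                         date = fx$obs$date[1],
                                         item = "mystery", value = 1))
  w <- testthat::capture_warnings(
    tn <- build_ehr_tensor(obs, fx$meta, fx$ranges, preprocess_config()))
  expect_true(any(grepl("unknown item", w)))
  expect_false("mystery" %in% tn$features$feature)
})
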