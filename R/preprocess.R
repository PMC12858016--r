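#' Preprocessing configuration
#'
#' Controls how raw long-format EHR observations are turned into per-patient
#' observation tensors: which items play which feature role, how many
#' laboratory items to keep, the correlation-redundancy threshold, and the
#' retained sequence-length window.
#'
#' @param n_lab_items Number of laboratory items kept, ranked by abnormal
#'   count (default 50).
#' @param correlation_threshold Pairwise Pearson correlation above which a
#'   lower-ranked lab item is dropped as redundant (default 0.7).
#' @param min_steps Minimum retained sequence length; shorter patients are
#'   excluded (default 50).
#' @param max_steps Maximum length; longer sequences keep their most recent
#'   `max_steps` days (default 238).
#' @param anthropometric_items,gender_item,vital_items Item codes mapped to
#'   the anthropometric (2), gender (1) and vital (4) feature slots; all
#'   remaining observed items are treated as laboratory tests.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(n_lab_items = 50,
                              correlation_threshold = 0.7,
                              min_steps = 50,
                              max_steps = 238,
                              anthropometric_items = c("height", "weight"),
                              gender_item = "gender",
                              vital_items = c("temp", "pulse", "bp_max", "bp_min")) {
  stopifnot(is_count(n_lab_items), is_count(min_steps), is_count(max_steps),
            min_steps <= max_steps,
            correlation_threshold > 0, correlation_threshold <= 1)
  structure(list(
    n_lab_items = as.integer(n_lab_items),
    correlation_threshold = correlation_threshold,
    min_steps = as.integer(min_steps), max_steps = as.integer(max_steps),
    anthropometric_items = anthropometric_items,
    gender_item = gender_item, vital_items = vital_items
  ), class = "preprocess_config")
}

#' Code a laboratory value against its reference range
#'
#' Values above the upper reference bound code to 1 (abnormally high), below
#' the lower bound to 0 (abnormally low), and inside the closed range to 0.5
#' (normal). Boundary values are normal. Missing values propagate as `NA`.
#'
#' @param value Numeric vector of raw test values.
#' @param lower,upper Reference-range bounds (recycled; `lower < upper`).
#' @return Numeric vector of codes in \{0, 0.5, 1\} (with `NA` preserved).
#' @export
encode_abnormal <- function(value, lower, upper) {
  if (any(lower >= upper)) abort("reference range requires lower < upper")
  out <- rep(0.5, length(value))
  out[value > upper] <- 1
  out[value < lower] <- 0
  out[is.na(value)] <- NA_real_
  out
}

#' Select laboratory items by abnormal frequency with redundancy filtering
#'
#' Ranks items by descending count of abnormal codes (0 or 1), then scans
#' greedily: an item is kept iff its absolute pairwise Pearson correlation
#' (on pairwise-complete coded values aligned by patient-day) with every
#' already-kept item is at most `correlation_threshold`. Stops after
#' `n_lab_items` survivors or exhaustion.
#'
#' @param coded Long tibble of coded lab observations with columns
#'   `patient_id`, `time_index`, `item`, `value` (values in \{0, 0.5, 1\}).
#' @param config A [preprocess_config()].
#' @return Tibble of kept items in rank order with their abnormal counts.
#' @export
select_lab_items <- function(coded, config = preprocess_config()) {
  if (nrow(coded) == 0) abort("coded table is empty")
  counts <- coded |>
    dplyr::group_by(.data$item) |>
    dplyr::summarise(abnormal = sum(.data$value != 0.5, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$abnormal), .data$item)

  wide <- coded |>
    dplyr::mutate(key = paste(.data$patient_id, .data$time_index)) |>
    tidyr::pivot_wider(id_cols = "key", names_from = "item",
                       values_from = "value", values_fn = min)
  mat <- as.matrix(wide[, -1, drop = FALSE])

  kept <- character(0)
  for (it in counts$item) {
    ok <- TRUE
    for (kp in kept) {
      r <- suppressWarnings(cor(mat[, it], mat[, kp],
                                use = "pairwise.complete.obs"))
      if (is.finite(r) && abs(r) > config$correlation_threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, it)
    if (length(kept) >= config$n_lab_items) break
  }
  if (length(kept) < config$n_lab_items) {
    warn(sprintf("only %d of %d requested lab items survive the correlation filter",
                 length(kept), config$n_lab_items))
  }
  dplyr::filter(counts, .data$item %in% kept)
}

#' Min-max normalize a numeric vector
#'
#' Rescales observed values to `[0, 1]` using the given (or observed) min and
#' max; `NA` stays `NA`. A constant series maps to 0 with a warning.
#'
#' @param x Numeric vector, possibly with `NA`.
#' @param lo,hi Optional frozen cohort-wide bounds; default `range(x)`.
#' @return Numeric vector in `[0, 1]`.
#' @export
minmax_normalize <- function(x, lo = NULL, hi = NULL) {
  if (all(is.na(x))) abort("cannot normalize an all-missing series")
  lo <- lo %||% min(x, na.rm = TRUE)
  hi <- hi %||% max(x, na.rm = TRUE)
  if (hi <= lo) {
    warn("constant series: min-max range is degenerate, mapping to 0")
    out <- rep(0, length(x)); out[is.na(x)] <- NA_real_
    return(out)
  }
  pmin(1, pmax(0, (x - lo) / (hi - lo)))
}

#' Zero-order-spline (LOCF) imputation
#'
#' Fills each missing entry with the most recent earlier observed value
#' (piecewise-constant interpolation); missing entries before the first
#' observation are back-filled from it. The original observedness is
#' recoverable as `!is.na(x)`.
#'
#' @param x Numeric vector with `NA` for missing entries and at least one
#'   observed value.
#' @return Fully observed numeric vector of the same length.
#' @export
impute_locf <- function(x) {
  obs <- which(!is.na(x))
  if (length(obs) == 0) abort("cannot impute an all-missing series")
  idx <- cummax(ifelse(is.na(x), 0L, seq_along(x)))
  idx[idx == 0L] <- obs[1]
  x[idx]
}

locf_matrix <- function(x, fallback = NULL) {
  for (j in seq_len(ncol(x))) {
    if (all(is.na(x[, j]))) {
      if (is.null(fallback)) abort("all-missing column with no fallback")
      x[, j] <- fallback[j]
    } else {
      x[, j] <- impute_locf(x[, j])
    }
  }
  x
}

# Per-group daily mode; ties broken by the smaller value (deterministic).
stat_mode_min <- function(v) {
  tab <- table(v)
  as.numeric(names(tab)[which(tab == max(tab))[1]])
}

#' Assemble per-patient observation tensors from long-format EHR
#'
#' The full preprocessing path: optional abnormal coding of laboratory values
#' against reference ranges, daily-mode aggregation, abnormal-frequency item
#' selection with correlation filtering, chronological assembly into one
#' `T x D` matrix per patient (feature order: anthropometrics, gender,
#' vitals, labs, plus a trailing inter-measurement-interval channel),
#' cohort-wide min-max normalization, sequence-length filtering and
#' truncation to the most recent `max_steps` days, LOCF imputation, and
#' observation masks.
#'
#' @param obs Long tibble with columns `patient_id`, `date` (Date or
#'   ISO-8601 string) or integer `time_index`, `item`, `value`.
#' @param meta Patient metadata tibble (`patient_id`, `sex`, `death_flag`,
#'   optional `drugs` semicolon-separated).
#' @param ranges Optional reference-range tibble (`item`, `lower`, `upper`);
#'   when supplied, lab values are coded against it, otherwise lab values
#'   must already be coded in \{0, 0.5, 1\}.
#' @param config A [preprocess_config()].
#' @return An `ehr_tensor`: list with per-patient value matrices `x` (`NA` at
#'   unobserved cells), LOCF-imputed `x_imp`, logical masks, `lengths`,
#'   `patient_id`, `features` tibble, frozen min-max `stats`, kept `items`,
#'   `meta`, and a missingness report.
#' @export
build_ehr_tensor <- function(obs, meta, ranges = NULL,
                             config = preprocess_config()) {
  stopifnot(all(c("patient_id", "item", "value") %in% names(obs)))
  if (!"time_index" %in% names(obs)) {
    if (!"date" %in% names(obs)) abort("obs needs a `date` or `time_index` column")
    d <- as.Date(obs$date)
    obs$time_index <- as.integer(d - min(d, na.rm = TRUE)) + 1L
  }

  special <- c(config$anthropometric_items, config$gender_item, config$vital_items)
  lab_obs <- dplyr::filter(obs, !(.data$item %in% special))
  known_bad <- setdiff(unique(lab_obs$item),
                       if (is.null(ranges)) unique(lab_obs$item) else ranges$item)
  if (!is.null(ranges) && length(known_bad)) {
    warn(sprintf("skipping %d unknown item code(s): %s", length(known_bad),
                 paste(head(known_bad, 5), collapse = ", ")))
    lab_obs <- dplyr::filter(lab_obs, !(.data$item %in% known_bad))
  }
  if (!is.null(ranges)) {
    lab_obs <- lab_obs |>
      dplyr::inner_join(ranges, by = "item") |>
      dplyr::mutate(value = encode_abnormal(.data$value, .data$lower, .data$upper)) |>
      dplyr::select("patient_id", "time_index", "item", "value")
  } else {
    bad <- !lab_obs$value %in% c(0, 0.5, 1)
    if (any(bad)) abort("without reference ranges, lab values must be coded in {0, 0.5, 1}")
  }

  # daily aggregation: mode, ties to the smaller value
  agg <- dplyr::bind_rows(
    lab_obs,
    dplyr::filter(obs, .data$item %in% special) |>
      dplyr::select("patient_id", "time_index", "item", "value")
  ) |>
    dplyr::group_by(.data$patient_id, .data$time_index, .data$item) |>
    dplyr::summarise(value = stat_mode_min(.data$value), .groups = "drop")

  kept <- select_lab_items(
    dplyr::semi_join(agg, dplyr::distinct(lab_obs, .data$item), by = "item"),
    config)

  feat <- tibble::tibble(
    feature = c(config$anthropometric_items, config$gender_item,
                config$vital_items, kept$item),
    category = c(rep("anthropometric", length(config$anthropometric_items)),
                 "gender",
                 rep("vital", length(config$vital_items)),
                 rep("lab", nrow(kept)))
  )

  agg <- dplyr::filter(agg, .data$item %in% feat$feature)
  per_patient <- split(agg, agg$patient_id)
  meta <- dplyr::filter(meta, .data$patient_id %in% names(per_patient))

  seqs <- list(); pids <- character(0); dropped <- 0L
  for (pid in meta$patient_id) {
    pd <- per_patient[[pid]]
    days <- sort(unique(pd$time_index))
    if (length(days) < config$min_steps) { dropped <- dropped + 1L; next }
    x <- matrix(NA_real_, length(days), nrow(feat),
                dimnames = list(NULL, feat$feature))
    x[cbind(match(pd$time_index, days), match(pd$item, feat$feature))] <- pd$value
    x[, config$gender_item] <- meta$sex[meta$patient_id == pid]
    dt <- c(diff(days), 0)
    if (length(days) > config$max_steps) {
      keep_rows <- (length(days) - config$max_steps + 1):length(days)
      x <- x[keep_rows, , drop = FALSE]
      dt <- dt[keep_rows]; dt[length(dt)] <- 0
    }
    seqs[[pid]] <- list(x = x, dt = dt)
    pids <- c(pids, pid)
  }
  if (length(seqs) == 0) abort("no patient meets the minimum sequence length")

  # frozen cohort-wide min-max statistics (observed cells of retained rows)
  all_x <- do.call(rbind, lapply(seqs, `[[`, "x"))
  all_dt <- unlist(lapply(seqs, `[[`, "dt"))
  stats <- tibble::tibble(
    feature = c(feat$feature, "delta_t"),
    min = c(apply(all_x, 2, min, na.rm = TRUE), min(all_dt)),
    max = c(apply(all_x, 2, max, na.rm = TRUE), max(all_dt))
  )

  x_list <- list(); m_list <- list(); xi_list <- list()
  col_mean <- colMeans(all_x, na.rm = TRUE)
  norm_cols <- function(x) {
    for (j in seq_len(ncol(x))) {
      x[, j] <- suppressWarnings(
        minmax_normalize(x[, j], stats$min[j], stats$max[j]))
    }
    x
  }
  fallback <- norm_cols(matrix(col_mean, 1,
                               dimnames = list(NULL, feat$feature)))[1, ]
  fallback[is.na(fallback)] <- 0
  for (pid in pids) {
    x <- seqs[[pid]]$x
    mask <- !is.na(x)
    xn <- norm_cols(x)
    dtn <- suppressWarnings(
      minmax_normalize(seqs[[pid]]$dt,
                       stats$min[stats$feature == "delta_t"],
                       stats$max[stats$feature == "delta_t"]))
    xn <- cbind(xn, delta_t = dtn)
    mask <- cbind(mask, delta_t = TRUE)
    xi <- xn
    xi[, seq_len(ncol(xn) - 1)] <-
      locf_matrix(xn[, seq_len(ncol(xn) - 1), drop = FALSE], fallback)
    x_list[[pid]] <- xn; m_list[[pid]] <- mask; xi_list[[pid]] <- xi
  }

  raw_missing <- 1 - nrow(obs) /
    (sum(vapply(x_list, nrow, integer(1))) * nrow(feat))
  agg_missing <- 1 - mean(unlist(lapply(m_list, function(m) m[, -ncol(m)])))

  structure(list(
    x = x_list, x_imp = xi_list, mask = m_list,
    lengths = vapply(x_list, nrow, integer(1)),
    patient_id = pids,
    features = dplyr::bind_rows(feat,
                                tibble::tibble(feature = "delta_t",
                                               category = "interval")),
    stats = stats, items = kept,
    meta = dplyr::filter(meta, .data$patient_id %in% pids),
    report = list(n_dropped_short = dropped,
                  missing_rate_aggregated = agg_missing,
                  missing_rate_raw_cells = max(0, raw_missing)),
    config = config
  ), class = "ehr_tensor")
}

#' @export
print.ehr_tensor <- function(x, ...) {
  cat(sprintf(
    "<ehr_tensor> %d patients, %d features (+interval), lengths %d-%d, %.1f%% missing\n",
    length(x$x), nrow(x$features) - 1L, min(x$lengths), max(x$lengths),
    100 * x$report$missing_rate_aggregated))
  invisible(x)
}

#' Convert a synthetic cohort directly to a model-ready tensor
#'
#' Shortcut that bypasses the CSV round trip: the cohort's coded/continuous
#' item matrices become the observation tensor through the same
#' normalization, interval-channel, and LOCF steps as [build_ehr_tensor()],
#' keeping all items (no abnormal-count selection) so the generator's planted
#' structure stays intact.
#'
#' @param cohort A `synthetic_cohort`.
#' @return An `ehr_tensor`.
#' @export
as_ehr_tensor <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  feat <- tibble::tibble(feature = cohort$items$item,
                         category = cohort$items$category)
  all_x <- do.call(rbind, lapply(cohort$sequences, `[[`, "x"))
  stats <- tibble::tibble(
    feature = c(feat$feature, "delta_t"),
    min = c(suppressWarnings(apply(all_x, 2, min, na.rm = TRUE)), 0),
    max = c(suppressWarnings(apply(all_x, 2, max, na.rm = TRUE)), 0)
  )
  col_mean <- colMeans(all_x, na.rm = TRUE)

  x_list <- list(); m_list <- list(); xi_list <- list()
  for (s in cohort$sequences) {
    xn <- s$x
    for (j in seq_len(ncol(xn))) {
      xn[, j] <- suppressWarnings(
        minmax_normalize(
          if (all(is.na(xn[, j]))) rep(col_mean[j], nrow(xn)) else xn[, j],
          stats$min[j], stats$max[j]))
    }
    if (any(is.na(xn) & s$mask)) xn[is.na(xn) & s$mask] <- 0
    xn <- cbind(xn, delta_t = 0)
    mask <- cbind(s$mask, delta_t = TRUE)
    xn[!mask] <- NA_real_
    fallback <- (col_mean - stats$min[-nrow(stats)]) /
      pmax(stats$max[-nrow(stats)] - stats$min[-nrow(stats)], 1e-12)
    fallback[!is.finite(fallback)] <- 0
    xi <- xn
    xi[, seq_len(ncol(xn) - 1)] <-
      locf_matrix(xn[, seq_len(ncol(xn) - 1), drop = FALSE], fallback)
    pid <- s$patient_id
    x_list[[pid]] <- xn; m_list[[pid]] <- mask; xi_list[[pid]] <- xi
  }
  structure(list(
    x = x_list, x_imp = xi_list, mask = m_list,
    lengths = vapply(x_list, nrow, integer(1)),
    patient_id = names(x_list),
    features = dplyr::bind_rows(feat,
                                tibble::tibble(feature = "delta_t",
                                               category = "interval")),
    stats = stats, items = NULL,
    meta = cohort$meta,
    report = list(n_dropped_short = 0L,
                  missing_rate_aggregated = 1 - mean(unlist(
                    lapply(m_list, function(m) m[, -ncol(m)]))),
                  missing_rate_raw_cells = NA_real_),
    config = NULL
  ), class = "ehr_tensor")
}
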