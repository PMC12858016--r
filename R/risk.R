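#' 1-D order-1 Wasserstein distance between discrete distributions
#'
#' Closed-form earth mover's distance on the real line for two probability
#' vectors on a shared ordered support: the sum over support gaps of the
#' absolute CDF difference times the gap width. Equivalent to the
#' minimum-cost-coupling definition in one dimension.
#'
#' @param support Strictly increasing numeric vector.
#' @param wa,wb Nonnegative weight vectors on `support`, each summing to 1.
#' @return Nonnegative scalar.
#' @export
wasserstein_1d <- function(support, wa, wb) {
  m <- length(support)
  if (length(wa) != m || length(wb) != m) abort("weights must match the support")
  if (is.unsorted(support, strictly = TRUE)) abort("support must be strictly increasing")
  if (any(wa < 0) || any(wb < 0) ||
      abs(sum(wa) - 1) > 1e-9 || abs(sum(wb) - 1) > 1e-9) {
    abort("weights must be nonnegative and sum to 1")
  }
  if (m == 1) return(0)
  cdf_gap <- abs(cumsum(wa) - cumsum(wb))[-m]
  sum(cdf_gap * diff(support))
}

#' Per-cluster empirical distributions of coded test items
#'
#' Associates every originally observed coded laboratory cell with the
#' cluster label of its (patient, time) latent point and tallies, per item
#' and cluster, the empirical distribution over the coded support
#' \{0 = abnormally low, 0.5 = normal, 1 = abnormally high\}. Only observed
#' cells (mask = 1) contribute; values parked at masked cells are ignored.
#'
#' @param tensor An `ehr_tensor` (coded lab features are selected by their
#'   `"lab"` category).
#' @param labels Tibble `(patient_id, t, cluster)` covering every retained
#'   time point (e.g. from [cluster_latents()]).
#' @param cells `"observed"` (default) tallies only originally observed
#'   cells; `"completed"` tallies every cell using the model-completed
#'   matrices (`x_model` from [impute_missing()], falling back to the LOCF
#'   completion) rounded to the nearest code.
#' @return Tibble `(item, cluster, p_low, p_normal, p_high, n_obs)`.
#' @export
cluster_item_distributions <- function(tensor, labels,
                                       cells = c("observed", "completed")) {
  stopifnot(inherits(tensor, "ehr_tensor"),
            all(c("patient_id", "t", "cluster") %in% names(labels)))
  cells <- match.arg(cells)
  lab_cols <- tensor$features$feature[tensor$features$category == "lab"]
  long <- purrr::map_dfr(seq_along(tensor$x), function(i) {
    if (cells == "observed") {
      x <- tensor$x[[i]][, lab_cols, drop = FALSE]
      m <- tensor$mask[[i]][, lab_cols, drop = FALSE]
    } else {
      src <- if (!is.null(tensor$x_model)) tensor$x_model else tensor$x_imp
      x <- src[[i]][, lab_cols, drop = FALSE]
      x <- round(x * 2) / 2          # snap completions to the coded support
      x <- pmin(1, pmax(0, x))
      m <- matrix(TRUE, nrow(x), ncol(x))
    }
    obs <- which(m, arr.ind = TRUE)
    tibble::tibble(patient_id = tensor$patient_id[i],
                   t = obs[, 1], item = lab_cols[obs[, 2]],
                   value = x[obs])
  })
  long |>
    dplyr::inner_join(labels, by = c("patient_id", "t")) |>
    dplyr::group_by(.data$item, .data$cluster) |>
    dplyr::summarise(
      p_low = mean(.data$value == 0), p_normal = mean(.data$value == 0.5),
      p_high = mean(.data$value == 1), n_obs = dplyr::n(), .groups = "drop")
}

#' Summed pairwise Wasserstein statistic per item
#'
#' For every item with a defined distribution in all three clusters, computes
#' the three pairwise 1-Wasserstein distances on the coded support and their
#' sum W — the between-cluster distributional-difference score used to rank
#' temporal risk factors. Items with fewer than `min_obs` observations in
#' any cluster are flagged and excluded from scoring.
#'
#' @param dists Output of [cluster_item_distributions()] with exactly three
#'   distinct cluster labels.
#' @param min_obs Minimum per-cluster observation count for an item to be
#'   scored (default 30).
#' @return A `risk_score_table` tibble: one row per scored item with `w`,
#'   the three pairwise terms, and per-cluster proportions; unscored items
#'   are kept in the `skipped` attribute.
#' @export
w_statistic <- function(dists, min_obs = 30) {
  cl <- sort(unique(dists$cluster))
  if (length(cl) != 3) abort("exactly three clusters are required")
  wide <- dists |>
    tidyr::pivot_wider(names_from = "cluster",
                       values_from = c("p_low", "p_normal", "p_high", "n_obs"))
  complete <- stats::complete.cases(wide)
  nmin <- do.call(pmin, c(wide[paste0("n_obs_", cl)], na.rm = FALSE))
  ok <- complete & !is.na(nmin) & nmin >= min_obs
  skipped <- wide$item[!ok]
  if (length(skipped)) {
    warn(sprintf("%d item(s) lack %d observations in some cluster and are not scored",
                 length(skipped), min_obs))
  }
  wide <- wide[ok, , drop = FALSE]
  support <- c(0, 0.5, 1)
  dist_of <- function(row, k) {
    unlist(row[paste0(c("p_low_", "p_normal_", "p_high_"), k)], use.names = FALSE)
  }
  pair <- function(row, a, b) wasserstein_1d(support, dist_of(row, a), dist_of(row, b))
  scored <- purrr::map_dfr(seq_len(nrow(wide)), function(i) {
    row <- wide[i, ]
    w12 <- pair(row, cl[1], cl[2]); w23 <- pair(row, cl[2], cl[3])
    w31 <- pair(row, cl[3], cl[1])
    tibble::tibble(item = row$item, w = w12 + w23 + w31,
                   w_12 = w12, w_23 = w23, w_31 = w31)
  })
  out <- dplyr::left_join(scored, wide, by = "item")
  attr(out, "skipped") <- skipped
  attr(out, "clusters") <- cl
  class(out) <- c("risk_score_table", class(out))
  out
}

#' Rank items by the W statistic
#'
#' Orders scored items by descending W (ties broken lexicographically by item
#' code) and returns the top `top_n` with their per-cluster coded-value
#' proportions, the layout consumed by the bubble-plot summary.
#'
#' @param scores A `risk_score_table` from [w_statistic()].
#' @param top_n Number of leading items to keep (default 10).
#' @return The ranked subset with a `rank` column.
#' @export
rank_items <- function(scores, top_n = 10) {
  if (nrow(scores) < top_n) {
    warn(sprintf("only %d scored item(s); returning all", nrow(scores)))
  }
  out <- scores |>
    dplyr::arrange(dplyr::desc(.data$w), .data$item) |>
    dplyr::slice_head(n = min(top_n, nrow(scores))) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
  class(out) <- c("risk_score_table", setdiff(class(out), "risk_score_table"))
  attr(out, "clusters") <- attr(scores, "clusters")
  out
}

#' Risk-factor ranking stratified by drug exposure
#'
#' Re-runs the distribution / W-statistic / ranking pipeline on the
#' sub-cohort of patients who ever received each drug of the panel
#' (patient-level exposure from the semicolon-separated `drugs` metadata
#' column).
#'
#' @param tensor An `ehr_tensor` whose `meta` carries a `drugs` column.
#' @param labels Cluster labels as in [cluster_item_distributions()].
#' @param drugs Character vector of drug names to stratify by.
#' @param top_n,min_obs Passed to [rank_items()] / [w_statistic()].
#' @param min_patients Strata with fewer exposed patients are skipped with a
#'   warning (default 10).
#' @return Named list of ranked `risk_score_table`s, one per retained drug.
#' @export
stratify_by_drug <- function(tensor, labels, drugs, top_n = 10, min_obs = 30,
                             min_patients = 10) {
  stopifnot(length(drugs) >= 1, "drugs" %in% names(tensor$meta))
  membership <- strsplit(tensor$meta$drugs, ";", fixed = TRUE)
  out <- list()
  for (d in drugs) {
    pids <- tensor$meta$patient_id[vapply(membership, function(v) d %in% trimws(v), TRUE)]
    if (length(pids) < min_patients) {
      warn(sprintf("drug %s: only %d exposed patient(s), skipped", d, length(pids)))
      next
    }
    sub <- subset_tensor(tensor, pids)
    sub_labels <- dplyr::filter(labels, .data$patient_id %in% pids)
    dists <- cluster_item_distributions(sub, sub_labels)
    out[[d]] <- rank_items(suppressWarnings(w_statistic(dists, min_obs)), top_n)
  }
  out
}

# restrict an ehr_tensor to a patient subset, preserving frozen statistics
subset_tensor <- function(tensor, pids) {
  keep <- tensor$patient_id %in% pids
  tensor$x <- tensor$x[keep]; tensor$x_imp <- tensor$x_imp[keep]
  tensor$mask <- tensor$mask[keep]
  tensor$lengths <- tensor$lengths[keep]
  tensor$patient_id <- tensor$patient_id[keep]
  tensor$meta <- dplyr::filter(tensor$meta, .data$patient_id %in% pids)
  tensor
}

#' @rdname w_statistic
#' @param object A `risk_score_table`.
#' @param ... Unused.
#' @method autoplot risk_score_table
#' @export
autoplot.risk_score_table <- function(object, ...) {
  cl <- attr(object, "clusters")
  long <- object |>
    dplyr::select("item", "w", dplyr::starts_with("p_")) |>
    tidyr::pivot_longer(dplyr::starts_with("p_"), names_to = "key",
                        values_to = "proportion") |>
    tidyr::separate_wider_regex(
      "key", c("p_", coding = "low|normal|high", "_", cluster = ".*")) |>
    dplyr::mutate(coding = factor(.data$coding, c("low", "normal", "high")),
                  item = stats::reorder(.data$item, .data$w))
  ggplot2::ggplot(long, ggplot2::aes(.data$coding, .data$item,
                                     size = .data$proportion,
                                     colour = .data$cluster)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.6),
                        alpha = 0.8) +
    ggplot2::scale_size_area(max_size = 8) +
    ggplot2::labs(x = "coded value", y = NULL, size = "proportion",
                  colour = "cluster",
                  title = "Per-cluster coded-value proportions (top W items)") +
    ggplot2::theme_minimal()
}
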