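latent_matrix <- function(latents) {
  zc <- grep("^z[0-9]+$", names(latents), value = TRUE)
  if (length(zc) == 0) abort("no latent columns z1..zK found")
  as.matrix(latents[, zc])
}

#' Select the number of latent-state clusters
#'
#' Fits seeded k-means (10 restarts) for every candidate `k`, recording the
#' mean silhouette score and a scale-free variance of cluster sizes
#' (population variance of member counts divided by `(n/k)^2`). The chosen
#' `k` maximizes the silhouette; ties break toward lower size variance, then
#' smaller `k`. Silhouettes are evaluated on a seeded subsample of at most
#' `silhouette_cap` points, since the index is quadratic in the number of
#' points.
#'
#' @param latents Tibble of pooled latent states with columns `z1..zK`
#'   (native-space posterior means, one row per patient-time point).
#' @param k_grid Candidate cluster counts (default 2:8).
#' @param seed Integer seed.
#' @param silhouette_cap Maximum points entering the silhouette computation.
#' @return List with the chosen `k` and the selection `trace` tibble.
#' @export
choose_k <- function(latents, k_grid = 2:8, seed = 1L, silhouette_cap = 2000L) {
  Z <- latent_matrix(latents)
  if (nrow(unique(Z)) <= max(k_grid)) abort("pooled latents are degenerate for this k grid")
  sub <- with_seed(derive_seed(seed, "silhouette"),
                   sample.int(nrow(Z), min(nrow(Z), silhouette_cap)))
  dsub <- stats::dist(Z[sub, , drop = FALSE])
  trace <- purrr::map_dfr(k_grid, function(k) {
    km <- with_seed(derive_seed(seed, paste0("kmeans", k)),
                    stats::kmeans(Z, centers = k, nstart = 10, iter.max = 50))
    sil <- mean(cluster::silhouette(km$cluster[sub], dsub)[, "sil_width"])
    sizes <- tabulate(km$cluster, k)
    tibble::tibble(k = k, silhouette = sil,
                   size_variance = mean((sizes - mean(sizes))^2) /
                     (nrow(Z) / k)^2)
  })
  best <- trace |>
    dplyr::arrange(dplyr::desc(.data$silhouette), .data$size_variance, .data$k)
  list(k = best$k[1], trace = trace)
}

#' Cluster pooled latent states with k-means
#'
#' Stratifies every (patient, time) latent point into `k` clusters on the
#' native latent space (never on 2-D embeddings). Deterministic given the
#' seed.
#'
#' @param latents Pooled latent tibble (`patient_id`, `t`, `z1..zK`).
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @return A `cluster_model`: `k`, `centroids`, `labels` tibble
#'   (`patient_id`, `t`, `cluster`), within-cluster sum of squares, and
#'   unset `roles`.
#' @export
cluster_latents <- function(latents, k, seed = 1L) {
  Z <- latent_matrix(latents)
  if (k > nrow(Z)) abort("k exceeds the number of latent points")
  km <- with_seed(derive_seed(seed, "cluster_latents"),
                  stats::kmeans(Z, centers = k, nstart = 10, iter.max = 50))
  structure(list(
    k = k, centroids = km$centers,
    labels = tibble::tibble(patient_id = latents$patient_id, t = latents$t,
                            cluster = km$cluster),
    tot_withinss = km$tot.withinss,
    roles = NULL, seed = seed
  ), class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k = %d on %d points", x$k, nrow(x$labels)))
  if (!is.null(x$roles)) {
    cat(": ", paste(sprintf("%d=%s", x$roles$cluster, x$roles$role), collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Assign dangerous / intermediate / stable roles to clusters
#'
#' Each patient's endpoint is the cluster of their final retained time
#' point. The cluster with the highest deceased fraction among endpoint
#' events becomes the dangerous state, the lowest the stable state, and the
#' remaining one the intermediate state (k = 3 required). Exact ties and
#' clusters without endpoints fall back to cluster-index order with a
#' warning.
#'
#' @param model A `cluster_model` with `k = 3`.
#' @param death_flags Tibble (`patient_id`, `death_flag` in \{0, 1\}).
#' @return The model with a `roles` tibble (`cluster`, `role`,
#'   `deceased_fraction`, `n_endpoints`).
#' @export
assign_roles <- function(model, death_flags) {
  stopifnot(inherits(model, "cluster_model"))
  if (model$k != 3) abort("role assignment requires exactly 3 clusters")
  endpoints <- model$labels |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice_max(.data$t, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::inner_join(death_flags, by = "patient_id")
  stats_tbl <- tibble::tibble(cluster = seq_len(3)) |>
    dplyr::left_join(
      endpoints |>
        dplyr::group_by(.data$cluster) |>
        dplyr::summarise(deceased_fraction = mean(.data$death_flag),
                         n_endpoints = dplyr::n(), .groups = "drop"),
      by = "cluster") |>
    dplyr::mutate(n_endpoints = dplyr::coalesce(.data$n_endpoints, 0L))
  if (any(stats_tbl$n_endpoints == 0)) {
    warn("cluster(s) without endpoint events; roles for them follow index order")
  }
  if (anyDuplicated(stats_tbl$deceased_fraction[!is.na(stats_tbl$deceased_fraction)])) {
    warn("tied deceased fractions; breaking ties by cluster index")
  }
  ord <- order(-dplyr::coalesce(stats_tbl$deceased_fraction, -Inf),
               stats_tbl$cluster)
  stats_tbl$role <- NA_character_
  stats_tbl$role[ord] <- c("dangerous", "intermediate", "stable")
  model$roles <- stats_tbl[, c("cluster", "role", "deceased_fraction", "n_endpoints")]
  model
}

#' @rdname cluster_latents
#' @param x A `cluster_model`.
#' @param ... Unused.
#' @method tidy cluster_model
#' @export
tidy.cluster_model <- function(x, ...) {
  out <- x$labels |>
    dplyr::count(.data$cluster, name = "n_points")
  if (!is.null(x$roles)) out <- dplyr::left_join(out, x$roles, by = "cluster")
  out
}

#' Markov transition summaries between latent-state clusters
#'
#' Counts consecutive-step cluster transitions (self-transitions included)
#' within each patient, tallied separately for all, deceased and surviving
#' patients, and row-normalizes the counts into transition probabilities.
#'
#' @param labels Tibble (`patient_id`, `t`, `cluster`) with at least two
#'   steps per patient, or a `cluster_model`.
#' @param death_flags Tibble (`patient_id`, `death_flag`).
#' @param k Number of clusters (inferred from labels when missing).
#' @return A `transition_summary`: lists `counts` and `probs` with
#'   `k x k` matrices for groups `all`, `deceased`, `surviving`.
#' @export
transition_matrices <- function(labels, death_flags, k = NULL) {
  if (inherits(labels, "cluster_model")) {
    k <- k %||% labels$k
    labels <- labels$labels
  }
  k <- k %||% max(labels$cluster)
  lab <- labels |>
    dplyr::arrange(.data$patient_id, .data$t) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(to = dplyr::lead(.data$cluster)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$to)) |>
    dplyr::left_join(death_flags, by = "patient_id")
  tally <- function(df) {
    m <- matrix(0L, k, k, dimnames = list(seq_len(k), seq_len(k)))
    if (nrow(df)) {
      tb <- table(factor(df$cluster, seq_len(k)), factor(df$to, seq_len(k)))
      m[] <- as.integer(tb)
    }
    m
  }
  groups <- list(all = lab,
                 deceased = dplyr::filter(lab, .data$death_flag == 1),
                 surviving = dplyr::filter(lab, .data$death_flag == 0))
  if (any(vapply(groups, nrow, 1L) == 0)) warn("empty patient group: zero matrices")
  counts <- lapply(groups, tally)
  probs <- lapply(counts, function(m) {
    rs <- rowSums(m)
    p <- m / ifelse(rs > 0, rs, 1)
    p[rs == 0, ] <- 0
    p
  })
  structure(list(counts = counts, probs = probs, k = k),
            class = "transition_summary")
}

#' @export
print.transition_summary <- function(x, ...) {
  cat(sprintf("<transition_summary> %d clusters, %d transitions (%d deceased, %d surviving)\n",
              x$k, sum(x$counts$all), sum(x$counts$deceased), sum(x$counts$surviving)))
  invisible(x)
}

#' @rdname transition_matrices
#' @param x A `transition_summary`.
#' @param ... Unused.
#' @method tidy transition_summary
#' @export
tidy.transition_summary <- function(x, ...) {
  purrr::map_dfr(names(x$counts), function(g) {
    idx <- expand.grid(from = seq_len(x$k), to = seq_len(x$k))
    tibble::tibble(group = g, from = idx$from, to = idx$to,
                   count = x$counts[[g]][cbind(idx$from, idx$to)],
                   prob = x$probs[[g]][cbind(idx$from, idx$to)])
  })
}

#' @rdname transition_matrices
#' @param object A `transition_summary`.
#' @method autoplot transition_summary
#' @export
autoplot.transition_summary <- function(object, ...) {
  df <- tidy.transition_summary(object)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$to), factor(.data$from),
                                   fill = .data$prob)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$prob)),
                       colour = "white", size = 3) +
    ggplot2::facet_wrap(~group) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "to cluster", y = "from cluster", fill = "probability",
                  title = "Cluster transition probabilities") +
    ggplot2::theme_minimal()
}

#' 2-D UMAP projection of pooled latent states
#'
#' Visualization-only embedding of the native latent space: the first
#' `skip_first_steps` steps of each patient are excluded (early posterior
#' estimates are unstable), patients may be downsampled for parameter
#' trials, and the embedding is seeded.
#'
#' @param latents Pooled latent tibble (`patient_id`, `t`, `z1..zK`).
#' @param n_neighbors UMAP neighborhood size (default 15).
#' @param min_dist UMAP minimum embedding distance (default 0.1).
#' @param skip_first_steps Leading steps per patient to exclude (default 3).
#' @param downsample_fraction Fraction of patients retained (default 1).
#' @param seed Integer seed.
#' @return Tibble (`patient_id`, `t`, `u1`, `u2`).
#' @export
project_umap <- function(latents, n_neighbors = 15, min_dist = 0.1,
                         skip_first_steps = 3, downsample_fraction = 1,
                         seed = 1L) {
  stopifnot(skip_first_steps >= 0,
            downsample_fraction > 0, downsample_fraction <= 1)
  kept <- dplyr::filter(latents, .data$t > skip_first_steps)
  if (downsample_fraction < 1) {
    pids <- unique(kept$patient_id)
    sel <- with_seed(derive_seed(seed, "downsample"),
                     sample(pids, max(1, floor(length(pids) * downsample_fraction))))
    kept <- dplyr::filter(kept, .data$patient_id %in% sel)
  }
  Z <- latent_matrix(kept)
  if (nrow(Z) <= n_neighbors) abort("fewer points than n_neighbors")
  emb <- with_seed(derive_seed(seed, "umap"),
                   uwot::umap(Z, n_neighbors = n_neighbors, min_dist = min_dist,
                              n_components = 2, n_threads = 1,
                              n_sgd_threads = 0))
  tibble::tibble(patient_id = kept$patient_id, t = kept$t,
                 u1 = emb[, 1], u2 = emb[, 2])
}

#' UMAP hyperparameter sensitivity sweep
#'
#' Re-embeds a patient downsample across a grid of neighborhood sizes and
#' reports, per grid value, the adjusted Rand index between k-means labels
#' computed in the native latent space and on the 2-D embedding — a
#' cluster-structure stability summary.
#'
#' @inheritParams project_umap
#' @param n_grid Neighborhood sizes to sweep (default c(15, 30, 50, 100)).
#' @param k Cluster count used for the stability comparison (default 3).
#' @return Tibble (`n_neighbors`, `ari`, `n_points`).
#' @export
umap_sweep <- function(latents, n_grid = c(15, 30, 50, 100), min_dist = 0.1,
                       skip_first_steps = 3, downsample_fraction = 0.1,
                       k = 3, seed = 1L) {
  kept <- dplyr::filter(latents, .data$t > skip_first_steps)
  pids <- unique(kept$patient_id)
  sel <- with_seed(derive_seed(seed, "sweep_downsample"),
                   sample(pids, max(1, floor(length(pids) * downsample_fraction))))
  kept <- dplyr::filter(kept, .data$patient_id %in% sel)
  native <- cluster_latents(kept, k, seed = derive_seed(seed, "sweep_native"))
  purrr::map_dfr(n_grid, function(n) {
    emb <- project_umap(kept, n_neighbors = n, min_dist = min_dist,
                        skip_first_steps = 0, seed = derive_seed(seed, paste0("sweep", n)))
    km <- with_seed(derive_seed(seed, paste0("sweep_km", n)),
                    stats::kmeans(as.matrix(emb[, c("u1", "u2")]), k,
                                  nstart = 10, iter.max = 50))
    tibble::tibble(n_neighbors = n,
                   ari = adjusted_rand_index(native$labels$cluster, km$cluster),
                   n_points = nrow(emb))
  })
}

#' Plot a 2-D embedding colored by cluster role
#'
#' @param embedding Output of [project_umap()].
#' @param model Optional `cluster_model` (with or without roles) whose
#'   labels color the points.
#' @return A ggplot object.
#' @export
plot_embedding <- function(embedding, model = NULL) {
  df <- embedding
  if (!is.null(model)) {
    lab <- model$labels
    if (!is.null(model$roles)) {
      lab <- dplyr::left_join(lab, model$roles[, c("cluster", "role")],
                              by = "cluster")
    } else lab$role <- factor(lab$cluster)
    df <- dplyr::inner_join(df, lab, by = c("patient_id", "t"))
  } else df$role <- "all"
  ggplot2::ggplot(df, ggplot2::aes(.data$u1, .data$u2, colour = .data$role)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(dangerous = "#d73027",
                                            intermediate = "#fee08b",
                                            stable = "#1a9850"),
                                 na.value = "grey50") +
    ggplot2::labs(x = "UMAP 1", y = "UMAP 2", colour = NULL,
                  title = "Latent states in 2-D") +
    ggplot2::theme_minimal()
}
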