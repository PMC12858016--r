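blob_latents <- function(k, n_per, sep = 10, sd = 1, d = 8, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(k * d), k, d)
  centers <- centers / sqrt(rowSums(centers^2)) * sep * sd
  Z <- do.call(rbind, lapply(seq_len(k), function(i) {
    sweep(matrix(rnorm(n_per * d, sd = sd), n_per, d), 2, centers[i, ], "+")
  }))
  n <- k * n_per
  tibble::tibble(patient_id = sprintf("P%03d", rep(seq_len(n %/% 5 + 1),
                                                   each = 5)[seq_len(n)]),
                 t = unlist(lapply(table(sprintf("P%03d", rep(seq_len(n %/% 5 + 1),
                                                              each = 5)[seq_len(n)])), seq_len)),
                 !!!setNames(as.data.frame(Z), paste0("z", seq_len(d))))
}

test_that("silhouette selection finds the true blob count", {
  for (s in 1:2) {
    lat3 <- blob_latents(3, 150, seed = s)
    expect_equal(choose_k(lat3, 2:6, seed = s)$k, 3)
  }
  lat2 <- blob_latents(2, 150, seed = 3)
  expect_equal(choose_k(lat2, 2:6, seed = 3)$k, 2)
  # singleton grid is trivial and traces one row
  sel <- choose_k(blob_latents(3, 60, seed = 4), k_grid = 3, seed = 4)
  expect_equal(sel$k, 3)
  expect_equal(nrow(sel$trace), 1)
  expect_error(choose_k(dplyr::mutate(lat2, dplyr::across(dplyr::starts_with("z"),
                                                          ~0))), "degenerate")
})

test_that("k-means on its own centroid set has zero inertia", {
  set.seed(5)
  cents <- matrix(rnorm(24), 3, 8)
  lat <- tibble::tibble(patient_id = sprintf("P%d", 1:9), t = 1L,
                        !!!setNames(as.data.frame(cents[rep(1:3, 3), ]),
                                    paste0("z", 1:8)))
  cm <- cluster_latents(lat, 3, seed = 1)
  expect_equal(cm$tot_withinss, 0)
  expect_equal(length(unique(cm$labels$cluster)), 3)
  expect_error(cluster_latents(lat, 99), "exceeds")
})

test_that("k-means matches the brute-force optimum on a tiny instance", {
  set.seed(6)
  Z <- rbind(matrix(rnorm(6, 0, .5), 3, 2), matrix(rnorm(6, 5, .5), 3, 2),
             matrix(rnorm(6, -5, .5), 3, 2))
  lat <- tibble::tibble(patient_id = sprintf("P%d", 1:9), t = 1L,
                        z1 = Z[, 1], z2 = Z[, 2])
  cm <- cluster_latents(lat, 3, seed = 2)
  # exhaustive search over all 3^9 assignments
  best <- Inf
  grid <- expand.grid(rep(list(1:3), 9))
  for (r in seq_len(nrow(grid))) {
    a <- unlist(grid[r, ])
    if (length(unique(a)) < 3) next
    ss <- sum(vapply(1:3, function(c3) {
      pts <- Z[a == c3, , drop = FALSE]
      sum(scale(pts, scale = FALSE)^2)
    }, numeric(1)))
    best <- min(best, ss)
  }
  expect_equal(cm$tot_withinss, best, tolerance = 1e-9)
})

make_model <- function(labels_df, k = 3) {
  structure(list(k = k, centroids = NULL, labels = labels_df,
                 tot_withinss = NA, roles = NULL, seed = 0),
            class = "cluster_model")
}

test_that("roles follow the deceased-endpoint ordering", {
  # endpoints: cluster 1 -> 90% deceased, cluster 2 -> 50%, cluster 3 -> 5%
  lab <- tibble::tibble(
    patient_id = sprintf("P%03d", 1:60),
    t = 1L,
    cluster = rep(1:3, each = 20))
  deaths <- tibble::tibble(
    patient_id = lab$patient_id,
    death_flag = c(rep(1, 18), rep(0, 2), rep(1, 10), rep(0, 10),
                   rep(1, 1), rep(0, 19)))
  m <- assign_roles(make_model(lab), deaths)
  expect_equal(m$roles$role[m$roles$cluster == 1], "dangerous")
  expect_equal(m$roles$role[m$roles$cluster == 2], "intermediate")
  expect_equal(m$roles$role[m$roles$cluster == 3], "stable")
  expect_equal(m$roles$deceased_fraction, c(0.9, 0.5, 0.05))

  # equal fractions: tie broken by cluster index with a warning
  deaths2 <- dplyr::mutate(deaths, death_flag = rep(c(1, 0), 30))
  expect_warning(m2 <- assign_roles(make_model(lab), deaths2), "tie")
  expect_equal(m2$roles$role, c("dangerous", "intermediate", "stable"))

  expect_error(assign_roles(make_model(lab, k = 2), deaths), "3 clusters")
})

test_that("role assignment is invariant to cluster relabeling and patient order", {
  set.seed(7)
  lab <- tibble::tibble(
    patient_id = rep(sprintf("P%03d", 1:30), each = 4),
    t = rep(1:4, 30),
    cluster = sample(1:3, 120, TRUE))
  deaths <- tibble::tibble(patient_id = sprintf("P%03d", 1:30),
                           death_flag = rbinom(30, 1, 0.4))
  m <- suppressWarnings(assign_roles(make_model(lab), deaths))
  sets <- function(model, lab_df) {
    lapply(c("dangerous", "intermediate", "stable"), function(r) {
      cl <- model$roles$cluster[model$roles$role == r]
      sort(paste(lab_df$patient_id, lab_df$t)[lab_df$cluster == cl])
    })
  }
  perm <- c(3, 1, 2)   # relabel clusters
  lab2 <- dplyr::mutate(lab, cluster = perm[cluster])
  m2 <- suppressWarnings(assign_roles(make_model(lab2), deaths))
  expect_identical(sets(m, lab), sets(m2, lab2))
  # shuffled patient order
  lab3 <- lab[sample(nrow(lab)), ]
  m3 <- suppressWarnings(assign_roles(make_model(lab3), deaths))
  expect_identical(m$roles$deceased_fraction, m3$roles$deceased_fraction)
})

test_that("transition tallies are hand-countable and conserve mass", {
  lab <- tibble::tibble(patient_id = "P1", t = 1:3, cluster = c(1L, 1L, 2L))
  deaths <- tibble::tibble(patient_id = "P1", death_flag = 0L)
  ts <- suppressWarnings(transition_matrices(lab, deaths, k = 3))
  expect_equal(unname(ts$counts$all),
               matrix(c(1, 1, 0, 0, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(unname(ts$probs$all[1, ]), c(0.5, 0.5, 0), ignore_attr = TRUE)
  expect_equal(sum(ts$counts$all), nrow(lab) - 1)

  # conservation and exact row normalization on a larger random fixture
  set.seed(8)
  lab2 <- purrr::map_dfr(1:20, function(i) {
    Tn <- sample(5:15, 1)
    tibble::tibble(patient_id = sprintf("P%02d", i), t = seq_len(Tn),
                   cluster = sample(1:3, Tn, TRUE))
  })
  deaths2 <- tibble::tibble(patient_id = sprintf("P%02d", 1:20),
                            death_flag = rbinom(20, 1, 0.5))
  ts2 <- transition_matrices(lab2, deaths2)
  lens <- table(lab2$patient_id)
  expect_equal(sum(ts2$counts$all), sum(lens - 1))
  expect_equal(ts2$counts$all, ts2$counts$deceased + ts2$counts$surviving)
  for (g in names(ts2$probs)) {
    rs <- rowSums(ts2$counts[[g]])
    live <- rs > 0
    expect_lt(max(abs(rowSums(ts2$probs[[g]][live, , drop = FALSE]) - 1)), 1e-12)
    # probs are exact normalizations: cross-multiplication check
    expect_equal(ts2$probs[[g]] * ifelse(rs > 0, rs, 1), ts2$counts[[g]] + 0,
                 ignore_attr = TRUE)
  }
})

test_that("estimated transition probabilities are consistent for a known chain", {
  P <- matrix(c(0.9, 0.07, 0.03,
                0.05, 0.9, 0.05,
                0.02, 0.08, 0.9), 3, 3, byrow = TRUE)
  co <- generate_cohort(synth_config(n_patients = 200, n_items = 10,
                                     regime_transition_matrix = P,
                                     abnormal_prob = array(0.1, c(3, 3, 2)),
                                     length_range = c(60, 60), seed = 13))
  ts <- transition_matrices(regime_labels(co), death_flags_of(co))
  expect_gte(sum(ts$counts$all), 1e4)
  expect_lt(max(abs(ts$probs$all - P)), 0.05)
})

test_that("UMAP projection drops leading steps, is seeded, and preserves blobs", {
  lat <- blob_latents(3, 120, seed = 9)
  emb <- project_umap(lat, n_neighbors = 15, seed = 3)
  expected_n <- nrow(lat) - sum(pmin(3, table(lat$patient_id)))
  expect_equal(nrow(emb), expected_n)
  expect_named(emb, c("patient_id", "t", "u1", "u2"))
  emb2 <- project_umap(lat, n_neighbors = 15, seed = 3)
  expect_identical(emb, emb2)
  expect_error(project_umap(lat[1:10, ], n_neighbors = 15), "n_neighbors")

  sweep <- umap_sweep(lat, n_grid = c(15, 30), downsample_fraction = 1,
                      skip_first_steps = 3, k = 3, seed = 5)
  expect_true(all(sweep$ari >= 0.8))
})
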