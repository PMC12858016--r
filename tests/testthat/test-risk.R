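test_that("1-D Wasserstein matches the exhaustive coupling oracle", {
  s <- c(0, 0.5, 1)
  expect_equal(wasserstein_1d(s, c(.2, .5, .3), c(.2, .5, .3)), 0)
  expect_equal(wasserstein_1d(s, c(1, 0, 0), c(0, 0, 1)), 1)
  expect_equal(wasserstein_1d(s, c(1, 0, 0), c(0, 1, 0)), 0.5)
  expect_error(wasserstein_1d(s, c(1, 0), c(0, 1)), "support")
  expect_error(wasserstein_1d(c(1, 0.5, 0), c(1, 0, 0), c(0, 0, 1)),
               "increasing")
  set.seed(1)
  for (i in 1:200) {
    a <- runif(3); a <- a / sum(a)
    b <- runif(3); b <- b / sum(b)
    sup <- sort(runif(3, 0, 2))
    expect_equal(wasserstein_1d(sup, a, b), wasserstein_lp_3pt(sup, a, b),
                 tolerance = 1e-9)
  }
})

test_that("wasserstein_1d is a metric on random instances", {
  set.seed(2)
  s <- c(0, 0.5, 1)
  rdist <- function() { a <- runif(3); a / sum(a) }
  for (i in 1:100) {
    a <- rdist(); b <- rdist(); cc <- rdist()
    expect_gte(wasserstein_1d(s, a, b), 0)
    expect_equal(wasserstein_1d(s, a, b), wasserstein_1d(s, b, a))
    expect_lte(wasserstein_1d(s, a, cc),
               wasserstein_1d(s, a, b) + wasserstein_1d(s, b, cc) + 1e-12)
  }
  expect_equal(wasserstein_1d(s, c(.3, .3, .4), c(.3, .3, .4)), 0)
})

hand_tensor <- function() {
  # 2 patients x 3 steps x 2 lab items with a hand-checkable layout
  x1 <- cbind(labA = c(0, 0.5, 1), labB = c(0.5, 0.5, 0))
  x2 <- cbind(labA = c(1, 1, 0.5), labB = c(0, 0.5, 0.5))
  m1 <- cbind(labA = c(TRUE, TRUE, FALSE), labB = rep(TRUE, 3))
  m2 <- cbind(labA = rep(TRUE, 3), labB = c(TRUE, FALSE, TRUE))
  x1[!m1] <- NA; x2[!m2] <- NA
  structure(list(
    x = list(P1 = x1, P2 = x2),
    x_imp = list(P1 = x1, P2 = x2),
    mask = list(P1 = m1, P2 = m2),
    lengths = c(P1 = 3L, P2 = 3L), patient_id = c("P1", "P2"),
    features = tibble::tibble(feature = c("labA", "labB"),
                              category = "lab"),
    meta = tibble::tibble(patient_id = c("P1", "P2"), sex = 0L,
                          death_flag = c(1L, 0L), drugs = ""),
    report = list()), class = "ehr_tensor")
}

test_that("per-cluster item distributions equal a hand tally and respect masks", {
  tn <- hand_tensor()
  labels <- tibble::tibble(patient_id = rep(c("P1", "P2"), each = 3),
                           t = rep(1:3, 2), cluster = c(1, 1, 2, 2, 2, 1))
  d <- cluster_item_distributions(tn, labels)
  # hand tally: labA cluster 1 sees P1 t1 (0), P1 t2 (0.5), P2 t3 (0.5)
  a1 <- dplyr::filter(d, item == "labA", cluster == 1)
  expect_equal(c(a1$p_low, a1$p_normal, a1$p_high), c(1 / 3, 2 / 3, 0))
  expect_equal(a1$n_obs, 3L)
  # labA cluster 2: P2 t1 (1), P2 t2 (1); P1 t3 masked
  a2 <- dplyr::filter(d, item == "labA", cluster == 2)
  expect_equal(c(a2$p_low, a2$p_normal, a2$p_high), c(0, 0, 1))
  expect_equal(a2$n_obs, 2L)

  # values parked at masked cells never leak
  tn2 <- tn
  tn2$x$P1[3, "labA"] <- 1
  tn2$x$P2[2, "labB"] <- 0
  expect_equal(cluster_item_distributions(tn2, labels), d)

  # a constant item yields point masses in every cluster
  tn3 <- tn
  tn3$x$P1[, "labB"] <- 0.5; tn3$x$P2[, "labB"] <- 0.5
  tn3$x$P1[!tn3$mask$P1] <- NA; tn3$x$P2[!tn3$mask$P2] <- NA
  d3 <- dplyr::filter(cluster_item_distributions(tn3, labels), item == "labB")
  expect_true(all(d3$p_normal == 1))
})

fake_dists <- function(tbl) {
  # tbl: item, cluster, weights list
  purrr::pmap_dfr(tbl, function(item, cluster, w, n) {
    tibble::tibble(item = item, cluster = cluster,
                   p_low = w[1], p_normal = w[2], p_high = w[3], n_obs = n)
  })
}

test_that("the W statistic sums the three pairwise distances exactly", {
  d <- fake_dists(tibble::tibble(
    item = "labA", cluster = c("I", "II", "III"),
    w = list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), n = 100))
  ws <- w_statistic(d, min_obs = 30)
  expect_equal(ws$w, 2)   # 0.5 + 0.5 + 1 on the unit support
  expect_equal(ws$w, ws$w_12 + ws$w_23 + ws$w_31)

  same <- fake_dists(tibble::tibble(
    item = "labB", cluster = c("I", "II", "III"),
    w = list(c(.2, .5, .3), c(.2, .5, .3), c(.2, .5, .3)), n = 50))
  expect_equal(w_statistic(same, min_obs = 30)$w, 0)

  # invariance under relabeling clusters I <-> III
  set.seed(3)
  rw <- function() { a <- runif(3); a / sum(a) }
  w1 <- rw(); w2 <- rw(); w3 <- rw()
  d1 <- fake_dists(tibble::tibble(item = "x", cluster = c("I", "II", "III"),
                                  w = list(w1, w2, w3), n = 40))
  d2 <- fake_dists(tibble::tibble(item = "x", cluster = c("I", "II", "III"),
                                  w = list(w3, w2, w1), n = 40))
  expect_equal(w_statistic(d1, 30)$w, w_statistic(d2, 30)$w)
  # W can never exceed 2 on the coded support
  expect_lte(w_statistic(d1, 30)$w, 2)
})

test_that("items below the observation floor are flagged, not scored", {
  d <- dplyr::bind_rows(
    fake_dists(tibble::tibble(item = "ok", cluster = c("I", "II", "III"),
                              w = list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                              n = 100)),
    fake_dists(tibble::tibble(item = "thin", cluster = c("I", "II", "III"),
                              w = list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                              n = c(100, 5, 100))))
  expect_warning(ws <- w_statistic(d, min_obs = 30), "not scored")
  expect_equal(ws$item, "ok")
  expect_equal(attr(ws, "skipped"), "thin")
})

test_that("ranking is by descending W with lexicographic ties and unit rows", {
  set.seed(4)
  items <- purrr::map_dfr(sprintf("it%02d", 1:12), function(nm) {
    w <- if (nm == "it05") list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)) else
      list(c(.2, .6, .2), c(.2, .6, .2), c(.2, .6, .2))
    fake_dists(tibble::tibble(item = nm, cluster = c("I", "II", "III"),
                              w = w, n = 60))
  })
  rk <- rank_items(w_statistic(items, 30), top_n = 10)
  expect_equal(rk$item[1], "it05")   # dominant item ranks first
  expect_equal(rk$rank, 1:10)
  # ties broken lexicographically by item code
  expect_identical(rk$item[-1], sort(rk$item[-1]))
  # per-cluster proportion rows sum to one
  for (cl in c("I", "II", "III")) {
    rows <- rk[[paste0("p_low_", cl)]] + rk[[paste0("p_normal_", cl)]] +
      rk[[paste0("p_high_", cl)]]
    expect_lt(max(abs(rows - 1)), 1e-12)
  }
})

test_that("planted risky items dominate the W ranking on synthetic cohorts", {
  hits <- vapply(1:3, function(s) {
    co <- generate_cohort(synth_config(n_patients = 150, n_items = 30,
                                       length_range = c(40, 40),
                                       missing_rate = 0.4, seed = 500 + s))
    tn <- as_ehr_tensor(co)
    d <- cluster_item_distributions(tn, regime_labels(co))
    rk <- rank_items(suppressWarnings(w_statistic(d, 30)),
                     top_n = ceiling(1.5 * length(co$planted_risky_items)))
    mean(co$planted_risky_items %in% rk$item)
  }, numeric(1))
  expect_gte(mean(hits), 0.8)
})

test_that("drug stratification reduces to the pooled table when everyone is exposed", {
  co <- generate_cohort(synth_config(n_patients = 40, n_items = 20,
                                     length_range = c(30, 30),
                                     missing_rate = 0.3, seed = 600))
  tn <- as_ehr_tensor(co)
  tn$meta$drugs <- "DrugX"
  labels <- regime_labels(co)
  pooled <- rank_items(suppressWarnings(
    w_statistic(cluster_item_distributions(tn, labels), 30)), 10)
  strat <- suppressWarnings(
    stratify_by_drug(tn, labels, c("DrugX", "Ghost"), top_n = 10, min_obs = 30))
  expect_named(strat, "DrugX")   # Ghost has no patients and is skipped
  expect_equal(strat$DrugX$item, pooled$item)
  expect_equal(strat$DrugX$w, pooled$w)
})

test_that("a drug-specific planted item tops only that drug's ranking", {
  wins <- vapply(1:3, function(s) {
    mk <- function(planted_lab, seed, prefix) {
      ap <- array(0.1, dim = c(3, 13, 2))
      sev <- seq(0, 1, length.out = 3)
      ap[, planted_lab, 1] <- 0.05 + 0.65 * sev
      ap[, planted_lab, 2] <- 0.05
      co <- generate_cohort(synth_config(n_patients = 60, n_items = 20,
                                         abnormal_prob = ap,
                                         length_range = c(30, 30),
                                         missing_rate = 0.3, seed = seed))
      for (i in seq_along(co$sequences)) {
        co$sequences[[i]]$patient_id <- paste0(prefix, co$sequences[[i]]$patient_id)
      }
      co$meta$patient_id <- paste0(prefix, co$meta$patient_id)
      co
    }
    base <- mk(1:2, 700 + s, "A")          # labs 1-2 risky for the majority
    drugged <- mk(9, 800 + s, "B")         # lab 9 risky only under the drug
    combined <- base
    combined$sequences <- c(base$sequences, drugged$sequences)
    combined$meta <- dplyr::bind_rows(base$meta, drugged$meta)
    combined$meta$drugs <- rep(c("", "DrugZ"), c(60, 60))
    tn <- as_ehr_tensor(combined)
    labels <- dplyr::bind_rows(regime_labels(base), regime_labels(drugged))
    pooled <- rank_items(suppressWarnings(
      w_statistic(cluster_item_distributions(tn, labels), 30)), 3)
    per_drug <- suppressWarnings(
      stratify_by_drug(tn, labels, "DrugZ", top_n = 3, min_obs = 30))
    (per_drug$DrugZ$item[1] == "lab09") && (pooled$item[1] != "lab09")
  }, logical(1))
  expect_gte(mean(wins), 2 / 3)
})
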