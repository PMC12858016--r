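# Independent analytic oracles used across the suite: an exact Kalman
# filter/smoother for linear-Gaussian state-space models, a simulator for
# such models, a transportation-polytope vertex-enumeration solver for the
# 1-D Wasserstein distance, and small fixture builders.

# Kalman filter log-likelihood for
#   z_1 ~ N(0, I),  z_t = A z_{t-1} + N(0, q_sd^2 I),  x_t = t(C) z_t + N(0, r_sd^2 I)
# with x an (T x D) matrix; returns loglik and filtered/smoothed means.
kalman_filter <- function(x, A, C, q_sd, r_sd) {
  Tn <- nrow(x); D <- ncol(x); k <- nrow(A)
  H <- t(C)
  Q <- diag(q_sd^2, k); R <- diag(r_sd^2, D)
  mu_p <- rep(0, k); P_p <- diag(k)
  ll <- 0
  mu_f <- matrix(0, Tn, k)
  P_f <- array(0, c(Tn, k, k)); P_pred <- array(0, c(Tn, k, k))
  mu_pred <- matrix(0, Tn, k)
  for (t in seq_len(Tn)) {
    if (t > 1) {
      mu_p <- as.vector(A %*% mu_f[t - 1, ])
      P_p <- A %*% P_f[t - 1, , ] %*% t(A) + Q
    }
    mu_pred[t, ] <- mu_p; P_pred[t, , ] <- P_p
    S <- H %*% P_p %*% t(H) + R
    v <- x[t, ] - as.vector(H %*% mu_p)
    ll <- ll - 0.5 * (D * log(2 * pi) + determinant(S)$modulus +
                        t(v) %*% solve(S, v))
    K <- P_p %*% t(H) %*% solve(S)
    mu_f[t, ] <- mu_p + as.vector(K %*% v)
    P_f[t, , ] <- (diag(k) - K %*% H) %*% P_p
  }
  list(loglik = as.numeric(ll), mu_filt = mu_f, P_filt = P_f,
       mu_pred = mu_pred, P_pred = P_pred)
}

kalman_smoother <- function(x, A, C, q_sd, r_sd) {
  kf <- kalman_filter(x, A, C, q_sd, r_sd)
  Tn <- nrow(x); k <- nrow(A)
  mu_s <- kf$mu_filt
  P_s <- kf$P_filt
  for (t in seq(Tn - 1, 1)) {
    J <- kf$P_filt[t, , ] %*% t(A) %*% solve(kf$P_pred[t + 1, , ])
    mu_s[t, ] <- kf$mu_filt[t, ] +
      as.vector(J %*% (mu_s[t + 1, ] - kf$mu_pred[t + 1, ]))
    P_s[t, , ] <- kf$P_filt[t, , ] +
      J %*% (P_s[t + 1, , ] - kf$P_pred[t + 1, , ]) %*% t(J)
  }
  list(mu_smooth = mu_s, loglik = kf$loglik)
}

# simulate n sequences of length Tn from the same LGSSM
lgssm_sim <- function(n, Tn, A, C, q_sd, r_sd, seed = 1) {
  set.seed(seed)
  k <- nrow(A); D <- ncol(C)
  lapply(seq_len(n), function(i) {
    z <- matrix(0, Tn, k)
    z[1, ] <- rnorm(k)
    for (t in 2:Tn) z[t, ] <- as.vector(A %*% z[t - 1, ]) + rnorm(k, sd = q_sd)
    x <- z %*% C + matrix(rnorm(Tn * D, sd = r_sd), Tn, D)
    list(z = z, x = x)
  })
}

# a random stable transition matrix (spectral radius < rho_max)
random_stable_A <- function(k, rho_max = 0.95) {
  A <- matrix(rnorm(k * k), k, k)
  rho <- max(Mod(eigen(A, only.values = TRUE)$values))
  A * (rho_max * runif(1, 0.5, 1) / rho)
}

# wrap a list of fully observed (T x D) matrices as an ehr_tensor
toy_tensor <- function(x_list, mask_list = NULL) {
  D <- ncol(x_list[[1]])
  feats <- tibble::tibble(feature = paste0("f", seq_len(D)),
                          category = rep("lab", D))
  x_list <- lapply(x_list, function(x) { colnames(x) <- feats$feature; x })
  if (is.null(mask_list)) {
    mask_list <- lapply(x_list, function(x) {
      m <- !is.na(x); m
    })
  } else {
    mask_list <- lapply(seq_along(mask_list), function(i) {
      m <- mask_list[[i]]; colnames(m) <- feats$feature; m
    })
  }
  xi <- lapply(seq_along(x_list), function(i) {
    x <- x_list[[i]]
    x[!mask_list[[i]]] <- NA_real_
    for (j in seq_len(ncol(x))) {
      x[, j] <- if (all(is.na(x[, j]))) 0.5 else ehrstate:::impute_locf(x[, j])
    }
    x
  })
  xo <- lapply(seq_along(x_list), function(i) {
    x <- x_list[[i]]; x[!mask_list[[i]]] <- NA_real_; x
  })
  pid <- sprintf("S%03d", seq_along(x_list))
  names(xo) <- names(xi) <- names(mask_list) <- pid
  structure(list(
    x = xo, x_imp = xi, mask = mask_list,
    lengths = vapply(xo, nrow, integer(1)), patient_id = pid,
    features = feats, stats = NULL, items = NULL,
    meta = tibble::tibble(patient_id = pid, sex = 0L, death_flag = 0L,
                          drugs = ""),
    report = list(), config = NULL
  ), class = "ehr_tensor")
}

# Exact 1-D Wasserstein on a 3-point support by vertex enumeration of the
# transportation polytope: the 3x3 coupling has 4 free entries; every vertex
# of the feasible region solves 4 active constraints out of the 9
# nonnegativity constraints. The minimum transport cost over feasible
# vertices is the LP optimum.
wasserstein_lp_3pt <- function(support, a, b) {
  cost <- abs(outer(support, support, "-"))
  # free variables v = (P11, P12, P21, P22); remaining entries are affine in v
  # rows of G express each P_ij as g0 + G v >= 0
  G <- rbind(
    c(1, 0, 0, 0), c(0, 1, 0, 0), c(-1, -1, 0, 0),
    c(0, 0, 1, 0), c(0, 0, 0, 1), c(0, 0, -1, -1),
    c(-1, 0, -1, 0), c(0, -1, 0, -1), c(1, 1, 1, 1))
  g0 <- c(0, 0, a[1], 0, 0, a[2], b[1], b[2], 1 - a[1] - a[2] - b[1] - b[2])
  entry_cost <- c(cost[1, 1], cost[1, 2], cost[1, 3],
                  cost[2, 1], cost[2, 2], cost[2, 3],
                  cost[3, 1], cost[3, 2], cost[3, 3])
  best <- Inf
  combs <- utils::combn(9, 4)
  for (i in seq_len(ncol(combs))) {
    sel <- combs[, i]
    M <- G[sel, , drop = FALSE]
    if (abs(det(M)) < 1e-10) next
    v <- solve(M, -g0[sel])
    p <- g0 + as.vector(G %*% v)
    if (any(p < -1e-9)) next
    best <- min(best, sum(entry_cost * p))
  }
  best
}

# ground-truth latent tibble of a synthetic cohort
true_latents <- function(cohort) {
  purrr::map_dfr(cohort$sequences, function(s) {
    z <- s$z; colnames(z) <- paste0("z", seq_len(ncol(z)))
    dplyr::bind_cols(
      tibble::tibble(patient_id = s$patient_id, t = seq_len(nrow(z))),
      tibble::as_tibble(z))
  })
}

# true regime labels formatted as cluster labels
regime_labels <- function(cohort) {
  purrr::map_dfr(cohort$sequences, function(s) {
    tibble::tibble(patient_id = s$patient_id, t = seq_along(s$regimes),
                   cluster = s$regimes)
  })
}

death_flags_of <- function(cohort) cohort$meta[, c("patient_id", "death_flag")]
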