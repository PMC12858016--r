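# Comparison latent-state estimators under the same 8-dimensional budget:
# PCA (linear, no temporal structure), a row-wise VAE (nonlinear, no
# temporal structure), and the linearized state-space model (temporal,
# affine). All emit the same pooled latent tibble (patient_id, t, z1..zK)
# as infer_latent(), so the downstream clustering runs unchanged.

pooled_rows <- function(tensor) {
  do.call(rbind, tensor$x_imp)
}

pooled_index <- function(tensor) {
  tibble::tibble(
    patient_id = rep(tensor$patient_id, tensor$lengths),
    t = unname(unlist(lapply(tensor$lengths, seq_len)))
  )
}

latents_tibble <- function(tensor, Z) {
  colnames(Z) <- paste0("z", seq_len(ncol(Z)))
  dplyr::bind_cols(pooled_index(tensor), tibble::as_tibble(Z))
}

#' PCA baseline latent states
#'
#' Projects all pooled patient-time rows (LOCF-completed, since PCA has no
#' missing-data mechanism) onto the top principal components.
#'
#' @param tensor An `ehr_tensor`.
#' @param latent_dim Number of components (default 8).
#' @return A `pca_fit`: `latents` tibble (`patient_id`, `t`, `z1..zK`),
#'   the `prcomp` object, and the per-component variance explained.
#' @export
fit_pca <- function(tensor, latent_dim = 8) {
  X <- pooled_rows(tensor)
  r <- qr(scale(X, scale = FALSE))$rank
  if (r < latent_dim) {
    warn(sprintf("data rank %d < %d requested components; returning %d", r, latent_dim, r))
    latent_dim <- r
  }
  pc <- stats::prcomp(X, rank. = latent_dim)
  structure(list(
    latents = latents_tibble(tensor, pc$x[, seq_len(latent_dim), drop = FALSE]),
    prcomp = pc,
    variance_explained = pc$sdev^2 / sum(pc$sdev^2)
  ), class = "pca_fit")
}

vae_init <- function(D, hidden, dz, seed) {
  with_seed(derive_seed(seed, "vae_init"), {
    list(W1 = init_mat(D, hidden), b1 = rep(0, hidden),
         W2 = init_mat(hidden, hidden), b2 = rep(0, hidden),
         Wm = init_mat(hidden, dz), bm = rep(0, dz),
         Ws = init_mat(hidden, dz) * 0.1, bs = rep(softplus_inv(0.5), dz),
         V1 = init_mat(dz, hidden), c1 = rep(0, hidden),
         V2 = init_mat(hidden, D), c2 = rep(0.5, D),
         r = rep(softplus_inv(0.2), D))
  })
}

vae_fb <- function(p, X, eps, want_grads = FALSE) {
  B <- nrow(X); D <- ncol(X)
  h1 <- tanh(X %*% p$W1 + row_bias(p$b1, B))
  h2 <- tanh(h1 %*% p$W2 + row_bias(p$b2, B))
  qm <- h2 %*% p$Wm + row_bias(p$bm, B)
  aqs <- h2 %*% p$Ws + row_bias(p$bs, B)
  qs <- std_head(aqs)
  z <- qm + qs * eps
  d1 <- tanh(z %*% p$V1 + row_bias(p$c1, B))
  xm <- d1 %*% p$V2 + row_bias(p$c2, B)
  xs <- std_head(p$r)
  diff <- X - xm
  recon <- rowSums(-LOG_2PI_HALF - row_bias(log(xs), B) -
                     0.5 * (diff / row_bias(xs, B))^2)
  kl <- 0.5 * rowSums(qm^2 + qs^2 - 2 * log(qs) - 1)
  out <- list(elbo = recon - kl, q_mean = qm, kl = kl)
  if (!want_grads) return(out)

  g <- lapply(p, function(w) w * 0)
  xs_m <- row_bias(xs, B)
  dxm <- -(diff / xs_m^2) / B
  dr_vec <- -colSums(diff^2 / xs_m^3 - 1 / xs_m) / B
  g$r <- dr_vec * std_head_grad(p$r)
  dD1 <- (dxm %*% t(p$V2)) * (1 - d1^2)
  g$V2 <- t(d1) %*% dxm; g$c2 <- colSums(dxm)
  g$V1 <- t(z) %*% dD1; g$c1 <- colSums(dD1)
  dz_ <- dD1 %*% t(p$V1)
  dqm <- dz_ + qm / B
  dqs <- dz_ * eps + (qs - 1 / qs) / B
  daqs <- dqs * std_head_grad(aqs)
  dH2 <- (dqm %*% t(p$Wm) + daqs %*% t(p$Ws)) * (1 - h2^2)
  g$Wm <- t(h2) %*% dqm; g$bm <- colSums(dqm)
  g$Ws <- t(h2) %*% daqs; g$bs <- colSums(daqs)
  dH1 <- (dH2 %*% t(p$W2)) * (1 - h1^2)
  g$W2 <- t(h1) %*% dH2; g$b2 <- colSums(dH2)
  g$W1 <- t(X) %*% dH1; g$b1 <- colSums(dH1)
  out$grads <- g
  out
}

#' Row-wise variational autoencoder baseline
#'
#' A VAE on pooled patient-time rows with no temporal coupling: a
#' three-layer fully connected encoder (two tanh layers plus the Gaussian
#' mean/std heads) and a two-layer decoder, trained by reparameterized
#' gradient ascent on the ELBO. Rows are LOCF-completed, as the VAE has no
#' mask mechanism.
#'
#' @param tensor An `ehr_tensor`.
#' @param latent_dim Latent dimension (default 8).
#' @param hidden Hidden width (default 64).
#' @param epochs Training epochs (default 50).
#' @param learning_rate Adam step size (default 0.01).
#' @param batch_size Minibatch size (default 256).
#' @param seed Integer seed.
#' @return A `vae_fit`: `latents` tibble of encoder means, per-epoch `trace`
#'   (elbo, kl), and the parameter list.
#' @export
fit_vae <- function(tensor, latent_dim = 8, hidden = 64, epochs = 50,
                    learning_rate = 0.01, batch_size = 256, seed = 1L) {
  X <- pooled_rows(tensor)
  N <- nrow(X); D <- ncol(X)
  p <- vae_init(D, hidden, latent_dim, seed)
  st <- adam_state(p)
  trace <- tibble::tibble(epoch = seq_len(epochs), elbo = NA_real_, kl = NA_real_)
  for (e in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, paste0("vae_order", e)), sample.int(N))
    chunks <- split(ord, ceiling(seq_along(ord) / batch_size))
    tot <- 0; totkl <- 0
    for (ci in seq_along(chunks)) {
      idx <- chunks[[ci]]
      eps <- with_seed(derive_seed(seed, sprintf("vae_eps_%d_%d", e, ci)),
                       matrix(rnorm(length(idx) * latent_dim), length(idx), latent_dim))
      fb <- vae_fb(p, X[idx, , drop = FALSE], eps, want_grads = TRUE)
      if (!all(is.finite(fb$elbo))) {
        abort(sprintf("VAE training diverged at epoch %d", e))
      }
      up <- adam_step(p, fb$grads, st, learning_rate)
      p <- up$params; st <- up$state
      tot <- tot + sum(fb$elbo); totkl <- totkl + sum(fb$kl)
    }
    trace$elbo[e] <- tot / N; trace$kl[e] <- totkl / N
  }
  final <- vae_fb(p, X, matrix(0, N, latent_dim))
  structure(list(
    latents = latents_tibble(tensor, final$q_mean),
    trace = trace, params = p
  ), class = "vae_fit")
}

#' Linear state-space model baseline
#'
#' The linearized counterpart of the deep model: identical variational
#' training loop and masked bound, with every network replaced by an affine
#' map with Gaussian noise. See [train_dssm()].
#'
#' @param tensor An `ehr_tensor`.
#' @param ... Passed to [train_dssm()] (epochs, learning_rate, seed, ...).
#' @param latent_dim Latent dimension (default 8).
#' @return A `dssm_fit` with `flavor = "linear"`.
#' @export
fit_linear_ssm <- function(tensor, latent_dim = 8, ...) {
  train_dssm(tensor, latent_dim = latent_dim, flavor = "linear", ...)
}

#' Endpoint separation of deceased vs. surviving patients in latent space
#'
#' Takes each patient's final latent point and computes the mean silhouette
#' width of the two outcome groups (deceased vs. surviving) in the native
#' latent space — the quantitative counterpart of judging how clearly an
#' estimator's endpoint cloud separates the outcomes.
#'
#' @param latents Pooled latent tibble (`patient_id`, `t`, `z1..zK`).
#' @param death_flags Tibble (`patient_id`, `death_flag`).
#' @return Scalar mean silhouette width (larger = better separation).
#' @export
endpoint_separation <- function(latents, death_flags) {
  ep <- latents |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice_max(.data$t, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::inner_join(death_flags, by = "patient_id")
  if (length(unique(ep$death_flag)) < 2) abort("both outcome groups are required")
  Z <- latent_matrix(ep)
  mean(cluster::silhouette(ep$death_flag + 1L, stats::dist(Z))[, "sil_width"])
}

#' @rdname fit_vae
#' @param x A `vae_fit`.
#' @param ... Unused.
#' @method tidy vae_fit
#' @export
tidy.vae_fit <- function(x, ...) x$trace

#' @rdname fit_pca
#' @param x A `pca_fit`.
#' @param ... Unused.
#' @method tidy pca_fit
#' @export
tidy.pca_fit <- function(x, ...) {
  tibble::tibble(component = seq_along(x$variance_explained),
                 variance_explained = x$variance_explained)
}
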