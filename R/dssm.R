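#' KL divergence between diagonal Gaussians
#'
#' Closed-form Kullback-Leibler divergence `KL(q || p)` between two diagonal
#' Gaussian distributions, summed over dimensions.
#'
#' @param q_mean,q_sd Mean and standard deviation vectors of `q` (`q_sd > 0`).
#' @param p_mean,p_sd Mean and standard deviation vectors of `p` (defaults:
#'   the standard normal).
#' @return Nonnegative scalar.
#' @export
kl_diag_gaussian <- function(q_mean, q_sd, p_mean = 0, p_sd = 1) {
  if (any(q_sd <= 0) || any(p_sd <= 0)) abort("standard deviations must be positive")
  sum(log(p_sd / q_sd) + (q_sd^2 + (q_mean - p_mean)^2) / (2 * p_sd^2) - 0.5)
}

#' Fit the deep state-space model by variational inference
#'
#' Trains Gaussian transition, emission and amortized inference networks by
#' stochastic gradient ascent (Adam) on the mean per-patient masked evidence
#' lower bound: the reconstruction log-density is summed only over observed
#' cells, so missingness enters the objective solely through the mask. The
#' first `completion_from - 1` epochs feed the inference network
#' LOCF-completed inputs; from epoch `completion_from` onward the model's
#' own posterior-predictive emission means replace the missing input cells.
#'
#' @param tensor An `ehr_tensor` (see [build_ehr_tensor()] /
#'   [as_ehr_tensor()]); every sequence must have length at least 2.
#' @param latent_dim Latent dimension (default 8).
#' @param hidden Hidden width of every network (default 32).
#' @param epochs Training epochs (default 40).
#' @param learning_rate Adam step size (default 0.01).
#' @param batch_size Minibatch size (default 64; capped at the cohort size).
#' @param mc_samples Reparameterized draws per gradient step (default 1).
#' @param completion_from Epoch from which model-based input completion
#'   replaces LOCF (default 2); `Inf` keeps LOCF throughout.
#' @param flavor `"deep"` (tanh networks) or `"linear"` (all maps affine,
#'   the linearized baseline state-space model).
#' @param clip Global gradient-norm clip (default 10).
#' @param seed Integer seed; fits are bit-reproducible.
#' @param verbose Print the per-epoch bound.
#' @return A `dssm_fit` with elements `params`, `trace` (per-epoch mean
#'   ELBO), `dims`, `flavor`, `features`, `seed`.
#' @export
train_dssm <- function(tensor, latent_dim = 8, hidden = 32, epochs = 40,
                       learning_rate = 0.01, batch_size = 64, mc_samples = 1,
                       completion_from = 2, flavor = c("deep", "linear"),
                       clip = 10, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(tensor, "ehr_tensor"), epochs >= 1, learning_rate > 0)
  flavor <- match.arg(flavor)
  if (any(tensor$lengths < 2)) abort("all sequences must have length >= 2")
  big <- pack_batch(tensor)
  D <- big$D; B <- length(tensor$x)
  params <- dssm_init_params(D, hidden, latent_dim, flavor, seed)
  st <- adam_state(params)
  batch_size <- min(batch_size, B)
  dz <- latent_dim
  trace <- numeric(epochs)

  for (e in seq_len(epochs)) {
    if (e >= completion_from) {
      # model-based completion: emission means along the posterior mean path
      mp <- dssm_fb(params, big, array(0, c(B, big$Tm, dz)), keep_path = TRUE)
      for (t in seq_len(big$Tm)) {
        miss <- big$M[, t, ] == 0 & big$A[, t] == 1
        xt <- big$XI[, t, ]
        xt[miss] <- mp$emis_mean[[t]][miss]
        big$XI[, t, ] <- xt
      }
    }
    ord <- with_seed(derive_seed(seed, paste0("order", e)), sample.int(B))
    chunks <- split(ord, ceiling(seq_along(ord) / batch_size))
    tot <- 0
    for (ci in seq_along(chunks)) {
      bt <- slice_batch(big, chunks[[ci]])
      gsum <- NULL; esum <- 0
      for (s in seq_len(mc_samples)) {
        eps <- draw_eps(bt$B, bt$Tm, dz,
                        derive_seed(seed, sprintf("eps_%d_%d_%d", e, ci, s)))
        fb <- dssm_fb(params, bt, eps, want_grads = TRUE)
        esum <- esum + mean(fb$elbo)
        gsum <- if (is.null(gsum)) fb$grads else
          Map(`+`, gsum, fb$grads)
      }
      if (mc_samples > 1) gsum <- lapply(gsum, `/`, mc_samples)
      attributes(gsum) <- attributes(params)
      if (!is.finite(esum)) {
        abort(sprintf("training diverged (non-finite bound) at epoch %d", e))
      }
      up <- adam_step(params, gsum, st, learning_rate, clip = clip)
      params <- up$params; st <- up$state
      tot <- tot + (esum / mc_samples) * length(chunks[[ci]])
    }
    trace[e] <- tot / B
    if (verbose) message(sprintf("epoch %3d  mean ELBO %.3f", e, trace[e]))
  }

  structure(list(
    params = params,
    trace = tibble::tibble(epoch = seq_len(epochs), elbo = trace),
    dims = attr(params, "dims"), flavor = flavor,
    features = tensor$features, seed = seed,
    n_patients = B
  ), class = "dssm_fit")
}

#' @export
print.dssm_fit <- function(x, ...) {
  cat(sprintf(
    "<dssm_fit> %s state-space model: %d-dim latent, hidden %d, %d patients, %d epochs, final ELBO %.2f\n",
    x$flavor, x$dims$latent_dim, x$dims$hidden, x$n_patients,
    nrow(x$trace), utils::tail(x$trace$elbo, 1)))
  invisible(x)
}

resolve_params <- function(object) {
  if (inherits(object, "dssm_fit")) object$params
  else if (!is.null(attr(object, "dims"))) object
  else abort("expected a dssm_fit or a parameter list")
}

#' Masked evidence lower bound of a cohort
#'
#' Evaluates the per-patient evidence lower bound: masked reconstruction
#' log-density, initial-state KL against the standard-normal prior, and the
#' transition-consistency KLs, with expectations by seeded reparameterized
#' sampling. Inference-network inputs are completed from observed cells only
#' (LOCF plus the tensor's frozen fallback), so values stored at masked
#' cells cannot affect the result.
#'
#' @param object A `dssm_fit` or a raw parameter list (e.g. from
#'   [linear_gaussian_params()]).
#' @param tensor An `ehr_tensor`; all lengths must be at least 2.
#' @param mc_samples Number of Monte Carlo draws (default 1).
#' @param seed Seed for the draws.
#' @return Tibble (`patient_id`, `elbo`) with the Monte Carlo mean bound per
#'   patient; per-draw values are kept in the `draws` attribute.
#' @export
elbo <- function(object, tensor, mc_samples = 1, seed = 1L) {
  params <- resolve_params(object)
  stopifnot(inherits(tensor, "ehr_tensor"))
  if (any(tensor$lengths < 2)) {
    abort("sequences of length < 2 have no transition term; cannot evaluate")
  }
  big <- pack_batch(tensor)
  dz <- attr(params, "dims")$latent_dim
  draws <- matrix(0, big$B, mc_samples)
  for (s in seq_len(mc_samples)) {
    eps <- draw_eps(big$B, big$Tm, dz, derive_seed(seed, paste0("elbo", s)))
    draws[, s] <- dssm_fb(params, big, eps)$elbo
  }
  out <- tibble::tibble(patient_id = big$patient_id, elbo = rowMeans(draws))
  attr(out, "draws") <- draws
  out
}

#' Posterior latent trajectories
#'
#' Sequentially evaluates the variational posterior along the mean path
#' (each step conditions on the previous posterior mean) and returns the
#' per-time latent means and standard deviations.
#'
#' @param object A `dssm_fit`.
#' @param tensor An `ehr_tensor`.
#' @return Tibble `(patient_id, t, z1..zK, sd1..sdK)`, one row per retained
#'   patient-time point.
#' @export
infer_latent <- function(object, tensor) {
  params <- resolve_params(object)
  stopifnot(inherits(tensor, "ehr_tensor"))
  big <- pack_batch(tensor)
  dz <- attr(params, "dims")$latent_dim
  fb <- dssm_fb(params, big, array(0, c(big$B, big$Tm, dz)), keep_path = TRUE)
  purrr::map_dfr(seq_len(big$B), function(b) {
    Tb <- big$lengths[b]
    zm <- do.call(rbind, lapply(fb$q_mean[1:Tb], function(m) m[b, ]))
    zs <- do.call(rbind, lapply(fb$q_sd[1:Tb], function(m) m[b, ]))
    colnames(zm) <- paste0("z", seq_len(dz))
    colnames(zs) <- paste0("sd", seq_len(dz))
    dplyr::bind_cols(
      tibble::tibble(patient_id = big$patient_id[b], t = seq_len(Tb)),
      tibble::as_tibble(zm), tibble::as_tibble(zs))
  })
}

#' Model-based completion of missing observations
#'
#' Replaces masked cells with the emission means evaluated at the inferred
#' posterior-mean latents; observed cells pass through untouched.
#'
#' @param object A `dssm_fit`.
#' @param tensor An `ehr_tensor`.
#' @return The tensor with an extra per-patient list `x_model` of fully
#'   observed matrices.
#' @export
impute_missing <- function(object, tensor) {
  params <- resolve_params(object)
  big <- pack_batch(tensor)
  dz <- attr(params, "dims")$latent_dim
  fb <- dssm_fb(params, big, array(0, c(big$B, big$Tm, dz)), keep_path = TRUE)
  tensor$x_model <- setNames(lapply(seq_len(big$B), function(b) {
    Tb <- big$lengths[b]
    out <- tensor$x[[b]]
    em <- do.call(rbind, lapply(fb$emis_mean[1:Tb], function(m) m[b, ]))
    miss <- !tensor$mask[[b]]
    out[miss] <- em[miss]
    out
  }), big$patient_id)
  tensor
}

#' Exact linear-Gaussian parameters inside the model family
#'
#' Builds a parameter list of the linear flavor whose transition and
#' emission distributions equal a given linear-Gaussian state-space model
#' `z_t = A z_{t-1} + N(0, trans_sd^2 I)`, `x_t = C z_t + N(0, emis_sd^2 I)`,
#' with a standard-normal initial state. The inference network keeps its
#' (seeded) random initialization: any variational distribution yields a
#' valid lower bound on the exact marginal likelihood, which makes these
#' parameters the natural instrument for bound-validity checks against a
#' Kalman filter.
#'
#' @param A Square latent transition matrix (`k x k`).
#' @param C Emission loading matrix (`k x D`).
#' @param trans_sd,emis_sd Positive noise standard deviations (scalar or
#'   vector).
#' @param seed Seed for the inference-network initialization.
#' @return A parameter list accepted by [elbo()] and [infer_latent()].
#' @export
linear_gaussian_params <- function(A, C, trans_sd, emis_sd, seed = 1L) {
  dz <- nrow(A); D <- ncol(C)
  stopifnot(ncol(A) == dz, nrow(C) == dz, all(trans_sd > 0), all(emis_sd > 0))
  p <- dssm_init_params(D, hidden = dz, latent_dim = dz, flavor = "linear",
                        seed = seed)
  p$tra_W <- diag(dz); p$tra_b <- rep(0, dz)
  p$tra_Wm <- A - diag(dz); p$tra_bm <- rep(0, dz)
  p$tra_Ws <- matrix(0, dz, dz)
  p$tra_bs <- rep(softplus_inv(trans_sd - STD_FLOOR), length.out = dz)
  p$emi_W <- diag(dz); p$emi_b <- rep(0, dz)
  p$emi_Wm <- C; p$emi_bm <- rep(0, D)
  p$emi_Ws <- matrix(0, dz, D)
  p$emi_bs <- rep(softplus_inv(emis_sd - STD_FLOOR), length.out = D)
  p
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname train_dssm
#' @param x,object A `dssm_fit`.
#' @param ... Unused.
#' @method tidy dssm_fit
#' @export
tidy.dssm_fit <- function(x, ...) x$trace

#' @rdname train_dssm
#' @method glance dssm_fit
#' @export
glance.dssm_fit <- function(x, ...) {
  tibble::tibble(
    flavor = x$flavor, latent_dim = x$dims$latent_dim,
    hidden = x$dims$hidden, n_patients = x$n_patients,
    epochs = nrow(x$trace), final_elbo = utils::tail(x$trace$elbo, 1)
  )
}

#' @rdname train_dssm
#' @method autoplot dssm_fit
#' @export
autoplot.dssm_fit <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(.data$epoch, .data$elbo)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean evidence lower bound",
                  title = sprintf("%s state-space model training", object$flavor)) +
    ggplot2::theme_minimal()
}
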