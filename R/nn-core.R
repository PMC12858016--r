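# Minimal neural-network plumbing for the state-space models: parameter
# initialization, activation helpers, Adam, and batch packing. All math is
# plain base-R matrix algebra; gradients are derived analytically in
# dssm-core.R and checked against finite differences in the test suite.

act_fun <- function(flavor) {
  if (flavor == "deep") list(f = tanh, df = function(u) 1 - u^2)
  else list(f = identity, df = function(u) 1)
}

# std heads use softplus(a) + floor so standard deviations stay positive with
# a smooth, non-saturating gradient
STD_FLOOR <- 1e-3

std_head <- function(a) softplus(a) + STD_FLOOR
std_head_grad <- function(a) stats::plogis(a)   # d softplus / da

init_mat <- function(nr, nc) {
  matrix(rnorm(nr * nc, sd = 1 / sqrt(max(nr, 1))), nr, nc)
}

# Parameter set for the (deep or linearized) state-space model.
# Encoder RNN over completed observations, combiner producing
# q(z_t | z_{t-1}, x_{1:t}), transition p(z_t | z_{t-1}) with a residual mean,
# and emission p(x_t | z_t); every stddev through the softplus head.
dssm_init_params <- function(d_in, hidden = 32L, latent_dim = 8L,
                             flavor = c("deep", "linear"), seed = 1L,
                             init_std = 0.5) {
  flavor <- match.arg(flavor)
  H <- hidden; dz <- latent_dim; D <- d_in
  b0 <- softplus_inv(init_std - STD_FLOOR)
  with_seed(derive_seed(seed, "init_params"), {
    p <- list(
      enc_Wx = init_mat(D, H), enc_Wh = init_mat(H, H) * 0.5, enc_b = rep(0, H),
      com_W = init_mat(H + dz, H), com_b = rep(0, H),
      com_Wm = init_mat(H, dz), com_bm = rep(0, dz),
      com_Ws = init_mat(H, dz) * 0.1, com_bs = rep(b0, dz),
      tra_W = init_mat(dz, H), tra_b = rep(0, H),
      tra_Wm = init_mat(H, dz) * 0.1, tra_bm = rep(0, dz),
      tra_Ws = init_mat(H, dz) * 0.1, tra_bs = rep(b0, dz),
      emi_W = init_mat(dz, H), emi_b = rep(0, H),
      emi_Wm = init_mat(H, D), emi_bm = rep(0.5, D),
      emi_Ws = init_mat(H, D) * 0.1, emi_bs = rep(softplus_inv(0.2 - STD_FLOOR), D)
    )
    attr(p, "dims") <- list(d_in = D, hidden = H, latent_dim = dz)
    attr(p, "flavor") <- flavor
    p
  })
}

zero_like <- function(params) {
  g <- lapply(params, function(w) if (is.matrix(w)) w * 0 else rep(0, length(w)))
  attributes(g) <- attributes(params)
  g
}

adam_state <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = 10) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (!is.finite(gn)) abort("non-finite gradient")
  scale <- if (gn > clip) clip / gn else 1
  state$t <- state$t + 1L
  corr1 <- 1 - 0.9^state$t; corr2 <- 1 - 0.999^state$t
  for (nm in names(params)) {
    g <- grads[[nm]] * scale
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(params = params, state = state)
}

# Pack an ehr_tensor into padded arrays: values (NA -> 0), binary masks
# (0 beyond each patient's length), completed inputs, and an active matrix.
pack_batch <- function(tensor, idx = seq_along(tensor$x)) {
  B <- length(idx); Tm <- max(tensor$lengths[idx])
  D <- ncol(tensor$x[[idx[1]]])
  X <- array(0, c(B, Tm, D)); M <- array(0, c(B, Tm, D))
  XI <- array(0, c(B, Tm, D)); A <- matrix(0, B, Tm)
  for (b in seq_len(B)) {
    s <- idx[b]; Tb <- tensor$lengths[s]
    x <- tensor$x[[s]]
    # completed inputs are rebuilt from observed cells only, so values parked
    # at masked cells can never leak into the model input
    x[!tensor$mask[[s]]] <- NA_real_
    xi <- locf_matrix(x, fallback = tensor$x_imp[[s]][1, ])
    x[is.na(x)] <- 0
    X[b, 1:Tb, ] <- x
    M[b, 1:Tb, ] <- tensor$mask[[s]] * 1
    XI[b, 1:Tb, ] <- xi
    A[b, 1:Tb] <- 1
  }
  list(X = X, M = M, XI = XI, A = A, B = B, Tm = Tm, D = D,
       lengths = tensor$lengths[idx], patient_id = tensor$patient_id[idx])
}

# flatten / unflatten for finite-difference gradient checks
flatten_params <- function(params) unlist(params, use.names = FALSE)

unflatten_params <- function(theta, template) {
  out <- template; pos <- 1L
  for (nm in names(template)) {
    n <- length(template[[nm]])
    w <- theta[pos:(pos + n - 1L)]
    out[[nm]] <- if (is.matrix(template[[nm]])) {
      matrix(w, nrow(template[[nm]]), ncol(template[[nm]]))
    } else w
    pos <- pos + n
  }
  out
}
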