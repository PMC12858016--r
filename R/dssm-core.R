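# Forward and backward passes of the (deep or linearized) state-space model.
#
# Per time step t the computation graph is
#   h_t  = act(x~_t Wx + h_{t+1} Wh + b)                 backward encoder RNN
#                                                        over the completed
#                                                        inputs x~ (h_t
#                                                        summarizes x_{t:T})
#   u_t  = act([h_t, z_{t-1}] Wc + bc)                   combiner
#   q_t  = N(u_t Wm + bm, softplus(u_t Ws + bs) + floor) variational posterior
#   z_t  = q_mean + q_sd * eps_t                         reparameterized draw
#   p_t  = N(z_{t-1} + v_t Am + am, softplus(v_t As+as)) transition prior,
#          v_t = act(z_{t-1} At + at)                    residual mean
#   x_t ~ N(g_m(z_t), g_s(z_t))                          emission
# and the per-patient objective is the masked evidence lower bound
#   sum_t sum_d mask * log N(x | g_m, g_s)  -  KL(q_1 || N(0, I))
#                                           -  sum_{t>=2} KL(q_t || p_t).
# The backward pass accumulates analytic gradients of the negative mean bound
# through time (BPTT); it is validated against finite differences in the
# tests.

LOG_2PI_HALF <- 0.9189385332046727

row_bias <- function(b, B) rep(b, each = B)

# One forward (and optionally backward) pass over a packed batch.
# eps: B x Tm x dz array of standard-normal draws (zeros give the mean path).
# Returns per-patient ELBOs, the final-layer summaries needed by inference,
# and, when want_grads, the gradient list of the negative mean ELBO.
dssm_fb <- function(params, batch, eps, want_grads = FALSE,
                    keep_path = FALSE) {
  dims <- attr(params, "dims"); flavor <- attr(params, "flavor")
  af <- act_fun(flavor)
  H <- dims$hidden; dz <- dims$latent_dim; D <- dims$d_in
  p <- params
  B <- batch$B; Tm <- batch$Tm
  stopifnot(D == batch$D)

  z_prev <- matrix(0, B, dz)
  Ch <- Cuc <- Cqm <- Cqs <- Csqs <- Cz <- vector("list", Tm)
  Cut <- Cpm <- Cps <- Csps <- vector("list", Tm)
  Cue <- Cem <- Ces <- Cses <- vector("list", Tm)
  elbo_b <- numeric(B)

  # backward encoder sweep: h_t carries information from x_{t:T}, so the
  # combiner realizes the smoothing factorization q(z_t | z_{t-1}, x_{t:T})
  h_next <- matrix(0, B, H)
  for (t in rev(seq_len(Tm))) {
    xt_in <- matrix(batch$XI[, t, ], B, D)
    # zero the state at padded steps so each sequence's sweep starts at its
    # own final observation, independent of the batch padding length
    Ch[[t]] <- af$f(xt_in %*% p$enc_Wx + h_next %*% p$enc_Wh +
                      row_bias(p$enc_b, B)) * batch$A[, t]
    h_next <- Ch[[t]]
  }

  for (t in seq_len(Tm)) {
    h <- Ch[[t]]
    uc <- af$f(cbind(h, z_prev) %*% p$com_W + row_bias(p$com_b, B))
    qm <- uc %*% p$com_Wm + row_bias(p$com_bm, B)
    aqs <- uc %*% p$com_Ws + row_bias(p$com_bs, B)
    qs <- std_head(aqs); sqs <- std_head_grad(aqs)
    z <- qm + qs * matrix(eps[, t, ], B, dz)

    act_t <- batch$A[, t]
    if (t == 1L) {
      kl <- 0.5 * rowSums(qm^2 + qs^2 - 2 * log(qs) - 1)
    } else {
      ut <- af$f(z_prev %*% p$tra_W + row_bias(p$tra_b, B))
      pm <- z_prev + ut %*% p$tra_Wm + row_bias(p$tra_bm, B)
      aps <- ut %*% p$tra_Ws + row_bias(p$tra_bs, B)
      ps <- std_head(aps); sps <- std_head_grad(aps)
      kl <- rowSums(log(ps / qs) + (qs^2 + (qm - pm)^2) / (2 * ps^2) - 0.5)
      Cut[[t]] <- ut; Cpm[[t]] <- pm; Cps[[t]] <- ps; Csps[[t]] <- sps
    }

    ue <- af$f(z %*% p$emi_W + row_bias(p$emi_b, B))
    em <- ue %*% p$emi_Wm + row_bias(p$emi_bm, B)
    aes <- ue %*% p$emi_Ws + row_bias(p$emi_bs, B)
    es <- std_head(aes); ses <- std_head_grad(aes)
    xt <- matrix(batch$X[, t, ], B, D); mt <- matrix(batch$M[, t, ], B, D)
    ll <- rowSums(mt * (-LOG_2PI_HALF - log(es) - 0.5 * ((xt - em) / es)^2))
    elbo_b <- elbo_b + ll - act_t * kl

    Cuc[[t]] <- uc; Cqm[[t]] <- qm; Cqs[[t]] <- qs
    Csqs[[t]] <- sqs; Cz[[t]] <- z
    Cue[[t]] <- ue; Cem[[t]] <- em; Ces[[t]] <- es; Cses[[t]] <- ses
    z_prev <- z
  }

  out <- list(elbo = elbo_b)
  if (keep_path) {
    out$q_mean <- Cqm; out$q_sd <- Cqs; out$emis_mean <- Cem
  }
  if (!want_grads) return(out)

  g <- zero_like(p)
  dz_next <- matrix(0, B, dz)
  Cdh <- vector("list", Tm)
  for (t in rev(seq_len(Tm))) {
    xt <- matrix(batch$X[, t, ], B, D); mt <- matrix(batch$M[, t, ], B, D)
    h <- Ch[[t]]; uc <- Cuc[[t]]; qm <- Cqm[[t]]; qs <- Cqs[[t]]
    z <- Cz[[t]]; ue <- Cue[[t]]; em <- Cem[[t]]; es <- Ces[[t]]
    act_t <- batch$A[, t]
    z_prevm <- if (t > 1) Cz[[t - 1]] else matrix(0, B, dz)

    # emission head of the negative mean bound
    inv_es <- 1 / es; diff <- xt - em
    dem <- -(mt * diff * inv_es^2) / B
    daes <- (-(mt * (diff^2 * inv_es^3 - inv_es)) / B) * Cses[[t]]
    dUe <- (dem %*% t(p$emi_Wm) + daes %*% t(p$emi_Ws)) * af$df(ue)
    g$emi_Wm <- g$emi_Wm + t(ue) %*% dem
    g$emi_bm <- g$emi_bm + colSums(dem)
    g$emi_Ws <- g$emi_Ws + t(ue) %*% daes
    g$emi_bs <- g$emi_bs + colSums(daes)
    g$emi_W <- g$emi_W + t(z) %*% dUe
    g$emi_b <- g$emi_b + colSums(dUe)
    dzt <- dUe %*% t(p$emi_W) + dz_next

    # KL term
    w <- act_t / B
    if (t == 1L) {
      dqm_kl <- w * qm
      dqs_kl <- w * (qs - 1 / qs)
      dpm <- NULL
    } else {
      pm <- Cpm[[t]]; ps <- Cps[[t]]
      inv_ps2 <- 1 / ps^2
      dqm_kl <- w * (qm - pm) * inv_ps2
      dqs_kl <- w * (qs * inv_ps2 - 1 / qs)
      dpm <- w * (pm - qm) * inv_ps2
      dps <- w * (1 / ps - (qs^2 + (qm - pm)^2) / ps^3)
    }

    # reparameterized sample and combiner
    dqm <- dqm_kl + dzt
    dqs <- dqs_kl + dzt * matrix(eps[, t, ], B, dz)
    daqs <- dqs * Csqs[[t]]
    dUc <- (dqm %*% t(p$com_Wm) + daqs %*% t(p$com_Ws)) * af$df(uc)
    g$com_Wm <- g$com_Wm + t(uc) %*% dqm
    g$com_bm <- g$com_bm + colSums(dqm)
    g$com_Ws <- g$com_Ws + t(uc) %*% daqs
    g$com_bs <- g$com_bs + colSums(daqs)
    g$com_W <- g$com_W + t(cbind(h, z_prevm)) %*% dUc
    g$com_b <- g$com_b + colSums(dUc)
    dcin <- dUc %*% t(p$com_W)
    Cdh[[t]] <- dcin[, seq_len(H), drop = FALSE]
    dz_prev <- dcin[, H + seq_len(dz), drop = FALSE]

    # transition prior (depends on z_{t-1})
    if (t > 1L) {
      ut <- Cut[[t]]
      daps <- dps * Csps[[t]]
      dUt <- (dpm %*% t(p$tra_Wm) + daps %*% t(p$tra_Ws)) * af$df(ut)
      g$tra_Wm <- g$tra_Wm + t(ut) %*% dpm
      g$tra_bm <- g$tra_bm + colSums(dpm)
      g$tra_Ws <- g$tra_Ws + t(ut) %*% daps
      g$tra_bs <- g$tra_bs + colSums(daps)
      g$tra_W <- g$tra_W + t(z_prevm) %*% dUt
      g$tra_b <- g$tra_b + colSums(dUt)
      dz_prev <- dz_prev + dpm + dUt %*% t(p$tra_W)
    }

    dz_next <- dz_prev
  }

  # encoder backward: h_t feeds the combiner at t and the encoder at t-1,
  # so gradients chain in ascending time order
  dh_chain <- matrix(0, B, H)
  for (t in seq_len(Tm)) {
    xt_in <- matrix(batch$XI[, t, ], B, D)
    h_nextm <- if (t < Tm) Ch[[t + 1]] else matrix(0, B, H)
    da_h <- (Cdh[[t]] + dh_chain) * af$df(Ch[[t]]) * batch$A[, t]
    g$enc_Wx <- g$enc_Wx + t(xt_in) %*% da_h
    g$enc_Wh <- g$enc_Wh + t(h_nextm) %*% da_h
    g$enc_b <- g$enc_b + colSums(da_h)
    dh_chain <- da_h %*% t(p$enc_Wh)
  }

  out$grads <- g
  out
}

draw_eps <- function(B, Tm, dz, seed) {
  with_seed(seed, array(rnorm(B * Tm * dz), c(B, Tm, dz)))
}

slice_batch <- function(big, idx) {
  list(X = big$X[idx, , , drop = FALSE], M = big$M[idx, , , drop = FALSE],
       XI = big$XI[idx, , , drop = FALSE], A = big$A[idx, , drop = FALSE],
       B = length(idx), Tm = big$Tm, D = big$D,
       lengths = big$lengths[idx], patient_id = big$patient_id[idx])
}
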