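#' Continuously differentiable exponential linear unit
#'
#' `celu(x) = max(0, x) + min(0, alpha * (exp(x / alpha) - 1))`. The
#' `literal = TRUE` variant evaluates `alpha * exp(x / alpha - 1)` on the
#' negative branch instead (a discontinuous form occasionally seen in print);
#' the standard form is the default and the one used by the network.
#'
#' @param x Numeric vector/matrix.
#' @param alpha Positive scale of the negative branch.
#' @param literal Use the non-standard negative branch.
#' @return Same shape as `x`.
#' @examples
#' celu(c(-1, 0, 2))
#' @export
celu <- function(x, alpha = 1, literal = FALSE) {
  stopifnot(alpha > 0)
  neg <- if (literal) {
    # literal printed form: min(0, alpha * e^{x/alpha - 1}), zero on x >= 0
    ifelse(x < 0, pmin(0, alpha * exp(x / alpha - 1)), 0)
  } else {
    alpha * (exp(pmin(x, 0) / alpha) - 1)
  }
  pmax(x, 0) + neg
}

celu_grad <- function(x, alpha = 1) {
  ifelse(x > 0, 1, exp(pmin(x, 0) / alpha))
}

#' Training configuration for the multimodal autoencoder
#'
#' Defaults follow the package's standard setting for non-tumor tissues:
#' `batch_size = 64`, `epochs = 250`; layer widths taper geometrically.
#'
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size for training.
#' @param recon_weight Weight of the reconstruction loss in the training
#'   objective `L_d + recon_weight * L_r`. The deconvolution and
#'   reconstruction terms are mean-reduced over entries of very different
#'   counts (k vs m per sample); the default 0.1 keeps the proportion signal
#'   from being swamped by the reconstruction gradient through the shared
#'   encoder.
#' @param adapt_steps Alternating adaptation cycles per target sample.
#' @param adapt_lr Adam step size during adaptation.
#' @param anchor_weight Relative weight of the signature-anchor L1 term in
#'   the adaptive stage. Larger values keep per-sample signature deviations
#'   selective (only features the target data truly demands move away from
#'   the trained signatures), which controls false positives in downstream
#'   differential testing on purified profiles.
#' @param celu_alpha CELU scale for the encoder activations.
#' @param hidden Encoder hidden widths, input to latent.
#' @param dec_hidden Decoder chain inner widths, latent to output.
#' @param seed Integer seed.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 250L, batch_size = 64L, learning_rate = 1e-3,
                         recon_weight = 0.1, adapt_steps = 300L,
                         adapt_lr = 1e-5, anchor_weight = 3,
                         celu_alpha = 1,
                         hidden = c(128L, 64L, 32L, 16L),
                         dec_hidden = c(16L, 32L, 64L, 128L), seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0, recon_weight >= 0,
            adapt_steps >= 0, anchor_weight >= 0, celu_alpha > 0,
            length(hidden) == 4L, length(dec_hidden) == 4L)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, recon_weight = recon_weight,
                 adapt_steps = as.integer(adapt_steps),
                 adapt_lr = adapt_lr, anchor_weight = anchor_weight,
                 celu_alpha = celu_alpha,
                 hidden = as.integer(hidden), dec_hidden = as.integer(dec_hidden),
                 seed = as.integer(seed)),
            class = "train_config")
}

xavier <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -r, r), nin, nout)
}

ae_init_params <- function(m1, m2, k, cfg) {
  h <- cfg$hidden
  dims <- c(m1 + m2, h, k)
  enc_W <- vector("list", 5L); enc_b <- vector("list", 5L)
  for (l in 1:5) {
    enc_W[[l]] <- xavier(dims[l], dims[l + 1])
    enc_b[[l]] <- numeric(dims[l + 1])
  }
  # positive bias keeps the clamp-and-normalize latent head off its dead zone
  enc_b[[5]] <- rep(1, k)
  dh <- cfg$dec_hidden
  mk_dec <- function(m) {
    dd <- c(k, dh, m)
    lapply(1:5, function(l) xavier(dd[l], dd[l + 1]))
  }
  list(enc_W = enc_W, enc_b = enc_b,
       S1 = diag(k) + matrix(stats::rnorm(k * k, 0, 0.01), k, k),
       S2 = diag(k) + matrix(stats::rnorm(k * k, 0, 0.01), k, k),
       dec1 = mk_dec(m1), dec2 = mk_dec(m2),
       m1 = m1, m2 = m2, k = k, alpha = cfg$celu_alpha)
}

# clamp-at-zero + row L1-normalize head; eps keeps all-negative rows defined
simplex_head <- function(Z, eps = 1e-8) {
  R <- pmax(Z, 0) + eps
  list(p = R / rowSums(R), R = R, mask = Z > 0)
}

simplex_head_grad <- function(g, head) {
  S <- rowSums(head$R)
  p <- head$R / S
  dR <- (g - rowSums(g * p)) / S
  dR * head$mask
}

#' Per-sample input normalization for the encoder
#'
#' Divides each sample's transformed profile by its mean feature value within
#' each modality (sum-normalization up to the constant feature count), so
#' training pseudo-bulk and target bulk live on the same scale and entries
#' stay of order one for the network.
#'
#' @param Y Matrix (samples x features) on the transformed scale, or a vector.
#' @return Row-normalized matrix.
#' @export
normalize_rows <- function(Y) {
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1L)
  rm <- rowMeans(Y)
  rm[rm <= 0] <- 1
  Y / rm
}

#' Feature standardization statistics for the encoder input
#'
#' After per-sample normalization, each feature is centred and scaled by its
#' across-sample mean and standard deviation. Standardizing a target cohort
#' by its own statistics removes feature-level location/scale disparity
#' between the simulated training data and real bulk cohorts while
#' preserving the across-sample variation that carries the composition
#' signal.
#'
#' @param Y samples x features matrix on the transformed scale.
#' @return List with `mu` and `sd` (length-m vectors; `sd` floored at 1e-6).
#' @export
feature_stats <- function(Y) {
  Yn <- normalize_rows(Y)
  mu <- colMeans(Yn)
  sd_ <- apply(Yn, 2, stats::sd)
  sd_[!is.finite(sd_) | sd_ < 1e-6] <- 1
  list(mu = mu, sd = sd_)
}

#' Standardize transformed bulk profiles for the encoder
#'
#' Per-sample mean normalization followed by per-feature z-scoring with the
#' supplied [feature_stats()].
#'
#' @param Y samples x features matrix (or vector) on the transformed scale.
#' @param stats A [feature_stats()] list.
#' @return Standardized matrix.
#' @export
standardize_input <- function(Y, stats) {
  Yn <- normalize_rows(Y)
  sweep(sweep(Yn, 2, stats$mu, "-"), 2, stats$sd, "/")
}

# full forward pass; caches everything backward needs
ae_forward <- function(params, Y1n, Y2n) {
  X <- cbind(Y1n, Y2n)
  H <- vector("list", 6L); Z <- vector("list", 5L)
  H[[1]] <- X
  for (l in 1:4) {
    Z[[l]] <- sweep(H[[l]] %*% params$enc_W[[l]], 2, params$enc_b[[l]], "+")
    H[[l + 1]] <- celu(Z[[l]], params$alpha)
  }
  Z[[5]] <- sweep(H[[5]] %*% params$enc_W[[5]], 2, params$enc_b[[5]], "+")
  hp <- simplex_head(Z[[5]])
  p <- hp$p
  theta_raw1 <- p %*% params$S1
  theta_raw2 <- p %*% params$S2
  h1 <- simplex_head(theta_raw1)
  h2 <- simplex_head(theta_raw2)
  dec_chain <- function(W) {
    A <- vector("list", 5L)
    A[[1]] <- W[[1]]
    for (l in 2:5) A[[l]] <- A[[l - 1]] %*% W[[l]]
    A
  }
  A1 <- dec_chain(params$dec1); A2 <- dec_chain(params$dec2)
  M1 <- A1[[5]]; M2 <- A2[[5]]
  X1 <- pmax(M1, 0); X2 <- pmax(M2, 0)
  list(input = X, Z = Z, H = H, head_p = hp, p = p,
       theta_raw1 = theta_raw1, theta_raw2 = theta_raw2,
       head_t1 = h1, head_t2 = h2, theta1 = h1$p, theta2 = h2$p,
       A1 = A1, A2 = A2, M1 = M1, M2 = M2, X1 = X1, X2 = X2,
       yhat1 = theta_raw1 %*% X1, yhat2 = theta_raw2 %*% X2)
}

# gradients of a decoder 5-matrix chain given dM (k x m); everything stays
# k-rowed so the chain rule costs O(k * sum(h_l * h_{l+1}))
dec_chain_grads <- function(W, A, dM) {
  D <- vector("list", 5L)
  D[[5]] <- dM
  for (l in 4:1) D[[l]] <- D[[l + 1]] %*% t(W[[l + 1]])
  g <- vector("list", 5L)
  g[[1]] <- D[[1]]
  for (l in 2:5) g[[l]] <- crossprod(A[[l - 1]], D[[l]])
  g
}

# backward pass; dYhat*, dTheta* and dXsig* may be NULL (treated as zero).
# `parts` selects which parameter groups receive gradients.
ae_backward <- function(params, fw, dYhat1 = NULL, dYhat2 = NULL,
                        dTheta1 = NULL, dTheta2 = NULL,
                        dXsig1 = NULL, dXsig2 = NULL,
                        parts = c("encoder", "S", "decoders")) {
  k <- params$k
  B <- nrow(fw$p)
  g <- list()
  dtheta_raw1 <- matrix(0, B, k); dtheta_raw2 <- matrix(0, B, k)
  dX1 <- matrix(0, k, params$m1); dX2 <- matrix(0, k, params$m2)
  if (!is.null(dYhat1)) {
    dX1 <- dX1 + crossprod(fw$theta_raw1, dYhat1)
    dtheta_raw1 <- dtheta_raw1 + dYhat1 %*% t(fw$X1)
  }
  if (!is.null(dYhat2)) {
    dX2 <- dX2 + crossprod(fw$theta_raw2, dYhat2)
    dtheta_raw2 <- dtheta_raw2 + dYhat2 %*% t(fw$X2)
  }
  if (!is.null(dXsig1)) dX1 <- dX1 + dXsig1
  if (!is.null(dXsig2)) dX2 <- dX2 + dXsig2
  if ("decoders" %in% parts) {
    g$dec1 <- dec_chain_grads(params$dec1, fw$A1, dX1 * (fw$M1 > 0))
    g$dec2 <- dec_chain_grads(params$dec2, fw$A2, dX2 * (fw$M2 > 0))
  }
  if (!is.null(dTheta1)) dtheta_raw1 <- dtheta_raw1 + simplex_head_grad(dTheta1, fw$head_t1)
  if (!is.null(dTheta2)) dtheta_raw2 <- dtheta_raw2 + simplex_head_grad(dTheta2, fw$head_t2)
  if ("S" %in% parts) {
    g$S1 <- crossprod(fw$p, dtheta_raw1)
    g$S2 <- crossprod(fw$p, dtheta_raw2)
  }
  if ("encoder" %in% parts) {
    dp <- dtheta_raw1 %*% t(params$S1) + dtheta_raw2 %*% t(params$S2)
    dZ <- simplex_head_grad(dp, fw$head_p)
    g$enc_W <- vector("list", 5L); g$enc_b <- vector("list", 5L)
    for (l in 5:1) {
      g$enc_W[[l]] <- crossprod(fw$H[[l]], dZ)
      g$enc_b[[l]] <- colSums(dZ)
      if (l > 1) {
        dH <- dZ %*% t(params$enc_W[[l]])
        dZ <- dH * celu_grad(fw$Z[[l - 1]], params$alpha)
      }
    }
  }
  g
}

# ---- Adam over the nested parameter structure -------------------------------

adam_state <- function(params, groups) {
  zero_like <- function(x) if (is.list(x)) lapply(x, zero_like) else x * 0
  st <- list(t = 0L)
  for (nm in groups) st[[nm]] <- zero_like(params[[nm]])
  st
}

adam_apply <- function(params, grads, m, v, t, lr,
                       b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, mm, vv) {
    if (is.list(p)) {
      out_p <- p; out_m <- mm; out_v <- vv
      for (i in seq_along(p)) {
        r <- upd(p[[i]], g[[i]], mm[[i]], vv[[i]])
        out_p[[i]] <- r$p; out_m[[i]] <- r$m; out_v[[i]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    mm <- b1 * mm + (1 - b1) * g
    vv <- b2 * vv + (1 - b2) * g^2
    mhat <- mm / (1 - b1^t)
    vhat <- vv / (1 - b2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = mm, v = vv)
  }
  for (nm in names(grads)) {
    r <- upd(params[[nm]], grads[[nm]], m[[nm]], v[[nm]])
    params[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
  }
  list(params = params, m = m, v = v)
}

mean_abs <- function(x) mean(abs(x))

#' Deconvolution and reconstruction losses on a batch
#'
#' L1 losses, mean-reduced over entries: the deconvolution loss compares
#' reported proportions with the ground truth in both modalities; the
#' reconstruction loss compares the decoded bulk profiles with the
#' (normalized) input in both modalities.
#'
#' @param batch List with `Y1`, `Y2` (transformed-scale matrices) and
#'   `Theta1`, `Theta2` (ground-truth fractions).
#' @param model A `deconv_model` (or raw parameter list from training).
#' @return Named numeric vector `c(L_d, L_r)`.
#' @export
training_losses <- function(batch, model) {
  if (inherits(model, "deconv_model")) {
    params <- model$params
    Y1n <- standardize_input(batch$Y1, model$stats1)
    Y2n <- standardize_input(batch$Y2, model$stats2)
  } else {
    params <- model
    Y1n <- normalize_rows(batch$Y1); Y2n <- normalize_rows(batch$Y2)
  }
  fw <- ae_forward(params, Y1n, Y2n)
  c(L_d = mean_abs(batch$Theta1 - fw$theta1) + mean_abs(batch$Theta2 - fw$theta2),
    L_r = mean_abs(Y1n - fw$yhat1) + mean_abs(Y2n - fw$yhat2))
}

#' Encode bulk profiles to latent cell-count fractions
#'
#' Standardizes the transformed profiles (per-sample normalization +
#' per-feature z-scoring with the model's training statistics), then applies
#' five affine layers with CELU activations after layers 1-4 and a
#' clamp-and-normalize head, so the latent vector is a valid fraction vector.
#'
#' @param model A `deconv_model`.
#' @param Y1,Y2 Transformed-scale profiles (vector or matrix).
#' @return Matrix of latent fractions (rows sum to 1).
#' @export
encode <- function(model, Y1, Y2) {
  stopifnot(inherits(model, "deconv_model"))
  if (is.null(dim(Y1))) Y1 <- matrix(Y1, nrow = 1L)
  if (is.null(dim(Y2))) Y2 <- matrix(Y2, nrow = 1L)
  ae_forward(model$params, standardize_input(Y1, model$stats1),
             standardize_input(Y2, model$stats2))$p
}

#' Modality-specific proportions from the latent fractions
#'
#' Applies the connection layers `theta_i = p %*% S_i`, then clamps at zero
#' and renormalizes for reporting. The raw product is kept as an attribute
#' (it is what the decoders consume).
#'
#' @param p Latent fraction matrix (rows on the simplex).
#' @param S1,S2 k x k connection matrices.
#' @return List with `theta1`, `theta2` (reported, simplex rows) and
#'   attributes `raw1`, `raw2`.
#' @export
proportions_from_latent <- function(p, S1, S2) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  r1 <- p %*% S1; r2 <- p %*% S2
  out <- list(theta1 = simplex_head(r1)$p, theta2 = simplex_head(r2)$p)
  attr(out, "raw1") <- r1; attr(out, "raw2") <- r2
  out
}

#' Decode proportions to a reconstructed bulk profile
#'
#' The decoder is a product of five weight matrices without activations or
#' biases, wrapped in a ReLU so the implied signature matrix is nonnegative:
#' `X = ReLU(W1 W2 W3 W4 W5)`, `yhat = theta_raw %*% X`.
#'
#' @param theta_raw Un-normalized proportion matrix (`p %*% S_i`).
#' @param weights List of 5 decoder matrices.
#' @return List with `yhat` and the signature matrix `X` (k x m).
#' @export
decode <- function(theta_raw, weights) {
  if (is.null(dim(theta_raw))) theta_raw <- matrix(theta_raw, nrow = 1L)
  M <- weights[[1]]
  for (l in 2:5) M <- M %*% weights[[l]]
  X <- pmax(M, 0)
  list(yhat = theta_raw %*% X, X = X)
}

#' Train the multimodal autoencoder on a pseudo-bulk training set
#'
#' Mini-batch Adam optimization of the combined deconvolution (L1, against
#' ground-truth fractions in both modalities) and reconstruction (L1, against
#' the normalized input in both modalities) losses. The deconvolution loss
#' reaches only the encoder and connection layers; the reconstruction loss
#' additionally reaches the decoders.
#'
#' @param tset A [generate_training_set()] result.
#' @param cfg A [train_config()].
#' @return A `deconv_model`: trained parameters, per-epoch loss history,
#'   feature names and modality specs.
#' @export
train_deconvolver <- function(tset, cfg = train_config()) {
  stopifnot(inherits(tset, "training_set"), inherits(cfg, "train_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  m1 <- ncol(tset$Y1_train); m2 <- ncol(tset$Y2_train); k <- ncol(tset$Theta1)
  params <- ae_init_params(m1, m2, k, cfg)
  stats1 <- feature_stats(tset$Y1_train)
  stats2 <- feature_stats(tset$Y2_train)
  Y1n <- standardize_input(tset$Y1_train, stats1)
  Y2n <- standardize_input(tset$Y2_train, stats2)
  N <- nrow(Y1n)
  groups <- c("enc_W", "enc_b", "S1", "S2", "dec1", "dec2")
  m_st <- adam_state(params, groups); v_st <- adam_state(params, groups)
  t_adam <- 0L
  history <- data.frame(epoch = integer(0), L_d = numeric(0), L_r = numeric(0))
  for (ep in seq_len(cfg$epochs)) {
    idx <- sample.int(N)
    ld_ep <- 0; lr_ep <- 0; nb <- 0L
    for (start in seq(1L, N, by = cfg$batch_size)) {
      rows <- idx[start:min(start + cfg$batch_size - 1L, N)]
      B <- length(rows)
      y1 <- Y1n[rows, , drop = FALSE]; y2 <- Y2n[rows, , drop = FALSE]
      t1 <- tset$Theta1[rows, , drop = FALSE]; t2 <- tset$Theta2[rows, , drop = FALSE]
      fw <- ae_forward(params, y1, y2)
      L_d <- mean_abs(t1 - fw$theta1) + mean_abs(t2 - fw$theta2)
      L_r <- mean_abs(y1 - fw$yhat1) + mean_abs(y2 - fw$yhat2)
      if (!is.finite(L_d + L_r)) {
        stop(sprintf("non-finite loss at epoch %d", ep), call. = FALSE)
      }
      wr <- cfg$recon_weight
      g <- ae_backward(params, fw,
                       dYhat1 = wr * sign(fw$yhat1 - y1) / (B * m1),
                       dYhat2 = wr * sign(fw$yhat2 - y2) / (B * m2),
                       dTheta1 = sign(fw$theta1 - t1) / (B * k),
                       dTheta2 = sign(fw$theta2 - t2) / (B * k))
      t_adam <- t_adam + 1L
      upd <- adam_apply(params, g, m_st, v_st, t_adam, cfg$learning_rate)
      params <- upd$params; m_st <- upd$m; v_st <- upd$v
      ld_ep <- ld_ep + L_d; lr_ep <- lr_ep + L_r; nb <- nb + 1L
    }
    history <- rbind(history,
                     data.frame(epoch = ep, L_d = ld_ep / nb, L_r = lr_ep / nb))
  }
  structure(list(params = params, history = history, config = cfg,
                 stats1 = stats1, stats2 = stats2,
                 cell_types = tset$cell_types,
                 feature_names1 = colnames(tset$Y1_train),
                 feature_names2 = colnames(tset$Y2_train),
                 spec1 = tset$spec1, spec2 = tset$spec2),
            class = "deconv_model")
}

#' @export
print.deconv_model <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat(sprintf("<deconv_model> k = %d, m1 = %d, m2 = %d; %d epochs (final L_d %.4f, L_r %.4f)\n",
              x$params$k, x$params$m1, x$params$m2, nrow(x$history), h$L_d, h$L_r))
  invisible(x)
}

adapt_result <- function(fw, params, recon_before, recon_after, adapted) {
  list(p = drop(fw$p),
       theta1 = drop(fw$theta1), theta2 = drop(fw$theta2),
       X1 = fw$X1, X2 = fw$X2,
       yhat1 = drop(fw$yhat1), yhat2 = drop(fw$yhat2),
       recon_before = recon_before, recon_after = recon_after,
       adapted = adapted)
}

#' Adapt the trained network to one target bulk sample
#'
#' Starting from a copy of the trained parameters, alternates a
#' signature-anchored reconstruction step (updates the decoders against
#' target reconstruction plus an L1 anchor to the pre-adaptation signature
#' matrices) with a proportion-anchored step (updates the encoder and
#' connection layers against target reconstruction plus an L1 anchor to the
#' pre-adaptation proportions). Anchors are frozen snapshots of the trained
#' model. The returned state is the reconstruction-best checkpoint over all
#' cycles including the starting point, so adaptation never degrades the
#' target reconstruction loss; the trained model itself is left untouched.
#'
#' @param model A `deconv_model`.
#' @param y1,y2 Target bulk profiles on the transformed scale (vectors).
#' @param adapt_steps Number of alternating cycles (default from the model's
#'   config); `0` returns the plain forward pass.
#' @param stats1,stats2 [feature_stats()] used to standardize the target
#'   (default: the model's training statistics; [purify_cohort()] passes the
#'   target cohort's own statistics).
#' @return List with adapted `theta1`, `theta2`, latent `p`, per-sample
#'   signature matrices `X1`, `X2` (k x m, standardized scale),
#'   reconstructions and the reconstruction L1 before/after adaptation.
#' @export
adapt_sample <- function(model, y1, y2, adapt_steps = NULL,
                         stats1 = NULL, stats2 = NULL) {
  stopifnot(inherits(model, "deconv_model"))
  if (is.null(adapt_steps)) adapt_steps <- model$config$adapt_steps
  if (is.null(stats1)) stats1 <- model$stats1
  if (is.null(stats2)) stats2 <- model$stats2
  params <- model$params
  m1 <- params$m1; m2 <- params$m2; k <- params$k
  y1n <- standardize_input(matrix(y1, nrow = 1L), stats1)
  y2n <- standardize_input(matrix(y2, nrow = 1L), stats2)
  fw0 <- ae_forward(params, y1n, y2n)
  recon0 <- mean_abs(y1n - fw0$yhat1) + mean_abs(y2n - fw0$yhat2)
  if (adapt_steps == 0L) {
    return(adapt_result(fw0, params, recon0, recon0, adapted = FALSE))
  }
  anchor <- list(X1 = fw0$X1, X2 = fw0$X2,
                 theta1 = fw0$theta1, theta2 = fw0$theta2)
  dec_groups <- c("dec1", "dec2")
  enc_groups <- c("enc_W", "enc_b", "S1", "S2")
  m_d <- adam_state(params, dec_groups); v_d <- adam_state(params, dec_groups)
  m_e <- adam_state(params, enc_groups); v_e <- adam_state(params, enc_groups)
  lr <- model$config$adapt_lr
  aw <- model$config$anchor_weight %||% 1
  best <- list(recon = recon0, fw = fw0)
  t_d <- 0L; t_e <- 0L
  fw <- fw0
  for (s in seq_len(adapt_steps)) {
    # signature-anchored phase: decoders only
    g <- ae_backward(params, fw,
                     dYhat1 = sign(fw$yhat1 - y1n) / m1,
                     dYhat2 = sign(fw$yhat2 - y2n) / m2,
                     dXsig1 = aw * sign(fw$X1 - anchor$X1) / (k * m1),
                     dXsig2 = aw * sign(fw$X2 - anchor$X2) / (k * m2),
                     parts = "decoders")
    t_d <- t_d + 1L
    upd <- adam_apply(params, g, m_d, v_d, t_d, lr)
    params <- upd$params; m_d <- upd$m; v_d <- upd$v
    fw <- ae_forward(params, y1n, y2n)
    # proportion-anchored phase: encoder + connection layers only
    g <- ae_backward(params, fw,
                     dYhat1 = sign(fw$yhat1 - y1n) / m1,
                     dYhat2 = sign(fw$yhat2 - y2n) / m2,
                     dTheta1 = sign(fw$theta1 - anchor$theta1) / k,
                     dTheta2 = sign(fw$theta2 - anchor$theta2) / k,
                     parts = c("encoder", "S"))
    t_e <- t_e + 1L
    upd <- adam_apply(params, g, m_e, v_e, t_e, lr)
    params <- upd$params; m_e <- upd$m; v_e <- upd$v
    fw <- ae_forward(params, y1n, y2n)
    recon <- mean_abs(y1n - fw$yhat1) + mean_abs(y2n - fw$yhat2)
    if (!is.finite(recon)) {
      res <- adapt_result(best$fw, params, recon0, best$recon, adapted = FALSE)
      res$aborted <- TRUE
      return(res)
    }
    if (recon < best$recon) best <- list(recon = recon, fw = fw)
  }
  adapt_result(best$fw, params, recon0, best$recon, adapted = TRUE)
}

#' Deconvolve and purify a target cohort
#'
#' Runs per-sample adaptation over a cohort and stacks the results. Purified
#' profiles are the per-sample adapted signature columns weighted by the
#' sample's proportions, on the transformed scale (a raw-scale export is
#' available through [purified_matrix()]).
#'
#' @param model A `deconv_model`.
#' @param bulk A [bulk_multiome()] with feature order matching training.
#' @param adapt_steps Cycles per sample (default from the model config).
#' @param standardize `"cohort"` (default) standardizes the targets by the
#'   cohort's own feature statistics when the cohort has at least 5 samples
#'   (self-calibrating against reference-to-target disparity); `"training"`
#'   always uses the training statistics.
#' @return A `deconv_result` with `Theta1`, `Theta2`, latent `P` (n x k),
#'   per-sample purified profile lists `purified1`, `purified2`
#'   (features x cell types each, transformed scale), signature lists
#'   `signature1`, `signature2`, and reconstruction losses before/after
#'   adaptation.
#' @export
purify_cohort <- function(model, bulk, adapt_steps = NULL,
                          standardize = c("cohort", "training")) {
  stopifnot(inherits(model, "deconv_model"), inherits(bulk, "bulk_multiome"))
  standardize <- match.arg(standardize)
  check_feature_order <- function(have, want, label) {
    if (is.null(have) || is.null(want)) return(invisible())
    if (length(have) != length(want) || any(have != want)) {
      bad <- which(have != want)[1]
      if (is.na(bad)) bad <- min(length(have), length(want)) + 1L
      stop(sprintf("%s feature order does not match training (first mismatch at position %d: '%s' vs '%s')",
                   label, bad, have[min(bad, length(have))], want[min(bad, length(want))]),
           call. = FALSE)
    }
  }
  if (ncol(bulk$Y1) != model$params$m1 || ncol(bulk$Y2) != model$params$m2) {
    stop("bulk feature dimensions do not match the trained model", call. = FALSE)
  }
  check_feature_order(colnames(bulk$Y1), model$feature_names1, "RNA")
  check_feature_order(colnames(bulk$Y2), model$feature_names2, "non-RNA")
  n <- nrow(bulk$Y1); k <- model$params$k
  if (standardize == "cohort" && n >= 5) {
    stats1 <- feature_stats(bulk$Y1)
    stats2 <- feature_stats(bulk$Y2)
  } else {
    stats1 <- model$stats1
    stats2 <- model$stats2
  }
  Theta1 <- matrix(0, n, k); Theta2 <- matrix(0, n, k); P <- matrix(0, n, k)
  purified1 <- vector("list", n); purified2 <- vector("list", n)
  signature1 <- vector("list", n); signature2 <- vector("list", n)
  recon_before <- numeric(n); recon_after <- numeric(n)
  ct <- model$cell_types
  if (is.null(ct)) ct <- paste0("type", seq_len(k))
  # adapted signatures live on the standardized scale; map back to the
  # transformed scale through the standardization statistics (rows of the
  # reconstruction are affine images of theta-weighted signature sums, and
  # reported proportions sum to one)
  destd <- function(Xz, stats) {
    pmax(sweep(sweep(t(Xz), 1, stats$sd, "*"), 1, stats$mu, "+"), 0)
  }
  for (j in seq_len(n)) {
    r <- adapt_sample(model, bulk$Y1[j, ], bulk$Y2[j, ], adapt_steps,
                      stats1 = stats1, stats2 = stats2)
    Theta1[j, ] <- r$theta1; Theta2[j, ] <- r$theta2; P[j, ] <- r$p
    sig1 <- destd(r$X1, stats1)           # features x cell types
    sig2 <- destd(r$X2, stats2)
    w1 <- sig1 %*% diag(r$theta1, k)      # theta-weighted purified profiles
    w2 <- sig2 %*% diag(r$theta2, k)
    colnames(w1) <- colnames(w2) <- ct
    colnames(sig1) <- colnames(sig2) <- ct
    purified1[[j]] <- w1; purified2[[j]] <- w2
    signature1[[j]] <- sig1; signature2[[j]] <- sig2
    recon_before[j] <- r$recon_before; recon_after[j] <- r$recon_after
  }
  colnames(Theta1) <- colnames(Theta2) <- colnames(P) <- ct
  rownames(Theta1) <- rownames(Theta2) <- rownames(P) <- bulk$sample_ids
  structure(list(Theta1 = Theta1, Theta2 = Theta2, P = P,
                 purified1 = purified1, purified2 = purified2,
                 signature1 = signature1, signature2 = signature2,
                 recon_before = recon_before, recon_after = recon_after,
                 sample_ids = bulk$sample_ids, cell_types = ct,
                 spec1 = model$spec1, spec2 = model$spec2),
            class = "deconv_result")
}

#' @export
print.deconv_result <- function(x, ...) {
  cat(sprintf("<deconv_result> %d samples x %d cell types; mean recon L1 %.4g -> %.4g\n",
              nrow(x$Theta1), ncol(x$Theta1),
              mean(x$recon_before), mean(x$recon_after)))
  invisible(x)
}

#' Extract one cell type's purified profiles across a cohort
#'
#' @param result A [purify_cohort()] result.
#' @param cell_type Cell-type name or index.
#' @param modality 1 (RNA) or 2 (non-RNA).
#' @param weighted Use proportion-weighted purified profiles (default) or the
#'   unweighted adapted signature columns.
#' @param scale `"transformed"` (default) or `"raw"` (inverse-transformed).
#' @return samples x features matrix.
#' @export
purified_matrix <- function(result, cell_type, modality = 1,
                            weighted = TRUE, scale = c("transformed", "raw")) {
  stopifnot(inherits(result, "deconv_result"))
  scale <- match.arg(scale)
  src <- if (weighted) {
    if (modality == 1) result$purified1 else result$purified2
  } else {
    if (modality == 1) result$signature1 else result$signature2
  }
  M <- t(vapply(src, function(m) m[, cell_type], numeric(nrow(src[[1]]))))
  rownames(M) <- result$sample_ids
  if (scale == "raw") {
    spec <- if (modality == 1) result$spec1 else result$spec2
    M <- transform_inverse(M, spec)
  }
  M
}
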