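# Internal BiLSTM engine: parameter initialization, batched forward pass,
# cross-entropy heads, and backpropagation through time.  Written with plain
# matrix algebra; batches are processed one timestep at a time with B x *
# matrices, padded positions force hidden and cell states to zero so that
# padding never leaks into losses or pooled embeddings.

psp_sigmoid <- function(x) 1 / (1 + exp(-x))

# uniform(-r, r) init, r = 1/sqrt(hidden); forget-gate bias +1
psp_init_params <- function(cfg) {
  H <- cfg$hidden_units
  E <- cfg$embedding_dim
  V <- length(cfg$vocabulary)
  r <- 1 / sqrt(H)
  rmat <- function(n, m) matrix(runif(n * m, -r, r), n, m)
  params <- list(emb = matrix(runif(V * E, -0.1, 0.1), V, E))
  for (d in c("fwd", "bwd")) {
    for (l in seq_len(cfg$num_layers)) {
      inp <- if (l == 1) E else H
      params[[paste0(d, ".W", l)]] <- rmat(inp, 4 * H)
      params[[paste0(d, ".U", l)]] <- rmat(H, 4 * H)
      b <- rep(0, 4 * H)
      b[(H + 1):(2 * H)] <- 1  # forget gate bias
      params[[paste0(d, ".b", l)]] <- b
    }
    params[[paste0(d, ".oW")]] <- rmat(H, length(PSP_CANONICAL))
    params[[paste0(d, ".ob")]] <- rep(0, length(PSP_CANONICAL))
  }
  params
}

# One stacked-direction recurrent sweep over a padded batch.
# x_list: list over time of B x E input matrices (embedding rows; padded
# positions hold the pad embedding but are masked out of states).
# mask: B x T 0/1 matrix.  order_t: the processing order of timesteps.
# Returns final-layer hidden states per timestep plus caches for BPTT.
psp_direction_forward <- function(params, cfg, d, x_list, mask, keep_cache) {
  B <- nrow(mask); Tt <- ncol(mask); H <- cfg$hidden_units
  order_t <- if (d == "fwd") seq_len(Tt) else rev(seq_len(Tt))
  h_in <- x_list
  caches <- vector("list", cfg$num_layers)
  for (l in seq_len(cfg$num_layers)) {
    W <- params[[paste0(d, ".W", l)]]
    U <- params[[paste0(d, ".U", l)]]
    b <- params[[paste0(d, ".b", l)]]
    h <- matrix(0, B, H); cc <- matrix(0, B, H)
    h_out <- vector("list", Tt)
    cache_l <- if (keep_cache) vector("list", Tt) else NULL
    for (t in order_t) {
      x <- h_in[[t]]
      m <- mask[, t]
      z <- x %*% W + h %*% U
      z <- sweep(z, 2, b, "+")
      i_g <- psp_sigmoid(z[, 1:H, drop = FALSE])
      f_g <- psp_sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
      g_g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
      o_g <- psp_sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
      c_new <- (f_g * cc + i_g * g_g) * m
      tc <- tanh(c_new)
      h_new <- (o_g * tc) * m
      if (keep_cache) {
        cache_l[[t]] <- list(x = x, hp = h, cp = cc, i = i_g, f = f_g,
                             g = g_g, o = o_g, tc = tc, m = m)
      }
      h <- h_new; cc <- c_new
      h_out[[t]] <- h_new
    }
    caches[[l]] <- cache_l
    h_in <- h_out
  }
  list(h_final = h_in, caches = caches, order_t = order_t)
}

# BPTT for one direction. dh_top: list over time of B x H gradients w.r.t.
# the final layer's hidden states (zeros where no loss).  Returns parameter
# gradients plus dx_list (gradient w.r.t. the embedding inputs).
psp_direction_backward <- function(params, cfg, d, fwd, dh_top) {
  H <- cfg$hidden_units
  Tt <- length(dh_top)
  B <- nrow(dh_top[[1]])
  grads <- list()
  dh_in <- dh_top
  for (l in rev(seq_len(cfg$num_layers))) {
    W <- params[[paste0(d, ".W", l)]]
    U <- params[[paste0(d, ".U", l)]]
    tW <- t(W); tU <- t(U)
    cache_l <- fwd$caches[[l]]
    gW <- matrix(0, nrow(W), ncol(W))
    gU <- matrix(0, H, 4 * H)
    gb <- rep(0, 4 * H)
    dx_list <- vector("list", Tt)
    dh_next <- matrix(0, B, H)
    dc_next <- matrix(0, B, H)
    dz <- matrix(0, B, 4 * H)
    i_cols <- 1:H; f_cols <- (H + 1):(2 * H)
    g_cols <- (2 * H + 1):(3 * H); o_cols <- (3 * H + 1):(4 * H)
    for (t in rev(fwd$order_t)) {
      cc <- cache_l[[t]]
      dh <- dh_in[[t]] + dh_next
      do_ <- dh * cc$tc * cc$m
      dc <- dc_next + dh * cc$o * (1 - cc$tc^2) * cc$m
      dct <- dc * cc$m
      dc_next <- dct * cc$f
      dz[, i_cols] <- (dct * cc$g) * cc$i * (1 - cc$i)
      dz[, f_cols] <- (dct * cc$cp) * cc$f * (1 - cc$f)
      dz[, g_cols] <- (dct * cc$i) * (1 - cc$g^2)
      dz[, o_cols] <- do_ * cc$o * (1 - cc$o)
      gW <- gW + crossprod(cc$x, dz)
      gU <- gU + crossprod(cc$hp, dz)
      gb <- gb + colSums(dz)
      dx_list[[t]] <- dz %*% tW
      dh_next <- dz %*% tU
    }
    grads[[paste0(d, ".W", l)]] <- gW
    grads[[paste0(d, ".U", l)]] <- gU
    grads[[paste0(d, ".b", l)]] <- gb
    dh_in <- dx_list
  }
  grads$dx_list <- dh_in
  grads
}

# Valid prediction targets for one direction.  Forward predicts the next
# residue (source t -> target t+1), backward the previous (t -> t-1); targets
# beyond the sequence ends and non-canonical targets are excluded.
psp_targets <- function(toks, d) {
  src_b <- integer(0); src_t <- integer(0); tgt <- integer(0)
  for (b in seq_along(toks)) {
    tt <- toks[[b]]
    L <- length(tt)
    if (L < 2) next
    if (d == "fwd") { s <- seq_len(L - 1); y <- tt[s + 1] } else { s <- 2:L; y <- tt[s - 1] }
    cls <- y - PSP_VOCAB_OFFSET
    keep <- cls >= 1 & cls <= length(PSP_CANONICAL)
    src_b <- c(src_b, rep(b, sum(keep)))
    src_t <- c(src_t, s[keep])
    tgt <- c(tgt, cls[keep])
  }
  list(b = src_b, t = src_t, y = tgt)
}

# Full pass over a batch of token vectors.
# Returns cross-entropy sums/counts per direction, parameter grads when
# requested, and per-position final-layer states when requested.
psp_lm_pass <- function(params, cfg, toks, want_grads = FALSE, want_states = FALSE) {
  B <- length(toks)
  lens <- lengths(toks)
  Tt <- max(lens)
  H <- cfg$hidden_units
  mask <- matrix(0, B, Tt)
  for (b in seq_len(B)) mask[b, seq_len(lens[b])] <- 1
  batch <- matrix(1L, B, Tt)  # pad token index 1
  for (b in seq_len(B)) batch[b, seq_len(lens[b])] <- toks[[b]]
  x_list <- lapply(seq_len(Tt), function(t) params$emb[batch[, t], , drop = FALSE])

  out <- list(ce_sum = c(fwd = 0, bwd = 0), n = c(fwd = 0L, bwd = 0L))
  if (want_states) out$states <- list()
  if (want_grads) {
    grads <- list(emb = matrix(0, nrow(params$emb), ncol(params$emb)))
  }

  for (d in c("fwd", "bwd")) {
    fw <- psp_direction_forward(params, cfg, d, x_list, mask, keep_cache = want_grads)
    if (want_states) out$states[[d]] <- fw$h_final
    tg <- psp_targets(toks, d)
    nt <- length(tg$y)
    dh_top <- NULL
    if (nt > 0) {
      Hmat <- matrix(0, nt, H)
      for (j in seq_len(nt)) Hmat[j, ] <- fw$h_final[[tg$t[j]]][tg$b[j], ]
      oW <- params[[paste0(d, ".oW")]]
      ob <- params[[paste0(d, ".ob")]]
      logits <- sweep(Hmat %*% oW, 2, ob, "+")
      mx <- apply(logits, 1, max)
      lse <- mx + log(rowSums(exp(logits - mx)))
      picked <- logits[cbind(seq_len(nt), tg$y)]
      ce <- lse - picked
      out$ce_sum[d] <- sum(ce)
      out$n[d] <- nt
      if (want_grads) {
        P <- exp(logits - lse)  # softmax rows
        Y <- matrix(0, nt, ncol(P)); Y[cbind(seq_len(nt), tg$y)] <- 1
        dlogits <- (P - Y) / nt  # mean CE per direction
        grads[[paste0(d, ".oW")]] <- crossprod(Hmat, dlogits)
        grads[[paste0(d, ".ob")]] <- colSums(dlogits)
        dH <- dlogits %*% t(oW)
        dh_top <- lapply(seq_len(Tt), function(t) matrix(0, B, H))
        for (j in seq_len(nt)) {
          dh_top[[tg$t[j]]][tg$b[j], ] <- dh_top[[tg$t[j]]][tg$b[j], ] + dH[j, ]
        }
      }
    } else if (want_grads) {
      grads[[paste0(d, ".oW")]] <- matrix(0, H, length(PSP_CANONICAL))
      grads[[paste0(d, ".ob")]] <- rep(0, length(PSP_CANONICAL))
      dh_top <- lapply(seq_len(Tt), function(t) matrix(0, B, H))
    }
    if (want_grads) {
      bk <- psp_direction_backward(params, cfg, d, fw, dh_top)
      dx <- bk$dx_list
      bk$dx_list <- NULL
      grads[names(bk)] <- bk
      # embedding gradients: scatter masked dx rows back to token rows
      for (t in seq_len(Tt)) {
        live <- which(mask[, t] == 1)
        if (length(live) == 0) next
        rs <- rowsum(dx[[t]][live, , drop = FALSE], group = batch[live, t])
        tok_rows <- as.integer(rownames(rs))
        grads$emb[tok_rows, ] <- grads$emb[tok_rows, ] + rs
      }
    }
  }
  if (want_grads) out$grads <- grads
  out
}
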