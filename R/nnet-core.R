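# Internal dense/sparse neural-network primitives for the multi-view model:
# layer normalisation, a 3-layer feed-forward numeric encoder, sparse linear
# encoders for categorical embeddings and hashed text, linear aggregation,
# task heads, and Adam.

relu <- function(x) x * (x > 0)

layernorm_fwd <- function(x, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  sd_ <- sqrt(rowMeans(xc^2) + eps)
  y <- xc / sd_
  list(y = y, sd = sd_)
}

layernorm_bwd <- function(dy, cache) {
  y <- cache$y
  (dy - rowMeans(dy) - y * rowMeans(dy * y)) / cache$sd
}

init_matrix <- function(nr, nc, scale = NULL) {
  if (is.null(scale)) scale <- sqrt(2 / (nr + nc))
  matrix(stats::rnorm(nr * nc, 0, scale), nr, nc)
}

init_params <- function(blocks, cfg) {
  p <- list()
  if (blocks$n_num > 0) {
    h <- cfg$numeric_hidden
    dims <- c(2L * blocks$n_num, h)
    for (l in 1:3) {
      p[[paste0("W", l)]] <- init_matrix(dims[l], dims[l + 1],
                                         sqrt(2 / dims[l]))
      p[[paste0("b", l)]] <- numeric(dims[l + 1])
    }
  }
  p$E <- lapply(blocks$cat_vocab_sizes, function(v) {
    init_matrix(v, cfg$cat_dim, 0.1)
  })
  p$P <- lapply(blocks$txt_fields, function(f) {
    init_matrix(2^cfg$hash_bits, cfg$text_dim, 0.05)
  })
  names(p$P) <- blocks$txt_fields
  agg_in <- blocks$width
  p$Wa <- init_matrix(agg_in, cfg$agg_dim)
  p$ba <- numeric(cfg$agg_dim)
  p$Wh <- init_matrix(cfg$agg_dim, blocks$out_dim)
  p$bh <- numeric(blocks$out_dim)
  p
}

block_spec <- function(mats, cfg, out_dim) {
  n_num <- if (!is.null(mats$num)) ncol(mats$num$x) else 0L
  cat_vocab_sizes <- lapply(mats$cat, ncol)
  txt_fields <- names(mats$txt)
  width <- (if (n_num > 0) cfg$numeric_hidden[3] else 0L) +
    length(mats$cat) * cfg$cat_dim +
    length(mats$txt) * cfg$text_dim
  if (width == 0L) stop("model has no active input blocks", call. = FALSE)
  list(n_num = n_num, cat_vocab_sizes = cat_vocab_sizes,
       txt_fields = txt_fields, width = width, out_dim = out_dim)
}

slice_mats <- function(mats, idx) {
  list(
    num = if (!is.null(mats$num)) {
      list(x = mats$num$x[idx, , drop = FALSE],
           mask = mats$num$mask[idx, , drop = FALSE])
    },
    cat = lapply(mats$cat, function(m) m[idx, , drop = FALSE]),
    txt = lapply(mats$txt, function(m) m[idx, , drop = FALSE]),
    n = length(idx)
  )
}

# Forward pass. Each encoder output is layer-normalised before the linear
# aggregation; a block whose inputs are all zero (e.g. empty text) stays a
# zero vector through the normalisation.
nn_forward <- function(p, mats, cfg) {
  n <- mats$n
  cache <- list()
  blocks <- list()
  if (!is.null(mats$num)) {
    Xn <- cbind(mats$num$x, mats$num$mask)
    A1 <- sweep(Xn %*% p$W1, 2, p$b1, "+"); H1 <- relu(A1)
    A2 <- sweep(H1 %*% p$W2, 2, p$b2, "+"); H2 <- relu(A2)
    A3 <- sweep(H2 %*% p$W3, 2, p$b3, "+"); H3 <- relu(A3)
    ln <- layernorm_fwd(H3)
    cache$num <- list(Xn = Xn, A1 = A1, H1 = H1, A2 = A2, H2 = H2,
                      A3 = A3, ln = ln)
    blocks$num <- ln$y
  }
  if (length(mats$cat)) {
    Vc <- do.call(cbind, lapply(names(mats$cat), function(f) {
      as.matrix(mats$cat[[f]] %*% p$E[[f]])
    }))
    ln <- layernorm_fwd(Vc)
    cache$cat <- list(ln = ln)
    blocks$cat <- ln$y
  }
  if (length(mats$txt)) {
    Vt <- do.call(cbind, lapply(names(mats$txt), function(f) {
      as.matrix(mats$txt[[f]] %*% p$P[[f]])
    }))
    ln <- layernorm_fwd(Vt)
    cache$txt <- list(ln = ln)
    blocks$txt <- ln$y
  }
  Z <- do.call(cbind, blocks)
  A <- sweep(Z %*% p$Wa, 2, p$ba, "+")
  logits <- sweep(A %*% p$Wh, 2, p$bh, "+")
  list(logits = logits, A = A, Z = Z, cache = cache, blocks = blocks)
}

nn_backward <- function(p, mats, cfg, fwd, dlogits) {
  g <- list()
  g$Wh <- crossprod(fwd$A, dlogits)
  g$bh <- colSums(dlogits)
  dA <- dlogits %*% t(p$Wh)
  g$Wa <- crossprod(fwd$Z, dA)
  g$ba <- colSums(dA)
  dZ <- dA %*% t(p$Wa)

  off <- 0L
  if (!is.null(mats$num)) {
    w <- cfg$numeric_hidden[3]
    dZn <- dZ[, off + seq_len(w), drop = FALSE]; off <- off + w
    cn <- fwd$cache$num
    dH3 <- layernorm_bwd(dZn, cn$ln)
    dA3 <- dH3 * (cn$A3 > 0)
    g$W3 <- crossprod(cn$H2, dA3); g$b3 <- colSums(dA3)
    dA2 <- (dA3 %*% t(p$W3)) * (cn$A2 > 0)
    g$W2 <- crossprod(cn$H1, dA2); g$b2 <- colSums(dA2)
    dA1 <- (dA2 %*% t(p$W2)) * (cn$A1 > 0)
    g$W1 <- crossprod(cn$Xn, dA1); g$b1 <- colSums(dA1)
  }
  if (length(mats$cat)) {
    w <- length(mats$cat) * cfg$cat_dim
    dZc <- layernorm_bwd(dZ[, off + seq_len(w), drop = FALSE],
                         fwd$cache$cat$ln)
    off <- off + w
    g$E <- list()
    for (k in seq_along(mats$cat)) {
      f <- names(mats$cat)[k]
      dV <- dZc[, (k - 1L) * cfg$cat_dim + seq_len(cfg$cat_dim),
                drop = FALSE]
      g$E[[f]] <- as.matrix(Matrix::crossprod(mats$cat[[f]], dV))
    }
  }
  if (length(mats$txt)) {
    w <- length(mats$txt) * cfg$text_dim
    dZt <- layernorm_bwd(dZ[, off + seq_len(w), drop = FALSE],
                         fwd$cache$txt$ln)
    g$P <- list()
    for (k in seq_along(mats$txt)) {
      f <- names(mats$txt)[k]
      dV <- dZt[, (k - 1L) * cfg$text_dim + seq_len(cfg$text_dim),
                drop = FALSE]
      g$P[[f]] <- as.matrix(Matrix::crossprod(mats$txt[[f]], dV))
    }
  }
  g
}

# head-specific loss and dlogits; labels: vector (binary/multiclass/
# regression) or matrix (multilabel); weights: per-observation (binary) or
# per-cell (multilabel) weights, NULL = 1
head_loss_grad <- function(head, logits, labels, weights = NULL) {
  n <- nrow(logits)
  if (head %in% c("binary", "multilabel")) {
    y <- if (is.matrix(labels)) labels else matrix(labels, ncol = 1L)
    w <- if (is.null(weights)) 1 else weights
    pr <- stats::plogis(logits)
    eps <- 1e-12
    loss <- -mean(w * (y * log(pr + eps) + (1 - y) * log(1 - pr + eps)))
    dlogits <- w * (pr - y) / length(y)
    list(loss = loss, dlogits = dlogits)
  } else if (head == "multiclass") {
    zmax <- apply(logits, 1L, max)
    ez <- exp(logits - zmax)
    sm <- ez / rowSums(ez)
    onehot <- matrix(0, n, ncol(logits))
    onehot[cbind(seq_len(n), labels + 1L)] <- 1
    loss <- -mean(log(rowSums(sm * onehot) + 1e-12))
    list(loss = loss, dlogits = (sm - onehot) / n)
  } else if (head == "regression") {
    d <- logits[, 1] - labels
    list(loss = mean(d^2), dlogits = matrix(2 * d / n, ncol = 1L))
  } else stop("unknown head: ", head, call. = FALSE)
}

adam_init <- function(p) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = lapply(p, zero_like), v = lapply(p, zero_like), t = 0L)
}

adam_step <- function(p, g, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(par, grad, m, v) {
    if (is.list(par)) {
      out <- list(par = par, m = m, v = v)
      for (k in names(par)) {
        if (is.null(grad[[k]])) next
        r <- upd(par[[k]], grad[[k]], m[[k]], v[[k]])
        out$par[[k]] <- r$par; out$m[[k]] <- r$m; out$v[[k]] <- r$v
      }
      out
    } else {
      m <- beta1 * m + (1 - beta1) * grad
      v <- beta2 * v + (1 - beta2) * grad^2
      list(par = par - lr * (m / bc1) / (sqrt(v / bc2) + eps), m = m, v = v)
    }
  }
  for (k in names(p)) {
    if (is.null(g[[k]])) next
    r <- upd(p[[k]], g[[k]], state$m[[k]], state$v[[k]])
    p[[k]] <- r$par; state$m[[k]] <- r$m; state$v[[k]] <- r$v
  }
  list(p = p, state = state)
}
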