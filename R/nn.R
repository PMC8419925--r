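# Minimal CNN engine backing the SNP and indel networks.
#
# Feature tensors have small, fixed shapes (5 x 41 x 5 and 15 x 128 x 2), so
# convolutions are implemented as im2col gathers with index maps precomputed
# per layer at construction; the backward scatter is a single sparse
# matrix product. A batch is stored as a (H*W*C) x B matrix in R's
# column-major (h, w, c) flattening.
#
# Supported pieces: 2D convolution (same/valid padding, strides), dense
# layers, ReLU, inverted dropout, sigmoid/softmax heads, Xavier-uniform
# initialisation, Adam with L2 weight decay.

xavier_mat <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# convolution layer over input shape c(H, W, C)
conv_layer <- function(in_shape, kh, kw, nf, stride = c(1L, 1L),
                       pad = c("same", "valid")) {
  pad <- match.arg(pad)
  H <- in_shape[1]; W <- in_shape[2]; C <- in_shape[3]
  sh <- stride[1]; sw <- stride[2]
  if (pad == "same") {
    stopifnot(sh == 1L, sw == 1L)
    pt <- (kh - 1L) %/% 2L; pl <- (kw - 1L) %/% 2L
    pb <- kh - 1L - pt; pr <- kw - 1L - pl
  } else {
    pt <- pb <- pl <- pr <- 0L
  }
  OH <- (H + pt + pb - kh) %/% sh + 1L
  OW <- (W + pl + pr - kw) %/% sw + 1L
  stopifnot(OH >= 1L, OW >= 1L)
  K <- kh * kw * C
  N <- H * W * C

  g <- expand.grid(dh = seq_len(kh), dw = seq_len(kw), c = seq_len(C),
                   oh = seq_len(OH), ow = seq_len(OW))
  h <- (g$oh - 1L) * sh - pt + g$dh
  w <- (g$ow - 1L) * sw - pl + g$dw
  idx <- h + (w - 1L) * H + (g$c - 1L) * H * W
  idx[h < 1L | h > H | w < 1L | w > W] <- N + 1L   # sentinel zero row

  L <- new.env(parent = emptyenv())
  L$kind <- "conv"
  L$in_shape <- in_shape; L$out_shape <- c(OH, OW, nf)
  L$K <- K; L$OHOW <- OH * OW; L$nf <- nf; L$N <- N
  L$IDX <- as.integer(idx)
  L$S <- Matrix::sparseMatrix(i = L$IDX, j = seq_along(L$IDX), x = 1,
                              dims = c(N + 1L, length(L$IDX)))
  L$p <- list(W = xavier_mat(K, nf, K, nf), b = numeric(nf))
  L$g <- list(W = NULL, b = NULL)
  L$m <- lapply(L$p, function(x) x * 0)
  L$v <- lapply(L$p, function(x) x * 0)
  L
}

conv_forward <- function(L, X, cache = NULL) {
  B <- ncol(X)
  Xaug <- rbind(X, 0)
  cols <- Xaug[L$IDX, , drop = FALSE]                       # (K*OHOW) x B
  dim(cols) <- c(L$K, L$OHOW * B)                           # no-copy reshape
  Z <- crossprod(L$p$W, cols) + L$p$b                       # F x (OHOW*B)
  if (!is.null(cache)) { cache$cols <- cols; cache$B <- B }
  dim(Z) <- c(L$nf, L$OHOW, B)
  Y <- aperm(Z, c(2, 1, 3))
  dim(Y) <- c(L$OHOW * L$nf, B)
  Y
}

conv_backward <- function(L, dY, cache, need_dx = TRUE) {
  B <- cache$B
  dim(dY) <- c(L$OHOW, L$nf, B)
  dZ <- aperm(dY, c(2, 1, 3))
  dim(dZ) <- c(L$nf, L$OHOW * B)
  L$g$b <- rowSums(dZ)
  L$g$W <- tcrossprod(cache$cols, dZ)
  if (!need_dx) return(NULL)
  dcols <- L$p$W %*% dZ                                     # K x (OHOW*B)
  dim(dcols) <- c(L$K * L$OHOW, B)
  dXaug <- as.matrix(L$S %*% dcols)
  dXaug[seq_len(L$N), , drop = FALSE]
}

dense_layer <- function(din, dout) {
  L <- new.env(parent = emptyenv())
  L$kind <- "dense"; L$din <- din; L$dout <- dout
  L$p <- list(W = xavier_mat(din, dout, din, dout), b = numeric(dout))
  L$g <- list(W = NULL, b = NULL)
  L$m <- lapply(L$p, function(x) x * 0)
  L$v <- lapply(L$p, function(x) x * 0)
  L
}

dense_forward <- function(L, X, cache = NULL) {
  if (!is.null(cache)) cache$X <- X
  crossprod(L$p$W, X) + L$p$b
}

dense_backward <- function(L, dZ, cache, need_dx = TRUE) {
  L$g$b <- rowSums(dZ)
  L$g$W <- cache$X %*% t(dZ)
  if (!need_dx) return(NULL)
  L$p$W %*% dZ
}

relu <- function(Z) Z * (Z > 0)
relu_grad <- function(dY, Z) dY * (Z > 0)

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_cols <- function(Z) {
  Z <- sweep(Z, 2, apply(Z, 2, max))
  E <- exp(Z)
  sweep(E, 2, colSums(E), "/")
}

dropout_mask <- function(dim_like, rate) {
  keep <- 1 - rate
  matrix(stats::rbinom(length(dim_like), 1L, keep) / keep,
         nrow = nrow(dim_like))
}

# Adam update for one layer; L2 decay applies to weight matrices only
adam_update <- function(L, lr, l2, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  for (nm in names(L$p)) {
    g <- L$g[[nm]]
    if (is.null(g)) next
    if (nm == "W" && l2 > 0) g <- g + l2 * L$p[[nm]]
    L$m[[nm]] <- beta1 * L$m[[nm]] + (1 - beta1) * g
    L$v[[nm]] <- beta2 * L$v[[nm]] + (1 - beta2) * g^2
    mhat <- L$m[[nm]] / (1 - beta1^t)
    vhat <- L$v[[nm]] / (1 - beta2^t)
    L$p[[nm]] <- L$p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(L)
}

layer_params <- function(L) L$p
set_layer_params <- function(L, p) { L$p <- p; invisible(L) }

n_params <- function(layers) {
  sum(vapply(layers, function(L) sum(vapply(L$p, length, integer(1))),
             numeric(1)))
}

# shared convolutional trunk: three parallel first-layer kernels (row-wise,
# column-wise, 2D) summed, then two 2x3 convolution layers
conv_trunk <- function(in_shape, f1 = 16L, f23 = 32L,
                       row_k = 5L, col_k = 5L, k2d = 3L,
                       stride2 = c(1L, 1L), stride3 = c(1L, 1L)) {
  col_k <- min(col_k, in_shape[1])
  tk <- list(
    conv_row = conv_layer(in_shape, 1L, row_k, f1, pad = "same"),
    conv_col = conv_layer(in_shape, col_k, 1L, f1, pad = "same"),
    conv_2d  = conv_layer(in_shape, k2d, k2d, f1, pad = "same"))
  s1 <- tk$conv_row$out_shape
  tk$conv2 <- conv_layer(s1, 2L, 3L, f23, stride = stride2, pad = "valid")
  tk$conv3 <- conv_layer(tk$conv2$out_shape, 2L, 3L, f23, stride = stride3,
                         pad = "valid")
  tk$out_dim <- prod(tk$conv3$out_shape)
  tk
}

trunk_forward <- function(tk, X, train = FALSE) {
  cc <- lapply(tk[c("conv_row", "conv_col", "conv_2d", "conv2", "conv3")],
               function(.) new.env(parent = emptyenv()))
  Z1 <- conv_forward(tk$conv_row, X, cc$conv_row) +
        conv_forward(tk$conv_col, X, cc$conv_col) +
        conv_forward(tk$conv_2d, X, cc$conv_2d)
  H1 <- relu(Z1)
  Z2 <- conv_forward(tk$conv2, H1, cc$conv2)
  H2 <- relu(Z2)
  Z3 <- conv_forward(tk$conv3, H2, cc$conv3)
  H3 <- relu(Z3)
  list(out = H3, Z1 = Z1, Z2 = Z2, Z3 = Z3, cc = cc)
}

trunk_backward <- function(tk, fw, dH3) {
  dZ3 <- relu_grad(dH3, fw$Z3)
  dH2 <- conv_backward(tk$conv3, dZ3, fw$cc$conv3)
  dZ2 <- relu_grad(dH2, fw$Z2)
  dH1 <- conv_backward(tk$conv2, dZ2, fw$cc$conv2)
  dZ1 <- relu_grad(dH1, fw$Z1)
  conv_backward(tk$conv_row, dZ1, fw$cc$conv_row, need_dx = FALSE)
  conv_backward(tk$conv_col, dZ1, fw$cc$conv_col, need_dx = FALSE)
  conv_backward(tk$conv_2d, dZ1, fw$cc$conv_2d, need_dx = FALSE)
  invisible(NULL)
}

trunk_layers <- function(tk) tk[c("conv_row", "conv_col", "conv_2d",
                                  "conv2", "conv3")]

# serialise / restore all layer parameters of a model (list of layer envs)
collect_params <- function(layers) lapply(layers, layer_params)
restore_params <- function(layers, plist) {
  stopifnot(length(layers) == length(plist))
  for (i in seq_along(layers)) set_layer_params(layers[[i]], plist[[i]])
  invisible(layers)
}
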