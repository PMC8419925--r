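# snp_network: the SNP convolutional model, genotype decision rules and
# quality scores.
#
# The network maps a 5 x 41 x 5 candidate tensor to four independent
# per-base presence probabilities (head A) plus a two-class zygosity
# probability (head B). Head B receives head A's logits concatenated with
# the first hidden layer and is used only to propagate training signal;
# calling uses head A alone.

#' SNP network configuration
#'
#' @param filters1 filters in each of the three parallel first-layer paths.
#' @param filters23 filters in convolution layers 2 and 3 (2 x 3 kernels).
#' @param row_kernel,col_kernel,kernel2d first-layer kernel extents
#'   (1 x row, col x 1, 2D square).
#' @param hidden width of the first fully connected layer.
#' @param hidden_zyg width of the zygosity head's hidden layer.
#' @param dropout dropout rate on the first fully connected layer.
#' @param learning_rate,l2,epochs,batch_size training regime (defaults
#'   1e-3, 1e-3, 100, 32).
#' @param zygosity_into_trunk if `TRUE` the zygosity head's gradient also
#'   updates the shared trunk; if `FALSE` it trains only its own layers.
#' @param input_scale fixed multiplier applied to the tensor before the
#'   first layer; the default `1/30` normalises read counts to fractions
#'   of the default training coverage so activations start near unit
#'   scale.
#' @param seed RNG seed fixing initialisation and training order.
#' @return named list of class `snp_network_config`.
#' @export
snp_network_config <- function(filters1 = 16L, filters23 = 32L,
                               row_kernel = 5L, col_kernel = 5L,
                               kernel2d = 3L, hidden = 48L,
                               hidden_zyg = 16L, dropout = 0.5,
                               learning_rate = 1e-3, l2 = 1e-3,
                               epochs = 100L, batch_size = 32L,
                               zygosity_into_trunk = TRUE,
                               input_scale = 1 / 30, seed = 1L) {
  stopifnot(dropout >= 0, dropout < 1, filters1 > 0, hidden > 0)
  structure(as.list(environment()), class = "snp_network_config")
}

#' Build the SNP convolutional network
#'
#' @param config a [snp_network_config()].
#' @return model object of class `snp_cnn`.
#' @export
build_snp_network <- function(config = snp_network_config()) {
  set.seed(config$seed)
  in_shape <- c(5L, 41L, 5L)
  trunk <- conv_trunk(in_shape, f1 = config$filters1, f23 = config$filters23,
                      row_k = config$row_kernel, col_k = config$col_kernel,
                      k2d = config$kernel2d)
  fc1 <- dense_layer(trunk$out_dim, config$hidden)
  headA <- dense_layer(config$hidden, 4L)
  zyg1 <- dense_layer(4L + config$hidden, config$hidden_zyg)
  zyg2 <- dense_layer(config$hidden_zyg, 2L)
  model <- list(config = config, in_shape = in_shape, trunk = trunk,
                fc1 = fc1, headA = headA, zyg1 = zyg1, zyg2 = zyg2,
                history = NULL)
  class(model) <- "snp_cnn"
  model
}

snp_layers <- function(model) {
  c(trunk_layers(model$trunk),
    list(fc1 = model$fc1, headA = model$headA,
         zyg1 = model$zyg1, zyg2 = model$zyg2))
}

#' @export
print.snp_cnn <- function(x, ...) {
  cat(sprintf("<snp_cnn: 5x41x5 -> 4 base probs + 2 zygosity; %d parameters>\n",
              n_params(snp_layers(x))))
  invisible(x)
}

# flatten a list of 5x41x5 tensors into the (1025 x B) batch matrix
snp_batch_matrix <- function(tensors) {
  vapply(tensors, as.vector, numeric(5L * 41L * 5L))
}

# forward pass; X is (1025 x B); returns probabilities and caches
snp_forward <- function(model, X, train = FALSE) {
  X <- X * model$config$input_scale
  fw <- trunk_forward(model$trunk, X, train)
  c_fc1 <- new.env(parent = emptyenv())
  Zf <- dense_forward(model$fc1, fw$out, c_fc1)
  Hf <- relu(Zf)
  M <- NULL
  Hd <- Hf
  if (train && model$config$dropout > 0) {
    M <- dropout_mask(Hf, model$config$dropout)
    Hd <- Hf * M
  }
  c_headA <- new.env(parent = emptyenv())
  logitsA <- dense_forward(model$headA, Hd, c_headA)
  pA <- sigmoid(logitsA)
  Cc <- rbind(logitsA, Hd)
  c_zyg1 <- new.env(parent = emptyenv())
  Zz <- dense_forward(model$zyg1, Cc, c_zyg1)
  Hz <- relu(Zz)
  c_zyg2 <- new.env(parent = emptyenv())
  logitsB <- dense_forward(model$zyg2, Hz, c_zyg2)
  pB <- softmax_cols(logitsB)
  list(pA = pA, pB = pB, logitsA = logitsA, fw = fw, Zf = Zf, Hf = Hf,
       M = M, Hd = Hd, Zz = Zz,
       cc = list(fc1 = c_fc1, headA = c_headA, zyg1 = c_zyg1, zyg2 = c_zyg2))
}

# combined loss: per-base binary cross-entropy + zygosity cross-entropy
snp_loss <- function(f, Y, zyg) {
  B <- ncol(Y)
  eps <- 1e-12
  bce <- -sum(Y * log(f$pA + eps) + (1 - Y) * log(1 - f$pA + eps)) / B
  zoh <- rbind(zyg == 1L, zyg == 2L)
  ce <- -sum(zoh * log(f$pB + eps)) / B
  bce + ce
}

snp_backward <- function(model, f, Y, zyg) {
  B <- ncol(Y)
  dLogitsB <- (f$pB - rbind(zyg == 1L, zyg == 2L)) / B
  dHz <- dense_backward(model$zyg2, dLogitsB, f$cc$zyg2)
  dZz <- relu_grad(dHz, f$Zz)
  dC <- dense_backward(model$zyg1, dZz, f$cc$zyg1)
  nh <- model$config$hidden
  dLogitsA <- (f$pA - Y) / B
  dHd_extra <- matrix(0, nh, B)
  if (model$config$zygosity_into_trunk) {
    dLogitsA <- dLogitsA + dC[1:4, , drop = FALSE]
    dHd_extra <- dC[4L + seq_len(nh), , drop = FALSE]
  }
  dHd <- dense_backward(model$headA, dLogitsA, f$cc$headA) + dHd_extra
  dHf <- if (is.null(f$M)) dHd else dHd * f$M
  dZf <- relu_grad(dHf, f$Zf)
  dFlat <- dense_backward(model$fc1, dZf, f$cc$fc1)
  trunk_backward(model$trunk, f$fw, dFlat)
  invisible(NULL)
}

#' Train the SNP network
#'
#' Minimises the sum of the per-base binary cross-entropies and the
#' zygosity cross-entropy with Adam and L2 weight decay.
#'
#' @param model a [build_snp_network()] model.
#' @param examples a labelled example set from [make_training_examples()]
#'   (fields `features`, `base_labels`, `zygosity`).
#' @param epochs,batch_size,learning_rate overrides of the model config.
#' @param verbose print a per-epoch loss line.
#' @return the trained model (with `$history` of per-epoch mean loss).
#' @export
train_snp_network <- function(model, examples,
                              epochs = model$config$epochs,
                              batch_size = model$config$batch_size,
                              learning_rate = model$config$learning_rate,
                              verbose = FALSE) {
  X <- examples$features
  Y <- examples$base_labels
  zyg <- examples$zygosity
  n <- ncol(X)
  if (n == 0) stopf("empty training set")
  layers <- snp_layers(model)
  set.seed(model$config$seed + 1L)
  t <- 0L
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (s in seq(1L, n, by = batch_size)) {
      idx <- ord[s:min(s + batch_size - 1L, n)]
      f <- snp_forward(model, X[, idx, drop = FALSE], train = TRUE)
      losses <- c(losses, snp_loss(f, Y[, idx, drop = FALSE], zyg[idx]))
      snp_backward(model, f, Y[, idx, drop = FALSE], zyg[idx])
      t <- t + 1L
      for (L in layers)
        adam_update(L, learning_rate, model$config$l2, t)
    }
    history[ep] <- mean(losses)
    if (verbose) message(sprintf("epoch %d/%d loss %.4f", ep, epochs,
                                 history[ep]))
  }
  model$history <- history
  model
}

#' Predict base-presence probabilities for SNP candidates
#'
#' @param model trained [build_snp_network()] model.
#' @param tensors list of 5 x 41 x 5 tensors (or a prebuilt batch matrix).
#' @return list with `base_probs` (N x 4 matrix, columns A, G, T, C) and
#'   `zygosity_probs` (N x 2, hom/het; training diagnostic only).
#' @export
predict_snp_network <- function(model, tensors) {
  X <- if (is.matrix(tensors)) tensors else snp_batch_matrix(tensors)
  n <- ncol(X)
  pA <- matrix(NA_real_, n, 4L, dimnames = list(NULL, TENSOR_BASES))
  pB <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("hom", "het")))
  for (s in seq(1L, n, by = 512L)) {
    idx <- s:min(s + 511L, n)
    f <- snp_forward(model, X[, idx, drop = FALSE], train = FALSE)
    pA[idx, ] <- t(f$pA)
    pB[idx, ] <- t(f$pB)
  }
  list(base_probs = pA, zygosity_probs = pB)
}

#' Genotype decision from base-presence probabilities
#'
#' If at least two bases have probability above 0.5 the site is
#' heterozygous and the two highest-probability bases are called (`0/1`
#' when one is the reference, `1/2` otherwise). Otherwise the single
#' highest-probability base is taken: the reference base yields a no-call,
#' any other base a homozygous `1/1` call.
#'
#' @param probs named numeric vector of per-base probabilities (names
#'   A, G, T, C in any order).
#' @param ref_base reference base at the candidate.
#' @return `NULL` (no-call) or a list with `genotype`, `ref`, `alt`
#'   (alternative alleles, highest probability first) and `probs` of the
#'   called alleles.
#' @export
decide_genotype <- function(probs, ref_base) {
  stopifnot(length(probs) == 4, !is.null(names(probs)))
  ref_base <- toupper(ref_base)
  above <- sum(probs > 0.5)
  if (above >= 2) {
    top2 <- names(sort(probs, decreasing = TRUE))[1:2]
    if (ref_base %in% top2) {
      alt <- setdiff(top2, ref_base)
      list(genotype = "0/1", ref = ref_base, alt = alt,
           probs = probs[alt])
    } else {
      list(genotype = "1/2", ref = ref_base, alt = top2,
           probs = probs[top2])
    }
  } else {
    top <- names(probs)[which.max(probs)]
    if (top == ref_base) return(NULL)
    list(genotype = "1/1", ref = ref_base, alt = top, probs = probs[top])
  }
}

#' Phred-like call quality
#'
#' `-100 * log10(1 - P(B))` where `P(B)` is the probability of the
#' alternative allele; for multiallelic calls the alternative allele with
#' the smaller probability is used. Capped at `cap` when `P(B)` rounds
#' to 1.
#'
#' @param probs named per-base probability vector.
#' @param alt_alleles character vector of called alternative alleles.
#' @param cap maximum score (default 999).
#' @return non-negative float.
#' @export
quality_score <- function(probs, alt_alleles, cap = 999) {
  p <- min(probs[alt_alleles])
  if (p < 0 || p > 1) stopf("probability out of [0,1]")
  q <- -100 * log10(1 - p)
  if (!is.finite(q) || q > cap) cap else q
}

#' Save / load a SNP model
#'
#' Checkpoints are written as an RDS of the config plus all layer
#' parameters, with a small manifest alongside.
#'
#' @param model trained model.
#' @param path checkpoint path.
#' @return `path` invisibly (`save`), the model (`load`).
#' @export
save_snp_model <- function(model, path) {
  obj <- list(kind = "snp_cnn", config = model$config,
              params = collect_params(snp_layers(model)),
              history = model$history)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_snp_model
#' @export
load_snp_model <- function(path) {
  obj <- readRDS(path)
  stopifnot(identical(obj$kind, "snp_cnn"))
  model <- build_snp_network(obj$config)
  restore_params(snp_layers(model), obj$params)
  model$history <- obj$history
  model
}
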