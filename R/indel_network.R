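# indel_network: the 4-class indel zygosity convolutional model.
#
# Shares the trunk design of the SNP network (three parallel first-layer
# kernels, then two 2x3 convolutions; the wide 128-column input is walked
# with column stride 2 in layers 2-3); the head is a 4-class softmax over
# zygosity {hom-ref, hom-alt, het-ref, het-alt} after two hidden layers.

INDEL_CLASSES <- c("hom_ref", "hom_alt", "het_ref", "het_alt")

#' Indel network configuration
#'
#' @inheritParams snp_network_config
#' @param learning_rate,l2 training regime (defaults 1e-4 and 1e-5).
#' @param hidden2 width of the second hidden layer before the 4-class
#'   head.
#' @param input_scale fixed input multiplier (frequency tensors are
#'   already in `[-1, 1]`, so the default is 1).
#' @return named list of class `indel_network_config`.
#' @export
indel_network_config <- function(filters1 = 16L, filters23 = 32L,
                                 row_kernel = 5L, col_kernel = 5L,
                                 kernel2d = 3L, hidden = 48L,
                                 hidden2 = 16L, dropout = 0.5,
                                 learning_rate = 1e-4, l2 = 1e-5,
                                 epochs = 100L, batch_size = 32L,
                                 input_scale = 1, seed = 1L) {
  stopifnot(dropout >= 0, dropout < 1)
  structure(as.list(environment()), class = "indel_network_config")
}

#' Build the indel zygosity network
#'
#' @param config an [indel_network_config()].
#' @return model object of class `indel_cnn` mapping a 15 x 128 x 2 tensor
#'   to four zygosity probabilities.
#' @export
build_indel_network <- function(config = indel_network_config()) {
  set.seed(config$seed)
  in_shape <- c(15L, 128L, 2L)
  trunk <- conv_trunk(in_shape, f1 = config$filters1, f23 = config$filters23,
                      row_k = config$row_kernel, col_k = config$col_kernel,
                      k2d = config$kernel2d,
                      stride2 = c(1L, 2L), stride3 = c(1L, 2L))
  fc1 <- dense_layer(trunk$out_dim, config$hidden)
  fc2 <- dense_layer(config$hidden, config$hidden2)
  head <- dense_layer(config$hidden2, 4L)
  model <- list(config = config, in_shape = in_shape, trunk = trunk,
                fc1 = fc1, fc2 = fc2, head = head, history = NULL)
  class(model) <- "indel_cnn"
  model
}

indel_layers <- function(model)
  c(trunk_layers(model$trunk),
    list(fc1 = model$fc1, fc2 = model$fc2, head = model$head))

#' @export
print.indel_cnn <- function(x, ...) {
  cat(sprintf("<indel_cnn: 15x128x2 -> 4 zygosity classes; %d parameters>\n",
              n_params(indel_layers(x))))
  invisible(x)
}

indel_batch_matrix <- function(tensors) {
  vapply(tensors, as.vector, numeric(15L * 128L * 2L))
}

indel_forward <- function(model, X, train = FALSE) {
  X <- X * model$config$input_scale
  fw <- trunk_forward(model$trunk, X, train)
  c1 <- new.env(parent = emptyenv()); c2 <- new.env(parent = emptyenv())
  ch <- new.env(parent = emptyenv())
  Z1 <- dense_forward(model$fc1, fw$out, c1)
  H1 <- relu(Z1)
  M <- NULL; Hd <- H1
  if (train && model$config$dropout > 0) {
    M <- dropout_mask(H1, model$config$dropout)
    Hd <- H1 * M
  }
  Z2 <- dense_forward(model$fc2, Hd, c2)
  H2 <- relu(Z2)
  logits <- dense_forward(model$head, H2, ch)
  probs <- softmax_cols(logits)
  list(probs = probs, fw = fw, Z1 = Z1, M = M, Z2 = Z2,
       cc = list(fc1 = c1, fc2 = c2, head = ch))
}

indel_backward <- function(model, f, onehot) {
  B <- ncol(onehot)
  dLogits <- (f$probs - onehot) / B
  dH2 <- dense_backward(model$head, dLogits, f$cc$head)
  dZ2 <- relu_grad(dH2, f$Z2)
  dHd <- dense_backward(model$fc2, dZ2, f$cc$fc2)
  dH1 <- if (is.null(f$M)) dHd else dHd * f$M
  dZ1 <- relu_grad(dH1, f$Z1)
  dFlat <- dense_backward(model$fc1, dZ1, f$cc$fc1)
  trunk_backward(model$trunk, f$fw, dFlat)
  invisible(NULL)
}

#' Train the indel network
#'
#' Cross-entropy over the four zygosity classes with Adam and L2 decay.
#' Classes absent from the training data raise a warning but training
#' proceeds.
#'
#' @param model a [build_indel_network()] model.
#' @param examples labelled set with `features` (3840 x N matrix) and
#'   `class` (integers 1-4 over hom-ref, hom-alt, het-ref, het-alt).
#' @param epochs,batch_size,learning_rate overrides of the model config.
#' @param balance_classes if `TRUE`, each epoch resamples examples with
#'   inverse-class-frequency weights so rare zygosity classes (typically
#'   het-alt) are not drowned out.
#' @param verbose print per-epoch loss.
#' @return trained model with `$history`.
#' @export
train_indel_network <- function(model, examples,
                                epochs = model$config$epochs,
                                batch_size = model$config$batch_size,
                                learning_rate = model$config$learning_rate,
                                balance_classes = TRUE,
                                verbose = FALSE) {
  X <- examples$features
  cls <- examples$class
  n <- ncol(X)
  if (n == 0) stopf("empty training set")
  missing_cls <- setdiff(1:4, unique(cls))
  if (length(missing_cls) > 0)
    warning(sprintf("zygosity class(es) %s absent from training data",
                    paste(INDEL_CLASSES[missing_cls], collapse = ", ")),
            call. = FALSE)
  layers <- indel_layers(model)
  set.seed(model$config$seed + 1L)
  t <- 0L
  history <- numeric(epochs)
  wts <- if (balance_classes) {
    freq <- tabulate(cls, 4L)
    (1 / pmax(freq, 1L))[cls]
  } else rep(1, n)
  for (ep in seq_len(epochs)) {
    ord <- if (balance_classes) sample.int(n, n, replace = TRUE, prob = wts)
           else sample.int(n)
    losses <- c()
    for (s in seq(1L, n, by = batch_size)) {
      idx <- ord[s:min(s + batch_size - 1L, n)]
      oh <- vapply(cls[idx], function(k) as.numeric(1:4 == k), numeric(4))
      f <- indel_forward(model, X[, idx, drop = FALSE], train = TRUE)
      losses <- c(losses, -sum(oh * log(f$probs + 1e-12)) / length(idx))
      indel_backward(model, f, oh)
      t <- t + 1L
      for (L in layers) adam_update(L, learning_rate, model$config$l2, t)
    }
    history[ep] <- mean(losses)
    if (verbose) message(sprintf("epoch %d/%d loss %.4f", ep, epochs,
                                 history[ep]))
  }
  model$history <- history
  model
}

#' Predict zygosity probabilities for indel candidates
#'
#' @param model trained [build_indel_network()] model.
#' @param tensors list of 15 x 128 x 2 tensors (or a prebuilt batch
#'   matrix).
#' @return N x 4 matrix of class probabilities (columns hom_ref, hom_alt,
#'   het_ref, het_alt; rows sum to 1).
#' @export
predict_indel_network <- function(model, tensors) {
  X <- if (is.matrix(tensors)) tensors else indel_batch_matrix(tensors)
  n <- ncol(X)
  P <- matrix(NA_real_, n, 4L, dimnames = list(NULL, INDEL_CLASSES))
  for (s in seq(1L, n, by = 256L)) {
    idx <- s:min(s + 255L, n)
    f <- indel_forward(model, X[, idx, drop = FALSE], train = FALSE)
    P[idx, ] <- t(f$probs)
  }
  P
}

#' Call an indel from zygosity probabilities and pileups
#'
#' Hom-ref argmax yields no call. Hom-alt argmax takes the consensus of the
#' all-reads pileup and infers the allele against the reference window
#' (genotype `1/1`). A heterozygous argmax infers per-phase alleles from
#' the two phase pileups and combines them into a phased call. QUAL is
#' `-100 log10(1 - P(winning class))`.
#'
#' @param probs length-4 named probability vector (order hom_ref, hom_alt,
#'   het_ref, het_alt).
#' @param pileups list with `all`, `phase1`, `phase2` [msa_realign()]
#'   pileups (phase entries may be `NULL`).
#' @param candidate list with `chrom`, `pos` (0-based window start) and
#'   `ref_window`.
#' @return a [variant_calls()] table or `NULL` (no call).
#' @export
call_indel <- function(probs, pileups, candidate) {
  stopifnot(length(probs) == 4)
  win <- which.max(probs)
  if (win == 1L) return(NULL)
  qual <- quality_score(stats::setNames(probs[win], "x"), "x")
  if (win == 2L) {                         # homozygous alternative
    cons <- consensus_from_msa(pileups$all)
    a <- infer_allele(cons, candidate$ref_window)
    if (is.null(a)) return(NULL)
    return(variant_calls(candidate$chrom, candidate$pos + a$offset + 1L,
                         a$ref, a$alt, "1/1", qual))
  }
  inf_phase <- function(p) {
    if (is.null(p) || p$n_reads == 0) return(NULL)
    infer_allele(consensus_from_msa(p), candidate$ref_window)
  }
  a1 <- inf_phase(pileups$phase1)
  a2 <- inf_phase(pileups$phase2)
  combine_phase_calls(a1, a2, candidate$chrom, candidate$pos, qual)
}

#' Save / load an indel model
#' @param model trained model.
#' @param path checkpoint path.
#' @return `path` invisibly (`save`), the model (`load`).
#' @export
save_indel_model <- function(model, path) {
  saveRDS(list(kind = "indel_cnn", config = model$config,
               params = collect_params(indel_layers(model)),
               history = model$history), path)
  invisible(path)
}

#' @rdname save_indel_model
#' @export
load_indel_model <- function(path) {
  obj <- readRDS(path)
  stopifnot(identical(obj$kind, "indel_cnn"))
  model <- build_indel_network(obj$config)
  restore_params(indel_layers(model), obj$params)
  model$history <- obj$history
  model
}
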