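# Training protocol: Adam on squared error, seeded minibatch shuffling,
# per-epoch loss curves, and case-level k-fold assignment.

#' Adam optimizer configuration
#'
#' Defaults alpha = 0.001, beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8.
#'
#' @param alpha learning rate.
#' @param beta1,beta2 exponential decay rates of the moment estimates.
#' @param epsilon numerical stabilizer.
#' @export
optimizer_config <- function(alpha = 0.001, beta1 = 0.9, beta2 = 0.999,
                             epsilon = 1e-8) {
  stopifnot(alpha > 0, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1,
            epsilon > 0)
  structure(list(alpha = alpha, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon), class = "optimizer_config")
}

#' Training configuration
#'
#' The clinical protocol this emulates used 50 epochs with six-fold
#' cross-validation for the indirect method and 30 epochs with seven- and
#' ten-fold cross-validation for the direct and direct+HRC methods; toy
#' runs scale these down.
#'
#' @param epochs training epochs (>= 1).
#' @param batch_size minibatch size.
#' @param k_folds folds for cross-validation (>= 2), or `NULL`.
#' @param seed seed covering initialization-independent training
#'   stochasticity (batch shuffling).
#' @param loss only `"squared_error"` is supported.
#' @export
train_config <- function(epochs, batch_size = 8, k_folds = NULL, seed = 1,
                         loss = "squared_error") {
  stopifnot(epochs >= 1, batch_size >= 1,
            is.null(k_folds) || k_folds >= 2,
            identical(loss, "squared_error"))
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 k_folds = if (is.null(k_folds)) NULL else as.integer(k_folds),
                 seed = as.integer(seed), loss = loss),
            class = "train_config")
}

as_batch_array <- function(images) {
  if (is.array(images) && length(dim(images)) == 3L) {
    d <- dim(images)
    return(array(images, c(d[1], d[2], 1, d[3])))
  }
  if (is.list(images)) {
    if (!length(images))
      stop("argument error: empty pair set", call. = FALSE)
    d <- dim(images[[1]])
    out <- array(0, c(d[1], d[2], 1, length(images)))
    for (i in seq_along(images)) out[, , 1, i] <- images[[i]]
    return(out)
  }
  stop("images must be a list of matrices or an H x W x N array",
       call. = FALSE)
}

adam_step <- function(params, grads, state, opt, t) {
  corr1 <- 1 - opt$beta1^t
  corr2 <- 1 - opt$beta2^t
  for (nm in names(grads)) {
    for (pn in names(grads[[nm]])) {
      g <- grads[[nm]][[pn]]
      key <- paste0(nm, ".", pn)
      st <- state[[key]]
      if (is.null(st)) st <- list(m = 0 * g, v = 0 * g)
      st$m <- opt$beta1 * st$m + (1 - opt$beta1) * g
      st$v <- opt$beta2 * st$v + (1 - opt$beta2) * g * g
      state[[key]] <- st
      mhat <- st$m / corr1
      vhat <- st$v / corr2
      params[[nm]][[pn]] <- params[[nm]][[pn]] -
        opt$alpha * mhat / (sqrt(vhat) + opt$epsilon)
    }
  }
  list(params = params, state = state)
}

#' Train a U-net on image pairs
#'
#' Minimizes mean squared error between network output and target. Images
#' arrive on the 0-255 display scale and are divided by 255 internally for
#' conditioning; predictions are rescaled on output. Training is fully
#' seeded: identical `(model, pairs, opt, tcfg)` give identical weights and
#' loss curves on a fixed single-threaded BLAS.
#'
#' @param model a `petac_unet` from [build_unet()].
#' @param inputs,targets lists of matrices (or `H x W x N` arrays) on the
#'   0-255 scale, pairwise aligned.
#' @param opt an [optimizer_config()].
#' @param tcfg a [train_config()].
#' @return the trained model; the per-epoch mean training loss is attached
#'   as `model$loss_curve`.
#' @export
unet_train <- function(model, inputs, targets, opt = optimizer_config(),
                       tcfg) {
  stopifnot(inherits(model, "petac_unet"), inherits(opt, "optimizer_config"),
            inherits(tcfg, "train_config"))
  x <- as_batch_array(inputs) / 255
  y <- as_batch_array(targets) / 255
  if (!all(dim(x) == dim(y)))
    stop("argument error: input/target shapes differ", call. = FALSE)
  n <- dim(x)[4]
  if (n < 1) stop("argument error: empty pair set", call. = FALSE)
  state <- list()
  t_global <- 0L
  loss_curve <- numeric(tcfg$epochs)
  with_seed(tcfg$seed, {
    for (ep in seq_len(tcfg$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1, n, by = tcfg$batch_size)) {
        idx <- ord[start:min(start + tcfg$batch_size - 1L, n)]
        xb <- x[, , , idx, drop = FALSE]
        yb <- y[, , , idx, drop = FALSE]
        fw <- unet_forward(model, xb, training = TRUE)
        model <- merge_running_stats(model, fw$caches)
        resid <- fw$out - yb
        losses <- c(losses, mean(resid^2))
        dout <- 2 * resid / length(resid)
        grads <- unet_backward(model, fw, dout)
        t_global <- t_global + 1L
        upd <- adam_step(model$params, grads, state, opt, t_global)
        model$params <- upd$params
        state <- upd$state
      }
      loss_curve[ep] <- mean(losses)
    }
    # recalibrate batch-norm inference statistics under the final weights:
    # one pass over the training set accumulating fresh cumulative averages
    for (nm in names(model$params)) {
      if (!is.null(model$params[[nm]]$run_n)) model$params[[nm]]$run_n <- 0
    }
    for (start in seq(1, n, by = tcfg$batch_size)) {
      idx <- start:min(start + tcfg$batch_size - 1L, n)
      fw <- unet_forward(model, x[, , , idx, drop = FALSE], training = TRUE)
      model <- merge_running_stats(model, fw$caches)
    }
  })
  model$trained <- TRUE
  model$loss_curve <- loss_curve
  model
}

#' Assign cases to cross-validation folds
#'
#' Seeded uniform random partition of case identifiers into `k` folds whose
#' sizes differ by at most one. Splitting is by case: augmented copies of a
#' case always share its fold.
#'
#' @param case_ids character vector of unique case identifiers.
#' @param k number of folds (2 <= k <= number of cases).
#' @param seed integer seed.
#' @return named integer vector mapping case_id to fold in `1..k`.
#' @export
kfold_split <- function(case_ids, k, seed = 1) {
  n <- length(case_ids)
  if (k > n) stop("argument error: more folds than cases", call. = FALSE)
  if (anyDuplicated(case_ids)) stop("case_ids must be unique", call. = FALSE)
  perm <- with_seed(seed, sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), length.out = n)
  setNames(fold, case_ids)
}
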