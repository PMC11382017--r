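#' Specification of the multi-trait convolutional regression network
#'
#' The network has two parts. A nonlinear feature extractor — `conv_blocks`
#' blocks of (3x3 conv, batch norm, ReLU, 2x2 max pool), a flatten, and
#' `length(fc_dims)` hidden linear layers with ReLU and dropout — ends in a
#' linear layer of width `feature_dim` (the 30-dimensional latent bottleneck)
#' followed by a *non-affine* batch normalization, so the latent features are
#' approximately standardized during training. A purely linear regression
#' head (weights `W`: `feature_dim x 5`, bias `b`) maps features to the five
#' trait estimates; no activation follows it, so estimates are exactly
#' `X W + 1 b'`.
#'
#' With the defaults (5 conv blocks, 2 hidden linear layers) the network has
#' 14 weighted layers: 5 conv + 5 batch norm + 2 hidden linear + the feature
#' layer + the head. The exact published stack is not available; this default
#' is a documented reconstruction satisfying every stated constraint and is
#' fully overridable.
#'
#' @param variant `"rgb"` (3 input channels), `"dsm"` (1), or `"rgb_dsm"`
#'   (early fusion by channel concatenation, 4).
#' @param conv_filters filter counts per conv block.
#' @param fc_dims widths of the hidden linear layers.
#' @param feature_dim latent bottleneck width (default 30).
#' @param output_dim number of traits (default 5).
#' @param dropout_rate dropout on hidden linear activations during training.
#' @param use_batchnorm enable batch normalization in conv blocks.
#' @return A `model_spec` object.
#' @export
model_spec <- function(variant = c("rgb_dsm", "rgb", "dsm"),
                       conv_filters = c(8, 16, 32, 32, 64),
                       fc_dims = c(128, 64),
                       feature_dim = 30,
                       output_dim = 5,
                       dropout_rate = 0.1,
                       use_batchnorm = TRUE) {
  variant <- match.arg(variant)
  input_channels <- c(rgb = 3L, dsm = 1L, rgb_dsm = 4L)[[variant]]
  structure(list(variant = variant, input_channels = input_channels,
                 conv_filters = as.integer(conv_filters),
                 fc_dims = as.integer(fc_dims),
                 feature_dim = as.integer(feature_dim),
                 output_dim = as.integer(output_dim),
                 dropout_rate = dropout_rate,
                 use_batchnorm = isTRUE(use_batchnorm),
                 n_blocks = length(conv_filters),
                 bn_momentum = 0.1),
            class = "model_spec")
}

#' Training schedule for the network
#'
#' Defaults follow the published schedule: 100 epochs, Adam with initial
#' learning rate 0.001, batch size 128, MSE loss, and reduce-on-plateau
#' learning-rate scheduling (factor 0.5, patience 5, minimum 1e-6). The
#' checkpoint with the lowest validation MSE is returned.
#'
#' @param epochs,lr,batch_size,factor,patience,min_lr schedule parameters.
#' @param seed integer seed controlling initialization order, shuffling, and
#'   dropout.
#' @export
train_config <- function(epochs = 100, lr = 0.001, batch_size = 128,
                         factor = 0.5, patience = 5, min_lr = 1e-6,
                         seed = 1L) {
  stopifnot(epochs >= 1, lr > 0, batch_size >= 1, min_lr < lr)
  structure(list(epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size), factor = factor,
                 patience = as.integer(patience), min_lr = min_lr,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Build (initialize) a network for a given input size
#'
#' He-style initialization for conv and linear weights; batch-norm scales
#' start at 1, running statistics at (0, 1). The spatial size must be
#' divisible by `2^n_blocks` (each block halves it via max pooling).
#'
#' @param spec a [model_spec()].
#' @param input_h,input_w input image size in pixels.
#' @param seed initialization seed.
#' @return An `lsp_cnn`: list with `spec`, `params`, `input_h`, `input_w`,
#'   `n_params`.
#' @export
build_model <- function(spec, input_h, input_w, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  nb <- spec$n_blocks
  h <- input_h; w <- input_w
  for (l in seq_len(nb)) {
    if (h %% 2 != 0 || w %% 2 != 0)
      stop(sprintf("pool layer of conv block %d: input %dx%d is not even",
                   l, h, w), call. = FALSE)
    h <- h / 2; w <- w / 2
  }
  with_seed(seed, {
    in_c <- spec$input_channels
    conv_W <- conv_b <- bn_gamma <- bn_beta <- bn_rmean <- bn_rvar <-
      vector("list", nb)
    for (l in seq_len(nb)) {
      oc <- spec$conv_filters[l]
      conv_W[[l]] <- matrix(rnorm(oc * in_c * 9, 0, sqrt(2 / (in_c * 9))),
                            oc, in_c * 9)
      conv_b[[l]] <- rep(0, oc)
      bn_gamma[[l]] <- rep(1, oc); bn_beta[[l]] <- rep(0, oc)
      bn_rmean[[l]] <- rep(0, oc); bn_rvar[[l]] <- rep(1, oc)
      in_c <- oc
    }
    dims <- c(h * w * in_c, spec$fc_dims, spec$feature_dim)
    fc_W <- fc_b <- vector("list", length(dims) - 1)
    for (l in seq_along(fc_W)) {
      fc_W[[l]] <- matrix(rnorm(dims[l] * dims[l + 1], 0, sqrt(2 / dims[l])),
                          dims[l], dims[l + 1])
      fc_b[[l]] <- rep(0, dims[l + 1])
    }
    params <- list(conv_W = conv_W, conv_b = conv_b,
                   bn_gamma = bn_gamma, bn_beta = bn_beta,
                   bn_rmean = bn_rmean, bn_rvar = bn_rvar,
                   fc_W = fc_W, fc_b = fc_b,
                   feat_rmean = rep(0, spec$feature_dim),
                   feat_rvar = rep(1, spec$feature_dim),
                   head_W = matrix(rnorm(spec$feature_dim * spec$output_dim,
                                         0, sqrt(1 / spec$feature_dim)),
                                   spec$feature_dim, spec$output_dim),
                   head_b = rep(0, spec$output_dim))
    n_par <- sum(vapply(c(conv_W, conv_b, bn_gamma, bn_beta, fc_W, fc_b,
                          list(params$head_W, params$head_b)),
                        length, 0L))
    structure(list(spec = spec, params = params, input_h = input_h,
                   input_w = input_w, n_params = n_par),
              class = "lsp_cnn")
  })
}

cpp_spec <- function(spec) {
  list(n_blocks = spec$n_blocks, use_batchnorm = spec$use_batchnorm,
       bn_momentum = spec$bn_momentum)
}

check_input <- function(model, x) {
  d <- dim(x)
  if (length(d) != 4) stop("input must be a 4-d array [H, W, C, N]")
  if (d[3] != model$spec$input_channels)
    stop(sprintf("variant '%s' expects %d input channels, got %d",
                 model$spec$variant, model$spec$input_channels, d[3]),
         call. = FALSE)
  if (d[1] != model$input_h || d[2] != model$input_w)
    stop(sprintf("model built for %dx%d input, got %dx%d",
                 model$input_h, model$input_w, d[1], d[2]), call. = FALSE)
  invisible(TRUE)
}

#' Forward pass in inference mode
#'
#' @param model an `lsp_cnn`.
#' @param x input array `[H, W, C, N]`.
#' @return List with `features` (`N x feature_dim`, post-bottleneck,
#'   normalized with running statistics) and `preds` (`N x 5`).
#' @export
cnn_forward <- function(model, x) {
  check_input(model, x)
  out <- cnn_batch_cpp(model$params, cpp_spec(model$spec), x,
                       matrix(numeric(0), 0, 0), FALSE, FALSE, 0)
  list(features = out$features, preds = out$preds)
}

# Trainable leaves of the parameter list (running stats excluded).
.trainable <- c("conv_W", "conv_b", "bn_gamma", "bn_beta", "fc_W", "fc_b",
                "head_W", "head_b")

adam_init <- function(params) {
  zero_like <- function(x) if (is.list(x)) lapply(x, zero_like) else x * 0
  list(m = lapply(params[.trainable], zero_like),
       v = lapply(params[.trainable], zero_like), t = 0L)
}

adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - b1^state$t; corr2 <- 1 - b2^state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      for (i in seq_along(p)) {
        r <- upd(p[[i]], g[[i]], m[[i]], v[[i]])
        p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    if (is.null(dim(p))) g <- as.numeric(g) # C++ returns biases as 1 x n
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    p <- p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
    list(p = p, m = m, v = v)
  }
  for (nm in .trainable) {
    r <- upd(params[[nm]], grads[[nm]], state$m[[nm]], state$v[[nm]])
    params[[nm]] <- r$p; state$m[[nm]] <- r$m; state$v[[nm]] <- r$v
  }
  list(params = params, state = state)
}

#' Train the network
#'
#' Minimizes the mean squared error of the five (normalized) trait targets
#' jointly with Adam, shuffled mini-batches, and reduce-on-plateau learning
#' rate scheduling. The parameter snapshot with the lowest validation MSE is
#' the one returned ("best model"). Fully deterministic given `cfg$seed` in
#' single-threaded mode.
#'
#' @param model an `lsp_cnn` from [build_model()].
#' @param x_train,y_train training inputs `[H, W, C, N]` and normalized
#'   targets (`N x 5`).
#' @param x_val,y_val validation split used for checkpoint selection and the
#'   scheduler.
#' @param cfg a [train_config()].
#' @return List with `model` (best checkpoint), `log` (per-epoch data frame:
#'   `epoch`, `train_mse`, `val_mse`, `lr`), `best_epoch`.
#' @export
train_model <- function(model, x_train, y_train, x_val, y_val,
                        cfg = train_config()) {
  check_input(model, x_train)
  y_train <- as.matrix(y_train); y_val <- as.matrix(y_val)
  n <- dim(x_train)[4]
  stopifnot(n == nrow(y_train), dim(x_val)[4] == nrow(y_val), n >= 1)
  params <- model$params
  state <- adam_init(params)
  lr <- cfg$lr
  best_mse <- Inf; best_params <- params; best_epoch <- 0L
  plateau_best <- Inf; plateau_count <- 0L
  log <- vector("list", cfg$epochs)
  set.seed(cfg$seed)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    for (bi in seq_along(batches)) {
      ids <- batches[[bi]]
      out <- cnn_batch_cpp(params, cpp_spec(model$spec),
                           x_train[, , , ids, drop = FALSE],
                           y_train[ids, , drop = FALSE],
                           TRUE, TRUE, model$spec$dropout_rate)
      if (!is.finite(out$loss))
        stop(sprintf("non-finite loss at epoch %d batch %d (n=%d)",
                     epoch, bi, length(ids)), call. = FALSE)
      params$bn_rmean <- out$bn_rmean; params$bn_rvar <- out$bn_rvar
      params$feat_rmean <- out$feat_rmean; params$feat_rvar <- out$feat_rvar
      st <- adam_step(params, out$grads, state, lr)
      params <- st$params; state <- st$state
      ep_loss <- ep_loss + out$loss * length(ids)
    }
    val <- cnn_batch_cpp(params, cpp_spec(model$spec), x_val, y_val,
                         FALSE, FALSE, 0)
    val_mse <- val$loss
    log[[epoch]] <- data.frame(epoch = epoch, train_mse = ep_loss / n,
                               val_mse = val_mse, lr = lr)
    if (val_mse < best_mse) {
      best_mse <- val_mse; best_params <- params; best_epoch <- epoch
    }
    # reduce-on-plateau
    if (val_mse < plateau_best - 1e-8) {
      plateau_best <- val_mse; plateau_count <- 0L
    } else {
      plateau_count <- plateau_count + 1L
      if (plateau_count > cfg$patience) {
        lr <- max(lr * cfg$factor, cfg$min_lr)
        plateau_count <- 0L
      }
    }
  }
  model$params <- best_params
  list(model = model, log = do.call(rbind, log), best_epoch = best_epoch,
       best_val_mse = best_mse)
}

#' Extract standardized latent features and the matching linear head
#'
#' Runs the feature extractor on `x`, then standardizes the 30 features with
#' mean/SD computed on the reference rows (`ref_rows`, default all). The
#' regression head is re-expressed in the scaled coordinates (`W* = diag(s) W`,
#' `b* = b + W' m`), so `X W* + 1 b*'` reproduces the model's own estimates
#' exactly — the identity the PC-space weight rotation relies on. Features
#' that are constant on the reference set keep SD 1 (their contribution moves
#' entirely into the bias).
#'
#' @param model an `lsp_cnn`.
#' @param x input array `[H, W, C, N]`.
#' @param ref_rows rows used to fit the scaling statistics.
#' @return A `latent_features` object: `X` (`N x 30` scaled), `scaling_mean`,
#'   `scaling_sd`, `W` (`30 x 5`), `b` (length 5), `preds` (`N x 5`).
#' @export
extract_features <- function(model, x, ref_rows = NULL) {
  fw <- cnn_forward(model, x)
  f <- fw$features
  if (is.null(ref_rows)) ref_rows <- seq_len(nrow(f))
  mu <- colMeans(f[ref_rows, , drop = FALSE])
  sdv <- apply(f[ref_rows, , drop = FALSE], 2, sd)
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
  X <- sweep(sweep(f, 2, mu), 2, sdv, `/`)
  W <- model$params$head_W * sdv          # row-wise scale
  b <- model$params$head_b + as.numeric(crossprod(model$params$head_W, mu))
  structure(list(X = X, scaling_mean = mu, scaling_sd = sdv,
                 W = W, b = b, preds = fw$preds),
            class = "latent_features")
}

#' Cross-validation fold scheme
#'
#' k-fold assignments with repetitions over either plots or accessions
#' (accession-wise folds keep all replicates of a line together, avoiding
#' kinship leakage through the GRM).
#'
#' @param k number of folds (default 10).
#' @param repetitions number of repetitions (default 20).
#' @param unit `"accession"` or `"plot"`.
#' @param seed scheme seed; fold maps are deterministic in (seed, rep).
#' @export
cv_scheme <- function(k = 10, repetitions = 20,
                      unit = c("accession", "plot"), seed = 1L) {
  unit <- match.arg(unit)
  structure(list(k = as.integer(k), repetitions = as.integer(repetitions),
                 unit = unit, seed = as.integer(seed)),
            class = "cv_scheme")
}

#' @rdname cv_scheme
#' @param scheme a `cv_scheme`.
#' @param rep repetition index in `1:repetitions`.
#' @param units character vector of unit ids to partition.
#' @return Named integer vector mapping each unit to its fold.
#' @export
fold_map <- function(scheme, rep, units) {
  stopifnot(rep >= 1, rep <= scheme$repetitions)
  with_seed(derive_seed(scheme$seed, 1000L + rep), {
    f <- rep_len(seq_len(scheme$k), length(units))[sample.int(length(units))]
    names(f) <- units
    f
  })
}

#' Assemble the model input tensor for a dataset subset
#'
#' Stacks the channels the chosen variant consumes: RGB in \[0, 1\], and/or
#' the DSM divided by the dataset's `dsm_scale` so heights are O(1).
#'
#' @param dataset an `lsp_dataset`.
#' @param spec a [model_spec()].
#' @param rows plot rows to include (default all).
#' @return Array `[H, W, C, length(rows)]`.
#' @export
build_input <- function(dataset, spec, rows = seq_len(nrow(dataset$meta))) {
  h <- dim(dataset$rgb)[1]; w <- dim(dataset$rgb)[2]
  n <- length(rows)
  x <- array(0, dim = c(h, w, spec$input_channels, n))
  if (spec$variant %in% c("rgb", "rgb_dsm"))
    x[, , 1:3, ] <- dataset$rgb[, , , rows, drop = FALSE]
  if (spec$variant == "dsm")
    x[, , 1, ] <- dataset$dsm[, , rows, drop = FALSE] / dataset$dsm_scale
  if (spec$variant == "rgb_dsm")
    x[, , 4, ] <- dataset$dsm[, , rows, drop = FALSE] / dataset$dsm_scale
  x
}

# Flip augmentation on an assembled tensor (training folds only by default).
augment_tensor <- function(x, y) {
  h <- dim(x)[1]; w <- dim(x)[2]
  xs <- list(x,
             x[h:1, , , , drop = FALSE],
             x[, w:1, , , drop = FALSE],
             x[h:1, w:1, , , drop = FALSE])
  list(x = array(unlist(xs), dim = c(h, w, dim(x)[3], 4 * dim(x)[4])),
       y = do.call(rbind, rep(list(as.matrix(y)), 4)))
}

#' Cross-validated training and evaluation of the network
#'
#' For each repetition and fold: a fresh model is trained on the training
#' plots (optionally flip-augmented; the held-out fold doubles as the
#' validation split for checkpoint selection, replicating the published
#' protocol), held-out estimates are produced, and Pearson correlations are
#' computed per trait overall and within each treatment subgroup. Subgroups
#' with fewer than 3 held-out plots yield an undefined `r` (`NA`), excluded
#' from the summary with a logged count.
#'
#' @param dataset an `lsp_dataset` from [prepare_dataset()].
#' @param spec a [model_spec()].
#' @param cfg a [train_config()].
#' @param scheme a [cv_scheme()].
#' @param augment_train flip-augment training folds.
#' @param augment_before_split fidelity flag: augment the whole dataset
#'   before splitting (replicates the published protocol's leakage of
#'   flipped twins; off by default).
#' @return List with `metrics` (rep, fold, trait, subgroup, r, n),
#'   `summary` (mean/sd of r by trait and subgroup), `n_undefined`,
#'   `predictions`.
#' @export
crossvalidate <- function(dataset, spec, cfg, scheme,
                          augment_train = FALSE,
                          augment_before_split = FALSE) {
  meta <- dataset$meta
  y <- dataset$traits$normalized
  units <- if (scheme$unit == "accession") unique(meta$accession)
           else meta$plot_id
  rows_of <- function(f, fold) {
    sel <- names(f)[f == fold]
    if (scheme$unit == "accession") which(meta$accession %in% sel)
    else which(meta$plot_id %in% sel)
  }
  metrics <- list(); preds_out <- list()
  for (r in seq_len(scheme$repetitions)) {
    fm <- fold_map(scheme, r, units)
    for (k in seq_len(scheme$k)) {
      test_rows <- rows_of(fm, k)
      train_rows <- setdiff(seq_len(nrow(meta)), test_rows)
      if (length(test_rows) == 0) next
      x_tr <- build_input(dataset, spec, train_rows)
      y_tr <- y[train_rows, , drop = FALSE]
      x_te <- build_input(dataset, spec, test_rows)
      y_te <- y[test_rows, , drop = FALSE]
      if (augment_before_split) {
        a <- augment_tensor(x_tr, y_tr); x_tr <- a$x; y_tr <- a$y
        a <- augment_tensor(x_te, y_te) # flipped twins of test plots exist
        x_tr <- array(c(x_tr, a$x), dim = dim(x_tr) + c(0, 0, 0, dim(a$x)[4]))
        y_tr <- rbind(y_tr, a$y)
      } else if (augment_train) {
        a <- augment_tensor(x_tr, y_tr); x_tr <- a$x; y_tr <- a$y
      }
      model <- build_model(spec, dim(x_tr)[1], dim(x_tr)[2],
                           seed = derive_seed(cfg$seed, r * 100L + k))
      fit <- train_model(model, x_tr, y_tr, x_te, y_te,
                         modifyList(cfg, list(
                           seed = derive_seed(cfg$seed, r * 100L + k + 17L))))
      est <- cnn_forward(fit$model, x_te)$preds
      preds_out[[paste(r, k)]] <-
        data.frame(rep = r, fold = k, row = test_rows, est)
      groups <- c(list(overall = seq_along(test_rows)),
                  split(seq_along(test_rows), meta$treatment[test_rows]))
      for (gn in names(groups)) {
        g <- groups[[gn]]
        for (t in seq_along(TRAITS)) {
          rr <- if (length(g) < 3) NA_real_ else pearson(est[g, t], y_te[g, t])
          metrics[[length(metrics) + 1]] <-
            data.frame(rep = r, fold = k, trait = TRAITS[t], subgroup = gn,
                       r = rr, n = length(g))
        }
      }
    }
  }
  metrics <- do.call(rbind, metrics)
  summ <- do.call(rbind, lapply(split(metrics, list(metrics$trait,
                                                    metrics$subgroup)),
    function(d) data.frame(trait = d$trait[1], subgroup = d$subgroup[1],
                           mean_r = mean(d$r, na.rm = TRUE),
                           sd_r = sd(d$r, na.rm = TRUE),
                           n_folds = sum(!is.na(d$r)))))
  rownames(summ) <- NULL
  list(metrics = metrics, summary = summ,
       n_undefined = sum(is.na(metrics$r)),
       predictions = do.call(rbind, preds_out))
}
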