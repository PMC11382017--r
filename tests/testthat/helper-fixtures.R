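# Shared fixtures, built in code and cached per test run.

.fixtures <- new.env()

# A small rendered field: 12 accessions x 2 treatments x 2 reps, 32x32 px.
small_field <- function() {
  if (is.null(.fixtures$field)) {
    cfg <- field_config(n_accessions = 12, n_reps = 2, n_snps = 80,
                        n_qtl = 10, image_height = 32, image_width = 32,
                        missing_rate = 0.05, rng_seed = 42)
    .fixtures$field <- simulate_field(cfg)
  }
  .fixtures$field
}

small_dataset <- function() {
  if (is.null(.fixtures$dataset)) .fixtures$dataset <-
      prepare_dataset(small_field())
  .fixtures$dataset
}

# A tiny trained network on the small dataset (rgb_dsm, few epochs).
small_trained <- function() {
  if (is.null(.fixtures$trained)) {
    ds <- small_dataset()
    spec <- model_spec("rgb_dsm", conv_filters = c(4, 8), fc_dims = c(16),
                       feature_dim = 30, dropout_rate = 0)
    n <- nrow(ds$meta)
    val <- seq(1, n, by = 5)
    tr <- setdiff(seq_len(n), val)
    x_tr <- build_input(ds, spec, tr)
    x_val <- build_input(ds, spec, val)
    model <- build_model(spec, 32, 32, seed = 9)
    fit <- train_model(model, x_tr, ds$traits$normalized[tr, ],
                       x_val, ds$traits$normalized[val, ],
                       train_config(epochs = 4, batch_size = 16, seed = 2))
    .fixtures$trained <- list(fit = fit, ds = ds, spec = spec,
                              tr = tr, val = val)
  }
  .fixtures$trained
}

# Genotype matrix built directly from a score matrix.
geno_from_scores <- function(scores, acc = NULL, snp = NULL) {
  acc <- acc %||% sprintf("A%02d", seq_len(nrow(scores)))
  snp <- snp %||% sprintf("S%02d", seq_len(ncol(scores)))
  lspheno:::new_genotype_matrix(scores, acc, snp)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Direct (loop-based) 3x3 same-padding convolution oracle.
conv3_oracle <- function(x, W, b) {
  H <- dim(x)[1]; Wd <- dim(x)[2]; C <- dim(x)[3]
  oc <- nrow(W)
  out <- array(0, c(H, Wd, oc))
  for (o in seq_len(oc)) {
    for (i in seq_len(H)) for (j in seq_len(Wd)) {
      acc <- b[o]
      for (c in seq_len(C)) for (di in -1:1) for (dj in -1:1) {
        si <- i + di; sj <- j + dj
        if (si >= 1 && si <= H && sj >= 1 && sj <= Wd) {
          r <- (c - 1) * 9 + (di + 1) * 3 + (dj + 1) + 1
          acc <- acc + W[o, r] * x[si, sj, c]
        }
      }
      out[i, j, o] <- acc
    }
  }
  out
}

# A small latent "world" with genetic signal confined to a rank-2 direction:
# two polygenic scores u1, u2 spread across all 30 latent features; the
# remaining variation is plot-level noise no genomic model can predict.
make_latent_world <- function(m = 24, reps = 2, n_snps = 150, seed = 1,
                              treatments = "control", noise_sd = 0.5,
                              trait_noise = 0) {
  cfg <- field_config(n_accessions = m, n_reps = reps,
                      treatments = treatments, n_snps = n_snps, n_qtl = 20,
                      missing_rate = 0, rng_seed = seed)
  geno <- simulate_genotypes(cfg)
  set.seed(seed + 1)
  Xc <- scale(geno$scores, scale = FALSE)
  u <- sapply(1:2, function(i)
    scale(Xc %*% (rnorm(n_snps) * (runif(n_snps) < 0.2)))[, 1])
  meta <- expand.grid(replicate = seq_len(reps), accession = geno$accession_ids,
                      treatment = treatments, stringsAsFactors = FALSE)
  n <- nrow(meta)
  s <- u[match(meta$accession, geno$accession_ids), ] * 2 +
    matrix(rnorm(n * 2, 0, 0.3), n, 2)
  a1 <- rnorm(30); a2 <- rnorm(30)
  X <- outer(s[, 1], a1) + outer(s[, 2], a2) +
    matrix(rnorm(n * 30, 0, noise_sd), n, 30)
  set.seed(seed + 2)
  W <- matrix(rnorm(30 * 5, 0, 0.3), 30, 5)
  b <- rnorm(5)
  preds <- sweep(X %*% W, 2, b, `+`)
  traits <- preds + matrix(rnorm(n * 5, 0, trait_noise), n, 5)
  colnames(traits) <- TRAITS
  feats <- structure(list(X = X, scaling_mean = rep(0, 30),
                          scaling_sd = rep(1, 30), W = W, b = b,
                          preds = preds),
                     class = "latent_features")
  # tiny panels can produce monomorphic columns; the GRM warning is expected
  list(features = feats, traits = traits, meta = meta,
       grm = suppressWarnings(compute_grm(geno)), geno = geno)
}

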