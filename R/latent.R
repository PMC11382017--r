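#' PCA of the standardized latent features
#'
#' Eigendecomposition of the covariance of the (already column-standardized)
#' latent feature matrix. Scores are `S = (X - 1 center') E`; because `E` is
#' orthonormal, `X` is recovered exactly as `S E' + 1 center'`. The stored
#' `center` keeps the bias algebra of the PC-space head exact on held-out
#' rows. Rank-deficient covariances have their eigenvalues clipped at 0 with
#' a warning.
#'
#' @param X numeric matrix (rows = samples), or a `latent_features` object.
#' @return A `pca_model`: `E` (p x p eigenvector matrix, columns sorted by
#'   descending eigenvalue), `center`, `explained_variance`,
#'   `proportion_of_variance`.
#' @export
fit_pca <- function(X) {
  if (inherits(X, "latent_features")) X <- X$X
  X <- as.matrix(X)
  center <- colMeans(X)
  ev <- eigen(cov(X), symmetric = TRUE)
  if (min(ev$values) < 1e-12 * max(ev$values)) {
    warning("covariance is rank deficient; eigenvalues clipped at 0")
  }
  lam <- pmax(ev$values, 0)
  structure(list(E = ev$vectors, center = center,
                 explained_variance = lam,
                 proportion_of_variance = lam / sum(lam)),
            class = "pca_model")
}

#' @rdname fit_pca
#' @param pca a `pca_model`.
#' @export
pca_scores <- function(pca, X) {
  if (inherits(X, "latent_features")) X <- X$X
  sweep(as.matrix(X), 2, pca$center) %*% pca$E
}

#' Rotate the regression head into the principal component basis
#'
#' `W' = E' W`. Because `E` is orthogonal, scores times `W'` reproduce the
#' original linear head exactly when all components are kept:
#' `S W' = (X - 1 c') W`, so the companion bias is `b' = b + W' c` (returned
#' by [pc_head()]).
#'
#' @param W `p x q` head weight matrix.
#' @param E `p x p` eigenvector matrix.
#' @return `W'`, a `p x q` matrix.
#' @export
transform_weights <- function(W, E) {
  W <- as.matrix(W); E <- as.matrix(E)
  if (nrow(W) != nrow(E) || nrow(E) != ncol(E))
    stop("shape mismatch: W must be p x q and E p x p")
  t(E) %*% W
}

#' @rdname transform_weights
#' @param pca a `pca_model`.
#' @param b length-q head bias.
#' @return For `pc_head`: list with `W_prime`, `b` (bias adjusted so
#'   `S W' + 1 b'` equals `X W + 1 b` exactly), and the trial's
#'   `proportion_of_variance`.
#' @export
pc_head <- function(pca, W, b) {
  list(W_prime = transform_weights(W, pca$E),
       b = as.numeric(b + crossprod(as.matrix(W), pca$center)),
       proportion_of_variance = pca$proportion_of_variance)
}

#' Align eigenvector sign patterns across cross-validation trials
#'
#' The sign of an eigenvector is arbitrary, so the rows of `W'` from
#' different trials may be globally negated relative to each other. For each
#' of the first `n_pcs` components, each trial's row may be flipped; the flip
#' maximizing agreement of the row's sign vector with the running modal
#' pattern (accumulated sign sums over the trials processed so far) is
#' chosen, with ties broken toward no flip. Components are matched across
#' trials by rank of explained variance. Flipping a `W'` row must be
#' accompanied by negating the corresponding score column; the returned
#' `flips` matrix records the choice.
#'
#' @param trials list of `W'` matrices (or lists with a `W_prime` field).
#' @param n_pcs number of leading components to align (default 3).
#' @return List with `aligned` (list of `W'` with rows `1:n_pcs` flipped as
#'   chosen), `flips` (trials x n_pcs matrix of +/-1), `modal_pattern`
#'   (n_pcs x q matrix in \{-1, 0, 1\}).
#' @export
align_sign_patterns <- function(trials, n_pcs = 3) {
  stopifnot(length(trials) >= 2)
  get_w <- function(t) if (is.list(t)) as.matrix(t$W_prime) else as.matrix(t)
  ws <- lapply(trials, get_w)
  q <- ncol(ws[[1]])
  n_pcs <- min(n_pcs, nrow(ws[[1]]))
  sign_sum <- matrix(0, n_pcs, q)
  flips <- matrix(1, length(ws), n_pcs)
  for (i in seq_along(ws)) {
    for (pc in seq_len(n_pcs)) {
      s <- sign(ws[[i]][pc, ])
      agree_keep <- sum(s * sign(sign_sum[pc, ]))
      if (agree_keep < 0) {
        flips[i, pc] <- -1
        ws[[i]][pc, ] <- -ws[[i]][pc, ]
        s <- -s
      }
      sign_sum[pc, ] <- sign_sum[pc, ] + s
    }
  }
  list(aligned = ws, flips = flips, modal_pattern = sign(sign_sum))
}

#' Average aligned PC-space weights across trials
#'
#' Entry-wise mean of the aligned `W'` matrices, plus the mean and SD of the
#' per-component proportion of explained variance across trials when the
#' trials carry one.
#'
#' @param aligned list of aligned `W'` matrices (from
#'   [align_sign_patterns()]), or the full result of that function.
#' @param proportions optional list/matrix of per-trial
#'   proportion-of-variance vectors.
#' @return List with `mean_W_prime`, and (when proportions are supplied)
#'   `pov_mean`, `pov_sd` per component.
#' @export
average_weights <- function(aligned, proportions = NULL) {
  if (is.list(aligned) && !is.null(aligned$aligned)) aligned <- aligned$aligned
  mw <- Reduce(`+`, aligned) / length(aligned)
  out <- list(mean_W_prime = mw)
  if (!is.null(proportions)) {
    pm <- do.call(rbind, lapply(proportions, as.numeric))
    out$pov_mean <- colMeans(pm)
    out$pov_sd <- apply(pm, 2, sd)
  }
  out
}

#' Annotation graph linking latent PCs to traits
#'
#' Bipartite edge list for visualization: one edge per (component, trait)
#' over the first `n_pcs` components, carrying the signed mean `W'` weight
#' (sign maps to an edge color class, magnitude to a width class).
#'
#' @param mean_W_prime averaged `W'` matrix (components x traits).
#' @param n_pcs number of leading components to emit.
#' @param traits trait labels for the columns.
#' @return Data frame with columns `pc`, `trait`, `weight`, `sign`.
#' @export
annotation_graph <- function(mean_W_prime, n_pcs = 3, traits = TRAITS) {
  n_pcs <- min(n_pcs, nrow(mean_W_prime))
  df <- expand.grid(trait = seq_len(ncol(mean_W_prime)), pc = seq_len(n_pcs))
  data.frame(pc = paste0("PC", df$pc),
             trait = traits[df$trait],
             weight = mean_W_prime[cbind(df$pc, df$trait)],
             sign = sign(mean_W_prime[cbind(df$pc, df$trait)]))
}
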