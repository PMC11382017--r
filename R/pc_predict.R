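#' Predict traits from (genomically predicted) PC scores
#'
#' `Y~ = S~ W'_l + 1 b'`, where `S~` holds the first `l` PC scores (typically
#' predicted by GBLUP) and `W'_l` the first `l` rows of the PC-space weight
#' matrix. With the true scores and all components, this reproduces the
#' network head's estimates exactly.
#'
#' @param S_tilde `n x >= l` matrix of PC scores.
#' @param W_prime PC-space weight matrix (rows = components).
#' @param b length-q bias (the PC-space bias from [pc_head()]).
#' @param l number of leading components to use (>= 1).
#' @return `n x q` matrix of predicted trait values.
#' @export
predict_traits_from_pcs <- function(S_tilde, W_prime, b, l = ncol(S_tilde)) {
  if (l < 1) stop("l must be >= 1")
  S_tilde <- as.matrix(S_tilde); W_prime <- as.matrix(W_prime)
  if (l > ncol(S_tilde) || l > nrow(W_prime))
    stop("l exceeds the number of available components")
  sweep(S_tilde[, seq_len(l), drop = FALSE] %*%
          W_prime[seq_len(l), , drop = FALSE], 2, b, `+`)
}

#' Accuracy of trait prediction from genomically predicted PCs, sweeping l
#'
#' Realizes the latent-route genomic prediction with fold-local PCA: per
#' cross-validation repetition and fold (accessions partitioned), (1) the
#' latent features are re-standardized on the training plots only, with the
#' head re-expressed accordingly; (2) PCA is fitted on training-fold features
#' only; (3) one GBLUP per component and treatment is fitted on the
#' training-fold PC scores; (4) held-out accessions' scores are predicted;
#' (5) traits are reconstructed via `Y~ = S~ W' + 1 b'` for each
#' `l = 1..l_max`; (6) accuracy is the Pearson correlation with the observed
#' traits per treatment. Test-fold rows never enter scaling, PCA, or GBLUP
#' fitting. (A global sign flip of an eigenvector negates both the predicted
#' score and the corresponding `W'` row, leaving `Y~` unchanged, so no sign
#' alignment is needed inside the sweep.)
#'
#' @param features a `latent_features` object (see [extract_features()])
#'   covering every plot in `meta`, in row order.
#' @param traits observed plot x trait matrix (raw or normalized; Pearson
#'   accuracy is affine-invariant).
#' @param meta data frame with `accession` and `treatment` per plot.
#' @param grm a `grm` covering all accessions.
#' @param scheme a [cv_scheme()] over accessions.
#' @param l_max sweep upper bound (default 10).
#' @return List with `accuracy` (treatment, trait, l, rep, fold, r),
#'   `summary` (mean/sd by treatment x trait x l), `scheme`, and
#'   `fold_detail` (per fold: the training rows used for scaling/PCA/GBLUP,
#'   for leakage audits).
#' @export
sweep_components <- function(features, traits, meta, grm, scheme,
                             l_max = 10) {
  stopifnot(inherits(features, "latent_features"),
            nrow(features$X) == nrow(meta))
  traits <- as.matrix(traits)
  trait_names <- colnames(traits) %||% paste0("T", seq_len(ncol(traits)))
  units <- unique(meta$accession)
  acc_rows <- split(seq_len(nrow(meta)), meta$accession)
  out <- list(); detail <- list()
  for (r in seq_len(scheme$repetitions)) {
    fm <- fold_map(scheme, r, units)
    for (k in seq_len(scheme$k)) {
      test_acc <- names(fm)[fm == k]
      test_rows <- sort(unlist(acc_rows[test_acc], use.names = FALSE))
      train_rows <- setdiff(seq_len(nrow(meta)), test_rows)
      if (length(test_acc) < 3) next

      # fold-local feature scaling (training statistics only)
      mu <- colMeans(features$X[train_rows, , drop = FALSE])
      sdv <- apply(features$X[train_rows, , drop = FALSE], 2, sd)
      sdv[!is.finite(sdv) | sdv < 1e-12] <- 1
      Xs <- sweep(sweep(features$X, 2, mu), 2, sdv, `/`)
      Wf <- features$W * sdv
      bf <- features$b + as.numeric(crossprod(features$W, mu))

      pca <- fit_pca(Xs[train_rows, , drop = FALSE])
      head_pc <- pc_head(pca, Wf, bf)
      S <- pca_scores(pca, Xs)
      l_use <- min(l_max, ncol(S))

      # genomic prediction of each leading PC score, per treatment
      S_tilde <- matrix(NA_real_, nrow(meta), l_use)
      for (tr in unique(meta$treatment)) {
        tr_rows <- meta$treatment == tr
        fit_rows <- intersect(train_rows, which(tr_rows))
        pred_rows <- intersect(test_rows, which(tr_rows))
        if (length(pred_rows) == 0) next
        for (j in seq_len(l_use)) {
          fit <- fit_gblup(S[fit_rows, j], meta$accession[fit_rows], grm)
          S_tilde[pred_rows, j] <-
            predict_unobserved(fit, meta$accession[pred_rows])
        }
      }

      for (l in seq_len(l_use)) {
        Y_tilde <- predict_traits_from_pcs(
          S_tilde[test_rows, , drop = FALSE], head_pc$W_prime, head_pc$b, l)
        for (tr in unique(meta$treatment)) {
          g <- which(meta$treatment[test_rows] == tr)
          if (length(g) < 3) next
          for (t in seq_along(trait_names)) {
            out[[length(out) + 1]] <- data.frame(
              treatment = tr, trait = trait_names[t], l = l, rep = r,
              fold = k, r = pearson(Y_tilde[g, t], traits[test_rows[g], t]))
          }
        }
      }
      detail[[paste(r, k)]] <- list(rep = r, fold = k,
                                    train_rows = train_rows,
                                    test_rows = test_rows)
    }
  }
  acc <- do.call(rbind, out)
  summ <- do.call(rbind, lapply(
    split(acc, list(acc$treatment, acc$trait, acc$l), drop = TRUE),
    function(d) data.frame(treatment = d$treatment[1], trait = d$trait[1],
                           l = d$l[1], mean_r = mean(d$r, na.rm = TRUE),
                           sd_r = sd(d$r, na.rm = TRUE),
                           n_folds = sum(!is.na(d$r)))))
  summ <- summ[order(summ$treatment, summ$trait, summ$l), ]
  rownames(summ) <- NULL
  list(accuracy = acc, summary = summ, scheme = scheme, fold_detail = detail)
}

#' Compare direct GBLUP-on-trait accuracy with the PC-mediated route
#'
#' Joins the accuracy of direct genomic prediction of each trait (from
#' [cv_gblup()]) with the accuracy of reconstruction from genomically
#' predicted PC scores (from [sweep_components()]), per treatment, trait,
#' and number of components. Both inputs must have been produced under the
#' identical fold scheme (same k, repetitions, unit, and seed) or an error
#' is raised.
#'
#' @param sweep result of [sweep_components()].
#' @param direct named list (by trait) of [cv_gblup()] results run on the
#'   same scheme.
#' @return Data frame with `treatment`, `trait`, `l`, `pc_mean_r`,
#'   `direct_mean_r`, `difference`.
#' @export
compare_direct_vs_pc <- function(sweep, direct) {
  for (t in names(direct)) {
    s1 <- sweep$scheme; s2 <- direct[[t]]$scheme
    if (is.null(s2) || s1$k != s2$k || s1$repetitions != s2$repetitions ||
        s1$seed != s2$seed || s1$unit != s2$unit)
      stop("fold scheme mismatch for trait ", t, call. = FALSE)
  }
  rows <- list()
  for (i in seq_len(nrow(sweep$summary))) {
    s <- sweep$summary[i, ]
    d <- direct[[s$trait]]$summary
    d <- d[d$treatment == s$treatment, ]
    rows[[i]] <- data.frame(treatment = s$treatment, trait = s$trait,
                            l = s$l, pc_mean_r = s$mean_r,
                            direct_mean_r = d$mean_r,
                            difference = s$mean_r - d$mean_r)
  }
  do.call(rbind, rows)
}
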