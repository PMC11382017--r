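#' Filter SNPs by minor allele frequency and missing rate
#'
#' Keeps biallelic SNP columns with MAF >= `maf_min` and missing fraction
#' < `missing_max` (published thresholds: MAF >= 0.025, missing rate
#' < 0.05). Allele frequencies are computed from non-missing entries only.
#'
#' @param geno a `genotype_matrix`.
#' @param maf_min minimum minor allele frequency.
#' @param missing_max exclusive upper bound on the per-SNP missing fraction.
#' @return The filtered `genotype_matrix`, with a `filter_report` attribute
#'   counting SNPs dropped by each criterion.
#' @export
filter_snps <- function(geno, maf_min = 0.025, missing_max = 0.05) {
  p <- geno$allele_freq
  maf <- pmin(p, 1 - p)
  miss <- colMeans(is.na(geno$scores))
  keep <- maf >= maf_min & miss < missing_max
  if (!any(keep)) stop("all SNPs removed by filtering", call. = FALSE)
  out <- new_genotype_matrix(geno$scores[, keep, drop = FALSE],
                             geno$accession_ids, geno$snp_ids[keep])
  attr(out, "filter_report") <- list(
    n_input = length(keep), n_kept = sum(keep),
    n_low_maf = sum(maf < maf_min),
    n_high_missing = sum(miss >= missing_max))
  out
}

# Mode imputation on a raw score matrix; ties broken toward the lower score.
impute_missing_scores <- function(scores) {
  for (k in which(colSums(is.na(scores)) > 0)) {
    s <- scores[, k]
    if (all(is.na(s)))
      stop("SNP column ", k, " is entirely missing; filter it first",
           call. = FALSE)
    tab <- table(factor(s[!is.na(s)], levels = c(-1, 0, 1)))
    scores[is.na(s), k] <- as.numeric(names(tab)[which.max(tab)])
  }
  scores
}

#' Impute missing genotype calls with the per-SNP modal score
#'
#' A deliberate simplification of LD-aware imputation, adequate for
#' missing-completely-at-random synthetic data. Never changes non-missing
#' entries; errors on entirely missing SNPs (which the filter should have
#' removed). Ties are broken toward the lower score.
#'
#' @param geno a `genotype_matrix`.
#' @return A complete `genotype_matrix`.
#' @export
impute_missing <- function(geno) {
  if (!anyNA(geno$scores)) return(geno)
  new_genotype_matrix(impute_missing_scores(geno$scores),
                      geno$accession_ids, geno$snp_ids)
}

#' Genomic relationship matrix G = XX'/c
#'
#' VanRaden-style GRM from \{-1, 0, 1\} scores: with `center = TRUE`
#' (default) each SNP column has its Hardy-Weinberg expectation `2p - 1`
#' subtracted before the cross-product; the normalization constant is
#' `c = 2 * sum(p * (1 - p))` over the markers used. Monomorphic SNPs
#' contribute nothing to `c` and are excluded with a warning.
#' `center = FALSE` reproduces the literal uncentered formula.
#'
#' @param geno a complete `genotype_matrix` (run [impute_missing()] first).
#' @param center subtract `2p - 1` per SNP column.
#' @return A `grm`: list with `G` (m x m), `c`, `allele_freq`,
#'   `accession_ids`.
#' @export
compute_grm <- function(geno, center = TRUE) {
  X <- geno$scores
  if (anyNA(X)) stop("genotypes contain missing entries; impute first",
                     call. = FALSE)
  p <- (colMeans(X) + 1) / 2
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) excluded from the GRM")
    X <- X[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  if (center) X <- sweep(X, 2, 2 * p - 1)
  cc <- 2 * sum(p * (1 - p))
  G <- tcrossprod(X) / cc
  dimnames(G) <- list(geno$accession_ids, geno$accession_ids)
  structure(list(G = G, c = cc, allele_freq = p,
                 accession_ids = geno$accession_ids),
            class = "grm")
}

#' Fit the GBLUP mixed model by REML
#'
#' Model: `y = 1 mu + Z g + e`, with `g ~ MVN(0, G sigma2_g)` and
#' `e ~ MVN(0, I sigma2_e)`, where `Z` is the plot-to-accession incidence
#' matrix. Variance components are estimated by restricted maximum
#' likelihood via a deterministic 1-D golden-section/Brent search over
#' `log(sigma2_g / sigma2_e)` on the eigenbasis of `Z G Z'` (one `O(n^3)`
#' eigendecomposition, then each likelihood evaluation is `O(n)`).
#' Breeding values for *all* accessions in `G` — observed or not — are the
#' BLUP `g_hat = sigma2_g G Z' V^{-1} (y - 1 mu)`, which equals the
#' conditional-MVN prediction for unobserved accessions.
#'
#' @param y numeric vector of plot phenotypes (or PC scores).
#' @param Z `n x m` incidence matrix (one 1 per row), or a character vector
#'   of accession ids (one per observation) resolved against `G`'s ids.
#' @param G a `grm` or a plain symmetric m x m matrix.
#' @param ratio_bounds search interval for `log10(sigma2_g / sigma2_e)`.
#' @return A `gblup_fit`: `mu`, `sigma2_g`, `sigma2_e`, `g_hat` (named,
#'   length m), `h2_plot` (plot-level variance ratio), `boundary` flag,
#'   `loglik`.
#' @export
fit_gblup <- function(y, Z, G, ratio_bounds = c(-6, 6)) {
  if (inherits(G, "grm")) { ids <- G$accession_ids; G <- G$G }
  else ids <- rownames(G) %||% paste0("g", seq_len(nrow(G)))
  if (is.character(Z) || is.factor(Z)) {
    zi <- match(as.character(Z), ids)
    if (anyNA(zi)) stop("accession id absent from G: ",
                        paste(unique(Z[is.na(zi)]), collapse = ", "))
    Zm <- matrix(0, length(zi), length(ids))
    Zm[cbind(seq_along(zi), zi)] <- 1
    Z <- Zm
  }
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(Z) == n, ncol(Z) == nrow(G), all(is.finite(y)))
  ev_g <- eigen((G + t(G)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev_g) < -1e-8) {
    warning("G is not PSD; eigenvalues clipped at 0")
    eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
    G <- eg$vectors %*% diag(pmax(eg$values, 0)) %*% t(eg$vectors)
  }
  H <- Z %*% G %*% t(Z)
  eh <- eigen((H + t(H)) / 2, symmetric = TRUE)
  d <- pmax(eh$values, 0)
  yt <- as.numeric(crossprod(eh$vectors, y))
  xt <- as.numeric(crossprod(eh$vectors, rep(1, n)))

  # REML log-likelihood profiled over mu and sigma2_e, as a function of
  # lambda = sigma2_g / sigma2_e
  neg_rll <- function(log10_lam) {
    lam <- 10^log10_lam
    v <- lam * d + 1
    xvx <- sum(xt^2 / v)
    beta <- sum(xt * yt / v) / xvx
    r2 <- sum((yt - xt * beta)^2 / v)
    s2e <- r2 / (n - 1)
    0.5 * ((n - 1) * log(s2e) + sum(log(v)) + log(xvx))
  }
  opt <- optimize(neg_rll, ratio_bounds, tol = 1e-9)
  lam <- 10^opt$minimum
  boundary <- opt$minimum <= ratio_bounds[1] + 1e-6 ||
    opt$minimum >= ratio_bounds[2] - 1e-6
  v <- lam * d + 1
  xvx <- sum(xt^2 / v)
  mu <- sum(xt * yt / v) / xvx
  s2e <- sum((yt - xt * mu)^2 / v) / (n - 1)
  s2g <- lam * s2e
  # g_hat = s2g * G Z' V^{-1} (y - mu), V^{-1} = U diag(1/(s2e*v)) U'
  vinv_r <- eh$vectors %*% ((yt - xt * mu) / (s2e * v))
  g_hat <- as.numeric(s2g * G %*% crossprod(Z, vinv_r))
  names(g_hat) <- ids
  structure(list(mu = mu, sigma2_g = s2g, sigma2_e = s2e, g_hat = g_hat,
                 h2_plot = s2g / (s2g + s2e), boundary = boundary,
                 loglik = -opt$objective, Z = Z, ids = ids),
            class = "gblup_fit")
}

#' Predict phenotypic values for unobserved accessions
#'
#' Reads the BLUP breeding values of the requested accessions from a fitted
#' model (the joint-MVN conditional given the training observations) and
#' adds the grand mean. With `sigma2_g = 0` every prediction collapses to
#' `mu`.
#'
#' @param fit a `gblup_fit`.
#' @param accessions character ids present in the fitted G.
#' @return Named numeric vector of predicted values.
#' @export
predict_unobserved <- function(fit, accessions) {
  miss <- setdiff(accessions, fit$ids)
  if (length(miss) > 0)
    stop("accession(s) absent from G: ", paste(miss, collapse = ", "))
  fit$mu + fit$g_hat[accessions]
}

#' Cross-validated genomic prediction accuracy
#'
#' Accession-wise k-fold cross-validation (all plots of an accession move
#' together): per repetition and fold, the model is fitted on the training
#' accessions' plots only and the held-out plots are predicted from the GRM;
#' accuracy is the Pearson correlation between predicted and observed values
#' of the held-out plots. Run independently per treatment when `treatment`
#' is supplied (models per irrigation level). Folds with fewer than 3
#' held-out accessions are skipped with a log entry.
#'
#' @param y numeric vector of plot phenotypes.
#' @param accession character vector (one per plot).
#' @param grm a `grm` covering all accessions.
#' @param scheme a [cv_scheme()] (`unit` must be `"accession"`).
#' @param treatment optional per-plot treatment labels.
#' @return List with `metrics` (treatment, rep, fold, r, n_test),
#'   `summary` (mean/sd by treatment), `n_skipped`.
#' @export
cv_gblup <- function(y, accession, grm, scheme, treatment = NULL) {
  stopifnot(length(y) == length(accession))
  if (is.null(treatment)) treatment <- rep("all", length(y))
  units <- unique(accession)
  metrics <- list(); skipped <- 0L
  for (r in seq_len(scheme$repetitions)) {
    fm <- fold_map(scheme, r, units)
    for (k in seq_len(scheme$k)) {
      test_acc <- names(fm)[fm == k]
      if (length(test_acc) < 3) { skipped <- skipped + 1L; next }
      for (tr in unique(treatment)) {
        tr_rows <- treatment == tr
        train <- tr_rows & !(accession %in% test_acc)
        test <- tr_rows & (accession %in% test_acc)
        if (sum(test) < 3 || sum(train) < 3) { skipped <- skipped + 1L; next }
        fit <- fit_gblup(y[train], accession[train], grm)
        pred <- predict_unobserved(fit, accession[test])
        metrics[[length(metrics) + 1]] <-
          data.frame(treatment = tr, rep = r, fold = k,
                     r = pearson(pred, y[test]), n_test = sum(test))
      }
    }
  }
  metrics <- do.call(rbind, metrics)
  summ <- do.call(rbind, lapply(split(metrics, metrics$treatment),
    function(d) data.frame(treatment = d$treatment[1],
                           mean_r = mean(d$r, na.rm = TRUE),
                           sd_r = sd(d$r, na.rm = TRUE),
                           n_folds = sum(!is.na(d$r)))))
  rownames(summ) <- NULL
  list(metrics = metrics, summary = summ, n_skipped = skipped,
       scheme = scheme)
}
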