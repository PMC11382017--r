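# Score matrix with exact allele frequencies for filter tests: mean score
# per column = 2p - 1 over 200 accessions.
freq_scores <- function(freqs, m = 500) {
  sapply(freqs, function(p) {
    n_alt <- round(2 * p * m)
    s <- c(rep(1, n_alt %/% 2), rep(0, n_alt %% 2))
    c(s, rep(-1, m - length(s)))
  })
}

test_that("SNP filtering applies the MAF and missing-rate rules", {
  sc <- freq_scores(c(0.5, 0.03, 0.02, 0.25, 0.024))
  g <- geno_from_scores(sc)
  expect_equal(unname(g$allele_freq), c(0.5, 0.03, 0.02, 0.25, 0.024),
               tolerance = 1e-12)
  kept <- filter_snps(g, maf_min = 0.025, missing_max = 0.05)
  expect_equal(ncol(kept$scores), 3)
  expect_setequal(kept$snp_ids, c("S01", "S02", "S04"))

  # p = 0.01 dropped by MAF; 6% missing dropped by missing rate
  sc2 <- freq_scores(c(0.01, 0.4))
  sc2[1:30, 2] <- NA  # 6% missing
  expect_error(filter_snps(geno_from_scores(sc2)), "all SNPs removed")

  sc3 <- freq_scores(c(0.01, 0.4, 0.3))
  sc3[1:30, 2] <- NA  # 6% missing
  g3 <- geno_from_scores(sc3)
  kept3 <- filter_snps(g3)
  expect_identical(kept3$snp_ids, "S03")
  rep <- attr(kept3, "filter_report")
  expect_equal(rep$n_low_maf, 1)
  expect_equal(rep$n_high_missing, 1)
})

test_that("modal imputation fills gaps without touching observed calls", {
  sc <- matrix(c(1, 1, -1, NA,
                 0, 0, NA, 1,
                 -1, -1, -1, -1), 4, 3)
  g <- geno_from_scores(sc)
  gi <- impute_missing(g)
  expect_false(anyNA(gi$scores))
  expect_equal(gi$scores[4, 1], 1)   # mode of {1, 1, -1}
  expect_equal(gi$scores[3, 2], 0)   # mode of {0, 0, 1}
  obs <- !is.na(sc)
  expect_identical(gi$scores[obs], sc[obs])
  # complete input returned unchanged
  expect_identical(impute_missing(gi)$scores, gi$scores)
  # entirely missing SNP errors
  sc[, 2] <- NA
  expect_error(impute_missing(geno_from_scores(sc)), "entirely missing")
})

test_that("GRM matches the hand-computed single-SNP example", {
  g <- geno_from_scores(matrix(c(-1, 1), 2, 1))
  grm <- compute_grm(g)
  expect_equal(grm$c, 0.5)
  expect_equal(unname(grm$G), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12)
})

test_that("GRM structural properties hold", {
  set.seed(10)
  sc <- matrix(sample(c(-1, 0, 1), 30 * 50, replace = TRUE), 30, 50)
  sc[2, ] <- sc[1, ] # duplicate accessions
  g <- geno_from_scores(sc)
  grm <- compute_grm(g)
  expect_equal(grm$G, t(grm$G))
  ev <- eigen(grm$G, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  expect_equal(grm$G[1, 2], grm$G[1, 1])
  expect_equal(grm$G[2, 2], grm$G[1, 1])
  # normalization constant recomputable from stored frequencies
  expect_equal(grm$c, 2 * sum(grm$allele_freq * (1 - grm$allele_freq)))
  # uncentered option reproduces the literal formula
  grm0 <- compute_grm(g, center = FALSE)
  expect_equal(grm0$G, tcrossprod(sc) / grm0$c, ignore_attr = TRUE)
  # monomorphic SNPs are excluded with a warning
  sc[, 1] <- 1
  expect_warning(compute_grm(geno_from_scores(sc)), "monomorphic")
})

sim_gblup_problem <- function(m = 30, n_snp = 120, h2 = 0.5, reps = 2,
                              seed = 1) {
  set.seed(seed)
  sc <- matrix(rbinom(m * n_snp, 2, 0.4) - 1, m, n_snp)
  g <- geno_from_scores(sc)
  grm <- compute_grm(g)
  gv <- as.numeric(chol(grm$G + diag(1e-6, m)) |> t() %*% rnorm(m))
  gv <- gv / sd(gv) * sqrt(h2)
  acc <- rep(g$accession_ids, each = reps)
  y <- gv[match(acc, g$accession_ids)] + rnorm(m * reps, 0, sqrt(1 - h2))
  list(g = g, grm = grm, gv = gv, acc = acc, y = y)
}

test_that("REML fit matches the Henderson mixed-model-equations solve", {
  pr <- sim_gblup_problem(m = 8, reps = 2, seed = 2)
  fit <- fit_gblup(pr$y, pr$acc, pr$grm)
  # Henderson MME at the fitted variance components (independent oracle)
  Z <- fit$Z; n <- length(pr$y); m <- 8
  lam <- fit$sigma2_e / fit$sigma2_g
  Ginv <- solve(pr$grm$G + diag(1e-10, m))
  X1 <- matrix(1, n, 1)
  lhs <- rbind(cbind(crossprod(X1), crossprod(X1, Z)),
               cbind(crossprod(Z, X1), crossprod(Z) + Ginv * lam))
  rhs <- rbind(crossprod(X1, pr$y), crossprod(Z, pr$y))
  sol <- solve(lhs, rhs)
  expect_equal(fit$mu, sol[1], tolerance = 1e-6)
  expect_lt(max(abs(fit$g_hat - sol[-1])), 1e-6)
})

test_that("with G = I the BLUP is the ridge shrinkage estimator", {
  set.seed(3)
  m <- 40
  y <- rnorm(m, 5, 2)
  G <- diag(m); rownames(G) <- colnames(G) <- paste0("A", 1:m)
  fit <- fit_gblup(y, paste0("A", 1:m), G)
  shrink <- fit$sigma2_g / (fit$sigma2_g + fit$sigma2_e)
  expect_equal(unname(fit$g_hat), shrink * (y - fit$mu), tolerance = 1e-6)
})

test_that("noise-free phenotypes push the residual variance to the boundary", {
  pr <- sim_gblup_problem(m = 25, reps = 2, h2 = 1, seed = 4)
  y <- pr$gv[match(pr$acc, pr$g$accession_ids)] # zero residual
  fit <- fit_gblup(y, pr$acc, pr$grm)
  expect_true(fit$boundary)
  expect_gt(fit$h2_plot, 0.99)
  expect_lt(max(abs(fit$mu + fit$g_hat - pr$gv - mean(y) + mean(pr$gv))), 0.05)
})

test_that("conditional-MVN prediction equals the masked-refit prediction", {
  pr <- sim_gblup_problem(m = 6, reps = 1, seed = 5)
  train <- 1:4; test <- 5:6
  ids <- pr$g$accession_ids
  fit <- fit_gblup(pr$y[train], pr$acc[train], pr$grm)
  got <- predict_unobserved(fit, ids[test])
  # independent conditional-MVN oracle at the fitted components
  G <- pr$grm$G
  V <- fit$sigma2_g * G[train, train] + diag(fit$sigma2_e, 4)
  cond <- fit$mu + fit$sigma2_g * G[test, train] %*%
    solve(V, pr$y[train] - fit$mu)
  expect_lt(max(abs(got - cond)), 1e-8)
  # absent accession errors
  expect_error(predict_unobserved(fit, "NOPE"), "absent")
})

test_that("duplicate accessions inherit each other's breeding value", {
  set.seed(6)
  sc <- matrix(sample(c(-1, 0, 1), 10 * 80, replace = TRUE), 10, 80)
  sc[10, ] <- sc[1, ]
  g <- geno_from_scores(sc)
  grm <- compute_grm(g)
  y <- rnorm(9, 0, 1)
  fit <- fit_gblup(y, g$accession_ids[1:9], grm) # A10 unobserved
  expect_equal(unname(predict_unobserved(fit, "A10")),
               unname(fit$mu + fit$g_hat["A01"]), tolerance = 1e-8)
})

test_that("GBLUP predictions are invariant to rescaling G", {
  pr <- sim_gblup_problem(m = 15, reps = 2, seed = 7)
  f1 <- fit_gblup(pr$y, pr$acc, pr$grm)
  G5 <- pr$grm$G * 5
  f2 <- fit_gblup(pr$y, pr$acc, G5)
  expect_lt(max(abs(f1$g_hat - f2$g_hat)), 1e-5)
  expect_equal(f1$sigma2_g, 5 * f2$sigma2_g, tolerance = 1e-3)
})

test_that("cross-validated accuracy tracks heritability", {
  accs <- sapply(c(1, 0.5, 0.1), function(h2) {
    cfg <- field_config(n_accessions = 100, n_reps = 1, treatments = "control",
                        n_snps = 100, n_qtl = 20, missing_rate = 0,
                        heritability = c(DW = h2, SL = h2, NN = h2, NB = h2,
                                         PH = h2), rng_seed = 31)
    field <- simulate_field(cfg, render = FALSE)
    grm <- compute_grm(impute_missing(field$geno))
    cv <- cv_gblup(field$plots$DW, field$plots$accession, grm,
                   cv_scheme(k = 5, repetitions = 2, seed = 17))
    cv$summary$mean_r
  })
  expect_gt(accs[1], 0.8)                 # h2 = 1: near-perfect
  expect_true(all(diff(accs) < 0.05))     # monotone within sampling noise
  # permuted phenotypes: null accuracy
  cfg <- field_config(n_accessions = 100, n_reps = 1, treatments = "control",
                      n_snps = 100, n_qtl = 20, missing_rate = 0,
                      rng_seed = 31)
  field <- simulate_field(cfg, render = FALSE)
  grm <- compute_grm(impute_missing(field$geno))
  set.seed(1)
  cv0 <- cv_gblup(sample(field$plots$DW), field$plots$accession, grm,
                  cv_scheme(k = 5, repetitions = 2, seed = 17))
  expect_lt(abs(cv0$summary$mean_r), 0.2)
})
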