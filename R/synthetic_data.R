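#' Trait codes used throughout the package
#'
#' Five above-ground biomass traits of a row-crop (soybean-like) trial:
#' dry weight (`DW`, g), main stem length (`SL`, cm), number of nodes (`NN`),
#' number of branches (`NB`), and plant height (`PH`, cm).
#' @export
TRAITS <- c("DW", "SL", "NN", "NB", "PH")

#' Configuration of a synthetic field trial
#'
#' Describes a complete synthetic world: a germplasm panel genotyped at
#' biallelic SNPs, an oligogenic additive architecture shared across five
#' correlated biomass traits, a two-treatment (control/drought) field layout
#' with replicates, and a procedural renderer that turns per-plot trait values
#' into an RGB image and a DSM. The full generation is a pure function of this
#' configuration (including `rng_seed`).
#'
#' Trait means/SDs are deliberate, documented stand-ins (no published per-plot
#' summary statistics exist to anchor them); all numeric defaults are
#' configurable. Drought acts multiplicatively on both the genetic and
#' residual components of a trait, which yields uniformly lower values under
#' drought while preserving the configured heritability.
#'
#' @param n_accessions number of accessions (default 198).
#' @param n_reps replicates per accession and treatment (default 2).
#' @param treatments treatment labels; the label `"drought"` triggers the
#'   drought multipliers.
#' @param n_snps,n_qtl number of simulated SNPs and of causal SNPs.
#' @param maf_range range the per-SNP generating allele frequency is drawn
#'   from; must lie in (0, 0.5].
#' @param ld_block_size number of consecutive SNPs sharing a latent gamete
#'   variable (linkage-disequilibrium block). A scaled-down marker panel must
#'   carry LD to emulate a dense real panel: the effective number of
#'   independent genome segments — which bounds genomic-prediction accuracy —
#'   is roughly `n_snps / ld_block_size`. Set to 1 for independent SNPs.
#' @param ld_rho latent within-block gamete correlation in \[0, 1).
#' @param missing_rate fraction of genotype calls set missing completely at
#'   random, in \[0, 1).
#' @param heritability named per-trait narrow-sense h² in \[0, 1\].
#' @param trait_cor 5 x 5 genetic correlation matrix of QTL effects.
#' @param drought_multipliers named per-trait positive scale factors applied
#'   under the drought label.
#' @param trait_mean,trait_sd named per-trait control-treatment means and SDs
#'   on the raw measurement scale.
#' @param image_height,image_width rendered plot image size in pixels
#'   (each must be >= 32 and divisible by 32 for the default network).
#' @param soil_red,soil_blue soil palette ranges (8-bit) for the red and blue
#'   components; soil green is drawn as `soil_green_frac * (R + B) / 2`,
#'   which keeps soil VDVI <= 0 (below the 0.057 segmentation threshold with
#'   margin).
#' @param soil_green_frac range of the soil green fraction (<= 1).
#' @param canopy_green,canopy_red,canopy_blue canopy palette ranges (8-bit);
#'   defaults keep canopy VDVI > 0.1.
#' @param n_dark_pixels number of near-black pixels (green < 10) injected in
#'   the canopy to exercise the dark-pixel filter.
#' @param rng_seed integer master seed.
#' @return An object of class `field_config`.
#' @export
field_config <- function(n_accessions = 198,
                         n_reps = 2,
                         treatments = c("control", "drought"),
                         n_snps = 1000,
                         n_qtl = min(50, n_snps),
                         maf_range = c(0.05, 0.5),
                         ld_block_size = 10,
                         ld_rho = 0.95,
                         missing_rate = 0.02,
                         heritability = c(DW = 0.6, SL = 0.7, NN = 0.6,
                                          NB = 0.5, PH = 0.7),
                         trait_cor = default_trait_cor(),
                         drought_multipliers = c(DW = 0.6, SL = 0.85, NN = 0.9,
                                                 NB = 0.8, PH = 0.85),
                         trait_mean = c(DW = 60, SL = 90, NN = 15, NB = 6, PH = 80),
                         trait_sd = c(DW = 20, SL = 15, NN = 3, NB = 2, PH = 15),
                         image_height = 96,
                         image_width = 128,
                         soil_red = c(110, 135),
                         soil_blue = c(75, 95),
                         soil_green_frac = c(0.85, 1.0),
                         canopy_green = c(110, 180),
                         canopy_red = c(40, 80),
                         canopy_blue = c(30, 70),
                         n_dark_pixels = 12,
                         rng_seed = 1L) {
  stopifnot(n_accessions >= 2, n_snps >= 1, n_reps >= 1, n_qtl >= 1,
            n_qtl <= n_snps, image_height >= 32, image_width >= 32)
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  heritability <- heritability[TRAITS]
  if (anyNA(heritability) || any(heritability < 0 | heritability > 1))
    stop("heritability must name all five traits with values in [0, 1]",
         call. = FALSE)
  trait_cor <- as.matrix(trait_cor)
  if (!isTRUE(all.equal(trait_cor, t(trait_cor))) ||
      !isTRUE(all.equal(unname(diag(trait_cor)), rep(1, 5))))
    stop("trait_cor must be symmetric with unit diagonal", call. = FALSE)
  if (min(eigen(trait_cor, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("trait_cor must be positive semi-definite", call. = FALSE)
  stopifnot(ld_block_size >= 1, ld_rho >= 0, ld_rho < 1)
  cfg <- list(n_accessions = as.integer(n_accessions),
              n_reps = as.integer(n_reps), treatments = treatments,
              n_snps = as.integer(n_snps), n_qtl = as.integer(n_qtl),
              maf_range = maf_range,
              ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
              missing_rate = missing_rate,
              heritability = heritability, trait_cor = trait_cor,
              drought_multipliers = drought_multipliers[TRAITS],
              trait_mean = trait_mean[TRAITS], trait_sd = trait_sd[TRAITS],
              image_height = as.integer(image_height),
              image_width = as.integer(image_width),
              soil_red = soil_red, soil_blue = soil_blue,
              soil_green_frac = soil_green_frac,
              canopy_green = canopy_green, canopy_red = canopy_red,
              canopy_blue = canopy_blue,
              n_dark_pixels = as.integer(n_dark_pixels),
              rng_seed = as.integer(rng_seed))
  structure(cfg, class = "field_config")
}

#' @rdname field_config
#' @export
default_trait_cor <- function() {
  m <- matrix(0.5, 5, 5, dimnames = list(TRAITS, TRAITS))
  diag(m) <- 1
  m
}

new_genotype_matrix <- function(scores, accession_ids, snp_ids) {
  dimnames(scores) <- list(accession_ids, snp_ids)
  p <- apply(scores, 2, function(s) (mean(s, na.rm = TRUE) + 1) / 2)
  structure(list(scores = scores, allele_freq = p,
                 snp_ids = snp_ids, accession_ids = accession_ids),
            class = "genotype_matrix")
}

#' Simulate biallelic SNP genotypes for a germplasm panel
#'
#' Per-SNP generating allele frequencies are drawn uniformly from
#' `cfg$maf_range`. Each accession carries two gametes; a gamete's allele at
#' SNP k is 1 when a latent standard-normal variable falls below
#' `qnorm(p_k)`, so every SNP is marginally Bernoulli(`p_k`) per gamete and
#' the two independent gametes give Hardy-Weinberg genotype proportions with
#' scores `dosage - 1` in \{-1, 0, 1\}. Within an LD block of
#' `cfg$ld_block_size` consecutive SNPs the latent variables share a common
#' component with correlation `cfg$ld_rho`, producing the marker redundancy
#' of a dense real panel; across blocks SNPs are independent. Missing calls
#' are inserted completely at random at `cfg$missing_rate`. `allele_freq` is
#' re-estimated from the non-missing entries only.
#'
#' @param cfg a [field_config()].
#' @return A `genotype_matrix`: list with `scores` (accessions x SNPs, `NA`
#'   for missing), `allele_freq`, `snp_ids`, `accession_ids`.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "field_config"))
  with_seed(derive_seed(cfg$rng_seed, 1L), {
    m <- cfg$n_accessions
    p_gen <- runif(cfg$n_snps, cfg$maf_range[1], cfg$maf_range[2])
    block <- ceiling(seq_len(cfg$n_snps) / cfg$ld_block_size)
    thr <- matrix(qnorm(p_gen), m, cfg$n_snps, byrow = TRUE)
    rho <- cfg$ld_rho
    gamete <- function() {
      z <- matrix(rnorm(m * max(block)), m, max(block))
      u <- sqrt(rho) * z[, block, drop = FALSE] +
        sqrt(1 - rho) * matrix(rnorm(m * cfg$n_snps), m, cfg$n_snps)
      (u < thr) * 1
    }
    scores <- gamete() + gamete() - 1
    if (cfg$missing_rate > 0) {
      miss <- matrix(runif(length(scores)) < cfg$missing_rate,
                     nrow = m)
      scores[miss] <- NA_real_
    }
    new_genotype_matrix(scores,
                        sprintf("ACC%03d", seq_len(m)),
                        sprintf("SNP%05d", seq_len(cfg$n_snps)))
  })
}

#' Simulate breeding values and plot-level trait measurements
#'
#' `cfg$n_qtl` causal SNPs receive effect vectors drawn iid from a
#' multivariate normal with covariance `cfg$trait_cor`, so the five traits
#' share genetic architecture. Per trait, the genetic score is standardized
#' empirically and re-scaled so the additive variance is exactly
#' `h² * trait_sd²`; the plot value adds an iid residual with variance
#' `(1 - h²) * trait_sd²`, replicated `n_reps` times per accession and
#' treatment. Under the drought label, the genetic and residual components
#' are both multiplied by `drought_multipliers`, so realized heritability is
#' unchanged while the trait scale shrinks.
#'
#' @param geno a `genotype_matrix` (missing entries are mode-imputed for the
#'   causal columns before computing genetic values).
#' @param cfg a [field_config()].
#' @return A `ground_truth` list: `breeding_values` (accession x trait, on
#'   the control scale), `plot_traits` (data frame with plot metadata and the
#'   five traits), `qtl_effects` (SNP x trait; zero rows for non-causal
#'   SNPs), `qtl_index`.
#' @export
simulate_traits <- function(geno, cfg) {
  stopifnot(inherits(geno, "genotype_matrix"), inherits(cfg, "field_config"))
  m <- length(geno$accession_ids)
  with_seed(derive_seed(cfg$rng_seed, 2L), {
    qtl <- sort(sample.int(ncol(geno$scores), cfg$n_qtl))
    # Cholesky of the genetic correlation, clipping non-PD inputs at 0.
    ev <- eigen(cfg$trait_cor, symmetric = TRUE)
    if (min(ev$values) < 1e-10) {
      warning("trait_cor is singular; eigenvalues clipped at 0")
      ev$values <- pmax(ev$values, 0)
    }
    half <- ev$vectors %*% diag(sqrt(ev$values)) %*% t(ev$vectors)
    B <- matrix(rnorm(cfg$n_qtl * 5), cfg$n_qtl, 5) %*% half
    colnames(B) <- TRAITS

    Xq <- geno$scores[, qtl, drop = FALSE]
    if (anyNA(Xq)) Xq <- impute_missing_scores(Xq)
    Xq <- scale(Xq, center = TRUE, scale = FALSE)
    g_raw <- Xq %*% B
    g_std <- apply(g_raw, 2, function(v) {
      s <- sd(v)
      if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
    })

    bv <- sweep(g_std, 2, sqrt(cfg$heritability) * cfg$trait_sd, `*`)
    bv <- sweep(bv, 2, cfg$trait_mean, `+`)
    dimnames(bv) <- list(geno$accession_ids, TRAITS)

    meta <- expand.grid(replicate = seq_len(cfg$n_reps),
                        accession = geno$accession_ids,
                        treatment = cfg$treatments,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    meta <- meta[, c("accession", "treatment", "replicate")]
    meta$plot_id <- sprintf("P%04d", seq_len(nrow(meta)))
    resid_sd <- sqrt(1 - cfg$heritability) * cfg$trait_sd
    vals <- matrix(NA_real_, nrow(meta), 5, dimnames = list(NULL, TRAITS))
    for (t in TRAITS) {
      e <- rnorm(nrow(meta), 0, resid_sd[t])
      mult <- ifelse(meta$treatment == "drought",
                     cfg$drought_multipliers[t], 1)
      vals[, t] <- mult * (bv[meta$accession, t] + e)
    }
    structure(list(breeding_values = bv,
                   plot_traits = cbind(meta, as.data.frame(vals)),
                   qtl_effects = {
                     full <- matrix(0, ncol(geno$scores), 5,
                                    dimnames = list(geno$snp_ids, TRAITS))
                     full[qtl, ] <- B
                     full
                   },
                   qtl_index = qtl),
              class = "ground_truth")
  })
}

# Trait clipping bounds applied before rendering (documented plausible range).
.render_clip <- list(DW = c(0, 500), SL = c(0, 300), NN = c(0, 60),
                     NB = c(0, 30), PH = c(0, 300))

#' Render one plot scene from its trait values
#'
#' Procedural canopy renderer with the causal hooks the pipeline assumes:
#' the DSM maximum above the (flat, zero-height) ground plane equals plant
#' height `PH` in meters (`PH / 100`); the vegetation-pixel count grows
#' monotonically with dry weight `DW` (canopy ellipse area); the number of
#' brightness sub-blobs (texture granularity) grows with `NN + NB`; soil
#' pixels are drawn from a palette with VDVI <= 0 (below the 0.057
#' threshold); and `cfg$n_dark_pixels` near-black pixels (green < 10) are
#' injected into the canopy. Deterministic given `seed`. Trait values are
#' clipped to a plausible range before rendering.
#'
#' @param traits named numeric vector with entries `DW`, `SL`, `NN`, `NB`,
#'   `PH` on the raw scale.
#' @param cfg a [field_config()].
#' @param seed integer seed for this scene.
#' @param plot_id label carried on the output.
#' @return A `plot_image_pair`: list with `rgb` (H x W x 3 integer array),
#'   `dsm` (H x W meters above ground), `mask` (H x W logical ground-truth
#'   canopy mask), `plot_id`.
#' @export
render_plot_scene <- function(traits, cfg, seed, plot_id = "plot") {
  stopifnot(all(TRAITS %in% names(traits)), all(is.finite(traits[TRAITS])))
  tr <- vapply(TRAITS, function(t)
    min(max(traits[[t]], .render_clip[[t]][1]), .render_clip[[t]][2]), 0)
  names(tr) <- TRAITS
  H <- cfg$image_height; W <- cfg$image_width
  with_seed(seed, {
    cy <- (H + 1) / 2; cx <- (W + 1) / 2
    frac <- min(0.10 + 0.5 * tr["DW"] / (tr["DW"] + 100), 0.55)
    area <- frac * H * W
    ar <- 0.75                       # vertical/horizontal semi-axis ratio
    a <- sqrt(area / (pi * ar))
    b <- ar * a
    a <- min(a, 0.48 * W); b <- min(b, 0.48 * H)
    yy <- matrix(seq_len(H), H, W)
    xx <- matrix(seq_len(W), H, W, byrow = TRUE)
    r2 <- ((xx - cx) / a)^2 + ((yy - cy) / b)^2
    mask <- r2 <= 1 & tr["DW"] > 0

    dsm <- matrix(0, H, W)
    dome <- sqrt(pmax(0, 1 - r2))
    dsm[mask] <- (tr["PH"] / 100) * dome[mask]

    # soil background: G = frac * (R + B) / 2 with frac <= 1 => VDVI <= 0
    n_px <- H * W
    Rch <- matrix(round(runif(n_px, cfg$soil_red[1], cfg$soil_red[2])), H, W)
    Bch <- matrix(round(runif(n_px, cfg$soil_blue[1], cfg$soil_blue[2])), H, W)
    Gch <- round((Rch + Bch) / 2 *
                   matrix(runif(n_px, cfg$soil_green_frac[1],
                                cfg$soil_green_frac[2]), H, W))

    # canopy palette
    nv <- sum(mask)
    if (nv > 0) {
      Gch[mask] <- round(runif(nv, cfg$canopy_green[1], cfg$canopy_green[2]))
      Rch[mask] <- round(runif(nv, cfg$canopy_red[1], cfg$canopy_red[2]))
      Bch[mask] <- round(runif(nv, cfg$canopy_blue[1], cfg$canopy_blue[2]))

      # texture: sub-blob count tracks node + branch counts
      k <- max(1L, round((tr["NN"] + tr["NB"]) / 2))
      rb <- max(2, round(0.6 * min(a, b) / sqrt(k)))
      theta <- runif(k, 0, 2 * pi); rad <- sqrt(runif(k))
      bx <- cx + rad * a * 0.8 * cos(theta)
      by <- cy + rad * b * 0.8 * sin(theta)
      bright <- runif(k, 0.75, 1.25)
      for (i in seq_len(k)) {
        bm <- mask & ((xx - bx[i])^2 + (yy - by[i])^2 <= rb^2)
        Gch[bm] <- pmin(pmax(round(Gch[bm] * bright[i]), 95), 255)
      }

      # occluded near-black pixels exercising the dark-pixel filter;
      # capped at 1% of the canopy so segmentation recovery stays >= 95%
      nd <- min(cfg$n_dark_pixels, max(1, floor(0.01 * nv)))
      if (nd > 0) {
        dk <- sample(which(mask), nd)
        Rch[dk] <- 6L; Gch[dk] <- 8L; Bch[dk] <- 7L
      }
    }
    rgb <- array(0L, dim = c(H, W, 3))
    rgb[, , 1] <- as.integer(Rch); rgb[, , 2] <- as.integer(Gch)
    rgb[, , 3] <- as.integer(Bch)
    structure(list(rgb = rgb, dsm = dsm, mask = mask, plot_id = plot_id),
              class = "plot_image_pair")
  })
}

#' Generate a complete synthetic field trial
#'
#' Runs [simulate_genotypes()], [simulate_traits()], and (optionally)
#' [render_plot_scene()] for every plot, returning a single `lsp_field`
#' object that downstream stages consume. Bitwise-reproducible given
#' `cfg$rng_seed`.
#'
#' @param cfg a [field_config()].
#' @param render render plot imagery (set `FALSE` for genetics-only studies).
#' @return An `lsp_field` list: `cfg`, `geno`, `truth`, `plots` (metadata +
#'   raw traits), `images` (list of `plot_image_pair`, or `NULL`).
#' @export
simulate_field <- function(cfg, render = TRUE) {
  geno <- simulate_genotypes(cfg)
  truth <- simulate_traits(geno, cfg)
  plots <- truth$plot_traits
  images <- NULL
  if (render) {
    images <- lapply(seq_len(nrow(plots)), function(i) {
      render_plot_scene(unlist(plots[i, TRAITS]), cfg,
                        seed = derive_seed(cfg$rng_seed, 100L + i),
                        plot_id = plots$plot_id[i])
    })
    names(images) <- plots$plot_id
  }
  structure(list(cfg = cfg, geno = geno, truth = truth, plots = plots,
                 images = images),
            class = "lsp_field")
}
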