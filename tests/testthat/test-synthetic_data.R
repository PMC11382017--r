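test_that("field_config validates its inputs", {
  expect_error(field_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(field_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(field_config(missing_rate = 1), "missing_rate")
  expect_error(field_config(heritability = c(DW = 1.2, SL = 0.5, NN = 0.5,
                                             NB = 0.5, PH = 0.5)),
               "heritability")
  bad <- default_trait_cor(); bad[1, 2] <- 0.9
  expect_error(field_config(trait_cor = bad), "symmetric")
  bad <- default_trait_cor(); bad[1, 2] <- bad[2, 1] <- -0.99
  bad[1, 3] <- bad[3, 1] <- 0.99; bad[2, 3] <- bad[3, 2] <- 0.99
  expect_error(field_config(trait_cor = bad), "positive semi-definite")
})

test_that("simulated genotypes honor score coding, missingness, determinism", {
  cfg <- field_config(n_accessions = 30, n_snps = 50, missing_rate = 0,
                      rng_seed = 7)
  g <- simulate_genotypes(cfg)
  expect_false(anyNA(g$scores))
  expect_true(all(g$scores %in% c(-1, 0, 1)))
  expect_identical(dim(g$scores), c(30L, 50L))

  cfg2 <- field_config(n_accessions = 30, n_snps = 50, missing_rate = 0.2,
                       rng_seed = 7)
  g2 <- simulate_genotypes(cfg2)
  expect_gt(sum(is.na(g2$scores)), 0)
  # allele_freq uses non-missing entries only
  k <- which(colSums(is.na(g2$scores)) > 0)[1]
  s <- g2$scores[, k]
  expect_equal(g2$allele_freq[[k]], (mean(s[!is.na(s)]) + 1) / 2)

  expect_identical(simulate_genotypes(cfg)$scores, g$scores)
})

test_that("estimated allele frequency converges to the generating value", {
  cfg <- field_config(n_accessions = 5000, n_snps = 4,
                      maf_range = c(0.3, 0.3), missing_rate = 0,
                      rng_seed = 11)
  g <- simulate_genotypes(cfg)
  expect_true(all(abs(g$allele_freq - 0.3) < 0.02))
})

test_that("trait simulation respects heritability and treatment scaling", {
  h1 <- c(DW = 1, SL = 1, NN = 1, NB = 1, PH = 1)
  cfg <- field_config(n_accessions = 40, n_snps = 100, n_qtl = 20,
                      heritability = h1, missing_rate = 0, rng_seed = 3)
  truth <- simulate_traits(simulate_genotypes(cfg), cfg)
  pt <- truth$plot_traits
  for (t in TRAITS) {
    mult <- ifelse(pt$treatment == "drought", cfg$drought_multipliers[t], 1)
    expect_equal(pt[[t]], unname(mult * truth$breeding_values[pt$accession, t]),
                 tolerance = 1e-12)
  }

  h0 <- c(DW = 0, SL = 0, NN = 0, NB = 0, PH = 0)
  cfg0 <- field_config(n_accessions = 40, n_snps = 100, n_qtl = 20,
                       heritability = h0, missing_rate = 0, rng_seed = 3)
  truth0 <- simulate_traits(simulate_genotypes(cfg0), cfg0)
  # no additive variance: breeding values collapse to the trait mean and
  # plot values are independent of the raw genetic score
  expect_true(all(apply(truth0$breeding_values, 2, sd) == 0))
})

test_that("OLS of plot trait on breeding value recovers slope 1 at h2 = 0.5", {
  hs <- c(DW = 0.5, SL = 0.5, NN = 0.5, NB = 0.5, PH = 0.5)
  cfg <- field_config(n_accessions = 500, n_reps = 1,
                      treatments = "control", n_snps = 200, n_qtl = 50,
                      heritability = hs, missing_rate = 0, rng_seed = 5)
  truth <- simulate_traits(simulate_genotypes(cfg), cfg)
  pt <- truth$plot_traits
  for (t in c("DW", "PH")) {
    bv <- truth$breeding_values[pt$accession, t]
    slope <- stats::coef(stats::lm(pt[[t]] ~ bv))[2]
    expect_true(abs(slope - 1) < 0.1)
  }
})

test_that("realized genetic variance fraction matches configured h2", {
  hs <- c(DW = 0.3, SL = 0.5, NN = 0.7, NB = 0.5, PH = 0.9)
  cfg <- field_config(n_accessions = 250, n_reps = 1, treatments = "control",
                      n_snps = 200, n_qtl = 40, heritability = hs,
                      missing_rate = 0, rng_seed = 13)
  truth <- simulate_traits(simulate_genotypes(cfg), cfg)
  pt <- truth$plot_traits
  for (t in TRAITS) {
    g <- truth$breeding_values[pt$accession, t]
    e <- pt[[t]] - g
    frac <- var(g) / (var(g) + var(e))
    expect_true(abs(frac - hs[[t]]) < 0.1)
  }
})

test_that("singular trait correlation is clipped with a warning", {
  cfg <- field_config(n_accessions = 10, n_snps = 40, n_qtl = 5,
                      trait_cor = matrix(1, 5, 5), rng_seed = 1)
  expect_warning(simulate_traits(simulate_genotypes(cfg), cfg), "clipped")
})

test_that("rendered scenes encode traits as documented", {
  cfg <- field_config(image_height = 64, image_width = 64, rng_seed = 1)
  base <- c(DW = 60, SL = 90, NN = 15, NB = 6, PH = 80)

  flat <- render_plot_scene(replace(base, "PH", 0), cfg, seed = 21)
  expect_true(all(flat$dsm == 0))

  sc <- render_plot_scene(base, cfg, seed = 21)
  expect_equal(max(sc$dsm), 80 / 100, tolerance = 1e-3)

  # vegetation-pixel count strictly increases when dry weight doubles
  n1 <- vegetation_mask(sc$rgb)$count
  n2 <- vegetation_mask(render_plot_scene(replace(base, "DW", 120), cfg,
                                          seed = 21)$rgb)$count
  expect_gt(n2, n1)

  # soil pixels stay below the published VDVI threshold
  v <- vdvi(sc$rgb)
  expect_true(all(v[!sc$mask] <= 0.057))

  # dark pixels with green < 10 are present inside the canopy
  expect_gte(sum(sc$rgb[, , 2] < 10 & sc$mask), 1)

  # deterministic given seed
  sc2 <- render_plot_scene(base, cfg, seed = 21)
  expect_identical(sc$rgb, sc2$rgb)
  expect_identical(sc$dsm, sc2$dsm)
})

test_that("recovered vegetation masks overlap the renderer's canopy masks", {
  field <- small_field()
  for (img in field$images[seq(1, 40, by = 7)]) {
    vm <- vegetation_mask(img$rgb)
    expect_gte(mask_overlap(vm$mask, img$mask), 0.95)
  }
})

test_that("full field generation is reproducible from its config", {
  cfg <- field_config(n_accessions = 4, n_reps = 1, n_snps = 20, n_qtl = 4,
                      image_height = 32, image_width = 32, rng_seed = 99)
  f1 <- simulate_field(cfg)
  f2 <- simulate_field(cfg)
  expect_identical(f1$geno$scores, f2$geno$scores)
  expect_identical(f1$plots, f2$plots)
  expect_identical(f1$images[[3]]$rgb, f2$images[[3]]$rgb)
})
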