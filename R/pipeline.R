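#' Serialize and restore a trained network as plain text
#'
#' Checkpoints are JSON with every parameter array stored as
#' `{dim, data}` at full precision, plus the model spec and an optional
#' training log — inspectable and diffable.
#'
#' @param model an `lsp_cnn`.
#' @param path output path.
#' @param log optional per-epoch training log to embed.
#' @export
save_model <- function(model, path, log = NULL) {
  enc <- function(x) {
    if (is.list(x)) lapply(x, enc)
    else list(dim = dim(x) %||% length(x), data = as.numeric(x))
  }
  obj <- list(spec = unclass(model$spec),
              input_h = model$input_h, input_w = model$input_w,
              n_params = model$n_params,
              params = enc(model$params), log = log)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  dec <- function(x) {
    if (is.list(x) && !is.null(x$data)) {
      if (length(x$dim) == 2) matrix(x$data, x$dim[1], x$dim[2])
      else as.numeric(x$data)
    } else lapply(x, dec)
  }
  spec <- obj$spec
  spec$conv_filters <- as.integer(spec$conv_filters)
  spec$fc_dims <- as.integer(spec$fc_dims)
  class(spec) <- "model_spec"
  structure(list(spec = spec, params = dec(obj$params),
                 input_h = obj$input_h, input_w = obj$input_w,
                 n_params = obj$n_params),
            class = "lsp_cnn")
}

# Polynomial rolling hash of a serialized configuration, exact in double
# precision (no external digest dependency; cache invalidation only).
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2^32
  sprintf("%08x-%04d", as.integer(h %% 2^31), length(bytes) %% 10000)
}

#' End-to-end pipeline configuration
#'
#' Bundles the per-stage configurations with a global seed and the fidelity
#' flags. Every stage records the hash of its own configuration slice in its
#' manifest, making reruns skippable and outputs traceable.
#'
#' @param field a [field_config()].
#' @param spec a [model_spec()].
#' @param train a [train_config()].
#' @param scheme a [cv_scheme()] used by the genomic-prediction stages.
#' @param l_max component sweep bound for the PC-prediction stage.
#' @param maf_min,missing_max SNP filters.
#' @param n_pcs_annotate leading components in the annotation graph.
#' @param holdout fraction of plots held out as the training stage's
#'   validation split.
#' @param seed global seed.
#' @export
run_config <- function(field = field_config(),
                       spec = model_spec(),
                       train = train_config(),
                       scheme = cv_scheme(k = 5, repetitions = 2),
                       l_max = 10, maf_min = 0.025, missing_max = 0.05,
                       n_pcs_annotate = 3, holdout = 0.2, seed = 1L) {
  structure(list(field = field, spec = spec, train = train, scheme = scheme,
                 l_max = l_max, maf_min = maf_min, missing_max = missing_max,
                 n_pcs_annotate = n_pcs_annotate, holdout = holdout,
                 seed = as.integer(seed)),
            class = "run_config")
}

stage_manifest_path <- function(out_dir, stage)
  file.path(out_dir, stage, "manifest.json")

stage_fresh <- function(out_dir, stage, hash) {
  mp <- stage_manifest_path(out_dir, stage)
  if (!file.exists(mp)) return(FALSE)
  mf <- read_manifest(mp)
  if (!identical(mf$config_hash, hash)) return(FALSE)
  all(file.exists(file.path(out_dir, stage, mf$outputs)))
}

#' Run the full pipeline with stage caching
#'
#' Executes `simulate -> preprocess -> train -> latent -> gblup ->
#' pc_predict -> report` under `out_dir`, one subdirectory per stage, each
#' with a JSON manifest recording its configuration hash, seed, outputs, and
#' wall time. A stage is skipped when its manifest hash matches and all its
#' outputs (and every upstream stage) are unchanged; deleting an
#' intermediate re-runs only that stage and everything downstream. All
#' intermediates are plain text (CSV/PPM/PGM/JSON).
#'
#' @param config a [run_config()] or path to a JSON file of one (stage
#'   configs are rebuilt through their constructors).
#' @param out_dir run directory (created if needed).
#' @param dry_run print the stage plan and exit.
#' @return Invisibly, a list of per-stage results (`NULL` for skipped
#'   stages re-loaded from disk lazily).
#' @export
run_pipeline <- function(config, out_dir, dry_run = FALSE) {
  if (is.character(config)) {
    raw <- read_manifest(config)
    config <- run_config(
      field = do.call(field_config, raw$field),
      spec = do.call(model_spec, raw$spec[setdiff(names(raw$spec),
        c("input_channels", "n_blocks", "bn_momentum"))]),
      train = do.call(train_config, raw$train),
      scheme = do.call(cv_scheme, raw$scheme),
      l_max = raw$l_max %||% 10, maf_min = raw$maf_min %||% 0.025,
      missing_max = raw$missing_max %||% 0.05,
      n_pcs_annotate = raw$n_pcs_annotate %||% 3,
      holdout = raw$holdout %||% 0.2, seed = raw$seed %||% 1L)
  }
  stopifnot(inherits(config, "run_config"))
  stages <- c("simulate", "preprocess", "train", "latent", "gblup",
              "pc_predict", "report")
  hashes <- list(
    simulate = config_hash(config$field),
    preprocess = config_hash(list(config$field)),
    train = config_hash(list(config$field, unclass(config$spec),
                             unclass(config$train), config$holdout,
                             config$seed)),
    latent = config_hash(list("latent", config$n_pcs_annotate)),
    gblup = config_hash(list(unclass(config$scheme), config$maf_min,
                             config$missing_max)),
    pc_predict = config_hash(list(unclass(config$scheme), config$l_max)),
    report = config_hash("report"))
  # a stage's effective hash includes everything upstream
  for (i in seq_along(stages)[-1])
    hashes[[stages[i]]] <- config_hash(list(hashes[[stages[i - 1]]],
                                            hashes[[stages[i]]]))
  if (dry_run) {
    for (s in stages)
      message(sprintf("%-10s %s  %s", s, hashes[[s]],
                      if (stage_fresh(out_dir, s, hashes[[s]])) "skip"
                      else "run"))
    return(invisible(NULL))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  results <- list()
  upstream_ran <- FALSE
  run_stage <- function(stage, outputs, fn) {
    sdir <- file.path(out_dir, stage)
    if (!upstream_ran && stage_fresh(out_dir, stage, hashes[[stage]])) {
      message("skipping stage ", stage)
      return(NULL)
    }
    upstream_ran <<- TRUE
    t0 <- Sys.time()
    dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
    res <- tryCatch(fn(sdir), error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
    write_manifest(list(stage = stage, config_hash = hashes[[stage]],
                        seed = config$seed, outputs = outputs,
                        wall_seconds = as.numeric(difftime(Sys.time(), t0,
                                                           units = "secs"))),
                   stage_manifest_path(out_dir, stage))
    res
  }

  # shared in-memory state; stages re-derive from disk when skipped
  env <- new.env()
  need <- function(name, loader) {
    if (is.null(env[[name]])) env[[name]] <- loader()
    env[[name]]
  }

  results$simulate <- run_stage("simulate",
      c("traits.csv", "genotypes.csv"), function(sdir) {
    field <- simulate_field(config$field)
    write.csv(field$plots, file.path(sdir, "traits.csv"), row.names = FALSE)
    write_genotypes_csv(field$geno, file.path(sdir, "genotypes.csv"))
    img_dir <- file.path(sdir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    for (pid in names(field$images)) {
      write_ppm(field$images[[pid]]$rgb,
                file.path(img_dir, paste0(pid, ".ppm")))
      write_dsm(field$images[[pid]]$dsm,
                file.path(img_dir, paste0(pid, ".dsm.txt")))
    }
    env$field <- field
    field$plots$plot_id
  })
  load_field <- function() {
    # reconstruct deterministically from config (cheaper than re-reading
    # imagery, and bitwise-identical by construction)
    simulate_field(config$field)
  }

  results$preprocess <- run_stage("preprocess",
      c("traits_normalized.csv"), function(sdir) {
    field <- need("field", load_field)
    ds <- prepare_dataset(field)
    write.csv(cbind(ds$meta["plot_id"], ds$traits$normalized),
              file.path(sdir, "traits_normalized.csv"), row.names = FALSE)
    mask_dir <- file.path(sdir, "masks")
    dir.create(mask_dir, showWarnings = FALSE)
    for (i in seq_len(nrow(ds$meta)))
      write_pgm(ds$mask[, , i],
                file.path(mask_dir, paste0(ds$meta$plot_id[i], ".pgm")))
    env$dataset <- ds
    nrow(ds$meta)
  })
  load_dataset <- function() prepare_dataset(need("field", load_field))

  results$train <- run_stage("train",
      c("model.json", "training_log.csv"), function(sdir) {
    ds <- need("dataset", load_dataset)
    n <- nrow(ds$meta)
    val <- with_seed(derive_seed(config$seed, 5L),
                     sample.int(n, max(2, round(config$holdout * n))))
    tr <- setdiff(seq_len(n), val)
    x_tr <- build_input(ds, config$spec, tr)
    x_val <- build_input(ds, config$spec, val)
    model <- build_model(config$spec, dim(x_tr)[1], dim(x_tr)[2],
                         seed = config$seed)
    fit <- train_model(model, x_tr, ds$traits$normalized[tr, ],
                       x_val, ds$traits$normalized[val, ], config$train)
    save_model(fit$model, file.path(sdir, "model.json"))
    write.csv(fit$log, file.path(sdir, "training_log.csv"),
              row.names = FALSE)
    env$model <- fit$model
    fit$best_val_mse
  })
  load_cnn <- function() load_model(file.path(out_dir, "train", "model.json"))

  results$latent <- run_stage("latent",
      c("w_prime.csv", "annotation_graph.json"), function(sdir) {
    ds <- need("dataset", load_dataset)
    model <- need("model", load_cnn)
    feats <- extract_features(model, build_input(ds, config$spec))
    pca <- fit_pca(feats)
    hp <- pc_head(pca, feats$W, feats$b)
    write.csv(data.frame(pc = seq_len(nrow(hp$W_prime)), hp$W_prime),
              file.path(sdir, "w_prime.csv"), row.names = FALSE)
    write_manifest(annotation_graph(hp$W_prime, config$n_pcs_annotate),
                   file.path(sdir, "annotation_graph.json"))
    env$features <- feats
    hp$proportion_of_variance[seq_len(config$n_pcs_annotate)]
  })
  load_features <- function()
    extract_features(need("model", load_cnn),
                     build_input(need("dataset", load_dataset), config$spec))

  results$gblup <- run_stage("gblup", "trait_accuracy.csv", function(sdir) {
    field <- need("field", load_field)
    ds <- need("dataset", load_dataset)
    geno <- impute_missing(filter_snps(field$geno, config$maf_min,
                                       config$missing_max))
    env$grm <- compute_grm(geno)
    acc <- list()
    for (t in TRAITS) {
      cv <- cv_gblup(ds$meta[[t]], ds$meta$accession, env$grm,
                     config$scheme, ds$meta$treatment)
      acc[[t]] <- cbind(trait = t, cv$summary)
      env$direct[[t]] <- cv
    }
    acc <- do.call(rbind, acc)
    write.csv(acc, file.path(sdir, "trait_accuracy.csv"), row.names = FALSE)
    acc
  })
  load_grm <- function() {
    field <- need("field", load_field)
    compute_grm(impute_missing(filter_snps(field$geno, config$maf_min,
                                           config$missing_max)))
  }

  results$pc_predict <- run_stage("pc_predict", "pc_accuracy.csv",
      function(sdir) {
    ds <- need("dataset", load_dataset)
    feats <- need("features", load_features)
    grm <- need("grm", load_grm)
    sw <- sweep_components(feats, as.matrix(ds$meta[, TRAITS]),
                           ds$meta, grm, config$scheme, config$l_max)
    write.csv(sw$summary, file.path(sdir, "pc_accuracy.csv"),
              row.names = FALSE)
    env$sweep <- sw
    sw$summary
  })

  results$report <- run_stage("report", "summary.json", function(sdir) {
    rep <- list(config_hashes = hashes,
                seed = config$seed,
                stages_present = stages[file.exists(vapply(
                  stages, function(s) stage_manifest_path(out_dir, s), ""))])
    if (!is.null(env$sweep)) {
      best <- env$sweep$summary
      rep$best_pc_accuracy <- best[which.max(best$mean_r), ]
    }
    write_manifest(rep, file.path(sdir, "summary.json"))
    rep
  })
  invisible(results)
}
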