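#' Synthetic study specification
#'
#' Defines the synthetic cohort the end-to-end pipeline runs on when no real
#' image manifest is supplied: two groups of tongue images whose body and
#' coating mean colors, coating fraction and covariates are shifted in the
#' diabetes-analog class, with per-subject jitter. The default cohort of 120
#' images keeps the minority/majority ratio close to a 296/531-style
#' imbalanced clinical cohort while staying desk-sized.
#'
#' @param n_minority,n_majority Images in the diabetes-analog (label 1) and
#'   control (label 0) groups.
#' @param base Baseline image specification (a [synthetic_spec()]); per-image
#'   seeds are derived from `seed`.
#' @param body_shift,coating_shift RGB shifts added to the class-1 group's
#'   mean colors.
#' @param coating_fraction_shift Added to the class-1 coating fraction.
#' @param color_jitter_sd Per-subject SD of the mean-color jitter (RGB units).
#' @param age_mean,age_sd,age_shift,bmi_mean,bmi_sd,bmi_shift Covariate
#'   distributions (years, kg/m^2); shifts apply to class 1.
#' @param seed Integer seed.
#' @return Object of class `study_spec`.
#' @export
study_spec <- function(n_minority = 45, n_majority = 75,
                       base = synthetic_spec(),
                       body_shift = c(15, -10, -5),
                       coating_shift = c(-8, 0, 10),
                       coating_fraction_shift = 0.1,
                       color_jitter_sd = 4,
                       age_mean = 60, age_sd = 10, age_shift = 6,
                       bmi_mean = 24, bmi_sd = 3, bmi_shift = 3,
                       seed = 1) {
  structure(as.list(environment()), class = "study_spec")
}

#' Generate the synthetic study cohort
#'
#' @param spec A [study_spec()].
#' @return List of subjects; each has `image`, `body_mask`, `coating_mask`,
#'   `covariates` (gender, age, bmi) and `label`.
#' @export
make_study_cohort <- function(spec = study_spec()) {
  stopifnot(inherits(spec, "study_spec"))
  n <- spec$n_minority + spec$n_majority
  labels <- c(rep(1L, spec$n_minority), rep(0L, spec$n_majority))
  with_seed(spec$seed, {
    lapply(seq_len(n), function(i) {
      lab <- labels[i]
      jit <- function(v) v + stats::rnorm(length(v), 0, spec$color_jitter_sd)
      body_col <- clip255(jit(spec$base$body_color + lab * spec$body_shift))
      coat_col <- clip255(jit(spec$base$coating_color + lab * spec$coating_shift))
      frac <- min(max(spec$base$coating_fraction +
                        lab * spec$coating_fraction_shift +
                        stats::rnorm(1, 0, 0.03), 0.05), 0.9)
      img_seed <- derive_seed(spec$seed, i)
      s <- synthetic_spec(height = spec$base$height, width = spec$base$width,
                          body_color = body_col, coating_color = coat_col,
                          coating_fraction = frac,
                          texture_amplitude = spec$base$texture_amplitude,
                          noise_sigma = spec$base$noise_sigma,
                          seed = img_seed)
      fx <- make_tongue_image(s)
      list(image = fx$image, body_mask = fx$body_mask,
           coating_mask = fx$coating_mask,
           covariates = c(gender = stats::rbinom(1, 1, 0.5),
                          age = stats::rnorm(1, spec$age_mean + lab * spec$age_shift,
                                             spec$age_sd),
                          bmi = stats::rnorm(1, spec$bmi_mean + lab * spec$bmi_shift,
                                             spec$bmi_sd)),
           label = lab)
    })
  })
}

#' Extract the full feature vector of one tongue image
#'
#' Segments the image into body and coating and computes per-region color
#' means (RGB, HSI, CIELAB) and gray-level-difference texture statistics,
#' prefixed `body_` / `coating_`. With the three covariates this gives the
#' 29-column feature vector (3 + 18 + 8).
#'
#' @param image A [tongue_image()].
#' @param seg_cfg A [segmentation_config()].
#' @param displacements Texture displacements, see
#'   [region_texture_features()].
#' @param segmentation Optional precomputed `segmentation_result`.
#' @return Named numeric vector of 26 image features (coating features are
#'   NA when the coating is absent).
#' @export
extract_features <- function(image, seg_cfg = segmentation_config(),
                             displacements = list(c(0, 1), c(1, 0)),
                             segmentation = NULL) {
  seg <- segmentation %||% suppressWarnings(segment_body_coating(image, seg_cfg))
  out <- c()
  for (region in c("body", "coating")) {
    m <- seg[[paste0(region, "_mask")]]
    col <- region_color_means(image, m)
    tex <- region_texture_features(image, m, displacements)
    v <- c(col, tex)
    names(v) <- paste0(region, "_", c(names(col), names(tex)))
    out <- c(out, v)
  }
  out
}

#' Pipeline configuration
#'
#' Bundles the per-stage configurations and a global seed from which every
#' stochastic stage derives its own seed.
#'
#' @param study A [study_spec()] (the synthetic cohort), or NULL when
#'   `manifest` is given.
#' @param manifest Optional data.frame describing real images: columns
#'   `image`, `mask` (paths), `label`, and optionally `gender`, `age`,
#'   `bmi`.
#' @param segmentation A [segmentation_config()].
#' @param displacements Texture displacements.
#' @param smote_k SMOTE neighbor count.
#' @param retain PCA retained-variance fraction (0.95 keeps 95% of the
#'   variance); `use_pca = FALSE` skips the reduction.
#' @param use_pca Apply PCA after scaling.
#' @param train_fraction Train share of the 80/20-style split.
#' @param ga A [ga_config()].
#' @param knn_k,nnet_size,nnet_maxit Baseline settings.
#' @param seed Global seed.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(study = study_spec(), manifest = NULL,
                            segmentation = segmentation_config(),
                            displacements = list(c(0, 1), c(1, 0)),
                            smote_k = 5, retain = 0.95, use_pca = TRUE,
                            train_fraction = 0.8, ga = ga_config(),
                            knn_k = 5, nnet_size = 10, nnet_maxit = 200,
                            seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

log_line <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  if (!is.null(con)) writeLines(msg, con)
  message(msg)
}

#' Run the full pipeline
#'
#' Executes segmentation, feature extraction, a stratified train/test split,
#' SMOTE on the training rows only, [-1, 1] scaling and PCA fit on the
#' training rows, the GA search for the SVM parameters, and evaluation of
#' the GA-SVM against the k-NN, naive Bayes and BP-NN baselines. Every
#' intermediate is persisted in `outdir`; identical configuration and seed
#' give a byte-identical feature table and report.
#'
#' @param cfg A [pipeline_config()].
#' @param outdir Output directory (created if missing).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the feature table, fitted models, GA
#'   result, evaluation (`reports`, `summary`), segmentation IoU (synthetic
#'   cohorts only) and output paths.
#' @export
run_pipeline <- function(cfg = pipeline_config(), outdir = tempfile("tonguedx_run_"),
                         quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "log.txt")
  con <- file(log_path, "w")
  on.exit(close(con))
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    writeLines(msg, con)
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e) {
      say("STAGE %s FAILED: %s", name, conditionMessage(e))
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    say("stage %-12s done in %.2fs", name, proc.time()[3] - t0)
    out
  }

  # --- images and features -------------------------------------------------
  seg_iou <- NULL
  feats <- stage("features", {
    if (!is.null(cfg$manifest)) {
      rows <- lapply(seq_len(nrow(cfg$manifest)), function(i) {
        r <- cfg$manifest[i, ]
        img <- read_tongue_png(r$image, if (!is.na(r$mask %||% NA)) r$mask else NULL,
                               full_mask = is.null(r$mask) || is.na(r$mask))
        fv <- extract_features(img, cfg$segmentation, cfg$displacements)
        cov <- c(gender = r$gender %||% NA_real_, age = r$age %||% NA_real_,
                 bmi = r$bmi %||% NA_real_)
        c(cov, fv, label = as.integer(r$label))
      })
      as.data.frame(do.call(rbind, rows))
    } else {
      cohort <- make_study_cohort(cfg$study)
      iou <- matrix(NA_real_, length(cohort), 2,
                    dimnames = list(NULL, c("body", "coating")))
      rows <- lapply(seq_along(cohort), function(i) {
        s <- cohort[[i]]
        seg <- suppressWarnings(segment_body_coating(s$image, cfg$segmentation))
        iou[i, ] <<- c(mask_iou(seg$body_mask, s$body_mask),
                       mask_iou(seg$coating_mask, s$coating_mask))
        fv <- extract_features(s$image, cfg$segmentation, cfg$displacements,
                               segmentation = seg)
        c(s$covariates, fv, label = s$label)
      })
      seg_iou <- colMeans(iou)
      say("mean segmentation IoU: body %.4f, coating %.4f",
          seg_iou["body"], seg_iou["coating"])
      as.data.frame(do.call(rbind, rows))
    }
  })
  feats$label <- as.integer(feats$label)
  features_path <- file.path(outdir, "features.csv")
  utils::write.csv(feats, features_path, row.names = FALSE)

  # --- split / SMOTE / scale / PCA ----------------------------------------
  split <- stage("split", split_dataset(feats, cfg$train_fraction,
                                        seed = derive_seed(cfg$seed, 101)))
  train <- impute_missing(split$train)
  test <- impute_missing(split$train, split$test)

  train <- stage("smote", smote_balance(train, k_neighbors = cfg$smote_k,
                                        seed = derive_seed(cfg$seed, 202)))
  scaler <- stage("scale", fit_scaler(train))
  train_s <- apply_scaler(scaler, train)
  test_s <- apply_scaler(scaler, test)

  if (cfg$use_pca) {
    pca <- stage("pca", fit_pca(train_s, retain = cfg$retain))
    train_p <- apply_pca(pca, train_s)
    test_p <- apply_pca(pca, test_s)
    say("PCA retained %d of %d components (%.2f%% variance)",
        pca$k, length(pca$var_ratio), 100 * sum(pca$var_ratio[seq_len(pca$k)]))
  } else {
    pca <- NULL
    train_p <- train_s; test_p <- test_s
  }
  jsonlite::write_json(
    list(scaler = list(cols = scaler$cols, min = scaler$min, max = scaler$max),
         pca = if (!is.null(pca)) list(cols = pca$cols, center = pca$center,
                                       rotation = pca$rotation,
                                       var_ratio = pca$var_ratio, k = pca$k)),
    file.path(outdir, "preprocess.json"), digits = NA)

  # --- GA-SVM --------------------------------------------------------------
  ga_cfg <- cfg$ga
  ga_cfg$seed <- derive_seed(cfg$seed, 303)
  ga <- stage("ga_svm", ga_optimize(train_p, ga_cfg))
  say("GA best: c = %.4g, g = %.4g, CV accuracy %.4f",
      ga$best_params$c, ga$best_params$g, ga$best_fitness)
  utils::write.csv(ga$trace, file.path(outdir, "trace.csv"), row.names = FALSE)

  model <- train_svm(train_p, ga$best_params)
  jsonlite::write_json(
    list(type = "rbf_c_svm", c = ga$best_params$c, g = ga$best_params$g,
         cv_fitness = ga$best_fitness, feature_cols = model$cols,
         support_vectors = model$fit$SV, coefficients = as.numeric(model$fit$coefs),
         rho = model$fit$rho, flip_decision = model$flip),
    file.path(outdir, "model.json"), digits = NA)

  # --- evaluation ----------------------------------------------------------
  ev <- stage("evaluate", run_baselines(train_p, test_p, ga$best_params,
                                        knn_k = cfg$knn_k,
                                        nnet_size = cfg$nnet_size,
                                        nnet_maxit = cfg$nnet_maxit,
                                        seed = derive_seed(cfg$seed, 404)))
  report <- list(
    seed = cfg$seed,
    n_subjects = nrow(feats),
    class_counts = as.list(table(feats$label)),
    train_rows = nrow(train_p), test_rows = nrow(test_p),
    smote = list(k = cfg$smote_k, synthetic_rows = sum(train$synthetic)),
    pca = if (!is.null(pca)) list(k = pca$k, n_features = length(pca$var_ratio),
                                  retained_variance = sum(pca$var_ratio[seq_len(pca$k)])),
    segmentation_mean_iou = as.list(seg_iou),
    ga = list(c = ga$best_params$c, g = ga$best_params$g,
              best_cv_accuracy = ga$best_fitness,
              first_generation_cv_accuracy = ga$trace$best_fitness[1],
              n_evaluations = ga$n_evaluations),
    classifiers = lapply(ev$reports, function(r) {
      list(accuracy = r$accuracy, sensitivity = r$sensitivity,
           specificity = r$specificity, auc = r$auc,
           counts = as.list(r$counts))
    }))
  report_path <- file.path(outdir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(ev$summary, file.path(outdir, "report_table.csv"),
                   row.names = FALSE)
  roc <- do.call(rbind, lapply(names(ev$reports), function(nm) {
    r <- ev$reports[[nm]]
    if (is.null(r$roc)) return(NULL)
    cbind(classifier = nm, rbind(cbind(class = "positive", r$roc$positive),
                                 cbind(class = "negative", r$roc$negative)))
  }))
  utils::write.csv(roc, file.path(outdir, "roc.csv"), row.names = FALSE)
  say("done: %s", report_path)

  invisible(list(features = feats, split = split, scaler = scaler, pca = pca,
                 ga = ga, model = model, evaluation = ev, report = report,
                 segmentation_iou = seg_iou,
                 paths = list(outdir = outdir, features = features_path,
                              report = report_path, log = log_path)))
}
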