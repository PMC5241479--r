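#' SVM hyperparameters
#'
#' The soft-margin penalty `c` and the RBF kernel parameter `g` of
#' `K(x, y) = exp(-g ||x - y||^2)`; both strictly positive, searched on a
#' log2 scale.
#'
#' @param c Penalty parameter (> 0).
#' @param g Kernel parameter (> 0).
#' @return Object of class `svm_params`.
#' @export
svm_params <- function(c, g) {
  if (c <= 0 || g <= 0) stop("c and g must be strictly positive")
  structure(list(c = c, g = g), class = "svm_params")
}

#' Genetic-algorithm configuration for SVM parameter search
#'
#' Chromosomes are `(log2 c, log2 g)` pairs. The defaults follow common
#' practice for GA-tuned RBF SVMs: population 20 evolved for 100
#' generations, tournament selection of size 2, uniform crossover with
#' probability 0.7, per-gene Gaussian mutation with probability 0.1 and
#' standard deviation 0.5 (log2 units) clipped to the bounds, and elitism of
#' the single best individual. Fitness is `cv_folds`-fold cross-validated
#' accuracy (10-fold by default).
#'
#' @param population_size,generations GA size and length.
#' @param bounds_log2c,bounds_log2g Search bounds on the log2 scale.
#' @param crossover_prob,mutation_prob,mutation_sd,tournament_size,elitism
#'   GA operator settings.
#' @param cv_folds Cross-validation folds used by the fitness.
#' @param seed Integer seed (drives init, selection, crossover, mutation and
#'   the fold assignment).
#' @return Object of class `ga_config`.
#' @export
ga_config <- function(population_size = 20, generations = 100,
                      bounds_log2c = c(-5, 15), bounds_log2g = c(-15, 3),
                      crossover_prob = 0.7, mutation_prob = 0.1,
                      mutation_sd = 0.5, tournament_size = 2, elitism = 1,
                      cv_folds = 10, seed = 1) {
  if (population_size < 2) stop("population_size must be >= 2")
  if (generations < 1) stop("generations must be >= 1")
  for (p in c(crossover_prob, mutation_prob)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  }
  structure(list(population_size = population_size, generations = generations,
                 bounds_log2c = bounds_log2c, bounds_log2g = bounds_log2g,
                 crossover_prob = crossover_prob, mutation_prob = mutation_prob,
                 mutation_sd = mutation_sd, tournament_size = tournament_size,
                 elitism = elitism, cv_folds = cv_folds, seed = seed),
            class = "ga_config")
}

# Stratified fold assignment: within each class, rows are permuted under the
# seed and dealt cyclically to folds.
stratified_folds <- function(y, folds, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

#' Cross-validated accuracy of an RBF SVM
#'
#' Mean held-out accuracy over stratified k folds of a C-classification RBF
#' SVM trained per fold at the given parameters. Identical inputs and seed
#' give identical fitness.
#'
#' @param data Data.frame with numeric features and a 0/1 `label` column
#'   (both classes must be present).
#' @param params An [svm_params()].
#' @param folds Number of folds (>= 2).
#' @param seed Seed for the fold assignment.
#' @param label_col Label column name.
#' @return Accuracy in [0, 1].
#' @export
cv_fitness <- function(data, params, folds = 10, seed = 1, label_col = "label") {
  stopifnot(inherits(params, "svm_params"), folds >= 2)
  y <- data[[label_col]]
  stopifnot_binary_labels(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  cols <- feature_cols(data, label_col)
  x <- as.matrix(data[, cols, drop = FALSE])
  yf <- factor(y, levels = c(0, 1))
  fold <- stratified_folds(y, folds, seed)
  acc <- vapply(seq_len(folds), function(f) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2 || !any(!tr)) return(NA_real_)
    fit <- e1071::svm(x[tr, , drop = FALSE], yf[tr],
                      type = "C-classification", kernel = "radial",
                      cost = params$c, gamma = params$g, scale = FALSE)
    mean(predict(fit, x[!tr, , drop = FALSE]) == yf[!tr])
  }, 1)
  mean(acc, na.rm = TRUE)
}

#' Genetic-algorithm search for SVM parameters
#'
#' Evolves `(log2 c, log2 g)` chromosomes by tournament selection, uniform
#' crossover, Gaussian mutation clipped to the bounds, and single-individual
#' elitism; fitness is cross-validated accuracy ([cv_fitness()] with a fold
#' assignment fixed across the whole run). Returns the best chromosome ever
#' evaluated, so the best-so-far fitness trace is non-decreasing by
#' construction.
#'
#' @param data Training table (preprocessed features plus `label`).
#' @param cfg A [ga_config()].
#' @param fitness_fn Optional fitness override, a
#'   `function(params)` returning a scalar (used for testing and for custom
#'   objectives); defaults to [cv_fitness()] on `data`.
#' @param label_col Label column name.
#' @return List: `best_params` ([svm_params()]), `best_fitness`, `trace`
#'   (data.frame per generation: `generation`, `best_fitness` so far,
#'   `mean_fitness` of the population, `log2c`, `log2g`, `c`, `g` of the
#'   best-so-far individual), and `n_evaluations`.
#' @export
ga_optimize <- function(data, cfg = ga_config(), fitness_fn = NULL,
                        label_col = "label") {
  stopifnot(inherits(cfg, "ga_config"))
  if (is.null(fitness_fn)) {
    force(data)
    fitness_fn <- function(params) {
      cv_fitness(data, params, folds = cfg$cv_folds, seed = cfg$seed,
                 label_col = label_col)
    }
  }
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  evaluate <- function(chrom) {
    key <- paste(sprintf("%.12g", chrom), collapse = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- fitness_fn(svm_params(2^chrom[1], 2^chrom[2]))
    n_eval <<- n_eval + 1L
    cache[[key]] <- f
    f
  }
  lo <- c(cfg$bounds_log2c[1], cfg$bounds_log2g[1])
  hi <- c(cfg$bounds_log2c[2], cfg$bounds_log2g[2])
  clipb <- function(v) pmin(pmax(v, lo), hi)

  with_seed(cfg$seed, {
    pop <- lapply(seq_len(cfg$population_size), function(i) {
      lo + stats::runif(2) * (hi - lo)
    })
    best_chrom <- NULL
    best_fit <- -Inf
    trace <- vector("list", cfg$generations)
    for (gen in seq_len(cfg$generations)) {
      fit <- vapply(pop, evaluate, 1)
      gi <- which.max(fit)
      if (fit[gi] > best_fit) {
        best_fit <- fit[gi]
        best_chrom <- pop[[gi]]
      }
      trace[[gen]] <- data.frame(generation = gen,
                                 best_fitness = best_fit,
                                 mean_fitness = mean(fit),
                                 log2c = best_chrom[1], log2g = best_chrom[2])
      if (gen == cfg$generations) break
      tournament <- function() {
        cand <- sample.int(cfg$population_size, cfg$tournament_size)
        pop[[cand[which.max(fit[cand])]]]
      }
      nxt <- list()
      if (cfg$elitism > 0) nxt[[1]] <- best_chrom
      while (length(nxt) < cfg$population_size) {
        p1 <- tournament(); p2 <- tournament()
        child <- if (stats::runif(1) < cfg$crossover_prob) {
          pick <- stats::runif(2) < 0.5
          ifelse(pick, p1, p2)
        } else p1
        mut <- stats::runif(2) < cfg$mutation_prob
        child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, cfg$mutation_sd)
        nxt[[length(nxt) + 1]] <- clipb(child)
      }
      pop <- nxt
    }
    trace <- do.call(rbind, trace)
    trace$c <- 2^trace$log2c
    trace$g <- 2^trace$log2g
    list(best_params = svm_params(2^best_chrom[1], 2^best_chrom[2]),
         best_fitness = best_fit, trace = trace, n_evaluations = n_eval)
  })
}

#' Train an RBF SVM / predict labels and decision values
#'
#' Thin wrapper around a C-classification RBF SVM; the quadratic program is
#' delegated to the e1071 solver. Decision values are oriented so positive
#' values correspond to label 1.
#'
#' @param data Preprocessed training table with a 0/1 `label` column.
#' @param params An [svm_params()].
#' @param label_col Label column name.
#' @return Object of class `ga_svm_model`.
#' @export
train_svm <- function(data, params, label_col = "label") {
  stopifnot(inherits(params, "svm_params"))
  y <- data[[label_col]]
  stopifnot_binary_labels(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  cols <- feature_cols(data, label_col)
  fit <- e1071::svm(as.matrix(data[, cols, drop = FALSE]),
                    factor(y, levels = c(0, 1)),
                    type = "C-classification", kernel = "radial",
                    cost = params$c, gamma = params$g, scale = FALSE)
  # e1071 orients the decision value toward the first training label
  positive_first <- fit$levels[fit$labels[1]] == "1"
  structure(list(fit = fit, params = params, cols = cols,
                 flip = !positive_first),
            class = "ga_svm_model")
}

#' @rdname train_svm
#' @param object A `ga_svm_model`.
#' @param newdata Data.frame containing the model's feature columns.
#' @param ... Unused.
#' @return `predict`: list with `labels` (integer 0/1) and `decision`
#'   (finite reals; positive sign corresponds to label 1).
#' @export
predict.ga_svm_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$cols, drop = FALSE])
  pr <- predict(object$fit, x, decision.values = TRUE)
  d <- as.numeric(attr(pr, "decision.values"))
  if (object$flip) d <- -d
  list(labels = as.integer(as.character(pr)), decision = d)
}

#' @export
print.ga_svm_model <- function(x, ...) {
  cat(sprintf("<ga_svm_model> RBF SVM, c = %.4g, g = %.4g, %d support vectors\n",
              x$params$c, x$params$g, x$fit$tot.nSV))
  invisible(x)
}
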