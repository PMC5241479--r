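test_that("cross-validated fitness is high on separable data and deterministic", {
  d <- make_feature_dataset(dataset_spec(n_minority = 100, n_majority = 100,
                                         n_features = 5, class_separation = 10,
                                         seed = 1))
  f <- cv_fitness(d, svm_params(1, 0.2), folds = 10, seed = 2)
  expect_gte(f, 0.99)
  expect_identical(f, cv_fitness(d, svm_params(1, 0.2), folds = 10, seed = 2))
})

test_that("fitness on permuted labels hovers at chance", {
  d <- make_feature_dataset(dataset_spec(n_minority = 200, n_majority = 200,
                                         n_features = 5, class_separation = 3,
                                         seed = 3))
  fits <- vapply(1:3, function(s) {
    dp <- d
    set.seed(s)
    dp$label <- sample(dp$label)
    cv_fitness(dp, svm_params(1, 0.2), folds = 10, seed = s)
  }, 1)
  expect_gte(mean(fits), 0.40)
  expect_lte(mean(fits), 0.60)
})

test_that("fitness is invariant to row order of the training table", {
  d <- make_feature_dataset(dataset_spec(n_minority = 60, n_majority = 80,
                                         n_features = 4, seed = 5))
  f1 <- cv_fitness(d, svm_params(2, 0.1), folds = 5, seed = 7)
  set.seed(11)
  # folds are assigned by seeded permutation of row indices, then fixed, so
  # shuffling rows relabels folds but pools the same per-class partitions
  f2 <- cv_fitness(d[sample(nrow(d)), ], svm_params(2, 0.1), folds = 5, seed = 7)
  expect_equal(f1, f2, tolerance = 0.05)
  expect_error(cv_fitness(d[d$label == 1, ], svm_params(1, 1)), "both classes")
})

test_that("the GA respects a stubbed constant fitness and is reproducible", {
  d <- make_feature_dataset(dataset_spec(n_minority = 20, n_majority = 20,
                                         n_features = 2))
  cfg <- ga_config(population_size = 6, generations = 5, seed = 9)
  res <- ga_optimize(d, cfg, fitness_fn = function(p) 0.42)
  expect_equal(res$best_fitness, 0.42)
  expect_true(all(res$trace$best_fitness == 0.42))
  expect_equal(nrow(res$trace), 5)

  res2 <- ga_optimize(d, cfg, fitness_fn = function(p) 0.42)
  expect_identical(res$trace, res2$trace)
})

test_that("best-so-far fitness is monotone and bounds are honored", {
  d <- make_feature_dataset(dataset_spec(n_minority = 40, n_majority = 40,
                                         n_features = 3, class_separation = 2,
                                         seed = 2))
  cfg <- ga_config(population_size = 8, generations = 8, cv_folds = 4, seed = 3)
  res <- ga_optimize(d, cfg)
  expect_false(is.unsorted(res$trace$best_fitness))
  expect_true(all(res$trace$log2c >= -5 & res$trace$log2c <= 15))
  expect_true(all(res$trace$log2g >= -15 & res$trace$log2g <= 3))
  expect_s3_class(res$best_params, "svm_params")
})

test_that("GA matches a coarse grid search within tolerance on a small task", {
  d <- make_feature_dataset(dataset_spec(n_minority = 50, n_majority = 50,
                                         n_features = 4, class_separation = 2.5,
                                         seed = 6))
  folds <- 5; fseed <- 4
  grid_best <- max(vapply(
    as.data.frame(t(expand.grid(lc = seq(-5, 15, length.out = 5),
                                lg = seq(-15, 3, length.out = 5)))),
    function(v) cv_fitness(d, svm_params(2^v[1], 2^v[2]), folds, fseed), 1))
  cfg <- ga_config(population_size = 10, generations = 15, cv_folds = folds,
                   seed = fseed)
  res <- ga_optimize(d, cfg)
  expect_gte(res$best_fitness, grid_best - 0.02)
})

test_that("GA dominates random search at equal evaluation budget in most trials", {
  d <- make_feature_dataset(dataset_spec(n_minority = 40, n_majority = 40,
                                         n_features = 3, class_separation = 2,
                                         seed = 8))
  wins <- 0
  for (s in 1:4) {
    cfg <- ga_config(population_size = 8, generations = 6, cv_folds = 4, seed = s)
    ga <- ga_optimize(d, cfg)
    budget <- ga$n_evaluations
    rnd <- local({
      set.seed(s + 100)
      max(vapply(seq_len(budget), function(i) {
        lc <- runif(1, -5, 15); lg <- runif(1, -15, 3)
        cv_fitness(d, svm_params(2^lc, 2^lg), folds = 4, seed = s)
      }, 1))
    })
    if (ga$best_fitness >= rnd) wins <- wins + 1
  }
  expect_gte(wins, 2)
})

test_that("training and prediction are definitionally consistent", {
  d <- make_feature_dataset(dataset_spec(n_minority = 60, n_majority = 60,
                                         n_features = 4, class_separation = 8,
                                         seed = 4))
  m <- train_svm(d, svm_params(100, 0.5))
  pr <- predict(m, d)
  expect_equal(mean(pr$labels == d$label), 1)          # separable, large c
  expect_true(all(is.finite(pr$decision)))
  expect_true(all((pr$decision > 0) == (pr$labels == 1)))
  expect_error(train_svm(d[d$label == 0, ], svm_params(1, 1)), "both classes")
})

test_that("decision values grow with distance from the boundary in 1-D", {
  d <- data.frame(x = c(-1, 1), label = c(0L, 1L))
  m <- train_svm(d, svm_params(10, 0.5))
  grid <- data.frame(x = seq(-1, 1, by = 0.25))
  dec <- predict(m, grid)$decision
  expect_true(all(diff(dec) > 0))
  expect_lt(abs(dec[grid$x == 0]), 1e-9)  # symmetric toy problem
})

test_that("configuration validation rejects degenerate settings", {
  expect_error(ga_config(population_size = 1), "population_size")
  expect_error(ga_config(generations = 0), "generations")
  expect_error(ga_config(crossover_prob = 1.5), "probabilities")
  expect_error(svm_params(0, 1), "strictly positive")
})
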