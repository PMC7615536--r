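design <- build_design(growth_spec())

test_that("identical config and seed give byte-identical cohorts", {
  cfg <- default_generator_config(200, seed = 5, aux = TRUE)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$cohort, g2$cohort)
  expect_identical(g1$truth$labels, g2$truth$labels)
})

test_that("degenerate noise-free single class reproduces its means exactly", {
  cfg <- generator_config(25, 1, list(c(3, 0, 0, 5, 0, 0)),
                          factor_covariance = matrix(0, 4, 4),
                          residual_variances = c(0, 0), seed = 2)
  Y <- trajmix:::trait_matrix(generate_cohort(cfg)$cohort, design)
  expect_true(all(Y[, 1:8] == 3))
  expect_true(all(Y[, 9:13] == 5))
})

test_that("generated scores are integers within the scale bounds", {
  g <- generate_cohort(default_generator_config(300, seed = 8))
  Y <- trajmix:::trait_matrix(g$cohort, design)
  v <- Y[!is.na(Y)]
  expect_true(all(v == round(v)))
  expect_true(all(Y[, 1:8] >= 0 & Y[, 1:8] <= 10, na.rm = TRUE))
  expect_true(all(Y[, 9:13] >= 0 & Y[, 9:13] <= 24, na.rm = TRUE))
})

test_that("class frequencies respect the binomial sampling bound", {
  p <- tiny_params()
  cfg <- generator_config(10000, c(0.5, 0.5),
                          list(p$alpha[1, ], p$alpha[2, ]),
                          factor_covariance = p$Psi,
                          residual_variances = p$theta, seed = 77)
  g <- generate_cohort(cfg)
  f1 <- mean(g$truth$labels == 1)
  expect_lt(abs(f1 - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("latent class mean curves match the loading-weighted means", {
  cfg <- default_generator_config(6000, seed = 10, missingness = FALSE)
  cfg$round_scores <- FALSE
  g <- generate_cohort(cfg)
  Y <- trajmix:::trait_matrix(g$cohort, design)
  Mu <- design$Lambda %*% t(do.call(rbind, cfg$class_growth_means))
  k <- 1  # majority class has plenty of subjects for a tight bound
  emp <- colMeans(Y[g$truth$labels == k, ])
  se <- sqrt(diag(trajmix:::full_sigma(g$truth$params, design))) /
    sqrt(sum(g$truth$labels == k))
  expect_true(all(abs(emp - Mu[, k]) < 4 * se))
})

test_that("minority mean curves cross the screening cut-points as configured", {
  cfg <- default_generator_config(10)
  Mu <- design$Lambda %*% t(do.call(rbind, cfg$class_growth_means))
  a_child <- 1:7   # waves up to the knot
  s_child <- 9:11
  # majority stays below both cut-points everywhere
  expect_true(all(Mu[1:8, 1] < 6) && all(Mu[9:13, 1] < 9))
  # declining class: above in childhood, below by the knot
  expect_gt(Mu[1, 2], 6)
  expect_lt(Mu[7, 2], 6)
  expect_gt(Mu[9, 2], 9)
  expect_lt(Mu[12, 2], 9)
  # late-emerging class: below in childhood, above by the knot
  expect_lt(Mu[1, 3], 6)
  expect_gt(Mu[7, 3], 6)
  expect_lt(Mu[9, 3], 9)
  expect_gt(Mu[12, 3], 9)
})

test_that("missingness rates follow the configured probabilities", {
  p <- tiny_params()
  cfg <- generator_config(5000, 1, list(p$alpha[1, ]),
                          factor_covariance = p$Psi,
                          residual_variances = p$theta,
                          missingness = list(prob = 0.2,
                                             class_multiplier = 1),
                          seed = 12)
  g <- generate_cohort(cfg)
  Y <- trajmix:::trait_matrix(g$cohort, design)
  total_cells <- 5000 * 13
  frac <- (sum(is.na(Y)) + attr(g$cohort, "n_dropped") * 13) / total_cells
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.16 / total_cells))
})

test_that("missingness edge cases behave as documented", {
  p <- tiny_params()
  cfg0 <- generator_config(50, 1, list(p$alpha[1, ]),
                           factor_covariance = p$Psi,
                           residual_variances = p$theta, seed = 13)
  complete <- generate_cohort(cfg0)$cohort
  # zero probability: output identical to input
  cfg0$missingness <- list(prob = 0, class_multiplier = 1, monotone = FALSE)
  out <- apply_missingness(complete, cfg0, seed = 4)
  expect_equal(as.data.frame(out)[, design$waves],
               as.data.frame(complete)[, design$waves])
  # probability one: everyone dropped
  cfg0$missingness <- list(prob = 1, class_multiplier = 1, monotone = FALSE)
  out1 <- apply_missingness(complete, cfg0, seed = 4)
  expect_equal(nrow(out1), 0)
  expect_equal(attr(out1, "n_dropped"), 50)
  expect_error({
    cfg0$missingness$prob <- 1.2
    generator_config(50, 1, list(p$alpha[1, ]),
                     factor_covariance = p$Psi,
                     residual_variances = p$theta,
                     missingness = cfg0$missingness)
  }, "\\[0, 1\\]")
})

test_that("monotone attrition produces dropout-shaped missingness", {
  cfg <- default_generator_config(400, seed = 31)
  g <- generate_cohort(cfg)
  Y <- trajmix:::trait_matrix(g$cohort, design)
  ages <- c(4, 7, 8, 9, 12, 13, 17, 25, 7, 10, 13, 17, 25)
  ok <- vapply(seq_len(nrow(Y)), function(i) {
    gone <- is.na(Y[i, ])
    !any(gone) || all(gone[ages >= min(ages[gone])])
  }, TRUE)
  expect_true(all(ok))
})

test_that("auxiliary variables follow their class-conditional laws", {
  labels <- rep(1:2, c(300, 300))
  aux <- generate_auxiliaries(labels,
                              list(ind2 = list(type = "binary", prob = c(0, 1))),
                              seed = 3)
  expect_equal(aux$ind2, as.integer(labels == 2))
  labels3 <- rep(1:3, c(4000, 500, 500))
  aux3 <- generate_auxiliaries(labels3,
                               list(pgs = list(type = "continuous",
                                               mean = c(0, 0.14, 0.14))),
                               seed = 9)
  m2 <- mean(aux3$pgs[labels3 == 2])
  expect_lt(abs(m2 - 0.14), 3 / sqrt(500))
  lab5050 <- rep(1:2, each = 2500)
  auxb <- generate_auxiliaries(lab5050,
                               list(v = list(type = "binary", prob = c(0.3, 0.6))),
                               seed = 11)
  expect_lt(abs(mean(auxb$v) - 0.45), 3 * sqrt(0.45 * 0.55 / 5000))
})

test_that("posterior simulator hits a requested entropy", {
  pi <- c(0.6, 0.4)
  delta <- calibrate_separation(0.7, pi)
  labs <- trajmix:::with_seed(99, sample.int(2, 4000, replace = TRUE, prob = pi))
  post <- simulate_posteriors(labs, delta, pi = pi, seed = 123)
  expect_lt(abs(relative_entropy(post) - 0.7), 0.05)
  expect_equal(rowSums(post), rep(1, 4000), tolerance = 1e-12)
})
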