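test_that("modal assignment takes the argmax with documented tie-breaking", {
  post <- rbind(c(0.2, 0.5, 0.3), c(0.5, 0.5, 0), c(1, 0, 0))
  lab <- modal_assignment(post)
  expect_equal(as.integer(lab), c(2, 1, 1))
  expect_equal(attr(lab, "n_ties"), 1)
})

test_that("classification-error matrix matches hand computation", {
  post <- rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.3, 0.7), c(0.2, 0.8))
  cem <- classification_error_matrix(post)
  expect_equal(cem$Q[1, 1], 1.7 / 2.2, tolerance = 1e-12)
  expect_equal(cem$Q[2, 1], 0.5 / 2.2, tolerance = 1e-12)
  expect_equal(cem$Q[1, 2], 0.3 / 1.8, tolerance = 1e-12)
  expect_equal(colSums(cem$Q), c(1, 1), tolerance = 1e-12)
  # perfect posteriors give the identity
  hard <- diag(2)[c(1, 1, 2, 2), ]
  expect_equal(classification_error_matrix(hard)$Q, diag(2))
})

test_that("three-step regression with identity error equals plain multinomial", {
  # 2x2 table closed form: exposure 30/100 in class 1, 60/100 in class 2
  labels <- rep(c(1, 2), each = 100)
  x <- c(rep(1, 30), rep(0, 70), rep(1, 60), rep(0, 40))
  res <- threestep_multinomial(labels, diag(2), x)
  expect_equal(res$OR[1], (60 / 40) / (30 / 70), tolerance = 1e-4)
  # and for K = 3 it agrees with an established multinomial fitter
  skip_if_not_installed("nnet")
  set.seed(42)
  n <- 900
  xx <- rnorm(n)
  lp2 <- -1 + 0.8 * xx
  lp3 <- -1.5 + 0.4 * xx
  den <- 1 + exp(lp2) + exp(lp3)
  u <- runif(n)
  p2 <- exp(lp2) / den
  p3 <- exp(lp3) / den
  cls <- ifelse(u < p2, 2L, ifelse(u < p2 + p3, 3L, 1L))
  res3 <- threestep_multinomial(cls, diag(3), xx)
  mfit <- nnet::multinom(factor(cls) ~ xx, trace = FALSE)
  co <- coef(mfit)
  expect_equal(res3$log_odds[res3$class == 2 & res3$reference == 1],
               unname(co["2", "xx"]), tolerance = 1e-3)
  expect_equal(res3$log_odds[res3$class == 3 & res3$reference == 1],
               unname(co["3", "xx"]), tolerance = 1e-3)
})

test_that("a covariate unrelated to class gives OR near 1", {
  set.seed(7)
  labels <- sample(1:2, 2000, replace = TRUE, prob = c(0.7, 0.3))
  x <- rbinom(2000, 1, 0.4)
  res <- threestep_multinomial(labels, diag(2), x)
  expect_lt(abs(res$log_odds[1]), 0.35)
  expect_gt(res$p[1], 0.001)
})

test_that("BCH weights follow the inverse error matrix algebra", {
  Q <- rbind(c(0.9, 0.2), c(0.1, 0.8))
  w <- bch_weights(c(1, 2, 1), Q)
  expect_equal(w$Qinv, rbind(c(8 / 7, -2 / 7), c(-1 / 7, 9 / 7)),
               tolerance = 1e-12)
  expect_equal(rowSums(w$W), rep(1, 3), tolerance = 1e-12)
  # identity error: one-hot indicators
  wI <- bch_weights(c(1, 2, 2), diag(2))
  expect_equal(wI$W, rbind(c(1, 0), c(0, 1), c(0, 1)))
  # near-singular Q refused
  Qbad <- rbind(c(0.51, 0.5), c(0.49, 0.5))
  expect_error(bch_weights(c(1, 2), Qbad, max_condition = 100), "singular")
})

test_that("BCH distal means reduce to per-label means under identity error", {
  set.seed(11)
  labels <- sample(1:3, 300, replace = TRUE)
  y <- rnorm(300, mean = labels)
  w <- bch_weights(labels, diag(3))
  res <- bch_distal(w, y)
  expect_equal(res$means$mean, as.numeric(tapply(y, labels, mean)),
               tolerance = 1e-12)
  # constant outcome: all means equal, Wald statistic zero
  res0 <- bch_distal(w, rep(2.5, 300))
  expect_equal(res0$means$mean, rep(2.5, 3), tolerance = 1e-12)
  expect_true(is.na(res0$wald$statistic) || res0$wald$statistic < 1e-8)
})

test_that("the Wald equality test is invariant to class relabelling", {
  set.seed(13)
  labels <- sample(1:3, 500, replace = TRUE)
  post <- simulate_posteriors(labels, 2.2, seed = 4)
  lab <- modal_assignment(post)
  Q <- classification_error_matrix(post, lab)$Q
  y <- rnorm(500, mean = c(0, 0.3, 0.6)[labels])
  w1 <- bch_weights(lab, Q)
  s1 <- bch_distal(w1, y)$wald$statistic
  # relabel classes consistently: new label j corresponds to old label inv[j]
  perm <- c(3, 1, 2)
  inv <- order(perm)
  lab2 <- perm[lab]
  Q2 <- Q[inv, inv]
  w2 <- bch_weights(lab2, Q2)
  s2 <- bch_distal(w2, y)$wald$statistic
  expect_equal(s1, s2, tolerance = 1e-8)
})

test_that("posterior-weighted proportions reduce to per-class rates when classes are certain", {
  set.seed(17)
  labels <- sample(1:2, 400, replace = TRUE)
  post <- diag(2)[labels, ]
  y <- rbinom(400, 1, c(0.2, 0.5)[labels])
  res <- dcat_proportions(post, y)
  expect_equal(res$proportions$proportion,
               as.numeric(tapply(y, labels, mean)), tolerance = 1e-5)
  # constant outcome is flagged
  resc <- dcat_proportions(post, rep(1, 400))
  expect_gt(length(resc$flag), 0)
})
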