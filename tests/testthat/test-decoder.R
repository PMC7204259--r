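test_that("regression recovers exact linear relations", {
  set.seed(1)
  M <- matrix(runif(100 * 3), 100, 3)
  a0 <- c(0.3, -0.2); A <- matrix(c(1.5, -0.7, 0.2, 0.1, 0.9, -1.1), 3, 2)
  Y <- sweep(M %*% A, 2, a0, "+")
  fit <- fit_regression(M, Y)
  expect_equal(unname(fit$a0), a0, tolerance = 1e-9)
  expect_equal(unname(fit$A), unname(A), tolerance = 1e-9)
  expect_equal(unname(fit$residual_scale), c(0, 0), tolerance = 1e-9)
})

test_that("constant targets give a pure bias, and the toy normal equations hold", {
  set.seed(2)
  M <- matrix(runif(50 * 2), 50, 2)
  fit <- fit_regression(M, matrix(3.5, 50, 1))
  expect_equal(unname(fit$a0), 3.5, tolerance = 1e-9)
  expect_equal(unname(fit$A), matrix(0, 2, 1), tolerance = 1e-9)
  # hand-solved: u = 1 + 2 m
  toy <- fit_regression(cbind(c(0, 1, 2)), cbind(c(1, 3, 5)))
  expect_equal(unname(toy$a0), 1, tolerance = 1e-12)
  expect_equal(unname(toy$A), matrix(2), tolerance = 1e-12)
})

test_that("rank-deficient designs warn and fall back to the minimum-norm fit", {
  M <- cbind(1:10, 1:10)  # duplicated regressor
  expect_warning(fit <- fit_regression(M, cbind(2 * (1:10))), "rank-deficient")
  pred <- cbind(1, M) %*% rbind(fit$a0, fit$A)
  expect_equal(as.numeric(pred), 2 * (1:10), tolerance = 1e-6)
})

# a small fitted decoder shared by the prediction tests
fit_tiny_decoder <- function(seed = 3, snr_db = Inf, ...) {
  sess <- tiny_session(seed = seed, snr_db = snr_db, n_max = 1, n_reps = 2, ...)
  prep <- preprocess_session(sess, zero_phase = TRUE)
  S <- extract_synergies_separate(prep$trials[[1]]$E, prep$trials[[2]]$E,
                                  4, 1, hals_config(seed = seed))
  list(model = fit_decoder(S, prep$trials[[1]], prep$trials[[2]]),
       prep = prep, sess = sess)
}

test_that("angle prediction is affine in the activations", {
  td <- fit_tiny_decoder()
  model <- td$model
  set.seed(4)
  M1 <- matrix(runif(30 * 5), 30, 5)
  M2 <- matrix(runif(30 * 5), 30, 5)
  al <- 0.3
  mix <- predict_angles(al * M1 + (1 - al) * M2, model)
  lin <- al * predict_angles(M1, model) + (1 - al) * predict_angles(M2, model)
  # affine in sum/diff space and the inverse transform is linear, so angles mix too
  expect_equal(mix, lin, tolerance = 1e-9)
  # zero activations give the constant bias angle
  z <- predict_angles(matrix(0, 5, 5), model)
  u0 <- unname(model$a0[1]); v0 <- unname(model$a0[2])
  expect_equal(unname(z[1, ]),
               c(model$norm_constants[["max_x"]] * (u0 + v0) / 2,
                 model$norm_constants[["max_y"]] * (u0 - v0) / 2),
               tolerance = 1e-12)
  expect_error(predict_angles(matrix(0, 5, 3), model), "expects")
})

test_that("training fit is at least as good as held-out fit", {
  sess <- tiny_session(seed = 5, snr_db = 15, n_max = 2, n_reps = 2)
  prep <- preprocess_session(sess, zero_phase = TRUE)
  S <- extract_synergies_separate(prep$trials[[1]]$E, prep$trials[[3]]$E,
                                  4, 1, hals_config(seed = 5))
  model <- fit_decoder(S, prep$trials[[1]], prep$trials[[3]])
  r_of <- function(tr) {
    ah <- predict_angles(project_activations(tr$E, S), model)
    mean(c(pearson_r(ah[, 1], tr$angles[, 1]),
           pearson_r(ah[, 2], tr$angles[, 2])))
  }
  expect_gte(r_of(prep$trials[[1]]), r_of(prep$trials[[2]]) - 1e-9)
})

test_that("grip-force calibration maps the training peak to one and is linear", {
  td <- fit_tiny_decoder()
  model <- td$model
  M_g <- project_activations(td$prep$trials[[2]]$E, model$synergies)
  est <- estimate_grip_force(M_g, model)
  expect_equal(max(est), 1, tolerance = 1e-9)
  expect_equal(estimate_grip_force(matrix(0, 4, 5), model), rep(0, 4))
})

test_that("quarter-force plateaus decode near one quarter of maximum", {
  sess <- tiny_session(seed = 6, snr_db = 20, n_max = 1, n_reps = 2,
                       extra = "force_quarter")
  prep <- preprocess_session(sess, zero_phase = TRUE)
  S <- extract_synergies_separate(prep$trials[[1]]$E, prep$trials[[2]]$E,
                                  4, 1, hals_config(seed = 6))
  model <- fit_decoder(S, prep$trials[[1]], prep$trials[[2]])
  trq <- prep$trials[[3]]
  est <- estimate_grip_force(project_activations(trq$E, S), model)
  plateau <- which(abs(trq$force - 0.25) < 1e-6)
  expect_gt(length(plateau), 10)
  expect_lt(abs(mean(est[plateau]) - 0.25), 0.1)
})

test_that("regression coefficients are recovered within their standard errors", {
  # repeated noisy fits: ~95% of coefficients should land within 3 SE
  set.seed(20)
  hits <- 0L; total <- 0L
  for (rep_ in 1:20) {
    M <- matrix(runif(120 * 3), 120, 3)
    a0 <- rnorm(1); beta <- rnorm(3)
    y <- a0 + M %*% beta + rnorm(120, sd = 0.3)
    fit <- fit_regression(M, y)
    X <- cbind(1, M)
    sigma2 <- sum((y - X %*% rbind(fit$a0, fit$A))^2) / (120 - 4)
    se <- sqrt(diag(solve(crossprod(X))) * sigma2)
    est <- c(fit$a0, fit$A)
    hits <- hits + sum(abs(est - c(a0, beta)) <= 3 * se)
    total <- total + 4L
  }
  expect_gte(hits / total, 0.95)
})
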