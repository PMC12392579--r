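test_that("abundances initialize uniformly over aligned transcripts", {
  inst <- random_instance(6, 4, seed = 1)
  rho <- initialize_rho(inst$sparse)
  expect_equal(unname(rho), rep(0.25, 4))
  one <- Matrix::sparseMatrix(i = 1, j = 1, x = 1, dims = c(1, 1),
                              dimnames = list("r1", "t1"))
  expect_equal(initialize_rho(one), c(t1 = 1))
  expect_error(initialize_rho(one[0, , drop = FALSE]), "no aligned reads")
})

test_that("the E-step weights compatibilities by abundance and normalizes", {
  X <- Matrix::sparseMatrix(i = c(1, 1), j = c(1, 2), x = c(1, exp(-1)),
                            dims = c(1, 2), dimnames = list("r1",
                                                            c("t1", "t2")))
  a <- e_step(c(t1 = 0.5, t2 = 0.5), X)
  expect_equal(as.numeric(a), c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-9)
  # equal X entries: alpha follows rho exactly
  Xe <- Matrix::sparseMatrix(i = c(1, 1), j = 1:2, x = c(1, 1),
                             dims = c(1, 2),
                             dimnames = list("r1", c("t1", "t2")))
  expect_equal(as.numeric(e_step(c(t1 = 0.9, t2 = 0.1), Xe)), c(0.9, 0.1))
  # single-entry row
  one <- Matrix::sparseMatrix(i = 1, j = 1, x = 0.4, dims = c(1, 1),
                              dimnames = list("r1", "t1"))
  expect_equal(as.numeric(e_step(c(t1 = 1), one)), 1)
})

test_that("the M-step sums fractions and divides by the fixed read total", {
  a <- Matrix::sparseMatrix(i = c(1, 2, 3), j = c(1, 1, 2), x = 1,
                            dims = c(3, 2),
                            dimnames = list(paste0("r", 1:3),
                                            c("t1", "t2")))
  est <- m_step(a)
  expect_equal(unname(est$rho), c(2 / 3, 1 / 3))
  split <- Matrix::sparseMatrix(i = c(1, 1), j = 1:2, x = c(0.731, 0.269),
                                dims = c(1, 2),
                                dimnames = list("r1", c("t1", "t2")))
  est2 <- m_step(split)
  expect_equal(unname(est2$read_count), c(0.731, 0.269))
  expect_equal(unname(est2$rho), c(0.731, 0.269))
})

test_that("drop zeroes below-threshold entries but never empties a row", {
  X <- Matrix::sparseMatrix(i = c(1, 1), j = 1:2, x = c(1, exp(-1)),
                            dims = c(1, 2),
                            dimnames = list("r1", c("t1", "t2")))
  a <- e_step(initialize_rho(X), X)  # (0.731, 0.269)
  Xd <- drop_compatibilities(a, X, drop_fraction = 0.1)  # tau' = 0.55
  expect_equal(as.numeric(Xd["r1", ]), c(1, 0))

  # all entries tied below tau': guard retains exactly the lowest index
  Xu <- Matrix::sparseMatrix(i = rep(1, 3), j = 1:3, x = 1,
                             dims = c(1, 3),
                             dimnames = list("r1", paste0("t", 1:3)))
  au <- e_step(initialize_rho(Xu), Xu)
  Xud <- drop_compatibilities(au, Xu, 0.1)
  expect_equal(as.numeric(Xud["r1", ] > 0), c(1, 0, 0))

  # a sole entry survives even though 1.0 < tau' = 1.1
  Xs <- Matrix::sparseMatrix(i = 1, j = 1, x = 0.7, dims = c(1, 1),
                             dimnames = list("r1", "t1"))
  as_ <- e_step(c(t1 = 1), Xs)
  expect_equal(as.numeric(drop_compatibilities(as_, Xs, 0.1)), 0.7)
})

test_that("dropped entries are absorbing: support never regrows", {
  inst <- random_instance(15, 5, seed = 42)
  fit <- suppressWarnings(run_em(
    inst$sparse, em_config(convergence_threshold = 1e-9,
                           max_iterations = 50)))
  lost <- inst$sparse != 0 & fit$X == 0
  expect_true(all(fit$alpha[methods::as(lost, "lMatrix")] == 0))
  expect_true(all(Matrix::rowSums(fit$X > 0) >= 1))
})

test_that("uniquely aligned reads converge immediately to exact counts", {
  X <- Matrix::sparseMatrix(i = 1:4, j = c(1, 1, 2, 1), x = 1,
                            dims = c(4, 2),
                            dimnames = list(paste0("r", 1:4),
                                            c("t1", "t2")))
  fit <- run_em(X, em_config(convergence_threshold = 1e-9))
  expect_equal(unname(fit$abundance$read_count), c(3, 1))
  expect_true(fit$converged)
})

test_that("the default absolute threshold ends tiny instances at iteration 1", {
  # 5 reads: the first L1 change equals N = 5 < 10, a reminder that the
  # default threshold is calibrated for experiments with millions of reads
  inst <- random_instance(5, 3, seed = 3)
  fit <- run_em(inst$sparse, em_config())
  expect_equal(fit$iterations, 1L)
  expect_true(fit$converged)
})

test_that("EM matches the naive dense oracle per iteration without drop", {
  for (seed in 1:25) {
    inst <- random_instance(sample(5:20, 1), sample(2:5, 1), seed)
    n_iter <- 15L
    fit <- em_history(inst$sparse, n_iter)
    oracle <- naive_em_history(inst$dense, n_iter)
    for (it in seq_len(min(length(fit$history), n_iter))) {
      expect_equal(unname(fit$history[[it]]$read_count),
                   unname(oracle[[it]]$read_count), tolerance = 1e-10)
      expect_equal(unname(fit$history[[it]]$rho),
                   unname(oracle[[it]]$rho), tolerance = 1e-10)
    }
  }
})

test_that("normalization holds after every E and M step", {
  inst <- random_instance(20, 5, seed = 11)
  fit <- em_history(inst$sparse, 30, drop_enabled = TRUE)
  expect_equal(unname(Matrix::rowSums(fit$alpha)), rep(1, 20),
               tolerance = 1e-9)
  for (h in fit$history) {
    expect_equal(sum(h$rho), 1, tolerance = 1e-9)
    expect_equal(sum(h$read_count), 20, tolerance = 1e-6)
  }
})

test_that("log-likelihood never decreases once drop has fixed X", {
  for (seed in 1:10) {
    inst <- random_instance(12, 4, seed = 100 + seed)
    fit <- em_history(inst$sparse, 40, drop_enabled = TRUE)
    ll <- vapply(fit$history, `[[`, numeric(1), "log_likelihood")
    expect_true(all(diff(ll) >= -1e-8))
  }
})

test_that("hitting the iteration cap warns but still returns estimates", {
  inst <- random_instance(20, 5, seed = 8)
  expect_warning(
    fit <- run_em(inst$sparse, em_config(convergence_threshold = 1e-15,
                                         max_iterations = 3)),
    "iteration cap")
  expect_false(fit$converged)
  expect_equal(fit$iterations, 3L)
})
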