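test_that("the normalized SSE matches hand-evaluated cases", {
  data1 <- expression_set(matrix(c(1, 2), 1), "a", c(0, 1))
  expect_equal(sse(matrix(c(1, 2), 1), data1), 0)
  expect_equal(sse(matrix(c(1, 1), 1), data1), 0.25)

  # scaling a gene's data and model jointly leaves its contribution alone
  data2 <- expression_set(matrix(c(2, 4), 1), "a", c(0, 1))
  expect_equal(sse(matrix(c(2, 2), 1), data2), 0.25)

  zero <- expression_set(matrix(0, 1, 2), "a", c(0, 1))
  expect_error(sse(matrix(0, 1, 2), zero), "all-zero")
})

test_that("sparsity projection floors, caps, and leaves the band alone", {
  K <- matrix(c(0.05, -0.5, 150, -120, 0, 0.1), 2, 3)
  P <- project_sparsity(K)
  expect_equal(P[1, 1], 0)
  expect_equal(P[2, 1], -0.5)
  expect_equal(P[1, 2], 100)
  expect_equal(P[2, 2], -100)
  expect_equal(P[2, 3], 0.1)
})

test_that("initializing at the truth on noise-free data is a rest point", {
  d <- gen_cim_dataset(n_genes = 4, n_edges = 2, noise_sd = 0,
                       n_times = 40, step = 0.5, seed = 21)
  tp <- d$truth$params
  f <- fit_first_cycle(d$data, tp$mask, stages = d$truth$schedule$labels,
                       n_starts = 1, seed = 1,
                       init = list(params = tp, schedule = d$truth$schedule),
                       opts = list(polish_maxit = 0))
  expect_lt(f$sse, 1e-4)
  expect_lt(max(abs(f$params$kr - tp$kr) / tp$kr), 0.01)
  expect_lt(max(abs(f$params$gamma - tp$gamma) / tp$gamma), 0.01)
  expect_lt(max(abs(f$schedule$times - d$truth$schedule$times)), 0.05)
  # stored SSE is the recomputed SSE of the stored fit
  tr <- simulate_cim(f$params, f$schedule, f$rna0, d$data$times)
  expect_lt(abs(f$sse - sse(tr, d$data)), 1e-8)
  # fitted interactions respect the sparsity band
  k <- f$params$K[f$params$K != 0]
  expect_true(all(abs(k) >= 0.1 & abs(k) <= 100))
})

test_that("the same seed reproduces the fit bit for bit", {
  d <- gen_cim_dataset(n_genes = 3, n_edges = 1, noise_sd = 0.02,
                       n_times = 24, step = 1, seed = 31)
  run <- function() fit_first_cycle(
    d$data, d$truth$params$mask, stages = c("G1", "S"), n_starts = 2,
    seed = 5, opts = list(maxiter = 25, polish_maxit = 200))
  f1 <- run()
  f2 <- run()
  expect_identical(f1$sse, f2$sse)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$schedule, f2$schedule)
  expect_identical(f1$per_start_sse, f2$per_start_sse)
})

test_that("best SSE never worsens as starts are added", {
  d <- gen_cim_dataset(n_genes = 3, n_edges = 1, noise_sd = 0.02,
                       n_times = 24, step = 1, seed = 31)
  f1 <- fit_first_cycle(d$data, d$truth$params$mask, stages = c("G1", "S"),
                        n_starts = 1, seed = 5,
                        opts = list(maxiter = 25, polish_maxit = 0))
  f3 <- fit_first_cycle(d$data, d$truth$params$mask, stages = c("G1", "S"),
                        n_starts = 3, seed = 5,
                        opts = list(maxiter = 25, polish_maxit = 0))
  expect_lte(f3$sse, f1$sse + 1e-12)
  expect_equal(f3$per_start_sse[1], f1$per_start_sse[1])
})

test_that("post-division fitting recovers the arrested fraction", {
  set.seed(41)
  sch <- stage_schedule(c("G1", "S"), times = c(7, 15),
                        weights = matrix(runif(12, 0.1, 1), 2, 6),
                        f_g0 = 0.3, t_post = c(20, 24))
  d <- gen_cim_dataset(n_genes = 6, schedule = sch, n_edges = 3,
                       noise_sd = 0.02, n_times = 60, step = 0.5, seed = 41)
  frozen <- list(params = d$truth$params, schedule = d$truth$schedule,
                 rna0 = d$truth$rna0, sse = 0,
                 opts = cimnet:::default_fit_opts())
  class(frozen) <- "cim_fit"
  frozen$schedule$f_g0 <- NA_real_
  frozen$schedule$t_post <- NULL
  before <- unclass(frozen$params)
  f <- fit_post_division(d$data, frozen, n_post = 2, seed = 3)
  expect_lt(abs(f$schedule$f_g0 - 0.3), 0.1)
  expect_identical(unclass(f$params), before)  # freeze contract
  expect_true(all(diff(c(f$schedule$division, f$schedule$t_post)) > 0))
})

test_that("a zero arrested fraction is recovered at the boundary", {
  set.seed(43)
  sch <- stage_schedule(c("G1", "S"), times = c(7, 15),
                        weights = matrix(runif(8, 0.1, 1), 2, 4),
                        f_g0 = 0, t_post = c(20, 24))
  d <- gen_cim_dataset(n_genes = 4, schedule = sch, n_edges = 2,
                       noise_sd = 0.02, n_times = 60, step = 0.5, seed = 43)
  frozen <- list(params = d$truth$params, schedule = d$truth$schedule,
                 rna0 = d$truth$rna0, sse = 0,
                 opts = cimnet:::default_fit_opts())
  class(frozen) <- "cim_fit"
  f <- fit_post_division(d$data, frozen, n_post = 2, seed = 3)
  expect_lte(f$schedule$f_g0, 0.05)
  no_post <- expression_set(d$data$values[, d$data$times <= 15],
                            d$data$gene_ids,
                            d$data$times[d$data$times <= 15])
  expect_error(fit_post_division(no_post, frozen), "no data beyond")
})

test_that("stage durations telescope and flag unreached change points", {
  sch <- stage_schedule(times = c(9.25, 14.43, 17.57, 23.71, 32.43, 40.20),
                        weights = matrix(1, 6, 2),
                        f_g0 = 0.3, t_post = c(49.82, 51.60))
  fake <- structure(list(schedule = sch), class = "cim_fit")
  d <- stage_durations(fake, data_end = 67)
  c1 <- d[d$cycle == 1, ]
  expect_equal(c1$duration, c(9.25, 5.18, 3.14, 6.14, 8.72, 7.77),
               tolerance = 1e-9)
  expect_equal(sum(c1$duration), 40.20)
  c2 <- d[d$cycle == 2, ]
  expect_equal(c2$stage, c("G1", "S1", "S2"))
  expect_equal(c2$duration, c(9.62, 1.78, 15.40), tolerance = 1e-9)
  expect_identical(c2$lower_bound, c(FALSE, FALSE, TRUE))
})
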