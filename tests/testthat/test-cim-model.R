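make_schedule <- function(n_genes = 3) {
  stage_schedule(labels = c("G1", "S1", "S2", "S3", "G2", "M"),
                 times = c(9.25, 14.43, 17.57, 23.71, 32.43, 40.20),
                 weights = matrix(runif(6 * n_genes, 0.1, 1), 6, n_genes))
}

test_that("stage lookup follows the left-closed boundary convention", {
  set.seed(1)
  sch <- make_schedule()
  expect_equal(stage_weights(0, sch), sch$weights[1, ], ignore_attr = TRUE)
  # exactly at the first transition the later stage applies
  expect_equal(stage_weights(9.25, sch), sch$weights[2, ],
               ignore_attr = TRUE)
  expect_equal(stage_weights(35, sch), sch$weights[6, ],
               ignore_attr = TRUE)
  expect_equal(stage_weights(40.20, sch), sch$weights[6, ],
               ignore_attr = TRUE)
  expect_error(stage_weights(45, sch), "outside the modeled span")
  expect_error(stage_weights(-1, sch), "outside the modeled span")
})

test_that("schedule weights are normalized per stage and validated", {
  sch <- stage_schedule(c("A", "B"), times = c(5, 10),
                        weights = rbind(c(2, 4), c(0.1, 0.05)))
  expect_equal(sch$weights, rbind(c(0.5, 1), c(1, 0.5)))
  expect_error(stage_schedule("A", times = 5, weights = matrix(-1, 1, 1)),
               "nonnegative")
  expect_error(stage_schedule(c("A", "B"), times = c(5, 4),
                              weights = matrix(1, 2, 1)),
               "strictly increasing")
  expect_error(stage_schedule("A", times = 5, weights = matrix(1, 1, 1),
                              f_g0 = 1.5), "f_g0")
})

test_that("matching and proportional laws evaluate as defined", {
  cv <- control_variables(w = 1, kr = 2, g = 3)
  expect_equal(cv$u, 1)
  expect_equal(cv$v, 1)

  cv2 <- control_variables(w = c(1, 1), kr = c(2, 1), g = c(1, 1))
  expect_equal(cv2$v, c(1, 0.5))
  expect_equal(cv2$u, c(2 / 3, 1 / 3))

  cv0 <- control_variables(w = c(0, 0), kr = c(1, 1), g = c(1, 1))
  expect_equal(cv0$u, c(0, 0))
  expect_equal(cv0$v, c(0, 0))
  expect_error(control_variables(-1, 1, 1), "nonnegative")
})

test_that("the uncoupled single-gene fixed point is a rest state", {
  fx <- single_gene_fixture()
  state <- c(fx$rna_star, fx$g_star)
  dv <- cim_rhs(1, state, fx$params, fx$schedule)[[1]]
  expect_equal(dv, c(0, 0), tolerance = 1e-12)

  # zero state: priming alpha is the only flux
  dv0 <- cim_rhs(1, c(0, 0), fx$params, fx$schedule)[[1]]
  expect_equal(dv0, c(0, fx$params$alpha))
})

test_that("repressive drive is clamped at the basal priming rate", {
  K <- matrix(c(0, -5, 0, 0), 2, 2)  # gene1 represses gene2's regulator
  params <- cim_parameters(kr = c(1, 1), gamma = c(0.5, 0.5),
                           g0 = c(1, 1), alpha = 0.4, beta = 0.2, K = K)
  sch <- stage_schedule("G1", times = 10, weights = matrix(1, 1, 2))
  dv <- cim_rhs(0, c(2, 2, 1, 1), params, sch)[[1]]
  # dg2 = alpha + u2 * max(-10, 0) - beta * g2 = alpha - beta
  expect_equal(dv[4], 0.4 - 0.2 * 1)
})

test_that("simulation holds the closed-form steady state", {
  fx <- single_gene_fixture()
  tr <- simulate_cim(fx$params, fx$schedule, rna0 = fx$rna_star,
                     t_grid = seq(0, 20, 0.5))
  expect_lt(max(abs(tr$rna - fx$rna_star)) / fx$rna_star, 1e-6)
  expect_lt(max(abs(tr$g - fx$g_star)) / fx$g_star, 1e-6)
})

test_that("control-law normalization and positivity hold along trajectories", {
  for (seed in 1:3) {
    d <- gen_cim_dataset(n_genes = 5, n_edges = 3, noise_sd = 0,
                         n_times = 40, step = 0.5, seed = seed)
    tr <- d$traj
    drive <- colSums(tr$v)  # nonzero drive iff some v > 0
    on <- drive > 1e-12
    expect_true(all(abs(colSums(tr$u)[on] - 1) < 1e-9))
    expect_true(all(abs(apply(tr$v, 2, max)[on] - 1) < 1e-9))
    expect_true(all(tr$rna >= 0))
    gmin <- pmin(d$truth$params$g0,
                 d$truth$params$alpha / d$truth$params$beta)
    expect_true(all(tr$g >= gmin - 1e-7))
  }
})

test_that("trajectories are invariant to per-stage weight rescaling", {
  set.seed(3)
  W <- matrix(runif(8, 0.2, 1), 2, 4)
  p <- cim_parameters(kr = runif(4, 0.5, 2), gamma = runif(4, 0.2, 1),
                      g0 = runif(4, 0.5, 2), alpha = 0.5, beta = 0.4,
                      K = matrix(0, 4, 4))
  s1 <- stage_schedule(c("A", "B"), c(6, 12), W)
  s2 <- stage_schedule(c("A", "B"), c(6, 12), W * c(3, 0.25))
  grid <- seq(0, 12, 0.5)
  t1 <- simulate_cim(p, s1, rep(1, 4), grid)
  t2 <- simulate_cim(p, s2, rep(1, 4), grid)
  expect_equal(t1$rna, t2$rna, tolerance = 1e-10)
})

test_that("halving solver tolerances barely moves the solution", {
  d <- gen_cim_dataset(n_genes = 4, n_edges = 2, noise_sd = 0,
                       n_times = 30, step = 1, seed = 4)
  tr2 <- simulate_cim(d$truth$params, d$truth$schedule, d$truth$rna0,
                      d$data$times, rtol = 5e-7, atol = 5e-10)
  rel <- max(abs(tr2$rna - d$traj$rna)) / max(d$traj$rna)
  expect_lt(rel, 1e-4)
})

test_that("post-division mixture interpolates between its branches", {
  base <- gen_cim_dataset(n_genes = 4, n_edges = 2, noise_sd = 0,
                          n_times = 20, step = 1, seed = 8)
  span <- 19
  sch <- base$truth$schedule
  sch$times <- c(7, 12)
  sch$division <- 12
  grid <- seq(0, span, 1)
  run <- function(f) {
    s <- sch; s$f_g0 <- f; s$t_post <- c(15, 17)
    simulate_cim(base$truth$params, s, base$truth$rna0, grid,
                 mode = "post_division")
  }
  m0 <- run(0); m1 <- run(1); mh <- run(0.25)
  post <- m0$times > 12
  bcols <- function(m, br) m$branches[[br]]$rna[
    , m$branches[[br]]$times %in% m$times[post], drop = FALSE]
  expect_equal(m0$rna[, post], bcols(m0, "cycle2"),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(m1$rna[, post], bcols(m1, "g0"),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(mh$rna[, post],
               0.25 * m1$rna[, post] + 0.75 * m0$rna[, post],
               tolerance = 1e-8)
})

test_that("repeating the stage pattern converges to a periodic orbit", {
  for (seed in c(2, 5)) {
    d <- gen_cim_dataset(n_genes = 4, n_edges = 2, noise_sd = 0,
                         n_times = 25, step = 1, seed = seed)
    period <- d$truth$schedule$division
    grid <- seq(0, 3 * period, by = period / 24)
    tr <- simulate_cim(d$truth$params, d$truth$schedule, d$truth$rna0,
                       grid, mode = "cyclic")
    per_cols <- function(k) which(tr$times >= (k - 1) * period - 1e-9 &
                                    tr$times <= k * period + 1e-9)
    amp <- max(tr$rna)
    d12 <- max(abs(tr$rna[, per_cols(1)] - tr$rna[, per_cols(2)])) / amp
    d23 <- max(abs(tr$rna[, per_cols(2)] - tr$rna[, per_cols(3)])) / amp
    expect_lt(d23, d12 + 1e-12)
  }
})

test_that("MRER reduces to closed forms on degenerate inputs", {
  fx <- single_gene_fixture()
  tr <- simulate_cim(fx$params, fx$schedule, fx$rna_star, seq(0, 20, 1))
  m <- mrer(tr, fx$params)
  expect_equal(unname(m$overall), fx$params$kr * fx$g_star,
               tolerance = 1e-6)

  # a gene with zero weight in every stage never transcribes
  p2 <- cim_parameters(kr = c(1, 1), gamma = c(0.5, 0.5), g0 = c(1, 1),
                       alpha = 0.5, beta = 0.5, K = matrix(0, 2, 2))
  s2 <- stage_schedule(c("A", "B"), c(5, 10), rbind(c(1, 0), c(1, 0)))
  tr2 <- simulate_cim(p2, s2, c(1, 1), seq(0, 10, 0.5))
  m2 <- mrer(tr2, p2)
  expect_equal(unname(m2$overall[2]), 0)
  # overall is the max over stage-specific values
  expect_equal(apply(m2$per_stage, 2, max), m2$overall)
})
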