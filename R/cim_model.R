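#' Parameters of the cybernetic transcription-regulation model
#'
#' The model couples, for each gene j, the measured transcript RNA_j and a
#' lumped latent "regulator of gene expression" g_j (aggregating
#' transcription factors, chromatin state, and other unmeasured layers):
#'
#'   dRNA_j/dt = v_j k_j^r g_j - gamma_j RNA_j
#'   dg_j/dt   = alpha + u_j max(sum_i k_{i,j}^g RNA_i, 0) - beta g_j
#'
#' `k_j^r` is the expression rate constant (1/h), `gamma_j` the transcript
#' degradation rate (1/h), `alpha`/`beta` shared basal priming and priming
#' decay rates, and `K[i, j] = k_{i,j}^g` the signed interaction strength of
#' source transcript i on the regulator of target j. The control variables
#' u (matching law) and v (proportional law) come from
#' [control_variables()]. Interactions are restricted to a boolean mask
#' (typically the TDMI network).
#'
#' @param kr,gamma,g0 positive numeric vectors (one per gene): expression
#'   rate constants, degradation rates, initial regulator levels.
#' @param alpha,beta positive scalars: basal priming rate and priming decay.
#' @param K numeric interaction matrix, rows = source RNA, columns = target
#'   regulator.
#' @param mask logical matrix of allowed interactions; entries outside the
#'   mask must be exactly zero. Default: nonzero pattern of `K`.
#' @param gene_ids optional gene identifiers.
#' @return Object of class `cim_parameters`.
#' @export
cim_parameters <- function(kr, gamma, g0, alpha, beta, K, mask = NULL,
                           gene_ids = NULL) {
  n <- length(kr)
  stopifnot(length(gamma) == n, length(g0) == n)
  K <- as.matrix(K)
  if (!all(dim(K) == c(n, n))) stop("K must be ", n, " x ", n)
  if (is.null(mask)) mask <- K != 0
  mask <- as.matrix(mask)
  if (any(K[!mask] != 0)) stop("K has nonzero entries outside the mask")
  if (any(kr <= 0) || any(gamma <= 0) || any(g0 <= 0) || alpha <= 0 ||
      beta <= 0)
    stop("all rate constants and initial regulator levels must be positive")
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(n))
  structure(list(kr = as.numeric(kr), gamma = as.numeric(gamma),
                 g0 = as.numeric(g0), alpha = alpha, beta = beta,
                 K = K, mask = mask, gene_ids = as.character(gene_ids)),
            class = "cim_parameters")
}

#' Stage schedule: piecewise-constant objectives over the cell cycle
#'
#' Each stage k carries a weight vector w_k (one weight per gene) defining
#' the stage objective "maximize sum_j w_{k,j} k_j^r g_j". Stage k applies
#' on the half-open interval [t_{k-1}, t_k) with t_0 = 0; the first stage
#' includes t = 0 and the last includes the division time t_K. Because the
#' control laws are invariant to a per-stage rescaling of the weights, each
#' stage's weights are normalized to maximum 1. After division a fraction
#' `f_g0` of the population arrests in G0 (same objective as G1) while the
#' remainder enters a second cycle with transition times `t_post`.
#'
#' @param labels ordered character stage labels (default
#'   `c("G1","S1","S2","S3","G2","M")`).
#' @param times strictly increasing transition times t_1 < ... < t_K in
#'   hours; the last is the division time.
#' @param weights nonnegative stage-by-gene matrix; each row is rescaled to
#'   max 1.
#' @param f_g0 post-division G0 fraction in \[0, 1\] (optional, `NA` if the
#'   model stops at division).
#' @param t_post numeric vector of second-cycle transition times
#'   (t_{K+1}, t_{K+2}, ...), strictly increasing and > division time.
#' @return Object of class `stage_schedule`.
#' @export
stage_schedule <- function(labels = c("G1", "S1", "S2", "S3", "G2", "M"),
                           times, weights, f_g0 = NA_real_, t_post = NULL) {
  labels <- as.character(labels)
  times <- as.numeric(times)
  weights <- as.matrix(weights)
  if (!length(labels)) stop("stage labels must be a nonempty ordered list")
  if (length(times) != length(labels))
    stop("need one transition time per stage (the last is division)")
  if (any(diff(c(0, times)) <= 0))
    stop("transition times must be strictly increasing and positive")
  if (nrow(weights) != length(labels))
    stop("weights must have one row per stage")
  if (any(weights < 0)) stop("weights must be nonnegative")
  rmax <- apply(weights, 1, max)
  if (any(rmax <= 0)) stop("every stage needs at least one positive weight")
  weights <- weights / rmax
  if (!is.na(f_g0) && (f_g0 < 0 || f_g0 > 1)) stop("f_g0 must be in [0, 1]")
  if (!is.null(t_post)) {
    t_post <- as.numeric(t_post)
    if (any(diff(c(times[length(times)], t_post)) <= 0))
      stop("post-division times must be strictly increasing and beyond ",
           "the division time")
  }
  structure(list(labels = labels, times = times, weights = weights,
                 f_g0 = f_g0, t_post = t_post,
                 division = times[length(times)]),
            class = "stage_schedule")
}

#' Stage weight vector at a time point
#'
#' Piecewise-constant lookup with left-closed/right-open stages; t = 0
#' belongs to the first stage and the division time to the last.
#'
#' @param t time in hours, within `[0, division]`.
#' @param schedule a [stage_schedule].
#' @return Named numeric weight vector of the active stage.
#' @export
stage_weights <- function(t, schedule) {
  k <- stage_index(t, schedule)
  setNames(schedule$weights[k, ], colnames(schedule$weights))
}

stage_index <- function(t, schedule) {
  K <- length(schedule$labels)
  if (t < 0 || t > schedule$division + 1e-9)
    stop("t = ", t, " outside the modeled span [0, ", schedule$division, "]")
  min(findInterval(t, schedule$times[-K]) + 1L, K)
}

#' Cybernetic control variables (matching and proportional laws)
#'
#' Solving the stage objective "maximize sum_j w_j k_j^r g_j" for the
#' resource-allocation and activation controls yields the matching law
#' `u_j = w_j k_j^r g_j / sum_i w_i k_i^r g_i` and the proportional law
#' `v_j = w_j k_j^r g_j / max_i w_i k_i^r g_i`. When the total drive is
#' numerically zero (below 1e-12) both are defined as zero vectors: no
#' production preference.
#'
#' @param w,kr,g nonnegative numeric vectors of equal length.
#' @return List with components `u` and `v`.
#' @export
control_variables <- function(w, kr, g) {
  if (any(w < 0) || any(kr < 0) || any(g < 0))
    stop("control inputs must be nonnegative")
  z <- w * kr * g
  m <- max(z)
  if (m < 1e-12)
    return(list(u = numeric(length(z)), v = numeric(length(z))))
  list(u = z / sum(z), v = z / m)
}

#' Time derivatives of the cybernetic ODE system
#'
#' Evaluates the right-hand sides of the RNA and regulator equations at
#' time `t` with the stage weights active at `t`. The priming drive
#' `sum_i k_{i,j}^g RNA_i` is clamped at zero from below so repression can
#' never push priming below the basal rate `alpha`.
#'
#' @param t time (hours).
#' @param state numeric vector `c(RNA, g)` of length `2 n`.
#' @param params a [cim_parameters].
#' @param schedule a [stage_schedule].
#' @return List of derivatives `c(dRNA, dg)` (deSolve convention).
#' @export
cim_rhs <- function(t, state, params, schedule) {
  if (anyNA(state)) stop("NaN in state at t = ", t)
  w <- stage_weights(t, schedule)
  cim_rhs_fixed_w(t, state, params, w)
}

# rhs with a fixed weight vector (weights are constant within a stage
# segment, so simulate() resolves the stage once per segment)
cim_rhs_fixed_w <- function(t, state, params, w) {
  n <- length(params$kr)
  RNA <- state[seq_len(n)]
  g <- state[n + seq_len(n)]
  z <- w * params$kr * g
  m <- max(z)
  if (m < 1e-12) {
    u <- numeric(n)
    v <- numeric(n)
  } else {
    u <- z / sum(z)
    v <- z / m
  }
  drive <- pmax(as.vector(crossprod(params$K, RNA)), 0)
  list(c(v * params$kr * g - params$gamma * RNA,
         params$alpha + u * drive - params$beta * g))
}

# fast right-hand side closure for a fixed weight vector; precomputes the
# per-gene products so the solver-facing function does minimal work
make_rhs <- function(params, w) {
  n <- length(params$kr)
  kr <- params$kr; gamma <- params$gamma
  alpha <- params$alpha; beta <- params$beta
  tK <- t(params$K)
  wkr <- w * kr
  i1 <- seq_len(n); i2 <- n + i1
  zero <- numeric(n)
  function(t, y, p) {
    g <- y[i2]
    z <- wkr * g
    m <- max(z)
    if (m < 1e-12) {
      u <- zero; v <- zero
    } else {
      v <- z / m
      u <- z / sum(z)
    }
    drive <- tK %*% y[i1]
    drive[drive < 0] <- 0
    list(c(v * kr * g - gamma * y[i1], alpha + u * drive - beta * g))
  }
}

# integrate over consecutive segments with per-segment constant weights.
# seg_bounds: sorted vector of segment boundary times covering t_grid;
# weight_at: function(segment midpoint) -> weight vector.
integrate_piecewise <- function(y0, t_grid, seg_bounds, weight_at, params,
                                rtol, atol) {
  n <- length(params$kr)
  grid_key <- round(t_grid, 9)
  out_t <- numeric(0)
  out_y <- NULL
  out_w <- NULL
  state <- y0
  for (s in seq_len(length(seg_bounds) - 1L)) {
    a <- seg_bounds[s]; b <- seg_bounds[s + 1L]
    w <- weight_at((a + b) / 2)
    inside <- t_grid[t_grid > a + 1e-12 & t_grid < b - 1e-12]
    times <- unique(c(a, inside, b))
    sol <- deSolve::ode(y = state, times = times, parms = NULL,
                        func = make_rhs(params, w),
                        method = "lsoda", rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop("ODE solver failure in segment [", a, ", ", b, "] at t = ",
           sol[nrow(sol), 1], "; state = ",
           paste(signif(sol[nrow(sol), -1], 4), collapse = ", "))
    state <- as.numeric(sol[nrow(sol), -1])
    keep <- !is.na(match(round(sol[, 1], 9), grid_key))
    rows <- sol[keep, , drop = FALSE]
    if (nrow(rows)) {
      out_t <- c(out_t, rows[, 1])
      out_y <- rbind(out_y, rows[, -1, drop = FALSE])
      out_w <- rbind(out_w, matrix(w, nrow(rows), n, byrow = TRUE))
    }
  }
  # a grid time on a boundary appears in both segments; keep the later
  # (post-switch) row, matching the left-closed stage convention
  dup <- rev(duplicated(rev(round(out_t, 9))))
  list(times = out_t[!dup],
       y = out_y[!dup, , drop = FALSE],
       w = out_w[!dup, , drop = FALSE],
       final = state)
}

# RNA-only simulation on the cycle-1 window; lean path for the fitting loop
sim_rna_cycle1 <- function(params, schedule, rna0, t_grid, rtol = 1e-6,
                           atol = 1e-9) {
  div <- schedule$division
  bounds <- unique(c(0, schedule$times[schedule$times <= div], div))
  res <- integrate_piecewise(c(rna0, params$g0), t_grid, bounds,
                             function(tm) stage_weights(tm, schedule),
                             params, rtol, atol)
  t(res$y[, seq_along(params$kr), drop = FALSE])
}

#' Simulate the stage-specific cybernetic model
#'
#' Integrates the stiff ODE system with `deSolve::ode` (lsoda; relative
#' tolerance 1e-6, absolute 1e-9 by default), restarting the integration at
#' every stage boundary so weight discontinuities never fall inside a solver
#' step. Three modes:
#'
#' * `"cycle1"`: one cell cycle, t in `[0, division]`.
#' * `"post_division"`: the full span. At the division time the population
#'   splits: a fraction `f_g0` arrests in G0 (G1 objective throughout) and
#'   the rest re-enters the cycle (G1 objective, then transitions at the
#'   schedule's `t_post` times through S1, S2, ...). Both branches inherit
#'   the division-time state unchanged and the observable signal is the
#'   mixture `f_g0 * RNA_G0 + (1 - f_g0) * RNA_cycle2`.
#' * `"cyclic"`: the cycle-1 objective pattern repeated with period equal to
#'   the division time, over any horizon.
#'
#' @param params a [cim_parameters].
#' @param schedule a [stage_schedule].
#' @param rna0 initial RNA levels (typically pinned to the first
#'   measurement).
#' @param t_grid output time grid (hours).
#' @param mode `"cycle1"`, `"post_division"`, or `"cyclic"`.
#' @param rtol,atol solver tolerances.
#' @return Object of class `cim_trajectories`: `times`, matrices `rna`,
#'   `g`, `u`, `v` (gene by time), `stage` labels per time, `branch`, and
#'   for `post_division` the two branch trajectories under `branches`
#'   (elements `g0` and `cycle2`) with the top-level `rna` holding the
#'   mixture.
#' @export
simulate_cim <- function(params, schedule, rna0, t_grid,
                         mode = c("cycle1", "post_division", "cyclic"),
                         rtol = 1e-6, atol = 1e-9) {
  mode <- match.arg(mode)
  n <- length(params$kr)
  stopifnot(length(rna0) == n)
  t_grid <- sort(unique(as.numeric(t_grid)))
  y0 <- c(rna0, params$g0)
  div <- schedule$division

  if (mode == "cycle1") {
    if (max(t_grid) > div + 1e-9) stop("cycle1 grid extends beyond division")
    bounds <- unique(c(0, schedule$times[schedule$times <= div], div))
    res <- integrate_piecewise(y0, t_grid, bounds,
                               function(tm) stage_weights(tm, schedule),
                               params, rtol, atol)
    return(traj_from(res, params, schedule, "cycle1"))
  }

  if (mode == "cyclic") {
    horizon <- max(t_grid)
    starts <- seq(0, horizon, by = div)
    bounds <- sort(unique(c(outer(c(0, schedule$times), starts, "+"))))
    bounds <- c(bounds[bounds < horizon - 1e-12], horizon)
    wrap <- function(tm) stage_weights(tm %% div, schedule)
    res <- integrate_piecewise(y0, t_grid, bounds, wrap, params, rtol, atol)
    return(traj_from(res, params, schedule, "cyclic", stage_fun = function(tt)
      schedule$labels[stage_index(tt %% div, schedule)]))
  }

  # post_division
  if (is.na(schedule$f_g0) || is.null(schedule$t_post))
    stop("post_division mode needs f_g0 and t_post in the schedule")
  horizon <- max(t_grid)
  if (horizon <= div + 1e-9) stop("grid does not extend beyond division")
  pre_grid <- t_grid[t_grid <= div + 1e-9]
  post_grid <- unique(c(div, t_grid[t_grid > div + 1e-9]))
  bounds1 <- unique(c(0, schedule$times[schedule$times <= div], div))
  res1 <- integrate_piecewise(y0, unique(c(pre_grid, div)), bounds1,
                              function(tm) stage_weights(tm, schedule),
                              params, rtol, atol)
  state_div <- res1$final
  # branch G0: G1 objective throughout
  w_g1 <- schedule$weights[1, ]
  res_g0 <- integrate_piecewise(state_div, post_grid, c(div, horizon),
                                function(tm) w_g1, params, rtol, atol)
  # branch cycle 2: G1, then transitions through subsequent stages at t_post
  tp <- schedule$t_post[schedule$t_post < horizon]
  bounds2 <- unique(c(div, tp, horizon))
  stage2_of <- function(tm) {
    k <- findInterval(tm, schedule$t_post) + 1L
    min(k, nrow(schedule$weights))
  }
  res_c2 <- integrate_piecewise(state_div, post_grid, bounds2,
                                function(tm) schedule$weights[stage2_of(tm), ],
                                params, rtol, atol)
  tr1 <- traj_from(res1, params, schedule, "cycle1")
  tr_g0 <- traj_from(res_g0, params, schedule, "G0",
                     stage_fun = function(tt) "G0")
  tr_c2 <- traj_from(res_c2, params, schedule, "cycle2",
                     stage_fun = function(tt)
                       schedule$labels[stage2_of(tt)])
  f <- schedule$f_g0
  post_keep <- tr_g0$times > div + 1e-9
  mix <- f * tr_g0$rna[, post_keep, drop = FALSE] +
    (1 - f) * tr_c2$rna[, post_keep, drop = FALSE]
  times <- c(tr1$times, tr_g0$times[post_keep])
  rna <- cbind(tr1$rna, mix)
  keep <- !duplicated(round(times, 9)) &
    vapply(times, function(tt) any(abs(tt - t_grid) < 1e-9), logical(1))
  structure(list(times = times[keep], rna = rna[, keep, drop = FALSE],
                 g = NULL, u = NULL, v = NULL,
                 stage = NULL, branch = "mixed",
                 branches = list(cycle1 = tr1, g0 = tr_g0, cycle2 = tr_c2),
                 gene_ids = params$gene_ids, schedule = schedule),
            class = "cim_trajectories")
}

# assemble a cim_trajectories from an integrate_piecewise result
traj_from <- function(res, params, schedule, branch, stage_fun = NULL) {
  n <- length(params$kr)
  nt <- length(res$times)
  rna <- t(res$y[, seq_len(n), drop = FALSE])
  g <- t(res$y[, n + seq_len(n), drop = FALSE])
  u <- matrix(0, n, nt)
  v <- matrix(0, n, nt)
  for (i in seq_len(nt)) {
    cv <- control_variables(res$w[i, ], params$kr, g[, i])
    u[, i] <- cv$u
    v[, i] <- cv$v
  }
  if (is.null(stage_fun))
    stage_fun <- function(tt) schedule$labels[stage_index(tt, schedule)]
  rownames(rna) <- rownames(g) <- rownames(u) <- rownames(v) <-
    params$gene_ids
  structure(list(times = res$times, rna = rna, g = g, u = u, v = v,
                 stage = vapply(res$times, stage_fun, character(1)),
                 branch = branch, gene_ids = params$gene_ids,
                 schedule = schedule),
            class = "cim_trajectories")
}

#' @export
print.cim_trajectories <- function(x, ...) {
  cat("cim_trajectories (", x$branch, "): ", length(x$gene_ids),
      " genes, ", length(x$times), " time points\n", sep = "")
  invisible(x)
}

#' Maximal RNA expression rate (MRER)
#'
#' The instantaneous transcription rate of gene j is `v_j k_j^r g_j`; the
#' MRER is its maximum over the trajectory, overall and restricted to each
#' stage. It ranks genes by how strongly the model ever drives their
#' transcription and feeds the network simplification rule.
#'
#' @param traj a `cim_trajectories` with `v` and `g` (a single branch, not
#'   a post-division mixture).
#' @param params the [cim_parameters] used to simulate it.
#' @return List with `overall` (named per-gene vector) and `per_stage`
#'   (stage-by-gene matrix; `NA` for stages absent from the trajectory).
#' @export
mrer <- function(traj, params) {
  if (is.null(traj$v) || is.null(traj$g))
    stop("trajectories lack v/g; compute MRER on a single branch")
  rate <- traj$v * params$kr * traj$g
  overall <- apply(rate, 1, max)
  stages <- unique(traj$stage)
  per_stage <- matrix(NA_real_, length(stages), length(params$gene_ids),
                      dimnames = list(stages, params$gene_ids))
  for (s in stages) {
    cols <- traj$stage == s
    per_stage[s, ] <- apply(rate[, cols, drop = FALSE], 1, max)
  }
  list(overall = setNames(overall, params$gene_ids), per_stage = per_stage)
}
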