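#' Normalized sum of squared errors
#'
#' Residuals are normalized per gene by that gene's maximal measured value,
#' so genes on different expression scales contribute comparably:
#' `SSE = sum_j sum_t ((RNA_j(t) - data_j(t)) / max_t data_j(t))^2`.
#'
#' @param model a `cim_trajectories` evaluated on the data's time stamps, or
#'   a gene-by-time matrix.
#' @param data an [expression_set].
#' @return The SSE (scalar).
#' @export
sse <- function(model, data) {
  m <- if (inherits(model, "cim_trajectories")) model$rna else as.matrix(model)
  if (!all(dim(m) == dim(data$values)))
    stop("model grid does not match the data (", nrow(m), "x", ncol(m),
         " vs ", nrow(data$values), "x", ncol(data$values), ")")
  dmax <- apply(data$values, 1, max)
  if (any(dmax <= 0))
    stop("gene '", data$gene_ids[which(dmax <= 0)[1]],
         "' has all-zero data; cannot normalize")
  sum(((m - data$values) / dmax)^2)
}

#' Sparsity projection of the interaction matrix
#'
#' Interaction strengths below the floor are snapped to exactly zero (only
#' material regulatory edges are kept) and large values are clipped at the
#' cap, giving the sparse signed matrix the network reconstruction reads.
#'
#' @param K interaction matrix.
#' @param floor zero-snap threshold on |k| (default 0.1).
#' @param cap clip bound on |k| (default 100).
#' @return The projected matrix.
#' @export
project_sparsity <- function(K, floor = 0.1, cap = 100) {
  K[abs(K) < floor] <- 0
  K[K > cap] <- cap
  K[K < -cap] <- -cap
  K
}

# interaction mask (allowed K entries) from a causal network:
# edge from -> to allows K[from, to] (source RNA regulates target's regulator)
mask_from_network <- function(net, gene_ids) {
  n <- length(gene_ids)
  mask <- matrix(FALSE, n, n, dimnames = list(gene_ids, gene_ids))
  if (nrow(net$edges)) {
    i <- match(net$edges$from, gene_ids)
    j <- match(net$edges$to, gene_ids)
    if (anyNA(i) || anyNA(j))
      stop("network nodes not present in the data: ",
           paste(setdiff(c(net$edges$from, net$edges$to), gene_ids),
                 collapse = ", "))
    mask[cbind(i, j)] <- TRUE
  }
  diag(mask) <- FALSE
  mask
}

# ---- parameter packing -----------------------------------------------------

# Positive rates are fitted on the log scale; interaction strengths on the
# raw scale in [-cap, cap]; stage weights raw in [w_floor, 1] (renormalized
# to per-stage max 1 on unpack, which the control laws are invariant to);
# transition times via positive increments mapped onto the span, keeping
# t_1 < ... < t_K = span.
make_packing <- function(gene_ids, mask, n_stages, span, opts) {
  n <- length(gene_ids)
  midx <- which(mask)
  m <- length(midx)
  lrate <- log(opts$rate_bounds)
  lg0 <- log(opts$g0_bounds)
  sizes <- c(kr = n, gamma = n, alpha = 1, beta = 1, g0 = n, K = m,
             w = n_stages * n, d = n_stages)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  slot <- function(name) {
    if (sizes[[name]] == 0L) integer(0) else starts[[name]]:ends[[name]]
  }
  logw <- identical(opts$w_scale, "log")
  w_lo <- if (logw) log(opts$w_floor) else opts$w_floor
  w_hi <- if (logw) 0 else 1
  lower <- c(rep(lrate[1], 2 * n + 2), rep(lg0[1], n), rep(-opts$cap, m),
             rep(w_lo, n_stages * n), rep(opts$min_gap, n_stages))
  upper <- c(rep(lrate[2], 2 * n + 2), rep(lg0[2], n), rep(opts$cap, m),
             rep(w_hi, n_stages * n), rep(span, n_stages))
  unpack <- function(theta) {
    K <- matrix(0, n, n)
    K[midx] <- theta[slot("K")]
    wv <- theta[slot("w")]
    W <- matrix(if (logw) exp(wv) else wv, n_stages, n)
    d <- theta[slot("d")]
    times <- span * cumsum(d) / sum(d)
    params <- cim_parameters(kr = exp(theta[slot("kr")]),
                             gamma = exp(theta[slot("gamma")]),
                             g0 = exp(theta[slot("g0")]),
                             alpha = exp(theta[slot("alpha")]),
                             beta = exp(theta[slot("beta")]),
                             K = K, mask = mask, gene_ids = gene_ids)
    schedule <- stage_schedule(labels = opts$stages, times = times,
                               weights = W)
    list(params = params, schedule = schedule)
  }
  pack <- function(params, schedule) {
    theta <- numeric(ends[["d"]])
    theta[slot("kr")] <- log(params$kr)
    theta[slot("gamma")] <- log(params$gamma)
    theta[slot("alpha")] <- log(params$alpha)
    theta[slot("beta")] <- log(params$beta)
    theta[slot("g0")] <- log(params$g0)
    theta[slot("K")] <- params$K[midx]
    wv <- pmax(as.vector(schedule$weights), opts$w_floor)
    theta[slot("w")] <- if (logw) log(wv) else wv
    theta[slot("d")] <- diff(c(0, schedule$times))
    pmin(pmax(theta, lower), upper)
  }
  list(lower = lower, upper = upper, unpack = unpack, pack = pack,
       slot = slot, mask_idx = midx, n_par = ends[["d"]])
}

default_fit_opts <- function() {
  list(rate_bounds = c(1e-3, 10), g0_bounds = c(1e-3, 10),
       floor = 0.1, cap = 100, w_floor = 1e-3, min_gap = 0.5,
       stages = NULL, maxiter = 150L, outer_iters = 3L,
       polish_maxit = 4000L, epsfcn = 1e-6, w_scale = "raw")
}

#' Fit the cybernetic model to one cell cycle
#'
#' Multistart bounded least squares: for each start, parameters are drawn
#' log-uniformly (rates, regulator levels) or uniformly (interaction
#' strengths, weights, stage increments) within bounds, then refined by
#' alternating box-constrained Levenberg-Marquardt ([minpack.lm::nls.lm])
#' with a bounded Hooke-Jeeves pattern search (the two-optimizer strategy);
#' the sparsity projection runs between passes and the alternation stops
#' when a round improves the SSE by less than 1%. All of `k^r`, `gamma`,
#' `alpha`, `beta`, the
#' masked interaction strengths, `g(0)`, stage weights, and transition times
#' are fitted; initial RNA is pinned to the first measurement, the division
#' time to the end of the supplied window, and the interior transition
#' times are optimized through a monotone increment parameterization.
#'
#' @param data an [expression_set] covering exactly the first cycle (time 0
#'   to division).
#' @param mask a `causal_network` (typically from [build_network()]) or a
#'   logical matrix of allowed interactions.
#' @param stages ordered stage labels for the cycle (e.g. `c("G1", "S")`).
#' @param n_starts number of multistart draws (default 10; the full-scale
#'   analysis uses 100).
#' @param seed master seed; every start draws from its own substream.
#' @param init optional list `(params, schedule)` used as the first start
#'   instead of a random draw.
#' @param opts list overriding entries of the default fitting options:
#'   `rate_bounds`, `g0_bounds`, `floor`, `cap`, `w_floor`, `min_gap`
#'   (hours), `maxiter` (LM iterations per pass), `outer_iters`
#'   (alternation rounds), `polish_maxit` (pattern-search evaluations per
#'   round), `epsfcn` (finite-difference step scale, sized to dominate the
#'   ODE integration error), `w_scale` (`"raw"` or `"log"` weight
#'   parameterization).
#' @return Object of class `cim_fit`: list with `params`
#'   ([cim_parameters], sparsity-projected), `schedule`
#'   ([stage_schedule]), `sse`, `rna0`, `per_start_sse`, `best_start`,
#'   `seed`, and `at_bounds` (names of parameters that ended on a bound).
#' @export
fit_first_cycle <- function(data, mask, stages, n_starts = 10, seed = 1,
                            init = NULL, opts = list()) {
  o <- utils::modifyList(default_fit_opts(), opts)
  o$stages <- stages
  gene_ids <- data$gene_ids
  if (inherits(mask, "causal_network")) mask <- mask_from_network(mask, gene_ids)
  if (!all(gene_ids %in% rownames(mask)) && !is.null(rownames(mask)))
    stop("mask genes do not cover the data genes")
  n <- length(gene_ids)
  span <- max(data$times)
  if (abs(min(data$times)) > 1e-9)
    stop("cycle-1 data must start at time 0")
  pk <- make_packing(gene_ids, mask, length(stages), span, o)
  rna0 <- data$values[, 1]
  dmax <- apply(data$values, 1, max)
  resid_fn <- function(theta) {
    rna <- try({
      up <- pk$unpack(theta)
      sim_rna_cycle1(up$params, up$schedule, rna0, data$times)
    }, silent = TRUE)
    if (inherits(rna, "try-error") || ncol(rna) != ncol(data$values))
      return(rep(1e3, length(data$values)))
    as.vector((rna - data$values) / dmax)
  }
  obj_fn <- function(theta) {
    theta <- pmin(pmax(theta, pk$lower), pk$upper)
    sum(resid_fn(theta)^2)
  }
  draw_start <- function(i) {
    set.seed(substream_seed(seed, paste0("multistart", i)))
    th <- numeric(pk$n_par)
    th[pk$slot("kr")] <- runif(n, log(0.2), log(3))
    th[pk$slot("gamma")] <- runif(n, log(0.1), log(2))
    th[pk$slot("alpha")] <- runif(1, log(0.1), log(2))
    th[pk$slot("beta")] <- runif(1, log(0.1), log(2))
    th[pk$slot("g0")] <- runif(n, log(0.2), log(3))
    m <- length(pk$mask_idx)
    th[pk$slot("K")] <- if (m) sample(c(-1, 1), m, TRUE) *
      exp(runif(m, log(0.5), log(5))) else numeric(0)
    wd <- runif(length(stages) * n, 0.05, 1)
    th[pk$slot("w")] <- if (identical(o$w_scale, "log")) log(wd) else wd
    th[pk$slot("d")] <- runif(length(stages), 0.2 * span, 0.8 * span)
    pmin(pmax(th, pk$lower), pk$upper)
  }
  project_theta <- function(theta) {
    theta[pk$slot("K")] <- as.vector(project_sparsity(theta[pk$slot("K")],
                                                      o$floor, o$cap))
    theta
  }
  # per start: alternate bounded Levenberg-Marquardt with a bounded
  # Hooke-Jeeves pattern search (the direct-search polish), applying the
  # sparsity projection between passes, until the SSE stops improving
  run_start <- function(theta0) {
    theta <- theta0
    best <- Inf
    for (pass in seq_len(o$outer_iters)) {
      # hitting the per-pass iteration cap is routine (the pattern-search
      # pass follows); only that warning is muffled
      lm <- try(withCallingHandlers(
        minpack.lm::nls.lm(
          par = theta, lower = pk$lower, upper = pk$upper, fn = resid_fn,
          control = minpack.lm::nls.lm.control(maxiter = o$maxiter,
                                               epsfcn = o$epsfcn)),
        warning = function(w) {
          if (grepl("maxiter", conditionMessage(w)))
            invokeRestart("muffleWarning")
        }),
        silent = TRUE)
      if (inherits(lm, "try-error")) {
        if (!is.finite(best)) return(list(sse = Inf, error = lm))
        break
      }
      theta <- project_theta(lm$par)
      if (o$polish_maxit > 0) {
        hj <- try(suppressWarnings(pracma::hooke_jeeves(
          theta, obj_fn, lb = pk$lower, ub = pk$upper,
          maxfeval = o$polish_maxit)), silent = TRUE)
        if (!inherits(hj, "try-error") && hj$fmin < obj_fn(theta))
          theta <- project_theta(pmin(pmax(hj$xmin, pk$lower), pk$upper))
      }
      cur <- sum(resid_fn(theta)^2)
      if (cur > 0.99 * best) {
        best <- min(cur, best)
        break
      }
      best <- cur
    }
    theta <- project_theta(theta)
    list(theta = theta, sse = sum(resid_fn(theta)^2))
  }
  starts <- lapply(seq_len(n_starts), function(i) {
    if (i == 1L && !is.null(init)) pk$pack(init$params, init$schedule)
    else draw_start(i)
  })
  results <- lapply(starts, run_start)
  sses <- vapply(results, `[[`, numeric(1), "sse")
  if (all(!is.finite(sses))) {
    msgs <- vapply(results, function(r)
      if (!is.null(r$error)) as.character(r$error) else "non-finite SSE",
      character(1))
    stop("all starts failed:\n", paste(" -", msgs, collapse = "\n"))
  }
  best <- which.min(sses)
  theta <- results[[best]]$theta
  up <- pk$unpack(theta)
  at_lower <- abs(theta - pk$lower) < 1e-8
  at_upper <- abs(theta - pk$upper) < 1e-8
  structure(list(params = up$params, schedule = up$schedule,
                 sse = sses[best], rna0 = rna0,
                 per_start_sse = sses, best_start = best, seed = seed,
                 at_bounds = which(at_lower | at_upper),
                 opts = o),
            class = "cim_fit")
}

#' @export
print.cim_fit <- function(x, ...) {
  cat("cim_fit: ", length(x$params$gene_ids), " genes, ",
      length(x$schedule$labels), " stages, SSE = ", signif(x$sse, 6),
      " (best of ", length(x$per_start_sse), " starts)\n", sep = "")
  invisible(x)
}

#' Fit the post-division G0 fraction and second-cycle transition times
#'
#' All cycle-1 parameters and weights are frozen; only the arrested fraction
#' `f_g0` and the second-cycle transition times (`t_post`, via positive
#' increments past the division time) are optimized against the data beyond
#' division, using the two-branch mixture simulation. The G0 branch uses
#' the G1 weights throughout (`w_G0 = w_G1`).
#'
#' @param data an [expression_set] extending beyond the fitted division
#'   time.
#' @param fitted a `cim_fit` from [fit_first_cycle()].
#' @param n_post number of second-cycle transition times to fit (default 2).
#' @param n_starts,seed multistart control for the small (1 + n_post)-
#'   dimensional search.
#' @param min_gap smallest transition increment, hours.
#' @return The `cim_fit`, augmented: `schedule` gains `f_g0` and `t_post`,
#'   and `sse_post` holds the post-division SSE.
#' @export
fit_post_division <- function(data, fitted, n_post = 2, n_starts = 10,
                              seed = 1, min_gap = 0.5) {
  div <- fitted$schedule$division
  post <- data$times > div + 1e-9
  if (!any(post)) stop("no data beyond the division time ", div)
  t_end <- max(data$times)
  dmax <- apply(data$values, 1, max)
  grid <- data$times
  frozen <- unclass(fitted$params)  # bit-identical freeze
  resid_fn <- function(theta) {
    f <- min(max(theta[1], 0), 1)
    d <- pmax(theta[-1], min_gap)
    sch <- fitted$schedule
    sch$f_g0 <- f
    sch$t_post <- div + cumsum(d)
    mod <- try(simulate_cim(fitted$params, sch, fitted$rna0, grid,
                            mode = "post_division"), silent = TRUE)
    if (inherits(mod, "try-error")) return(rep(1e3, sum(post) * nrow(data$values)))
    post_cols <- mod$times > div + 1e-9
    as.vector((mod$rna[, post_cols, drop = FALSE] -
                 data$values[, post, drop = FALSE]) / dmax)
  }
  lower <- c(0, rep(min_gap, n_post))
  upper <- c(1, rep(t_end - div, n_post))
  best <- NULL
  for (i in seq_len(n_starts)) {
    set.seed(substream_seed(seed, paste0("postdiv", i)))
    th0 <- c(runif(1), runif(n_post, min_gap, (t_end - div) / n_post))
    lm <- try(minpack.lm::nls.lm(par = th0, lower = lower, upper = upper,
                                 fn = resid_fn,
                                 control = minpack.lm::nls.lm.control(
                                   maxiter = 50)),
              silent = TRUE)
    if (inherits(lm, "try-error")) next
    s <- sum(resid_fn(lm$par)^2)
    if (is.null(best) || s < best$sse) best <- list(par = lm$par, sse = s)
  }
  if (is.null(best)) stop("all post-division starts failed")
  stopifnot(identical(unclass(fitted$params), frozen))
  fitted$schedule$f_g0 <- best$par[1]
  fitted$schedule$t_post <- div + cumsum(pmax(best$par[-1], min_gap))
  fitted$sse_post <- best$sse
  fitted
}

#' Stage durations implied by a fitted schedule
#'
#' Cycle-1 durations are the successive differences of
#' `{0, t_1, ..., t_K}`; second-cycle durations are differences of
#' `{division, t_post, data_end}`. A stage whose closing change point was
#' never reached within the data span is reported as a lower bound.
#'
#' @param fitted a `cim_fit` (optionally after [fit_post_division()]).
#' @param data_end end of the observed span, hours; needed to flag
#'   unreached second-cycle change points.
#' @return data.frame with `stage`, `cycle`, `duration` (h), and
#'   `lower_bound` (logical).
#' @export
stage_durations <- function(fitted, data_end = NULL) {
  sch <- fitted$schedule
  out <- data.frame(stage = sch$labels, cycle = 1L,
                    duration = diff(c(0, sch$times)),
                    lower_bound = FALSE, stringsAsFactors = FALSE)
  if (!is.null(sch$t_post) && !is.null(data_end)) {
    tp <- sch$t_post[sch$t_post <= data_end + 1e-9]
    bounds <- c(sch$division, tp, data_end)
    k <- length(bounds) - 1L
    out2 <- data.frame(stage = sch$labels[seq_len(k)], cycle = 2L,
                       duration = diff(bounds),
                       lower_bound = c(rep(FALSE, length(tp)), TRUE),
                       stringsAsFactors = FALSE)
    out <- rbind(out, out2)
  }
  out
}
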