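#' Synthetic expression series with planted lagged causal structure
#'
#' Emulates the causal structure the TDMI scan must detect, at the shape of
#' a cell-cycle time course. Root genes follow a smooth seeded latent
#' process (an AR(2) with complex roots, oscillation period drawn from
#' 20-30 sampling steps, mimicking cell-cycle-like dynamics); each effect
#' gene is `gain * cause` shifted by its planted delay plus independent
#' Gaussian noise with standard deviation `noise_sd * sd(cause)`. Series
#' are shifted to be nonnegative. The planted edge list must be acyclic.
#'
#' @param n_genes number of genes.
#' @param n_times number of uniform time points.
#' @param step sampling interval, hours.
#' @param edges data.frame with columns `cause`, `effect` (gene indices or
#'   ids), `delay` (steps, >= 1), `gain`; may be empty.
#' @param noise_sd noise level as a fraction of the cause signal sd.
#' @param seed master seed; regeneration from the same seed is
#'   bit-identical.
#' @return List with `data` (an [expression_set]) and `truth` (list:
#'   `edges`, `noise_sd`, `seed`).
#' @export
gen_lagged_network <- function(n_genes, n_times, step = 0.5,
                               edges = NULL, noise_sd = 0.1, seed = 1) {
  if (is.null(edges))
    edges <- data.frame(cause = integer(0), effect = integer(0),
                        delay = integer(0), gain = numeric(0))
  ids <- paste0("gene", seq_len(n_genes))
  to_idx <- function(v) if (is.numeric(v)) as.integer(v) else match(v, ids)
  cause <- to_idx(edges$cause)
  effect <- to_idx(edges$effect)
  if (nrow(edges) && any(edges$delay < 1))
    stop("planted delays must be >= 1 step")
  # topological order (errors on cycles)
  order_topo <- integer(0)
  remaining <- seq_len(n_genes)
  parents <- function(j) cause[effect == j]
  while (length(remaining)) {
    free <- remaining[vapply(remaining, function(j)
      !any(parents(j) %in% remaining), logical(1))]
    if (!length(free)) stop("planted edge list contains a cycle")
    order_topo <- c(order_topo, free)
    remaining <- setdiff(remaining, free)
  }
  set.seed(substream_seed(seed, "lagged_network"))
  lead <- max(0L, if (nrow(edges)) sum(edges$delay) else 0L) + 10L
  total <- n_times + lead
  series <- matrix(NA_real_, n_genes, total)
  for (j in order_topo) {
    pa <- which(effect == j)
    if (!length(pa)) {
      period <- runif(1, 20, 30)
      damp <- 0.97
      phi1 <- 2 * damp * cos(2 * pi / period)
      phi2 <- -damp^2
      x <- as.vector(arima.sim(list(ar = c(phi1, phi2)),
                               n = total, n.start = 200))
      series[j, ] <- x
    } else {
      acc <- numeric(total)
      for (e in pa) {
        src <- series[cause[e], ]
        d <- edges$delay[e]
        shifted <- c(rep(src[1], d), src[seq_len(total - d)])
        acc <- acc + edges$gain[e] * shifted
      }
      sd_sig <- sd(acc)
      if (sd_sig < 1e-12) sd_sig <- 1
      series[j, ] <- acc + rnorm(total, sd = noise_sd * sd_sig)
    }
  }
  series <- series[, (lead + 1):total, drop = FALSE]
  lo <- apply(series, 1, min)
  rng <- apply(series, 1, function(r) max(r) - min(r))
  series <- series - lo + 0.05 * pmax(rng, 1e-6)
  data <- expression_set(series, ids, seq(0, by = step,
                                          length.out = n_times))
  list(data = data,
       truth = list(edges = edges, noise_sd = noise_sd, seed = seed))
}

#' Synthetic dataset generated by the cybernetic model itself
#'
#' Draws model parameters inside the fitting bounds (rates and initial
#' regulator levels log-uniform in cell-cycle-plausible ranges, interaction
#' strengths with `|k|` uniform-log in \[0.5, 5\] and random signs on a
#' random acyclic off-diagonal support), simulates the stage-specific model
#' on a uniform grid, and applies mean-preserving multiplicative log-normal
#' noise (expression-like heteroscedasticity; additive Gaussian available
#' via `noise_kind`). Pathological draws (solver failure or runaway
#' trajectories) are resampled from an incremented substream with a
#' message. Because the forward model is exactly the fitted model, these
#' datasets close the loop on parameter-recovery tests.
#'
#' @param n_genes number of genes.
#' @param schedule a [stage_schedule]; default a two-stage cycle (G1, S)
#'   over the grid span with the transition at 40% of the span. If the
#'   schedule carries `f_g0` and `t_post`, the post-division mixture is
#'   simulated.
#' @param n_edges number of planted interactions (overrides `k_density`).
#' @param k_density fraction of off-diagonal entries planted (default 0.1).
#' @param noise_sd noise level (sdlog of the log-normal, or sd fraction for
#'   additive noise).
#' @param noise_kind `"lognormal"` or `"additive"`.
#' @param n_times,step uniform grid size and spacing (hours).
#' @param seed master seed.
#' @return List with `data` (an [expression_set]), `truth` (list: `params`,
#'   `schedule`, `rna0`, `noise_sd`, `noise_kind`, `seed`), and `traj` (the
#'   noiseless trajectories).
#' @export
gen_cim_dataset <- function(n_genes = 6, schedule = NULL, n_edges = NULL,
                            k_density = 0.1, noise_sd = 0.02,
                            noise_kind = c("lognormal", "additive"),
                            n_times = 60, step = 0.5, seed = 1) {
  noise_kind <- match.arg(noise_kind)
  if (k_density < 0 || k_density > 0.3)
    stop("k_density must be in [0, 0.3]")
  span <- (n_times - 1) * step
  if (is.null(schedule))
    schedule <- stage_schedule(labels = c("G1", "S"),
                               times = c(0.4 * span, span),
                               weights = matrix(1, 2, n_genes))
  post <- !is.na(schedule$f_g0) && !is.null(schedule$t_post)
  grid <- seq(0, span, by = step)
  ids <- paste0("gene", seq_len(n_genes))
  for (attempt in 0:9) {
    set.seed(substream_seed(seed, paste0("cim_dataset", attempt)))
    kr <- exp(runif(n_genes, log(0.5), log(2)))
    gamma <- exp(runif(n_genes, log(0.2), log(1)))
    g0 <- exp(runif(n_genes, log(0.5), log(2)))
    alpha <- exp(runif(1, log(0.2), log(1)))
    beta <- exp(runif(1, log(0.2), log(1)))
    off <- which(row(diag(n_genes)) != col(diag(n_genes)))
    m <- if (!is.null(n_edges)) n_edges
         else round(k_density * length(off))
    support <- sample(off, m)
    K <- matrix(0, n_genes, n_genes)
    K[support] <- sample(c(-1, 1), m, TRUE) * exp(runif(m, log(0.5), log(5)))
    W <- matrix(runif(nrow(schedule$weights) * n_genes, 0.05, 1),
                nrow(schedule$weights), n_genes)
    sch <- schedule
    sch$weights <- W / apply(W, 1, max)
    rna0 <- runif(n_genes, 0.5, 2)
    params <- try(cim_parameters(kr, gamma, g0, alpha, beta, K,
                                 gene_ids = ids), silent = TRUE)
    traj <- try(simulate_cim(params, sch, rna0, grid,
                             mode = if (post) "post_division" else "cycle1"),
                silent = TRUE)
    if (inherits(traj, "try-error") || anyNA(traj$rna) ||
        max(traj$rna) > 1e4) {
      message("pathological parameter draw (attempt ", attempt + 1,
              "); resampling")
      next
    }
    set.seed(substream_seed(seed, paste0("cim_noise", attempt)))
    clean <- traj$rna
    noisy <- if (noise_sd == 0) clean
    else if (noise_kind == "lognormal") {
      clean * matrix(rlnorm(length(clean), meanlog = -noise_sd^2 / 2,
                            sdlog = noise_sd), nrow(clean))
    } else {
      pmax(clean + matrix(rnorm(length(clean),
                                sd = noise_sd * sd(clean)), nrow(clean)), 0)
    }
    data <- expression_set(noisy, ids, grid)
    return(list(data = data,
                truth = list(params = params, schedule = sch, rna0 = rna0,
                             noise_sd = noise_sd, noise_kind = noise_kind,
                             seed = seed),
                traj = traj))
  }
  stop("could not draw a well-behaved parameter set in 10 attempts")
}
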