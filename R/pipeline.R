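#' Validated run configuration for the full pipeline
#'
#' Collects every tunable of the TDMI scan, the model fit, and the network
#' reduction, with the defaults used in the full-scale cell-cycle analysis:
#' delays scanned over \[-20, 20\] h, top-10-percentile edge selection,
#' interaction sparsity floor 0.1 and cap 100, simplification thresholds
#' MCC >= 7 and MRER > 1, stages G1/S1/S2/S3/G2/M.
#'
#' @param seed master seed; all randomness (multistart draws, synthetic
#'   data) flows from it through named substreams.
#' @param tau_max,tau_step TDMI delay grid (hours); `tau_step` defaults to
#'   the sampling interval.
#' @param max_lag AR/VAR order search bound; default `min(10, n %/% 10)`.
#' @param percentile top TDMI percentile retained, in (0, 100).
#' @param stages ordered cycle-1 stage labels.
#' @param division_time end of the first cycle (hours); default the end of
#'   the data (no post-division fit).
#' @param n_starts multistart count for the cycle-1 fit.
#' @param sparsity_floor,sparsity_cap interaction floor/cap.
#' @param mcc_min,mrer_min simplification thresholds.
#' @param resample_step uniform grid step (hours); default the median
#'   observed spacing.
#' @param log_transform if `TRUE`, fit on `log1p` expression.
#' @param n_post number of second-cycle transition times fitted.
#' @param fit_opts list of fitting options forwarded to
#'   [fit_first_cycle()] (e.g. `maxiter`, `polish_maxit`).
#' @param out_dir optional directory where [run_pipeline()] writes
#'   artifacts.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1, tau_max = 20, tau_step = NULL,
                       max_lag = NULL, percentile = 10,
                       stages = c("G1", "S1", "S2", "S3", "G2", "M"),
                       division_time = NULL, n_starts = 100,
                       sparsity_floor = 0.1, sparsity_cap = 100,
                       mcc_min = 7, mrer_min = 1, resample_step = NULL,
                       log_transform = FALSE, n_post = 2, fit_opts = list(),
                       out_dir = NULL) {
  if (!(percentile > 0 && percentile <= 100))
    stop("percentile must be in (0, 100]")
  if (percentile == 0) stop("percentile must be positive")
  if (sparsity_floor <= 0 || sparsity_cap <= 0 || mcc_min < 0)
    stop("thresholds must be positive")
  if (!length(stages)) stop("stage labels must be a nonempty ordered list")
  if (tau_max <= 0) stop("tau_max must be positive")
  if (n_starts < 1) stop("n_starts must be >= 1")
  structure(list(seed = seed, tau_max = tau_max, tau_step = tau_step,
                 max_lag = max_lag, percentile = percentile,
                 stages = stages, division_time = division_time,
                 n_starts = n_starts, sparsity_floor = sparsity_floor,
                 sparsity_cap = sparsity_cap, mcc_min = mcc_min,
                 mrer_min = mrer_min, resample_step = resample_step,
                 log_transform = log_transform, n_post = n_post,
                 fit_opts = fit_opts, out_dir = out_dir),
            class = "run_config")
}

#' Run the full TDMI -> fit -> network pipeline
#'
#' 1. Resample the data onto a uniform grid; 2. infer the preliminary
#' causal network by thresholded TDMI; 3. fit the cybernetic model for the
#' first cycle with the interaction matrix masked by the TDMI edges;
#' 4. if the data extend beyond the configured division time, fit the
#' post-division G0 fraction and second-cycle transition times; 5.
#' reconstruct the signed interaction network from the fitted matrix, score
#' nodes by MCC and MRER, and reduce it by the union rule. Fully
#' reproducible given `config$seed`.
#'
#' @param config a [run_config].
#' @param data an [expression_set].
#' @return List with `tdmi_network`, `fitted`, `trajectories`,
#'   `signed_network`, `node_scores`, `simplified_network`, `durations`,
#'   and `report` (run summary).
#' @export
run_pipeline <- function(config, data) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  step_ctx <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "': ", conditionMessage(e),
           call. = FALSE))
  }
  uni <- step_ctx("resample", resample_uniform(data, config$resample_step))
  if (config$log_transform)
    uni$values <- log1p(uni$values)
  profiles <- step_ctx("tdmi", tdmi_all_pairs(
    uni, tau_max = config$tau_max, tau_step = config$tau_step,
    max_lag = config$max_lag))
  net <- step_ctx("tdmi", build_network(profiles, config$percentile))
  div <- if (is.null(config$division_time)) max(uni$times)
         else config$division_time
  cyc1 <- uni
  pre <- uni$times <= div + 1e-9
  cyc1$values <- uni$values[, pre, drop = FALSE]
  cyc1$times <- uni$times[pre]
  cyc1 <- expression_set(cyc1$values, cyc1$gene_ids, cyc1$times, uni$meta)
  fitted <- step_ctx("fit", fit_first_cycle(
    cyc1, net, stages = config$stages, n_starts = config$n_starts,
    seed = config$seed,
    opts = utils::modifyList(
      list(floor = config$sparsity_floor, cap = config$sparsity_cap),
      config$fit_opts)))
  if (any(uni$times > div + 1e-9))
    fitted <- step_ctx("fit_post", fit_post_division(
      uni, fitted, n_post = config$n_post, seed = config$seed))
  traj <- step_ctx("simulate", simulate_cim(
    fitted$params, fitted$schedule, fitted$rna0, cyc1$times,
    mode = "cycle1"))
  snet <- step_ctx("network", reconstruct_network(
    fitted$params$K, uni$gene_ids,
    categories = uni$meta$category))
  rates <- step_ctx("network", mrer(traj, fitted$params))
  scores <- step_ctx("network", node_scores(snet, rates$overall,
                                            rates$per_stage))
  simp <- step_ctx("network", simplify_network(
    snet, scores, config$mcc_min, config$mrer_min))
  durations <- stage_durations(fitted, data_end = max(uni$times))
  report <- list(n_genes = length(uni$gene_ids),
                 n_times = length(uni$times),
                 tdmi_edges = nrow(net$edges),
                 fitted_interactions = sum(fitted$params$K != 0),
                 sse = fitted$sse,
                 simplified_nodes = nrow(simp$nodes),
                 simplified_edges = nrow(simp$edges),
                 seed = config$seed)
  out <- list(tdmi_network = net, fitted = fitted, trajectories = traj,
              signed_network = snet, node_scores = scores,
              simplified_network = simp, durations = durations,
              report = report)
  if (!is.null(config$out_dir)) write_pipeline_artifacts(out, config$out_dir)
  out
}

#' Write pipeline artifacts to a directory
#'
#' Emits `tdmi_network.sif`, `network.graphml`, `simplified.sif`, a flat
#' `parameters.tsv` (one row per fitted parameter: name, gene/pair, value,
#' bound status), `node_scores.tsv`, `durations.tsv`, and a tidy
#' `trajectories.tsv` (time, gene, rna, g, u, v, stage).
#'
#' @param result list from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_artifacts <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_network(result$tdmi_network, file.path(dir, "tdmi_network.sif"),
                "SIF")
  write_network(result$signed_network, file.path(dir, "network.graphml"),
                "GraphML", scores = result$node_scores)
  write_network(result$simplified_network, file.path(dir, "simplified.sif"),
                "SIF")
  write.table(result$node_scores, file.path(dir, "node_scores.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(result$durations, file.path(dir, "durations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(parameter_table(result$fitted),
              file.path(dir, "parameters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- result$trajectories
  tidy <- do.call(rbind, lapply(seq_along(tr$gene_ids), function(i)
    data.frame(time = tr$times, gene = tr$gene_ids[i], rna = tr$rna[i, ],
               g = tr$g[i, ], u = tr$u[i, ], v = tr$v[i, ],
               stage = tr$stage, stringsAsFactors = FALSE)))
  write.table(tidy, file.path(dir, "trajectories.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Flat table of fitted parameters
#'
#' @param fitted a `cim_fit`.
#' @return data.frame with `name`, `gene` (or `pair`), `value`, `at_bound`.
#' @export
parameter_table <- function(fitted) {
  p <- fitted$params
  sch <- fitted$schedule
  ids <- p$gene_ids
  rows <- list(
    data.frame(name = "kr", gene = ids, value = p$kr),
    data.frame(name = "gamma", gene = ids, value = p$gamma),
    data.frame(name = "g0", gene = ids, value = p$g0),
    data.frame(name = "alpha", gene = "(shared)", value = p$alpha),
    data.frame(name = "beta", gene = "(shared)", value = p$beta))
  nz <- which(p$K != 0, arr.ind = TRUE)
  if (nrow(nz))
    rows <- c(rows, list(data.frame(
      name = "k_g", gene = paste0(ids[nz[, 1]], "->", ids[nz[, 2]]),
      value = p$K[nz])))
  for (s in seq_along(sch$labels))
    rows <- c(rows, list(data.frame(
      name = paste0("w_", sch$labels[s]), gene = ids,
      value = sch$weights[s, ])))
  rows <- c(rows, list(data.frame(
    name = paste0("t", seq_along(sch$times)), gene = "(transition)",
    value = sch$times)))
  if (!is.na(sch$f_g0))
    rows <- c(rows, list(data.frame(name = "f_g0", gene = "(shared)",
                                    value = sch$f_g0)))
  if (!is.null(sch$t_post))
    rows <- c(rows, list(data.frame(
      name = paste0("t", length(sch$times) + seq_along(sch$t_post)),
      gene = "(transition)", value = sch$t_post)))
  out <- do.call(rbind, rows)
  o <- fitted$opts
  near <- function(v, b) abs(v - b) < 1e-8 * max(abs(b), 1)
  out$at_bound <- FALSE
  rate_rows <- out$name %in% c("kr", "gamma", "alpha", "beta")
  out$at_bound[rate_rows] <- near(out$value[rate_rows], o$rate_bounds[1]) |
    near(out$value[rate_rows], o$rate_bounds[2])
  g0_rows <- out$name == "g0"
  out$at_bound[g0_rows] <- near(out$value[g0_rows], o$g0_bounds[1]) |
    near(out$value[g0_rows], o$g0_bounds[2])
  k_rows <- out$name == "k_g"
  out$at_bound[k_rows] <- near(abs(out$value[k_rows]), o$cap)
  rownames(out) <- NULL
  out
}

#' Rebuild model objects from a flat parameter table
#'
#' Inverse of [parameter_table()]: reconstructs the [cim_parameters] and
#' [stage_schedule] from the TSV the pipeline and CLI write, so fitted
#' models can be re-simulated without refitting.
#'
#' @param tab data.frame as produced by [parameter_table()] (or the path of
#'   the written TSV).
#' @return List with `params` and `schedule`.
#' @export
read_parameter_table <- function(tab) {
  if (is.character(tab)) tab <- read.delim(tab, stringsAsFactors = FALSE)
  pick <- function(nm) tab[tab$name == nm, , drop = FALSE]
  ids <- pick("kr")$gene
  n <- length(ids)
  val <- function(nm) setNames(pick(nm)$value, pick(nm)$gene)[ids]
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  kg <- pick("k_g")
  if (nrow(kg)) {
    ends <- strsplit(kg$gene, "->", fixed = TRUE)
    K[cbind(match(vapply(ends, `[`, "", 1), ids),
            match(vapply(ends, `[`, "", 2), ids))] <- kg$value
  }
  params <- cim_parameters(kr = unname(val("kr")),
                           gamma = unname(val("gamma")),
                           g0 = unname(val("g0")),
                           alpha = pick("alpha")$value,
                           beta = pick("beta")$value,
                           K = K, gene_ids = ids)
  w_rows <- grep("^w_", tab$name, value = TRUE)
  labels <- unique(sub("^w_", "", w_rows))
  W <- do.call(rbind, lapply(labels, function(s)
    setNames(pick(paste0("w_", s))$value, pick(paste0("w_", s))$gene)[ids]))
  t_rows <- tab[grepl("^t[0-9]+$", tab$name), ]
  times_all <- t_rows$value[order(as.integer(sub("^t", "", t_rows$name)))]
  times <- times_all[seq_along(labels)]
  t_post <- if (length(times_all) > length(labels))
    times_all[-seq_along(labels)] else NULL
  f_g0 <- if (nrow(pick("f_g0"))) pick("f_g0")$value else NA_real_
  schedule <- stage_schedule(labels = labels, times = times, weights = W,
                             f_g0 = f_g0, t_post = t_post)
  list(params = params, schedule = schedule)
}
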