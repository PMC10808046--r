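#' Time-delayed mutual information profile for one gene pair
#'
#' Scans the normalized innovation MI over a grid of relative delays tau
#' (hours), using the single alignment `TDMI(tau) = I_norm(X_{t+tau}; Y_t)`:
#' the x series is shifted forward by tau against y, the non-overlapping
#' ends are dropped (no padding), and AR/VAR predictors are refit on each
#' aligned segment. A peak at tau > 0 means the recent past of Y predicts X,
#' i.e. Y is called the cause of X; a peak at tau < 0 calls X the cause.
#' The two directional maxima are taken over tau >= 0 and tau <= 0, so a
#' peak exactly at zero delay yields equal directional maxima (an
#' instantaneous, direction-free association).
#'
#' @param x,y numeric series on a uniform time grid.
#' @param tau_max largest |tau| scanned, hours (default 20).
#' @param step time spacing of the series in hours; the tau grid runs from
#'   -tau_max to +tau_max in multiples of `step`.
#' @param max_lag AR/VAR order search range, passed to
#'   [mutual_information()].
#' @param min_overlap smallest aligned segment length allowed (default 30).
#' @param pair optional character vector `c(gene_x, gene_y)` used for
#'   labeling.
#' @return An object of class `tdmi_profile`: list with `pair`, `tau`
#'   (hours), `values` (I_norm per tau), `tdmi_plus_max`, `argmax_plus`,
#'   `tdmi_minus_max`, `argmax_minus`, and `value_at_zero`.
#' @export
tdmi_scan <- function(x, y, tau_max = 20, step = 1, max_lag = NULL,
                      min_overlap = 30L, pair = c("x", "y")) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("series lengths differ")
  k_max <- floor(tau_max / step + 1e-9)
  shifts <- seq(-k_max, k_max)
  if (n - k_max < min_overlap)
    stop("insufficient overlap at |tau| = ", tau_max, ": ", n - k_max,
         " points < ", min_overlap)
  vals <- vapply(shifts, function(s) {
    a <- abs(s)
    if (s >= 0) {
      xs <- x[(1 + a):n]; ys <- y[1:(n - a)]
    } else {
      xs <- x[1:(n - a)]; ys <- y[(1 + a):n]
    }
    mutual_information(xs, ys, max_lag = max_lag)$mi_normalized
  }, numeric(1))
  tau <- shifts * step
  plus <- which(tau >= 0)
  minus <- which(tau <= 0)
  ip <- plus[which.max(vals[plus])]
  im <- minus[which.max(vals[minus])]
  structure(list(pair = pair, tau = tau, values = vals,
                 tdmi_plus_max = vals[ip], argmax_plus = tau[ip],
                 tdmi_minus_max = vals[im], argmax_minus = tau[im],
                 value_at_zero = vals[tau == 0]),
            class = "tdmi_profile")
}

#' TDMI profiles for all gene pairs of a series set
#'
#' Runs [tdmi_scan()] once per unordered gene pair (both directional maxima
#' come from the single profile), in deterministic lexicographic pair order
#' over the set's gene order.
#'
#' @param set an [expression_set] on a uniform grid (see
#'   [resample_uniform()]).
#' @param tau_max,max_lag,min_overlap passed to [tdmi_scan()].
#' @param tau_step tau grid spacing, hours; default the data spacing.
#' @param progress if `TRUE`, print a line every 500 pairs.
#' @return List of `tdmi_profile`, length `choose(n_genes, 2)`.
#' @export
tdmi_all_pairs <- function(set, tau_max = 20, tau_step = NULL,
                           max_lag = NULL, min_overlap = 30L,
                           progress = FALSE) {
  ng <- length(set$gene_ids)
  if (ng < 2) stop("need at least 2 genes")
  step <- grid_step(set$times)
  if (is.null(tau_step)) tau_step <- step
  if (abs(tau_step / step - round(tau_step / step)) > 1e-9)
    stop("tau_step must be a multiple of the sampling interval")
  pairs <- utils::combn(ng, 2)
  out <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    out[[k]] <- tdmi_scan(set$values[i, ], set$values[j, ],
                          tau_max = tau_max, step = tau_step,
                          max_lag = max_lag, min_overlap = min_overlap,
                          pair = c(set$gene_ids[i], set$gene_ids[j]))
    if (progress && k %% 500L == 0L)
      message(k, "/", ncol(pairs), " pairs done")
  }
  out
}

#' Directional TDMI maxima as a flat table
#'
#' @param profiles list of `tdmi_profile` from [tdmi_all_pairs()].
#' @return data.frame with one row per directed candidate: `gene_x`,
#'   `gene_y`, `direction` (`"plus"` = y causes x, `"minus"` = x causes y),
#'   `tdmi`, `lag` (hours).
#' @export
tdmi_maxima_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(gene_x = p$pair[1], gene_y = p$pair[2],
               direction = c("plus", "minus"),
               tdmi = c(p$tdmi_plus_max, p$tdmi_minus_max),
               lag = c(p$argmax_plus, p$argmax_minus),
               stringsAsFactors = FALSE)
  }))
}

#' Preliminary causal network from pooled directional TDMI maxima
#'
#' Pools the two directional maxima of every pair (2 * choose(n, 2) values)
#' and retains exactly the largest `floor(percentile/100 * M)` of the M
#' pooled values, ties broken by stable pair order. A retained plus-side
#' maximum of profile (X, Y) adds the edge Y -> X (Y causes X); a retained
#' minus-side maximum adds X -> Y. A pair is flagged bidirectional when
#' both of its directions are retained, which includes profiles peaking at
#' tau = 0 (both directional maxima then share the peak value).
#'
#' @param profiles list of `tdmi_profile`.
#' @param percentile top percentile retained, in (0, 100); default 10.
#' @return An object of class `causal_network`: list with `nodes`
#'   (character) and `edges` (data.frame: `from`, `to`, `tdmi`, `lag`,
#'   `bidirectional`).
#' @export
build_network <- function(profiles, percentile = 10) {
  if (!length(profiles)) stop("empty profile list")
  if (!(percentile > 0 && percentile < 100) && percentile != 100)
    stop("percentile must be in (0, 100]")
  tab <- tdmi_maxima_table(profiles)
  M <- nrow(tab)
  k <- floor(percentile / 100 * M)
  ord <- order(-tab$tdmi, seq_len(M))  # stable under ties
  keep <- tab[ord[seq_len(k)], , drop = FALSE]
  from <- ifelse(keep$direction == "plus", keep$gene_y, keep$gene_x)
  to <- ifelse(keep$direction == "plus", keep$gene_x, keep$gene_y)
  pair_key <- paste(pmin(keep$gene_x, keep$gene_y),
                    pmax(keep$gene_x, keep$gene_y))
  bidir <- pair_key %in% pair_key[duplicated(pair_key)]
  nodes <- unique(unlist(lapply(profiles, `[[`, "pair")))
  edges <- data.frame(from = from, to = to, tdmi = keep$tdmi,
                      lag = keep$lag, bidirectional = bidir,
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, percentile = percentile),
            class = "causal_network")
}

#' @export
print.causal_network <- function(x, ...) {
  cat("causal_network: ", length(x$nodes), " nodes, ", nrow(x$edges),
      " directed TDMI edges (top ", x$percentile, " percentile)\n", sep = "")
  invisible(x)
}
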