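#' Gene-labeled multivariate expression time series
#'
#' Container for longitudinal expression measurements: a nonnegative
#' gene-by-time matrix with strictly increasing time stamps (hours) and
#' unique gene identifiers. All pipeline stages (TDMI network inference,
#' cybernetic model fitting) consume this container.
#'
#' @param values numeric matrix, genes in rows, time points in columns.
#' @param gene_ids character vector of unique gene identifiers, one per row.
#' @param times numeric vector of strictly increasing time stamps in hours.
#' @param meta optional named list of free-form annotations (e.g. a
#'   `category` vector classifying genes as canonical cell-cycle,
#'   transcription factor, or checkpoint).
#'
#' @return An object of class `expression_set` with elements `gene_ids`,
#'   `times`, `values`, `meta`.
#' @export
expression_set <- function(values, gene_ids, times, meta = list()) {
  values <- as.matrix(values)
  gene_ids <- as.character(gene_ids)
  times <- as.numeric(times)
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene ids: ", paste(dup, collapse = ", "))
  }
  if (nrow(values) != length(gene_ids))
    stop("values has ", nrow(values), " rows but there are ",
         length(gene_ids), " gene ids")
  if (ncol(values) != length(times))
    stop("values has ", ncol(values), " columns but there are ",
         length(times), " time stamps")
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop("non-finite expression value at gene '", gene_ids[bad[1]],
         "', time ", times[bad[2]])
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop("negative expression value at gene '", gene_ids[bad[1]],
         "', time ", times[bad[2]])
  }
  if (length(times) < 2 || any(diff(times) <= 0))
    stop("time stamps must be strictly increasing and span > 0")
  dimnames(values) <- list(gene_ids, NULL)
  structure(list(gene_ids = gene_ids, times = times, values = values,
                 meta = meta),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat("expression_set: ", length(x$gene_ids), " genes x ",
      length(x$times), " time points (",
      format(min(x$times)), "-", format(max(x$times)), " h)\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_set <- function(x) dim(x$values)

#' Read an expression table from TSV/CSV
#'
#' Expected layout (dialect `"genes_in_rows"`): a header row of time stamps
#' in hours, a first column of gene identifiers, and a numeric body. The
#' transposed layout is supported via dialect `"genes_in_columns"`. The
#' delimiter is inferred from the file extension (`.csv` = comma, anything
#' else = tab).
#'
#' @param path path to the table.
#' @param dialect `"genes_in_rows"` (default) or `"genes_in_columns"`.
#' @return An [expression_set].
#' @export
read_expression_table <- function(path,
                                  dialect = c("genes_in_rows",
                                              "genes_in_columns")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.delim(path, sep = sep, header = FALSE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (dialect == "genes_in_columns") raw <- as.data.frame(t(raw))
  header <- suppressWarnings(as.numeric(unlist(raw[1, -1])))
  if (anyNA(header))
    stop("header row must contain numeric time stamps; offending column ",
         which(is.na(header))[1] + 1)
  ids <- as.character(raw[-1, 1])
  body <- raw[-1, -1, drop = FALSE]
  vals <- suppressWarnings(vapply(body, as.numeric, numeric(nrow(body))))
  vals <- matrix(as.numeric(vals), nrow = length(ids))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop("non-numeric cell at row ", bad[1] + 1, ", column ", bad[2] + 1,
         " (gene '", ids[bad[1]], "')")
  }
  expression_set(vals, ids, header)
}

#' Write an expression table
#'
#' Inverse of [read_expression_table()] with dialect `"genes_in_rows"`;
#' round-trips exactly (values written with full precision).
#'
#' @param set an [expression_set].
#' @param path output path; `.csv` selects comma separation, otherwise tab.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(set, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  header <- c("gene_id", format(set$times, digits = 17, trim = TRUE))
  body <- cbind(set$gene_ids,
                matrix(format(set$values, digits = 17, trim = TRUE),
                       nrow = nrow(set$values)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = sep), con)
  writeLines(apply(body, 1, paste, collapse = sep), con)
  invisible(path)
}

#' Resample a series set onto a uniform time grid
#'
#' AR/VAR innovation models and the TDMI delay grid assume uniform sampling;
#' measured series on mixed 0.5/1-h spacing are interpolated onto the grid
#' `t0, t0 + step, ...` first. Grid points that coincide with observed times
#' reproduce the observed values exactly.
#'
#' @param set an [expression_set].
#' @param step grid spacing in hours; defaults to the median observed spacing.
#' @param method `"linear"` interpolation or `"previous"` (last observation
#'   carried forward).
#' @return A resampled [expression_set].
#' @export
resample_uniform <- function(set, step = NULL,
                             method = c("linear", "previous")) {
  method <- match.arg(method)
  d <- diff(set$times)
  if (is.null(step)) step <- stats::median(d)
  span <- max(set$times) - min(set$times)
  if (step <= 0 || step > span) stop("step must be in (0, span]")
  if (step < 1e-9) stop("step below resolvable spacing")
  grid <- seq(min(set$times), max(set$times) + step / 2, by = step)
  grid <- grid[grid <= max(set$times) + 1e-9]
  vals <- t(apply(set$values, 1, function(row) {
    approx(set$times, row, xout = grid,
           method = if (method == "linear") "linear" else "constant",
           rule = 2)$y
  }))
  # snap grid points that fall on observed times to the observed values
  hit <- match(round(grid, 9), round(set$times, 9))
  on_grid <- which(!is.na(hit))
  if (length(on_grid)) vals[, on_grid] <- set$values[, hit[on_grid]]
  expression_set(vals, set$gene_ids, grid, set$meta)
}

# median spacing of a time grid; single uniform step if already uniform
grid_step <- function(times) {
  d <- diff(times)
  if (max(d) - min(d) < 1e-9) d[1] else stats::median(d)
}
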