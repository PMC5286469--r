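#' Time-series expression dataset
#'
#' Container for a gene-by-time expression experiment: one or more series
#' (e.g. different perturbations) measured on a shared, strictly increasing
#' time grid in hours. All downstream steps (correlation windows, lag
#' estimation, ODE fitting) consume this object.
#'
#' @param series a numeric matrix (genes in rows, time points in columns) or a
#'   list of such matrices, one per perturbation series.
#' @param times numeric vector of time points in hours, strictly increasing.
#' @param genes character vector of gene identifiers; defaults to the row
#'   names of the first series.
#' @param series_labels optional labels, one per series.
#' @return an object of class `grn_dataset` with fields `genes`, `times`,
#'   `series` (list of matrices) and `series_labels`.
#' @export
grn_dataset <- function(series, times, genes = NULL, series_labels = NULL) {
  if (is.matrix(series)) series <- list(series)
  if (!length(series)) stop("at least one expression series is required")
  if (is.null(genes)) genes <- rownames(series[[1]])
  if (is.null(genes)) genes <- paste0("G", seq_len(nrow(series[[1]])))
  genes <- as.character(genes)
  if (anyDuplicated(genes))
    stop("duplicate gene names: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  times <- as.numeric(times)
  if (length(times) < 2) stop("at least 2 time points are required")
  if (any(diff(times) <= 0)) stop("non-increasing times")
  series <- lapply(series, function(m) {
    m <- as.matrix(m)
    if (!is.numeric(m)) stop("expression values must be numeric")
    if (nrow(m) != length(genes))
      stop("series must have one row per gene")
    if (ncol(m) != length(times))
      stop("series must have one column per time point")
    if (anyNA(m)) stop("missing expression values are not allowed")
    dimnames(m) <- list(genes, times)
    m
  })
  if (is.null(series_labels)) series_labels <- paste0("S", seq_along(series))
  structure(
    list(genes = genes, times = times, series = series,
         series_labels = as.character(series_labels)),
    class = "grn_dataset"
  )
}

#' @export
print.grn_dataset <- function(x, ...) {
  cat("<grn_dataset> ", length(x$genes), " genes x ", length(x$times),
      " time points, ", length(x$series), " series\n", sep = "")
  cat("  genes: ", paste(head(x$genes, 8), collapse = ", "),
      if (length(x$genes) > 8) ", ..." else "", "\n", sep = "")
  cat("  times (h): ", paste(x$times, collapse = ", "), "\n", sep = "")
  invisible(x)
}

n_genes <- function(ds) length(ds$genes)
n_obs_per_gene <- function(ds) length(ds$times) * length(ds$series)

#' Read a tab-separated expression table
#'
#' Parses a TSV expression table with a header row. With
#' `orientation = "genes_in_rows"` the first column holds gene names and the
#' header holds numeric times (hours); with `"times_in_rows"` the layout is
#' transposed. A header whose time grid restarts (e.g. `0, 6, 12, 0, 6, 12`)
#' is split into multiple perturbation series sharing one grid; the repeated
#' blocks must be identical, otherwise the times are rejected as
#' non-increasing.
#'
#' @param file path to a tab-separated file (or a connection).
#' @param orientation `"genes_in_rows"` (default) or `"times_in_rows"`.
#' @return a [grn_dataset()].
#' @export
read_expression_table <- function(file,
                                  orientation = c("genes_in_rows",
                                                  "times_in_rows")) {
  orientation <- match.arg(orientation)
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("expression table needs a header and data rows")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  ncol_hdr <- length(cells[[1]])
  bad <- which(vapply(cells, length, 1L) != ncol_hdr)
  if (length(bad))
    stop("row ", bad[1], " has ", length(cells[[bad[1]]]),
         " fields, expected ", ncol_hdr)
  header <- cells[[1]]
  body <- cells[-1]

  parse_num <- function(x, row, col) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop("non-numeric cell at row ", row[i], ", column ", col[i],
           ": '", x[i], "'")
    }
    v
  }

  if (orientation == "genes_in_rows") {
    times_raw <- parse_num(header[-1], rep(1L, ncol_hdr - 1), 2:ncol_hdr)
    labels <- vapply(body, `[[`, "", 1L)
    vals <- t(vapply(seq_along(body), function(i)
      parse_num(body[[i]][-1], rep(i + 1L, ncol_hdr - 1), 2:ncol_hdr),
      numeric(ncol_hdr - 1)))
  } else {
    labels <- header[-1]
    times_raw <- vapply(seq_along(body), function(i)
      parse_num(body[[i]][1], i + 1L, 1L), 0)
    vals <- vapply(seq_along(body), function(i)
      parse_num(body[[i]][-1], rep(i + 1L, ncol_hdr - 1), 2:ncol_hdr),
      numeric(ncol_hdr - 1))
    vals <- matrix(vals, nrow = ncol_hdr - 1)
  }
  if (anyDuplicated(labels))
    stop("duplicate gene names: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))

  # split a restarting time axis into repeated, identical series blocks
  restarts <- which(diff(times_raw) <= 0) + 1L
  starts <- c(1L, restarts)
  ends <- c(restarts - 1L, length(times_raw))
  blocks <- Map(function(s, e) times_raw[s:e], starts, ends)
  same <- all(vapply(blocks, function(b) identical(b, blocks[[1]]), TRUE))
  if (!same || any(diff(blocks[[1]]) <= 0)) stop("non-increasing times")
  series <- Map(function(s, e) vals[, s:e, drop = FALSE], starts, ends)
  grn_dataset(series, blocks[[1]], genes = labels)
}

#' Normalize each gene to unit maximum
#'
#' Divides every gene's trajectory by its maximum over all time points and
#' series, so the maximum becomes 1. Genes whose maximum is not positive
#' (e.g. all-zero genes) are left unchanged with a warning. Idempotent.
#'
#' @param ds a [grn_dataset()].
#' @return the normalized [grn_dataset()].
#' @export
normalize_unit_max <- function(ds) {
  stopifnot(inherits(ds, "grn_dataset"))
  maxima <- apply(do.call(cbind, ds$series), 1, max)
  flat <- maxima <= 0
  if (any(flat))
    warning("gene(s) without positive maximum left unnormalized: ",
            paste(ds$genes[flat], collapse = ", "))
  scale <- ifelse(flat, 1, maxima)
  ds$series <- lapply(ds$series, function(m) m / scale)
  ds
}

#' @method tidy grn_dataset
#' @export
tidy.grn_dataset <- function(x, ...) {
  purrr::map2_dfr(x$series, x$series_labels, function(m, lab)
    tibble::tibble(
      series = lab,
      gene = rep(x$genes, times = length(x$times)),
      time = rep(x$times, each = length(x$genes)),
      value = as.vector(m)
    ))
}

#' @method glance grn_dataset
#' @export
glance.grn_dataset <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$genes), n_times = length(x$times),
    n_series = length(x$series),
    t_min = min(x$times), t_max = max(x$times)
  )
}

#' @method autoplot grn_dataset
#' @export
autoplot.grn_dataset <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value,
                                   colour = .data$gene)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~series) +
    ggplot2::labs(x = "time (h)", y = "expression (unit-max scale)")
}
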