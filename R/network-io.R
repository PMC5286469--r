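#' Gold-standard network
#'
#' A known true edge set in the DREAM convention, used to score inferred
#' networks. Scoring is over undirected gene pairs, so the derived pair set
#' is stored alongside the directed edges.
#'
#' @param edges tibble/data frame with columns `regulator`, `target` and
#'   optionally `sign`.
#' @param genes gene universe; defaults to all edge endpoints.
#' @return an object of class `grn_gold`.
#' @export
gold_standard <- function(edges, genes = NULL) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("regulator", "target") %in% names(edges)))
  edges$regulator <- as.character(edges$regulator)
  edges$target <- as.character(edges$target)
  if (any(edges$regulator == edges$target))
    stop("self-edges are not allowed in a gold standard")
  if (is.null(genes)) genes <- sort(unique(c(edges$regulator, edges$target)))
  genes <- as.character(genes)
  missing <- setdiff(c(edges$regulator, edges$target), genes)
  if (length(missing))
    stop("edge endpoints outside gene set: ", paste(missing, collapse = ", "))
  structure(list(genes = genes, edges = edges,
                 pairs = undirected_pairs(edges)),
            class = "grn_gold")
}

# canonical undirected pair key "a|b" with a < b
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

undirected_pairs <- function(edges) {
  unique(pair_key(edges$regulator, edges$target))
}

#' @export
print.grn_gold <- function(x, ...) {
  cat("<grn_gold> ", length(x$genes), " genes, ", nrow(x$edges),
      " directed edges (", length(x$pairs), " undirected pairs)\n", sep = "")
  invisible(x)
}

#' Read a DREAM-format gold standard
#'
#' Each line is `regulator<TAB>target<TAB>flag` with flag 1 (edge present)
#' or 0 (edge absent). Flag-0 lines contribute their genes to the universe
#' but no edge.
#'
#' @param file path or connection.
#' @return a [gold_standard()] object.
#' @export
read_gold_standard <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  cells <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(cells, length, 1L) != 3L)
  if (length(bad))
    stop("line ", bad[1], ": expected 'regulator<TAB>target<TAB>flag'")
  reg <- vapply(cells, `[[`, "", 1L)
  tgt <- vapply(cells, `[[`, "", 2L)
  flag <- vapply(cells, `[[`, "", 3L)
  if (!all(flag %in% c("0", "1"))) {
    i <- which(!flag %in% c("0", "1"))[1]
    stop("line ", i, ": unknown flag '", flag[i], "'")
  }
  keep <- flag == "1"
  if (any(reg[keep] == tgt[keep])) {
    i <- which(keep & reg == tgt)[1]
    stop("line ", i, ": self-edge ", reg[i], " -> ", tgt[i])
  }
  gold_standard(
    tibble::tibble(regulator = reg[keep], target = tgt[keep]),
    genes = sort(unique(c(reg, tgt)))
  )
}

empty_edges <- function() {
  tibble::tibble(regulator = character(), target = character(),
                 sign = character(), rate = numeric(),
                 window = integer(), delta_bic = numeric())
}

#' Inferred gene regulatory network
#'
#' Directed signed edge set with kinetic rate estimates, the window each
#' edge was inferred in, external inputs, and per-gene activation times and
#' zones.
#'
#' @param genes gene identifiers.
#' @param edges tibble with columns `regulator`, `target`, `sign` ("+" or
#'   "-"), `rate`, `window`, and optionally `delta_bic` (BIC improvement
#'   over the null model in the deciding window).
#' @param inputs tibble of external inputs: `gene`, `type` ("constant" or
#'   "sigmoid") and parameter columns.
#' @param activation tibble with `gene`, `activation_time` (hours, `NA` for
#'   never-activated genes) and `zone`.
#' @param config the resolved run configuration (echoed into outputs).
#' @param trace optional inference trace.
#' @return an object of class `grn_network`.
#' @export
grn_network <- function(genes, edges = NULL, inputs = NULL,
                        activation = NULL, config = NULL, trace = NULL) {
  genes <- as.character(genes)
  if (is.null(edges) || !nrow(tibble::as_tibble(edges))) {
    edges <- empty_edges()
  } else {
    edges <- tibble::as_tibble(edges)
    if (!"delta_bic" %in% names(edges)) edges$delta_bic <- NA_real_
    edges$regulator <- as.character(edges$regulator)
    edges$target <- as.character(edges$target)
    edges$rate <- as.numeric(edges$rate)
    edges$window <- as.integer(edges$window)
    edges$delta_bic <- as.numeric(edges$delta_bic)
    missing <- setdiff(c(edges$regulator, edges$target), genes)
    if (length(missing))
      stop("edge endpoints outside gene set: ",
           paste(missing, collapse = ", "))
    if (anyDuplicated(paste(edges$regulator, edges$target)))
      stop("duplicate directed edges")
    edges <- dplyr::arrange(edges, .data$regulator, .data$target)
  }
  if (is.null(inputs))
    inputs <- tibble::tibble(gene = character(), type = character(),
                             level = numeric(), u_max = numeric(),
                             t_half = numeric(), theta = numeric())
  structure(list(genes = genes, edges = edges,
                 inputs = tibble::as_tibble(inputs),
                 activation = if (is.null(activation)) NULL
                              else tibble::as_tibble(activation),
                 config = config, trace = trace),
            class = "grn_network")
}

#' @export
print.grn_network <- function(x, ...) {
  cat("<grn_network> ", length(x$genes), " genes, ", nrow(x$edges),
      " directed edges\n", sep = "")
  if (nrow(x$edges)) {
    arrow <- ifelse(x$edges$sign == "-", " -| ", " -> ")
    cat(paste0("  ", x$edges$regulator, arrow, x$edges$target,
               "  (rate ", signif(x$edges$rate, 3), ", window ",
               x$edges$window, ")\n"), sep = "")
  }
  invisible(x)
}

#' @method tidy grn_network
#' @export
tidy.grn_network <- function(x, ...) x$edges

#' @method glance grn_network
#' @export
glance.grn_network <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$genes), n_edges = nrow(x$edges),
    n_inhibitory = sum(x$edges$sign == "-"),
    n_inputs = nrow(x$inputs),
    n_zones = if (is.null(x$activation)) NA_integer_
              else max(x$activation$zone)
  )
}

#' Write an inferred network
#'
#' `"edge_list"` emits a TSV `regulator target sign rate window` table in a
#' fixed lexicographic order so outputs are bit-stable; `"json"`
#' additionally carries inputs, activation zones and the run configuration,
#' and round-trips losslessly through [read_network()].
#'
#' @param net a [grn_network()].
#' @param file output path.
#' @param format `"edge_list"` or `"json"`.
#' @return `file`, invisibly.
#' @export
write_network <- function(net, file, format = c("edge_list", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "grn_network"))
  if (format == "edge_list") {
    e <- dplyr::arrange(net$edges, .data$regulator, .data$target)
    lines <- c("regulator\ttarget\tsign\trate\twindow",
               if (nrow(e)) paste(e$regulator, e$target, e$sign,
                                  formatC(e$rate, digits = 17, format = "g"),
                                  e$window, sep = "\t"))
    writeLines(lines, file)
  } else {
    doc <- list(
      genes = net$genes,
      edges = net$edges,
      inputs = net$inputs,
      activation = net$activation,
      config = if (!is.null(net$config)) unclass(net$config)
    )
    jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", pretty = TRUE)
  }
  invisible(file)
}

#' Read a network written by [write_network()]
#'
#' @param file path.
#' @param format `"edge_list"` or `"json"`.
#' @return a [grn_network()].
#' @export
read_network <- function(file, format = c("edge_list", "json")) {
  format <- match.arg(format)
  if (format == "edge_list") {
    lines <- readLines(file)
    if (!length(lines) || lines[1] != "regulator\ttarget\tsign\trate\twindow")
      stop("not an edge-list network file")
    if (length(lines) == 1) return(grn_network(character()))
    cells <- strsplit(lines[-1], "\t", fixed = TRUE)
    edges <- tibble::tibble(
      regulator = vapply(cells, `[[`, "", 1L),
      target = vapply(cells, `[[`, "", 2L),
      sign = vapply(cells, `[[`, "", 3L),
      rate = as.numeric(vapply(cells, `[[`, "", 4L)),
      window = as.integer(vapply(cells, `[[`, "", 5L))
    )
    grn_network(sort(unique(c(edges$regulator, edges$target))), edges)
  } else {
    doc <- jsonlite::read_json(file, simplifyVector = TRUE)
    inputs <- if (length(doc$inputs)) {
      tb <- tibble::as_tibble(doc$inputs)
      for (col in c("level", "u_max", "t_half", "theta"))
        if (col %in% names(tb)) tb[[col]] <- as.numeric(tb[[col]])
      tb
    }
    grn_network(
      genes = doc$genes,
      edges = if (length(doc$edges)) tibble::as_tibble(doc$edges),
      inputs = inputs,
      activation = if (length(doc$activation))
        tibble::as_tibble(doc$activation),
      config = doc$config
    )
  }
}
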