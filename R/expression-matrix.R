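#' Expression matrix for one participant
#'
#' A thin wrapper around a numeric genes-by-timepoints matrix carrying the
#' sampling times (hours since the first sample; in the blood study design
#' t = 0 corresponds to 8am clock time) and a participant identifier.
#' Values are nonnegative FPKM-like expression. Timepoints must be
#' non-decreasing; repeated timepoints denote biological replicates (as
#' produced by [fold_duplicates()]). Unique timepoints must be evenly
#' spaced.
#'
#' @param values numeric matrix, one row per gene, one column per sample;
#'   rownames are gene identifiers.
#' @param timepoints numeric vector of sampling times in hours, one per
#'   column. If `NULL`, parsed from column names of the form `"t0"`,
#'   `"t2"`, ...
#' @param participant participant identifier (scalar character).
#' @return An object of class `expr_matrix` (a numeric matrix with
#'   attributes `timepoints` and `participant`).
#' @examples
#' m <- matrix(runif(12, 1, 5), 2, 6,
#'             dimnames = list(c("g1", "g2"), paste0("t", seq(0, 10, 2))))
#' em <- expression_matrix(m)
#' time_points(em)
#' @export
expression_matrix <- function(values, timepoints = NULL,
                              participant = NA_character_) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("'values' must be a numeric matrix")
  if (anyNA(values))
    stopf("expression matrix contains missing values; complete grids are required")
  if (any(values < 0))
    stopf("expression values must be nonnegative")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("gene_%04d", seq_len(nrow(values)))
  if (is.null(timepoints)) {
    cn <- colnames(values)
    if (is.null(cn) || !all(grepl("^t-?[0-9.]+$", cn)))
      stopf("timepoints not given and column names are not of the form 't<hours>'")
    timepoints <- as.numeric(sub("^t", "", cn))
  }
  timepoints <- as.numeric(timepoints)
  if (length(timepoints) != ncol(values))
    stopf("length(timepoints) != ncol(values)")
  if (is.unsorted(timepoints))
    stopf("timepoints must be non-decreasing")
  ut <- unique(timepoints)
  if (length(ut) < 2L) stopf("at least two distinct timepoints required")
  dt <- diff(ut)
  if (max(abs(dt - dt[1])) > 1e-8)
    stopf("unique timepoints must be evenly spaced")
  if (is.null(colnames(values)))
    colnames(values) <- make.unique(paste0("t", timepoints))
  structure(values,
            timepoints = timepoints,
            participant = as.character(participant),
            class = c("expr_matrix", class(values)))
}

#' @rdname expression_matrix
#' @param x an `expr_matrix`.
#' @export
time_points <- function(x) attr(x, "timepoints")

#' @rdname expression_matrix
#' @export
participant_id <- function(x) attr(x, "participant")

#' Sampling interval of an evenly spaced time grid
#' @param x an `expr_matrix` or numeric vector of timepoints.
#' @return interval in hours.
#' @export
sampling_interval <- function(x) {
  tp <- if (inherits(x, "expr_matrix")) time_points(x) else as.numeric(x)
  diff(unique(tp))[1]
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, participant %s\n",
              nrow(x), ncol(x), participant_id(x)))
  tp <- time_points(x)
  cat(sprintf("  timepoints: %sh ... %sh (interval %sh%s)\n",
              min(tp), max(tp), sampling_interval(x),
              if (anyDuplicated(tp)) ", with replicates" else ""))
  print(utils::head(unclass(x)[, seq_len(min(6L, ncol(x))), drop = FALSE], 4L))
  invisible(x)
}

#' Read / write an expression matrix as TSV
#'
#' Dialect: tab-separated, UTF-8, '.' decimal, header
#' `gene<TAB>t0<TAB>t2<TAB>...`, one row per gene.
#'
#' @param path file path.
#' @param participant participant id to attach on read.
#' @return [read_expression_tsv()] returns an `expr_matrix`;
#'   [write_expression_tsv()] returns `path` invisibly.
#' @export
read_expression_tsv <- function(path, participant = NA_character_) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stopf("expected a gene column plus >= 2 timepoints in %s", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  expression_matrix(m, participant = participant)
}

#' @rdname read_expression_tsv
#' @param x an `expr_matrix`.
#' @export
write_expression_tsv <- function(x, path) {
  df <- data.frame(gene = rownames(x), unclass(x), check.names = FALSE)
  colnames(df) <- c("gene", paste0("t", time_points(x)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
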