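#' Shuffle the time labels of an expression matrix
#'
#' Applies one random permutation of the timepoint labels to the columns.
#' By default the *same* permutation is applied to all genes (shared
#' shuffling preserves the gene-gene correlation structure); with
#' `per_gene = TRUE` every gene's values are permuted independently.
#' Either way each gene keeps its multiset of values.
#'
#' @param matrix an [expression_matrix()].
#' @param seed integer seed (`NULL` uses the current RNG state).
#' @param per_gene shuffle each gene independently.
#' @return `expr_matrix` with identical timepoints and permuted values.
#' @export
permute_time_labels <- function(matrix, seed = NULL, per_gene = FALSE) {
  shuffle <- function() {
    X <- unclass(matrix)
    if (per_gene) {
      for (g in seq_len(nrow(X))) X[g, ] <- X[g, sample.int(ncol(X))]
    } else {
      X <- X[, sample.int(ncol(X)), drop = FALSE]
    }
    colnames(X) <- colnames(matrix)
    expression_matrix(X, time_points(matrix), participant_id(matrix))
  }
  if (is.null(seed)) shuffle() else with_private_seed(seed, shuffle())
}

#' Permutation-based FDR for a classified gene list
#'
#' Estimates the false-discovery rate of a detector (e.g. the count of
#' ~12h-classified genes from the pencil decomposition,
#' [pencil_band_counter()]) by running it on `n_permutations` time-label
#' shuffled copies of the matrix with the same classification criteria.
#' The FDR estimate is the ratio of the mean permuted count (false
#' positives, since shuffling destroys any rhythm) to the observed count.
#'
#' @param matrix an [expression_matrix()].
#' @param detector deterministic function(matrix) -> count of classified
#'   genes.
#' @param n_permutations number of shuffles (the original study used
#'   5,000; 200 is a practical desk-scale default).
#' @param seed integer seed driving all shuffles.
#' @param per_gene passed to [permute_time_labels()].
#' @return list of class `permutation_fdr` with `observed_count`,
#'   `permuted_counts`, `n_permutations`, `fdr` (`NA` with a warning when
#'   the observed count is 0), `seed`.
#' @export
estimate_fdr <- function(matrix, detector, n_permutations = 200L,
                         seed = 1L, per_gene = FALSE) {
  if (!is.function(detector)) stopf("detector must be a function")
  if (!is_count(n_permutations) || n_permutations < 1)
    stopf("n_permutations must be a positive count")
  observed <- detector(matrix)
  permuted <- with_private_seed(seed, {
    vapply(seq_len(n_permutations), function(b)
      as.numeric(detector(permute_time_labels(matrix, seed = NULL,
                                              per_gene = per_gene))),
      numeric(1))
  })
  fdr <- if (observed > 0) mean(permuted) / observed else {
    warning("observed count is 0; FDR is undefined", call. = FALSE)
    NA_real_
  }
  structure(list(observed_count = observed, permuted_counts = permuted,
                 n_permutations = as.integer(n_permutations),
                 fdr = fdr, seed = seed),
            class = "permutation_fdr")
}

#' @export
print.permutation_fdr <- function(x, ...) {
  cat(sprintf("<permutation_fdr> observed %d, mean permuted %.2f over %d shuffles, FDR = %s\n",
              x$observed_count, mean(x$permuted_counts), x$n_permutations,
              ifelse(is.na(x$fdr), "undefined", sprintf("%.3f", x$fdr))))
  invisible(x)
}
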