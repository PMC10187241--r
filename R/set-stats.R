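#' Chi-square independence test for two gene sets
#'
#' Builds the 2x2 membership table of `setA` x `setB` over the universe
#' and tests independence with Pearson's chi-square (no continuity
#' correction by default, matching large-sample usage; an exact
#' hypergeometric tail is advisable when any expected cell is below 5 and
#' is suggested via a message). Also reports the observed and expected
#' overlap `nA * nB / N`.
#'
#' @param setA,setB character vectors, subsets of `universe`.
#' @param universe character vector of all eligible genes.
#' @param correct apply Yates continuity correction.
#' @return list of class `overlap_result`: `N`, `nA`, `nB`, `observed`,
#'   `expected`, `table`, `chisq`, `p_value`.
#' @export
independence_test <- function(setA, setB, universe, correct = FALSE) {
  if (!length(universe)) stopf("universe is empty")
  universe <- unique(universe)
  setA <- unique(setA); setB <- unique(setB)
  if (length(setdiff(setA, universe)) || length(setdiff(setB, universe)))
    stopf("sets must be subsets of the universe")
  inA <- universe %in% setA
  inB <- universe %in% setB
  N <- length(universe)
  nA <- sum(inA); nB <- sum(inB)
  obs <- sum(inA & inB)
  expected <- nA * nB / N
  tab <- matrix(c(obs, nA - obs, nB - obs, N - nA - nB + obs), 2L, 2L,
                dimnames = list(A = c("in", "out"), B = c("in", "out")))
  if (nA == 0 || nB == 0 || nA == N || nB == N) {
    chisq <- 0; p <- 1
  } else {
    emin <- min(outer(rowSums(tab), colSums(tab)) / N)
    if (emin < 5)
      message("minimum expected cell ", signif(emin, 3),
              " < 5; consider an exact hypergeometric test")
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    chisq <- unname(ct$statistic); p <- ct$p.value
  }
  structure(list(N = N, nA = nA, nB = nB, observed = obs,
                 expected = expected, table = tab, chisq = chisq,
                 p_value = p),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> N=%d, |A|=%d, |B|=%d: observed %d vs expected %.1f (X2=%.3g, p=%.3g)\n",
              x$N, x$nA, x$nB, x$observed, x$expected, x$chisq, x$p_value))
  invisible(x)
}

#' Cross-species conservation overlap
#'
#' Maps a second species' gene set into human identifier space through an
#' ortholog map (reduced to one-to-one: the first listed human ortholog
#' per foreign gene wins), restricts to the expressed universe, and
#' delegates to [independence_test()]. Unmapped foreign ids are counted
#' and excluded.
#'
#' @param human_set character vector of human gene ids.
#' @param other_set character vector of the other species' gene ids.
#' @param ortholog_map data.frame whose first column is the other
#'   species' id and second column the human id.
#' @param expressed_universe human genes expressed in the tissue; the
#'   analysis universe.
#' @return `overlap_result` with extra fields `n_unmapped` and
#'   `mapped_set` (other set in human id space, inside the universe).
#' @export
conservation_overlap <- function(human_set, other_set, ortholog_map,
                                 expressed_universe) {
  stopifnot(ncol(ortholog_map) >= 2)
  map <- ortholog_map[!duplicated(ortholog_map[[1]]), , drop = FALSE]
  hu <- map[[2]][match(other_set, map[[1]])]
  n_unmapped <- sum(is.na(hu))
  if (n_unmapped)
    message(n_unmapped, " foreign id(s) had no ortholog and were excluded")
  mapped <- intersect(unique(hu[!is.na(hu)]), expressed_universe)
  human_in <- intersect(unique(human_set), expressed_universe)
  res <- independence_test(human_in, mapped, expressed_universe)
  res$n_unmapped <- n_unmapped
  res$mapped_set <- mapped
  res
}

#' Three-way set overlap with expected counts under independence
#'
#' Counts the seven intersection regions of three sets over a universe,
#' the expected triple overlap under mutual independence
#' `nA * nB * nC / N^2`, and a chi-square statistic over the 2x2x2
#' membership table against the product of the marginal membership
#' probabilities (df = 4).
#'
#' @param setA,setB,setC character vectors, subsets of `universe`.
#' @param universe character vector.
#' @return list with `N`, sizes `nA`, `nB`, `nC`, `regions` (named counts
#'   `A_only`, ..., `ABC`), `observed_triple`, `expected_triple`,
#'   `chisq`, `df`, `p_value`.
#' @export
three_way_overlap <- function(setA, setB, setC, universe) {
  if (!length(universe)) stopf("universe is empty")
  universe <- unique(universe)
  a <- universe %in% setA
  b <- universe %in% setB
  cc <- universe %in% setC
  N <- length(universe)
  regions <- c(
    A_only = sum(a & !b & !cc), B_only = sum(!a & b & !cc),
    C_only = sum(!a & !b & cc), AB = sum(a & b & !cc),
    AC = sum(a & !b & cc), BC = sum(!a & b & cc), ABC = sum(a & b & cc))
  nA <- sum(a); nB <- sum(b); nC <- sum(cc)
  expected_triple <- nA * nB * nC / N^2
  pa <- nA / N; pb <- nB / N; pc <- nC / N
  chisq <- 0
  for (ia in 0:1) for (ib in 0:1) for (ic in 0:1) {
    o <- sum(a == ia & b == ib & cc == ic)
    e <- N * (if (ia) pa else 1 - pa) * (if (ib) pb else 1 - pb) *
      (if (ic) pc else 1 - pc)
    if (e > 0) chisq <- chisq + (o - e)^2 / e
  }
  df <- 4L  # 8 cells - 1 - 3 estimated marginals
  list(N = N, nA = nA, nB = nB, nC = nC, regions = regions,
       observed_triple = unname(regions["ABC"]),
       expected_triple = expected_triple, chisq = chisq, df = df,
       p_value = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Preranked gene-set enrichment (running-sum statistic)
#'
#' Classic weighted Kolmogorov-Smirnov-like enrichment: genes are walked
#' in ranking order, the running sum is incremented by `|score|^weight /
#' sum(|score_hits|^weight)` at set members and decremented by
#' `1/(N - Nh)` otherwise; the enrichment score ES is the maximum
#' deviation from zero. The null is gene-label permutation: set
#' membership is reassigned uniformly at random `n_permutations` times
#' and the p-value is the (add-one smoothed) fraction of permuted ES at
#' least as extreme on the same side.
#'
#' @param ranked_genes character vector of gene ids, already ordered by
#'   decreasing score.
#' @param scores numeric ranking scores aligned with `ranked_genes`.
#' @param gene_set character vector; must intersect the ranked list.
#' @param n_permutations permutation count (default 1000).
#' @param seed integer seed.
#' @param weight hit-weight exponent (0 gives the unweighted KS-type
#'   statistic; 1 is the classic weighted form).
#' @return list of class `enrichment_result`: `ES`, `p_value`,
#'   `direction` (`"positive"`/`"negative"`), `running_sum`, `hits`
#'   (logical along the list), `n_permutations`.
#' @export
preranked_enrichment <- function(ranked_genes, scores, gene_set,
                                 n_permutations = 1000L, seed = 1L,
                                 weight = 1) {
  N <- length(ranked_genes)
  if (length(scores) != N) stopf("ranked_genes/scores length mismatch")
  hits <- ranked_genes %in% gene_set
  Nh <- sum(hits)
  if (Nh == 0) stopf("gene set does not intersect the ranked list")
  if (Nh == N) stopf("gene set covers the whole ranked list")
  es_of <- function(hits) {
    w <- abs(scores)^weight
    inc <- numeric(N)
    inc[hits] <- w[hits] / sum(w[hits])
    inc[!hits] <- -1 / (N - Nh)
    rs <- cumsum(inc)
    i <- which.max(abs(rs))
    list(ES = rs[i], running_sum = rs)
  }
  obs <- es_of(hits)
  perm <- with_private_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      h <- logical(N)
      h[sample.int(N, Nh)] <- TRUE
      es_of(h)$ES
    }, numeric(1))
  })
  # compare against permuted ES of the same sign (the classic convention;
  # conditional on its sign the null p is uniform)
  p <- if (obs$ES >= 0) {
    same <- perm[perm >= 0]
    (1 + sum(same >= obs$ES)) / (length(same) + 1)
  } else {
    same <- perm[perm < 0]
    (1 + sum(same <= obs$ES)) / (length(same) + 1)
  }
  structure(list(ES = obs$ES, p_value = p,
                 direction = if (obs$ES >= 0) "positive" else "negative",
                 running_sum = obs$running_sum, hits = hits,
                 n_permutations = as.integer(n_permutations)),
            class = "enrichment_result")
}

#' Harmonic-artifact control: are circadian and ~12h calls independent?
#'
#' Non-sinusoidal circadian waveforms carry true ~12h harmonics, so an
#' excess of genes called both circadian and ~12h beyond the independence
#' expectation would indicate that the ~12h calls are harmonic artifacts.
#' To match the number of samples per period between the two scans, the
#' circadian set is built from a 4h-interval subsample of the matrix
#' scanned at the circadian period, while the ~12h set uses the full
#' 2h-interval matrix scanned at 12h; both sets are thresholded at the
#' same alpha and compared with [independence_test()] over all scanned
#' genes. Cumulative set sizes across a ladder of thresholds are also
#' returned.
#'
#' Membership can be defined by the rank scans (`membership = "scan"`,
#' the default, mirroring the published control design) or by the
#' matrix-pencil decomposition (`membership = "pencil"`: a gene is in a
#' band iff it carries a classified component there). The two routes
#' probe different things: rank scans detect non-sinusoidal waveforms at
#' their fundamental period, so their band calls are largely immune to
#' harmonic leakage, whereas spectral decomposition genuinely splits a
#' peaked circadian waveform into a 24h and a ~12h component — the
#' artifact the control is designed to expose.
#'
#' @param matrix an [expression_matrix()] on a 2h grid over 48h (raw; it
#'   is linearly detrended internally).
#' @param circadian_period,ultradian_period scan periods in hours.
#' @param subsample_h interval of the circadian subsample (default 4h).
#' @param alpha membership threshold on the per-period scan p-value.
#' @param B scan Monte-Carlo null size.
#' @param thresholds ladder for the cumulative size curves.
#' @param membership `"scan"` or `"pencil"` (see above).
#' @param rules [classification_rules()] for the pencil membership.
#' @return list with `overlap` (an `overlap_result`), `set_circadian`,
#'   `set_ultradian`, `curves` (data.frame threshold x set sizes; scan
#'   membership only), and the underlying scan/decomposition tables.
#' @export
harmonic_control <- function(matrix, circadian_period = 24,
                             ultradian_period = 12, subsample_h = 4,
                             alpha = 0.05, B = 4999L,
                             thresholds = c(0.001, 0.005, 0.01, 0.05, 0.1),
                             membership = c("scan", "pencil"),
                             rules = classification_rules()) {
  membership <- match.arg(membership)
  if (membership == "pencil") {
    tab <- decompose_matrix(matrix, rules)
    genes <- rownames(matrix)
    set24 <- unique(tab$gene[tab$label == "circadian"])
    set12 <- unique(tab$gene[tab$label == "ultradian12"])
    ov <- independence_test(set24, set12, genes)
    return(list(overlap = ov, set_circadian = set24, set_ultradian = set12,
                curves = NULL, components = tab))
  }
  det_full <- detrend_matrix(matrix)
  sub <- subsample_interval(matrix, subsample_h, offset = 0)
  det_sub <- detrend_matrix(sub)
  scan12 <- scan_matrix(det_full, period_grid = ultradian_period, B = B)
  scan24 <- scan_matrix(det_sub, period_grid = circadian_period, B = B)
  genes <- intersect(unique(scan12$gene), unique(scan24$gene))
  p12 <- scan12$p_value[match(genes, scan12$gene)]
  p24 <- scan24$p_value[match(genes, scan24$gene)]
  set12 <- genes[p12 < alpha]
  set24 <- genes[p24 < alpha]
  ov <- independence_test(set24, set12, genes)
  curves <- data.frame(
    threshold = thresholds,
    n_circadian = vapply(thresholds, function(a) sum(p24 < a), 0),
    n_ultradian12 = vapply(thresholds, function(a) sum(p12 < a), 0),
    n_joint = vapply(thresholds, function(a) sum(p24 < a & p12 < a), 0))
  list(overlap = ov, set_circadian = set24, set_ultradian = set12,
       curves = curves, scan_ultradian = scan12, scan_circadian = scan24)
}
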