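# Independent oracles used across tests. These re-derive expected values
# from first principles (enumeration, brute-force definitions) and stay
# independent of the package's computation paths.

tgrid <- function(span = 48, dt = 2) seq(0, span - dt, by = dt)

# small matrix with timepoints attribute (as scan_matrix accepts)
as_scan_input <- function(X, tp) {
  if (is.null(dim(X))) X <- matrix(X, 1L)
  if (is.null(rownames(X))) rownames(X) <- paste0("g", seq_len(nrow(X)))
  attr(X, "timepoints") <- tp
  X
}

# all permutations of 1..n (n <= 7) as a matrix, one permutation per row
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# Cyclic umbrella statistic from its definition, by explicit loops:
# groups are walked from the trough (peak - rise) up to the peak and
# down again; every ordered group pair along each limb contributes a
# Mann-Whitney count (midrank ties).
oracle_umbrella_stat <- function(values, groups, m, peak,
                                 rise = floor(m / 2)) {
  s <- ((peak - rise + seq_len(m) - 2L) %% m) + 1L
  pk <- rise + 1L
  mw <- function(lo, hi) {
    x <- values[groups == lo]; y <- values[groups == hi]
    tot <- 0
    for (xi in x) for (yi in y) tot <- tot + (xi < yi) + 0.5 * (xi == yi)
    tot
  }
  a <- 0
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    if (j <= pk) a <- a + mw(s[i], s[j])
    if (i >= pk) a <- a + mw(s[j], s[i])
  }
  a
}

# Exact p-value by exhaustive enumeration of all value permutations.
oracle_umbrella_p <- function(values, groups, m, peak) {
  obs <- oracle_umbrella_stat(values, groups, m, peak)
  perms <- all_perms(length(values))
  stats <- apply(perms, 1L, function(ix)
    oracle_umbrella_stat(values[ix], groups, m, peak))
  mean(stats >= obs - 1e-9)
}

# Brute-force Benjamini-Hochberg from the step-up definition (same
# floating-point operation order as the standard implementation so that
# results agree exactly).
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- (n / seq_len(n)) * p[o]
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Chi-square upper tail by numerical integration of the density.
oracle_chisq_tail <- function(x, df) {
  if (x <= 0) return(1)
  stats::integrate(function(u) stats::dchisq(u, df), lower = x,
                   upper = Inf, rel.tol = 1e-12)$value
}

# Two-sided exact independence p for a 2x2 table via the hypergeometric
# distribution, as a mid-p (half weight on equally probable outcomes):
# the discreteness-matched exact quantity that the uncorrected
# chi-square approximates.
oracle_hyper_p <- function(obs, nA, nB, N) {
  k <- max(0, nA + nB - N):min(nA, nB)
  pr <- stats::dhyper(k, nA, N - nA, nB)
  p0 <- pr[k == obs]
  sum(pr[pr < p0 * (1 - 1e-7)]) + 0.5 * sum(pr[abs(pr - p0) <= p0 * 1e-7])
}
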