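# Cyclic umbrella rank test for rhythms of arbitrary waveform.
#
# A series sampled on an even grid is phase-folded at a candidate period T
# into m = T/dt phase groups. Under the rhythm alternative the group
# locations rise to a peak and fall again (cyclically). For peak position
# q the statistic is a sum of pairwise Mann-Whitney counts along the
# cyclic umbrella ordering centred on q; the scan combines all m peak
# positions via a deterministic Monte-Carlo permutation null of the
# maximum standardized statistic (cached per group configuration).

.umbrella_cache <- new.env(parent = emptyenv())

# Pair-weight matrix of one cyclic umbrella ordering: groups are walked
# cyclically from the trough (q - rise) up to the peak q over `rise`
# steps, then down over the remaining m - 1 - rise steps. W[a, b] counts
# how often the ordered pair "group a below group b" enters the statistic.
umbrella_ordering_matrix <- function(m, q, rise) {
  s <- ((q - rise + seq_len(m) - 2L) %% m) + 1L
  pk <- rise + 1L  # position of the peak group q within s
  W <- matrix(0, m, m)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    if (j <= pk) W[s[i], s[j]] <- W[s[i], s[j]] + 1
    if (i >= pk) W[s[j], s[i]] <- W[s[j], s[i]] + 1
  }
  W
}

# Full umbrella shape set: every peak position q (1..m) crossed with
# every rise-limb length (1..m-1), as in waveform-agnostic rhythm
# detection (asymmetric rise/fall covers seesaw-like waveforms);
# duplicate weight matrices are removed. Returns the list of matrices
# plus the peak group of each.
umbrella_orderings <- function(m, shapes = c("all", "symmetric")) {
  shapes <- match.arg(shapes)
  if (m < 2) stopf("need at least 2 phase groups")
  rises <- if (shapes == "all") seq_len(m - 1L) else floor(m / 2)
  W <- list(); peak <- integer()
  for (q in seq_len(m)) for (r in rises) {
    W[[length(W) + 1L]] <- umbrella_ordering_matrix(m, q, r)
    peak[length(peak) + 1L] <- q
  }
  keep <- !duplicated(lapply(W, as.vector))
  list(W = W[keep], peak = peak[keep])
}

# Phase-group index (1..m) of each observation; errors on empty groups.
phase_groups <- function(timepoints, period, dt) {
  mr <- period / dt
  if (abs(mr - round(mr)) > 1e-9)
    stopf("period %gh is not a multiple of the sampling interval %gh", period, dt)
  m <- as.integer(round(mr))
  if (m < 2) stopf("period %gh gives fewer than 2 phase groups", period)
  g <- as.integer(round((timepoints %% period) / dt)) + 1L
  if (length(unique(g)) < m)
    stopf("period %gh leaves empty phase groups on this grid", period)
  list(g = g, m = m)
}

# Pairwise observation index vectors and per-ordering weight vectors for
# one concrete group assignment (cached).
umbrella_weights <- function(g, m) {
  key <- paste0("w:m", m, "g", paste(g, collapse = ""))
  hit <- get0(key, envir = .umbrella_cache)
  if (!is.null(hit)) return(hit)
  N <- length(g)
  ords <- umbrella_orderings(m)
  rowi <- rep(seq_len(N), times = N)
  coli <- rep(seq_len(N), each = N)
  Wvec <- vapply(ords$W, function(w) as.vector(w[cbind(g[rowi], g[coli])]),
                 numeric(N * N))
  out <- list(rowi = rowi, coli = coli, Wvec = Wvec, peak = ords$peak,
              n_orderings = ncol(unique(t(Wvec))))
  assign(key, out, envir = .umbrella_cache)
  out
}

# Cached deterministic permutation null for one group configuration:
# Monte-Carlo moments of every ordering statistic and the sorted null
# distribution of the max standardized statistic. Built on the *sorted*
# group vector: the null law depends on the group sizes only, so two
# scans whose observations fall into the same groups in different column
# orders (e.g. continuous vs folded duplicate mode) share one null.
umbrella_null <- function(g, m, B) {
  gs <- sort(g)
  key <- paste0("m", m, "g", paste(gs, collapse = ""), "B", B)
  hit <- get0(key, envir = .umbrella_cache)
  if (!is.null(hit)) return(hit)
  N <- length(g)
  w <- umbrella_weights(gs, m)
  P <- with_private_seed(seed_from_key(key), {
    t(vapply(seq_len(B), function(b) sample.int(N), integer(N)))
  })
  L <- (P[, w$rowi, drop = FALSE] < P[, w$coli, drop = FALSE]) + 0
  A <- L %*% w$Wvec
  mu <- colMeans(A)
  sdv <- pmax(apply(A, 2L, stats::sd), 1e-12)
  Z <- sweep(sweep(A, 2L, mu), 2L, sdv, `/`)
  maxZ <- sort(apply(Z, 1L, max))
  out <- list(mu = mu, sd = sdv, maxZ_sorted = maxZ, B = B, m = m,
              n_orderings = w$n_orderings)
  assign(key, out, envir = .umbrella_cache)
  out
}

# Per-gene umbrella statistics for all orderings: X is G x N (rows =
# genes). Returns the G x n_orderings matrix (midrank tie handling).
umbrella_stat_matrix <- function(X, w) {
  Rk <- t(apply(X, 1L, rank))
  if (nrow(X) == 1L) Rk <- matrix(Rk, 1L)
  Ru <- Rk[, w$rowi, drop = FALSE]
  Rv <- Rk[, w$coli, drop = FALSE]
  ((Ru < Rv) + 0.5 * (Ru == Rv)) %*% w$Wvec
}

# Enumerate all distinct assignments of N observations to groups with the
# given sizes (group labels in position order). Rows = assignments.
enum_assignments <- function(sizes) {
  N <- sum(sizes)
  out <- vector("list", 0L)
  g <- integer(N)
  rec <- function(avail, si) {
    if (si == length(sizes)) {
      g[avail] <<- si
      out[[length(out) + 1L]] <<- g
      g[avail] <<- 0L
      return(invisible())
    }
    cmb <- utils::combn(avail, sizes[si])
    for (cc in seq_len(ncol(cmb))) {
      idx <- cmb[, cc]
      g[idx] <<- si
      rec(setdiff(avail, idx), si + 1L)
      g[idx] <<- 0L
    }
  }
  rec(seq_len(N), 1L)
  do.call(rbind, out)
}

n_assignments <- function(sizes) {
  exp(lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1)))
}

#' Umbrella rank test at a single period and peak position
#'
#' Phase-folds the series at `period` into `m = period/dt` groups and
#' tests the cyclic umbrella alternative (locations rise to the peak group
#' and fall again) with a sum of pairwise Mann-Whitney counts along the
#' umbrella ordering. The p-value comes from exact enumeration of all
#' distinct group assignments when their number is at most `exact_limit`,
#' otherwise from a normal approximation whose mean and variance are taken
#' from the deterministic cached permutation null (the closed-form
#' Mack-Wolfe variance applies to a linear umbrella, not this cyclic one).
#' Ties are handled by midrank counting.
#'
#' @param series numeric vector.
#' @param timepoints evenly spaced times (hours), same length.
#' @param period candidate period (hours); must be a multiple of the
#'   sampling interval.
#' @param peak_index peak phase-group position, 1..m (group `k` collects
#'   phases `(k-1)*dt`).
#' @param exact_limit enumeration cutoff (number of distinct assignments).
#' @param B permutation-null size for the normal approximation.
#' @return p-value in (0, 1].
#' @export
umbrella_test <- function(series, timepoints, period, peak_index,
                          exact_limit = 2e5, B = 4999L) {
  N <- length(series)
  if (length(timepoints) != N) stopf("series/timepoints length mismatch")
  dt <- sampling_interval(timepoints)
  pg <- phase_groups(timepoints, period, dt)
  if (!is_count(peak_index) || peak_index < 1 || peak_index > pg$m)
    stopf("peak_index must be in 1..%d", pg$m)
  if (max(series) == min(series)) return(1)
  g <- pg$g
  sizes <- tabulate(g, pg$m)
  W <- umbrella_ordering_matrix(pg$m, peak_index, floor(pg$m / 2))
  Rk <- rank(series)
  Lx <- outer(Rk, Rk, `<`) + 0.5 * outer(Rk, Rk, `==`)
  diag(Lx) <- 0
  rowu <- rep(seq_len(N), times = N)  # pair index u, cycling fastest
  colv <- rep(seq_len(N), each = N)
  lx <- as.vector(Lx)                 # Lx[u, v] in the same (u fastest) order
  A_obs <- sum(W[cbind(g[rowu], g[colv])] * lx)
  if (n_assignments(sizes) <= exact_limit) {
    # observations are exchangeable under H0, so enumerating all distinct
    # group-label assignments over the fixed value vector is the exact
    # conditional null.
    asg <- enum_assignments(sizes)
    stats <- apply(asg, 1L, function(gg)
      sum(W[cbind(gg[rowu], gg[colv])] * lx))
    p <- mean(stats >= A_obs - 1e-9)
  } else {
    # permutation-estimated moments of this single statistic (cached,
    # deterministic seed derived from the configuration)
    key <- paste0("single:m", pg$m, "q", peak_index, "g",
                  paste(g, collapse = ""), "B", B)
    mom <- get0(key, envir = .umbrella_cache)
    if (is.null(mom)) {
      wv <- as.vector(W[cbind(g[rowu], g[colv])])
      P <- with_private_seed(seed_from_key(key), {
        t(vapply(seq_len(as.integer(B)), function(b) sample.int(N), integer(N)))
      })
      Anull <- ((P[, rowu, drop = FALSE] < P[, colv, drop = FALSE]) + 0) %*% wv
      mom <- list(mu = mean(Anull), sd = max(stats::sd(Anull), 1e-12))
      assign(key, mom, envir = .umbrella_cache)
    }
    p <- stats::pnorm((A_obs - mom$mu) / mom$sd, lower.tail = FALSE)
  }
  min(max(p, .Machine$double.xmin), 1)
}
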