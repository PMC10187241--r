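#' Fisher's method for combining independent p-values
#'
#' Combines k p-values into `X2 = -2 * sum(log(p_i))`, referred to the
#' upper tail of a chi-square distribution with `2k` degrees of freedom.
#' Participants are treated as independent studies of the same null
#' hypothesis (no rhythm).
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @param p_floor values of exactly 0 are clamped here (with a warning)
#'   to avoid `log(0)`.
#' @return list with `X2`, `df = 2k`, `meta_p`.
#' @export
fisher_combine <- function(p_values, p_floor = 1e-300) {
  p <- as.numeric(p_values)
  if (!length(p)) stopf("no p-values to combine")
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stopf("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warning("p-value of 0 clamped to the floor ", p_floor, call. = FALSE)
    p[p == 0] <- p_floor
  }
  X2 <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(X2 = X2, df = df,
       meta_p = stats::pchisq(X2, df = df, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment (a thin wrapper over
#' [stats::p.adjust()] keeping the package vocabulary).
#'
#' @param p_values numeric vector in (0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) stats::p.adjust(p_values, method = "BH")

#' Combine per-participant rhythm scans into a meta table
#'
#' Takes one [scan_matrix()] table per participant, restricts to the
#' genes and periods present in all of them (dropped genes are reported
#' via a message), and computes one Fisher combination per (gene,
#' period). `meta_adj_p` is the BH adjustment of `meta_p` across genes
#' *within each period*.
#'
#' @param scans list of scan tables (`gene`, `period_h`, `p_value`, ...).
#' @param period_grid optional period subset; defaults to the periods
#'   common to all scans.
#' @return data.frame with columns `gene`, `period_h`,
#'   `p_1` ... `p_k`, `X2`, `df`, `meta_p`, `meta_adj_p`.
#' @export
build_meta_table <- function(scans, period_grid = NULL) {
  k <- length(scans)
  if (k < 1) stopf("need at least one scan table")
  genes <- Reduce(intersect, lapply(scans, function(s) unique(s$gene)))
  dropped <- unique(unlist(lapply(scans, function(s)
    setdiff(unique(s$gene), genes))))
  if (length(dropped))
    message(length(dropped), " gene(s) absent from some participant were excluded")
  periods <- Reduce(intersect, lapply(scans, function(s) unique(s$period_h)))
  if (!is.null(period_grid)) periods <- intersect(periods, period_grid)
  if (!length(genes) || !length(periods))
    stopf("no common genes/periods across participants")
  pm <- lapply(seq_len(k), function(i) {
    s <- scans[[i]]
    s <- s[s$gene %in% genes & s$period_h %in% periods, ]
    # matrix genes x periods of p-values
    m <- matrix(NA_real_, length(genes), length(periods),
                dimnames = list(genes, periods))
    m[cbind(match(s$gene, genes), match(s$period_h, periods))] <- s$p_value
    m
  })
  out <- vector("list", length(periods))
  for (j in seq_along(periods)) {
    P <- vapply(pm, function(m) m[, j], numeric(length(genes)))
    if (length(genes) == 1L) P <- matrix(P, 1L)
    P[P == 0] <- 1e-300
    X2 <- -2 * rowSums(log(P))
    meta_p <- stats::pchisq(X2, df = 2 * k, lower.tail = FALSE)
    d <- data.frame(gene = genes, period_h = periods[j],
                    stringsAsFactors = FALSE)
    for (i in seq_len(k)) d[[paste0("p_", i)]] <- P[, i]
    d$X2 <- X2
    d$df <- 2L * k
    d$meta_p <- meta_p
    d$meta_adj_p <- bh_adjust(meta_p)
    out[[j]] <- d
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify genes into period bands from a meta table
#'
#' A gene belongs to a band iff its *minimal* meta p-value over the
#' band's period window passes the threshold. With `use = "meta_adj_p"`
#' (the default) BH is applied across genes to the per-gene window-minimum
#' p-value *within each band* before thresholding (so each band has its
#' own FDR); `use = "meta_p"` thresholds the raw combined p-value. Bands
#' are not exclusive: a gene can be both circadian and ultradian.
#'
#' @param meta_table from [build_meta_table()].
#' @param bands named list of `c(lo, hi)` period windows in hours
#'   (defaults: circadian 18-24h, ultradian12 10-14h).
#' @param alpha significance threshold in (0, 1).
#' @param use `"meta_adj_p"` (per-band BH FDR) or `"meta_p"`.
#' @param window_correction multiplicity handling for the minimum over
#'   the `w` grid periods inside a band window: `"bonferroni"` (default;
#'   the window minimum is multiplied by `w` before BH, so the band-level
#'   FDR is honestly controlled) or `"none"` (raw window minimum).
#' @return data.frame with one row per gene: `gene`, one logical column
#'   per band, and per-band `<band>_p` (window-minimum meta p, after the
#'   window correction) and `<band>_adj_p` columns.
#' @export
classify_bands <- function(meta_table,
                           bands = list(circadian = c(18, 24),
                                        ultradian12 = c(10, 14)),
                           alpha = 0.05,
                           use = c("meta_adj_p", "meta_p"),
                           window_correction = c("bonferroni", "none")) {
  use <- match.arg(use)
  window_correction <- match.arg(window_correction)
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  genes <- unique(meta_table$gene)
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  if (!nrow(meta_table)) {
    for (nm in names(bands)) out[[nm]] <- logical(0)
    return(out)
  }
  for (nm in names(bands)) {
    w <- bands[[nm]]
    sub <- meta_table[meta_table$period_h >= w[1] & meta_table$period_h <= w[2], ]
    pmin_g <- rep(NA_real_, length(genes))
    if (nrow(sub)) {
      agg <- tapply(sub$meta_p, sub$gene, min)
      nper <- length(unique(sub$period_h))
      if (window_correction == "bonferroni")
        agg <- pmin(agg * nper, 1)
      pmin_g[match(names(agg), genes)] <- as.numeric(agg)
    }
    adj_g <- bh_adjust(pmin_g)
    out[[paste0(nm, "_p")]] <- pmin_g
    out[[paste0(nm, "_adj_p")]] <- adj_g
    crit <- if (use == "meta_adj_p") adj_g else pmin_g
    out[[nm]] <- !is.na(crit) & crit < alpha
  }
  out
}
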