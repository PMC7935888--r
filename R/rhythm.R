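#' Cosine reference waveforms for the rank-correlation rhythm test
#'
#' Builds the set of rank-transformed cosine references
#' \eqn{\cos(2\pi (t - \phi)/P)} evaluated at the observed timepoints, for
#' all periods P that are multiples of the sampling interval inside the
#' period window and all phases \eqn{\phi} on the phase grid. References
#' whose rank vectors coincide (aliases, e.g. a phase equal to the period)
#' are de-duplicated; the count of distinct references is the Bonferroni
#' factor of \code{\link{rhythm_test}}.
#'
#' @param timepoints sampling times in hours (duplicates allowed for
#'   replicate columns); the sampling interval is the smallest positive gap
#'   between distinct times.
#' @param period_window numeric length-2, period search window in hours.
#'   The default 12-24 h window spans the circadian range testable from a
#'   3-hourly 24 h design.
#' @param phase_step phase grid spacing in hours; defaults to the sampling
#'   interval.
#' @return object of class \code{"rhythm_refs"}: list with \code{params}
#'   (data.frame period, phase per distinct reference), \code{values}
#'   (reference cosine values, references x timepoints), \code{ranks}
#'   (matching rank vectors), \code{n_distinct}, \code{timepoints}.
#' @examples
#' refs <- reference_waveforms(seq(0, 21, by = 3))
#' unique(refs$params$period)  # 12 15 18 21 24
#' @export
reference_waveforms <- function(timepoints, period_window = c(12, 24),
                                phase_step = NULL) {
  .assert(length(timepoints) >= 4, "need >= 4 timepoints")
  tp <- as.numeric(timepoints)
  ut <- sort(unique(tp))
  .assert(length(ut) >= 2, "need >= 2 distinct timepoints")
  delta <- min(diff(ut))
  span <- max(ut) - min(ut)
  .assert(period_window[1] <= period_window[2], "invalid period window")
  .assert(period_window[1] >= 2 * delta && period_window[2] <= span + delta,
          sprintf("period window must lie within [%g, %g] h", 2 * delta,
                  span + delta))
  if (is.null(phase_step)) phase_step <- delta

  periods <- seq(ceiling(period_window[1] / delta) * delta,
                 floor(period_window[2] / delta) * delta, by = delta)
  .assert(length(periods) >= 1, "no candidate period in window")

  params <- do.call(rbind, lapply(periods, function(P) {
    data.frame(period = P, phase = seq(0, P - phase_step, by = phase_step))
  }))
  vals <- t(apply(params, 1, function(pr) {
    round(cos(2 * pi * (tp - pr[["phase"]]) / pr[["period"]]), 9)
  }))
  rks <- t(apply(vals, 1, rank, ties.method = "average"))
  keep <- !duplicated(apply(rks, 1, paste, collapse = ","))
  out <- list(params = params[keep, , drop = FALSE],
              values = vals[keep, , drop = FALSE],
              ranks = rks[keep, , drop = FALSE],
              n_distinct = sum(keep), timepoints = tp)
  class(out) <- "rhythm_refs"
  out
}

#' Exact null distribution of the Kendall S statistic against a tied reference
#'
#' Distribution of \eqn{S = C - D} (concordant minus discordant pairs)
#' between a fixed reference ranking with tie groups of the given sizes and
#' a uniformly random permutation of distinct data values. Pairs inside a
#' reference tie group contribute 0, so \eqn{S = M - 2D} where M is the
#' number of cross-group pairs and D is the number of inversions of a
#' uniformly random multiset permutation with those multiplicities. The
#' inversion distribution is the normalized Gaussian (q-)multinomial
#' coefficient, computed by dynamic-programming polynomial convolution; no
#' enumeration is involved, so n up to the full multi-day design (24+
#' columns) is exact.
#'
#' @param tie_groups integer vector of reference tie-group sizes (sums to n);
#'   with \code{as_ranks = TRUE}, a reference rank vector from which group
#'   sizes are tabulated instead.
#' @param as_ranks interpret \code{tie_groups} as a rank vector.
#' @return list with \code{S} (support, decreasing by 2 from M to -M),
#'   \code{prob} (point masses summing to 1), \code{M} (max |S|).
#' @examples
#' d <- kendall_exact_null(c(1, 1, 1))   # n = 3, no ties
#' rbind(d$S, d$prob)                    # masses 1/6, 2/6, 2/6, 1/6
#' @export
kendall_exact_null <- function(tie_groups, as_ranks = FALSE) {
  g <- as.numeric(tie_groups)
  if (isTRUE(as_ranks)) g <- as.numeric(table(g))
  .assert(all(g >= 1), "tie group sizes must be >= 1")
  n <- sum(g)
  M <- (n^2 - sum(g^2)) / 2  # cross-group pairs

  # probability vector over inversion counts 0..M, built by convolving the
  # interleaving-inversion distribution (Gaussian binomial [s+k, k]_q,
  # normalized) for each successive tie group.
  p <- 1
  s <- 0
  for (k in g) {
    if (s > 0) {
      q <- .gaussian_binomial(s + k, k)
      p <- .convolve_full(p, q / sum(q))
    }
    s <- s + k
  }
  list(S = M - 2 * (seq_along(p) - 1), prob = p, M = M)
}

# Coefficients of the Gaussian binomial [n, k]_q as a numeric vector
# (constant term first), via the product form
# prod_{i=1..k} (1 - q^{n-k+i}) / (1 - q^i); degree (n-k) * k.
.gaussian_binomial <- function(n, k) {
  s <- n - k
  if (k == 0 || s == 0) return(1)
  deg <- s * k
  poly <- c(1, numeric(deg))
  for (i in seq_len(k)) {
    # multiply by (1 - q^{s+i})
    shift <- s + i
    upto <- length(poly) - shift
    if (upto >= 1) poly[(shift + 1):length(poly)] <-
        poly[(shift + 1):length(poly)] - poly[1:upto]
    # divide by (1 - q^i): b[j] = a[j] + b[j - i]
    if (length(poly) > i) for (j in (i + 1):length(poly))
      poly[j] <- poly[j] + poly[j - i]
  }
  poly
}

.convolve_full <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# Two-sided exact tail P(|S| >= |s_obs|) from a null returned by
# kendall_exact_null. Distribution is symmetric about 0.
.kendall_tail2 <- function(null, s_obs) {
  sum(null$prob[abs(null$S) >= abs(s_obs) - 1e-9])
}

#' Nonparametric rhythm test of expression series against cosine references
#'
#' For each gene the Kendall S statistic between the observed series and
#' every distinct rank reference is computed; the per-reference two-sided
#' exact tail probability comes from \code{\link{kendall_exact_null}} for
#' the reference's tie pattern, and the gene p-value is the Bonferroni
#' bound (minimum reference p times the number of distinct references,
#' capped at 1). The best reference gives period and acrophase; amplitude
#' is half the fitted peak-to-trough range of a least-squares cosine at the
#' best (period, phase). Constant series score p = 1, amplitude 0. Because
#' the statistic is computed on ranks, p-values are invariant under strictly
#' monotone transforms of the data.
#'
#' @param x numeric matrix genes x timepoints (a single series may be given
#'   as a vector), all values finite.
#' @param refs references from \code{\link{reference_waveforms}} built on
#'   the same timepoints; or NULL to build them with \code{period_window}.
#' @param period_window used when \code{refs} is NULL.
#' @param timepoints used when \code{refs} is NULL.
#' @param q_threshold FDR threshold for the \code{rhythmic} flag.
#' @return data.frame of class calls: gene_id, period, acrophase, amplitude,
#'   p_value, q_value, rhythmic.
#' @examples
#' t <- seq(0, 21, by = 3)
#' x <- rbind(peaked = cos(2 * pi * (t - 6) / 24), flat = rep(1, 8))
#' rhythm_test(x, timepoints = t)
#' @export
rhythm_test <- function(x, refs = NULL, period_window = c(12, 24),
                        timepoints = NULL, q_threshold = 0.05) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list("series1", NULL))
  .assert(all(is.finite(x)), "expression values must be finite")
  if (is.null(refs)) {
    .assert(!is.null(timepoints), "supply refs or timepoints")
    refs <- reference_waveforms(timepoints, period_window)
  }
  n <- length(refs$timepoints)
  .assert(ncol(x) == n, "series length must match reference length")
  .assert(!anyDuplicated(rownames(x)), "duplicate gene ids")

  pair <- combn(n, 2)
  i <- pair[1, ]; j <- pair[2, ]
  # sign of pairwise differences for references (fixed) and data
  SR <- apply(refs$ranks, 1, function(r) sign(r[j] - r[i]))   # npair x nref
  SX <- t(apply(x, 1, function(v) sign(v[j] - v[i])))         # ngene x npair
  if (nrow(x) == 1) SX <- matrix(SX, nrow = 1)
  S <- SX %*% SR                                              # ngene x nref

  # exact null per distinct tie pattern of the references
  pat <- apply(refs$ranks, 1, function(r) paste(sort(table(r)), collapse = ","))
  nulls <- lapply(unique(pat), function(p) {
    kendall_exact_null(as.numeric(strsplit(p, ",")[[1]]), as_ranks = FALSE)
  })
  names(nulls) <- unique(pat)

  nref <- refs$n_distinct
  P <- matrix(1, nrow(x), nref)
  for (r in seq_len(nref)) {
    null <- nulls[[pat[r]]]
    # tail lookup vectorized over genes via the ordered support
    P[, r] <- vapply(S[, r], function(s) .kendall_tail2(null, s), numeric(1))
  }

  # a reference and its half-period shift give S of opposite sign and the
  # same two-sided tail; among minimal-p references take the largest S so
  # the acrophase is the in-phase one
  best <- vapply(seq_len(nrow(x)), function(g) {
    cand <- which(P[g, ] <= min(P[g, ]) + 1e-15)
    cand[which.max(S[g, cand])]
  }, integer(1))
  p_gene <- pmin(1, P[cbind(seq_len(nrow(x)), best)] * nref)
  constant <- apply(x, 1, function(v) diff(range(v)) == 0)
  p_gene[constant] <- 1

  period <- refs$params$period[best]
  phase <- refs$params$phase[best]
  amp <- vapply(seq_len(nrow(x)), function(g) {
    if (constant[g]) return(0)
    cc <- cos(2 * pi * (refs$timepoints - phase[g]) / period[g])
    cc <- cc - mean(cc)
    if (sum(cc^2) == 0) return(0)
    abs(sum((x[g, ] - mean(x[g, ])) * cc) / sum(cc^2))
  }, numeric(1))
  amp[constant] <- 0

  q <- adjust_fdr(p_gene)
  data.frame(gene_id = rownames(x) %||% sprintf("series%d", seq_len(nrow(x))),
             period = period, acrophase = phase %% period, amplitude = amp,
             p_value = p_gene, q_value = q,
             rhythmic = q < q_threshold & !constant,
             stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg step-up q-values
#'
#' Thin wrapper over \code{stats::p.adjust(method = "BH")}; q-values are the
#' monotone step-up quantities \eqn{q_i = \min_{j \ge i} m p_{(j)} / j}.
#'
#' @param p p-values in (0, 1].
#' @return q-values in the input order; empty input gives empty output.
#' @export
adjust_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  .assert(all(p > 0 & p <= 1), "p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}
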