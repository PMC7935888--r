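#' Standardize time-course profiles for soft clustering
#'
#' Per gene: \code{x -> log10(x + pseudocount)}, then center to mean 0 and
#' scale to population standard deviation 1 (divisor n), the
#' log-homogenization used before soft clustering of expression time
#' courses. Genes whose log profile has zero variance carry no shape
#' information and are flagged for exclusion.
#'
#' @param x non-negative genes x timepoints matrix.
#' @param pseudocount added before the log; keep 0 only when all values are
#'   positive.
#' @return list with \code{profiles} (standardized matrix, zero-variance
#'   rows dropped) and \code{flagged} (ids of excluded zero-variance genes).
#' @export
standardize_profiles <- function(x, pseudocount = 0.01) {
  .assert(all(x >= 0), "expression values must be non-negative")
  lx <- log10(x + pseudocount)
  mu <- rowMeans(lx)
  sdp <- sqrt(rowMeans((lx - mu)^2))
  flagged <- rownames(x)[sdp == 0] %||% which(sdp == 0)
  .assert(any(sdp > 0), "all profiles have zero variance; nothing to cluster")
  z <- (lx - mu) / sdp
  list(profiles = z[sdp > 0, , drop = FALSE], flagged = flagged)
}

#' Fuzzy c-means clustering of standardized profiles
#'
#' Soft clustering with fuzzifier m by alternating optimization: centers
#' \eqn{v_i = \sum_j u_{ij}^m x_j / \sum_j u_{ij}^m}, memberships
#' \eqn{u_{ij} = 1 / \sum_k (d_{ij}/d_{kj})^{2/(m-1)}} with Euclidean
#' distance d. A profile coinciding with one or more centers gets its
#' membership split equally over those centers. Initial memberships are
#' seeded random row-stochastic weights; iteration stops when the largest
#' membership change falls below \code{tol} or at \code{max_iter}. The
#' defaults c = 12 and m = 1.25 are the parameters used for soft clustering
#' of detoxification-gene time courses.
#'
#' @param profiles genes x timepoints matrix (standardized; see
#'   \code{\link{standardize_profiles}}).
#' @param c number of clusters (>= 2).
#' @param m fuzzifier (> 1).
#' @param tol convergence tolerance on max |membership change|.
#' @param max_iter iteration cap.
#' @param seed integer seed for the initial memberships.
#' @param init optional genes x c initial membership matrix (rows summing to
#'   1), overriding the seeded initialization; used for oracle comparisons.
#' @return object of class \code{"fuzzy_clustering"}: list with
#'   \code{memberships} (genes x c, rows sum to 1), \code{centers}
#'   (c x timepoints), \code{objective_trace}
#'   (\eqn{J = \sum u^m d^2} per iteration, non-increasing),
#'   \code{iterations}, \code{converged}, and the parameters.
#' @export
fuzzy_cmeans <- function(profiles, c = 12, m = 1.25, tol = 1e-6,
                         max_iter = 1000, seed = 1L, init = NULL) {
  .assert(c >= 2, "c must be >= 2")
  .assert(m > 1, "fuzzifier m must be > 1")
  x <- as.matrix(profiles)
  n <- nrow(x)
  .assert(nrow(unique(x)) >= c, "need at least c distinct profiles")

  if (is.null(init)) {
    set.seed(as.integer(seed))
    u <- matrix(runif(n * c), n, c)
    u <- u / rowSums(u)
  } else {
    u <- as.matrix(init)
    .assert(nrow(u) == n && ncol(u) == c, "init must be genes x c")
    .assert(max(abs(rowSums(u) - 1)) < 1e-8, "init rows must sum to 1")
  }

  trace <- numeric(0)
  converged <- FALSE
  iter <- 0
  centers <- NULL
  repeat {
    iter <- iter + 1
    um <- u^m
    centers <- (t(um) %*% x) / colSums(um)
    # squared Euclidean distances genes x c
    d2 <- outer(rowSums(x^2), rep(1, c)) + outer(rep(1, n), rowSums(centers^2)) -
      2 * x %*% t(centers)
    d2[d2 < 0] <- 0
    u_new <- matrix(0, n, c)
    zero <- d2 <= .Machine$double.eps
    hit <- rowSums(zero) > 0
    if (any(hit)) u_new[hit, ] <- zero[hit, , drop = FALSE] /
        rowSums(zero[hit, , drop = FALSE])
    if (any(!hit)) {
      # u_ij = 1 / sum_k (d_ij/d_kj)^{2/(m-1)}; on the d^2 scale the weight
      # is d2^{-1/(m-1)}
      w <- d2[!hit, , drop = FALSE]^(-1 / (m - 1))
      u_new[!hit, ] <- w / rowSums(w)
    }
    trace <- c(trace, sum(u_new^m * d2))
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  rownames(u) <- rownames(x)
  colnames(centers) <- colnames(x)
  out <- list(memberships = u, centers = centers, objective_trace = trace,
              iterations = iter, converged = converged, c = c, m = m,
              tol = tol, seed = if (is.null(init)) as.integer(seed) else NA_integer_)
  class(out) <- "fuzzy_clustering"
  out
}

#' @export
print.fuzzy_clustering <- function(x, ...) {
  cat(sprintf("fuzzy c-means: %d genes, c = %d, m = %g, %d iteration(s)%s\n",
              nrow(x$memberships), x$c, x$m, x$iterations,
              if (x$converged) " (converged)" else " (iteration cap)"))
  invisible(x)
}

#' Per-cluster modal peak time and member count
#'
#' Hard-assigns each gene to its argmax-membership cluster (membership ties
#' go to the lowest cluster index) and reports, per cluster, the member
#' count and the modal peak timepoint of members' profiles (ties toward the
#' earliest timepoint).
#'
#' @param clustering a \code{\link{fuzzy_cmeans}} result.
#' @param profiles the matrix that was clustered (used for peak calling).
#' @param timepoints hours for the profile columns.
#' @return data.frame: cluster, n_members, modal_peak_hours (NA for empty
#'   clusters).
#' @export
cluster_phase_summary <- function(clustering, profiles, timepoints) {
  u <- clustering$memberships
  .assert(nrow(u) == nrow(profiles), "profiles must match the clustering")
  hard <- apply(u, 1, which.max)  # which.max takes the first maximum: ties low
  peak <- timepoints[apply(profiles, 1, which.max)]
  out <- data.frame(cluster = seq_len(ncol(u)), n_members = 0L,
                    modal_peak_hours = NA_real_)
  for (k in seq_len(ncol(u))) {
    sel <- hard == k
    out$n_members[k] <- sum(sel)
    if (any(sel)) {
      tab <- table(factor(peak[sel], levels = sort(unique(timepoints))))
      out$modal_peak_hours[k] <- as.numeric(names(tab)[which.max(tab)])
    }
  }
  out
}
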