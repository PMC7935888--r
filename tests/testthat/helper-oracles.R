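# Independent oracles used across the suite. These deliberately use naive
# brute-force formulations, not the package's algorithms.

# All n! permutations of distinct data against a fixed (possibly tied)
# reference: exact distribution of S = concordant - discordant pairs.
brute_force_kendall_null <- function(ref) {
  n <- length(ref)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  S <- vapply(perms(seq_len(n)), function(x) {
    s <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      s <- s + sign(x[j] - x[i]) * sign(ref[j] - ref[i])
    s
  }, numeric(1))
  tab <- table(S)
  list(S = as.numeric(names(tab)), prob = as.numeric(tab) / length(S))
}

# Plain-loop fuzzy c-means update rules, run from a given membership matrix.
brute_force_fcm <- function(x, u, m, tol = 1e-6, max_iter = 1000) {
  n <- nrow(x); c <- ncol(u)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    v <- matrix(0, c, ncol(x))
    for (i in seq_len(c)) {
      num <- rep(0, ncol(x)); den <- 0
      for (j in seq_len(n)) {
        w <- u[j, i]^m
        num <- num + w * x[j, ]
        den <- den + w
      }
      v[i, ] <- num / den
    }
    u_new <- matrix(0, n, c)
    for (j in seq_len(n)) {
      d2 <- vapply(seq_len(c), function(i) sum((x[j, ] - v[i, ])^2), numeric(1))
      if (any(d2 <= .Machine$double.eps)) {
        z <- d2 <= .Machine$double.eps
        u_new[j, z] <- 1 / sum(z)
      } else {
        for (i in seq_len(c)) {
          u_new[j, i] <- 1 / sum((d2[i] / d2)^(1 / (m - 1)))
        }
      }
    }
    J <- 0
    for (j in seq_len(n)) for (i in seq_len(c))
      J <- J + u_new[j, i]^m * sum((x[j, ] - v[i, ])^2)
    trace <- c(trace, J)
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol) break
  }
  list(memberships = u, centers = v, objective_trace = trace)
}

# Position-by-position E-box scan of a character sequence.
brute_force_ebox_scan <- function(s) {
  s <- toupper(s)
  L <- nchar(s)
  if (L < 6) return(data.frame(start = integer(0), motif = character(0)))
  starts <- integer(0); motifs <- character(0)
  for (i in seq_len(L - 5)) {
    w <- substr(s, i, i + 5)
    if (grepl("^CA[ACGT][ACGT]TG$", w)) {
      starts <- c(starts, i); motifs <- c(motifs, w)
    }
  }
  data.frame(start = starts, motif = motifs, stringsAsFactors = FALSE)
}

# Dense-grid least-squares period sweep (independent of estimate_period).
brute_force_period <- function(t, x, window = c(20, 28), step = 0.01) {
  grid <- seq(window[1], window[2], by = step)
  rss <- vapply(grid, function(P) {
    X <- cbind(1, cos(2 * pi * t / P), sin(2 * pi * t / P))
    sum(stats::lm.fit(X, x)$residuals^2)
  }, numeric(1))
  grid[which.min(rss)]
}

# 3-sigma binomial check helper.
within_binomial_3sigma <- function(phat, p, n) {
  abs(phat - p) <= 3 * sqrt(p * (1 - p) / n)
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
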