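# Independent brute-force oracles used to check the package's
# implementations. These deliberately use naive algorithms and closed
# forms, not the code paths they verify.

# O(n^2) nearest-neighbor detachment check on raw coordinates
bf_detached <- function(xy, radius) {
  n <- nrow(xy)
  if (n == 1) return(1L)
  out <- integer(0)
  for (i in seq_len(n)) {
    isolated <- TRUE
    for (j in seq_len(n)) {
      if (i == j) next
      if (sqrt(sum((xy[i, ] - xy[j, ])^2)) <= radius) {
        isolated <- FALSE
        break
      }
    }
    if (isolated) out <- c(out, i)
  }
  out
}

# recursive-stack flood fill, 8-connectivity, counting components
bf_n_components <- function(bin) {
  n <- nrow(bin); m <- ncol(bin)
  seen <- matrix(FALSE, n, m)
  comp <- 0L
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (!bin[i, j] || seen[i, j]) next
    comp <- comp + 1L
    stack <- list(c(i, j))
    seen[i, j] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= n && c >= 1 && c <= m &&
            bin[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  comp
}

# hand-applied Benjamini-Hochberg step-up rule
bf_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(ord)]
}

# exact hypergeometric upper tail by enumerating the pmf with choose()
bf_hyper_p <- function(overlap, n_set, n_univ, n_hits) {
  ks <- overlap:min(n_set, n_hits)
  sum(choose(n_set, ks) * choose(n_univ - n_set, n_hits - ks)) /
    choose(n_univ, n_hits)
}

# closed-form one-sample two-sided t test
bf_one_sample_t_p <- function(x) {
  t_stat <- mean(x) / (sd(x) / sqrt(length(x)))
  2 * pt(-abs(t_stat), df = length(x) - 1)
}

# closed-form Welch two-sample two-sided t test
bf_welch_t_p <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * pt(-abs(t_stat), df = df)
}

# mean silhouette of a 1-D embedding with two groups
bf_silhouette <- function(x, group) {
  n <- length(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- group == group[i]
    a <- mean(abs(x[i] - x[same & seq_len(n) != i]))
    b <- mean(abs(x[i] - x[!same]))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
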