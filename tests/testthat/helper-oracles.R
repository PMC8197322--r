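# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the implementation under test.

# Exact two-sided Mann-Whitney p by enumerating group assignments of the raw
# values and counting x > y pairs directly (ties as 1/2).
oracle_mwu <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  count_u <- function(a, b) {
    u <- 0
    for (ai in a) for (bi in b) u <- u + (ai > bi) + 0.5 * (ai == bi)
    u
  }
  u_obs <- count_u(x, y)
  sets <- utils::combn(length(pool), n1)
  us <- apply(sets, 2, function(idx) count_u(pool[idx], pool[-idx]))
  p <- 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9))
  list(U = u_obs, p = min(1, p))
}

# Direct implementation of the moderated-t moment equations, written
# scalar-style with uniroot for the trigamma inversion.
oracle_ebayes <- function(dct, ref_cols, tst_cols) {
  n1 <- length(ref_cols); n2 <- length(tst_cols)
  dg <- n1 + n2 - 2
  m <- nrow(dct)
  eff <- s2 <- numeric(m)
  for (i in seq_len(m)) {
    a <- dct[i, ref_cols]; b <- dct[i, tst_cols]
    eff[i] <- mean(a) - mean(b)
    s2[i] <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / dg
  }
  e <- log(s2) - digamma(dg / 2) + log(dg / 2)
  ev <- var(e) - trigamma(dg / 2)
  if (is.finite(ev) && ev > 0) {
    half_d0 <- uniroot(function(z) trigamma(z) - ev,
                       lower = 1e-8, upper = 1e8, tol = 1e-12)$root
    d0 <- 2 * half_d0
    s0 <- exp(mean(e) + digamma(half_d0) - log(half_d0))
  } else {
    d0 <- Inf
    s0 <- exp(mean(e))
  }
  post <- if (is.infinite(d0)) rep(s0, m) else (d0 * s0 + dg * s2) / (d0 + dg)
  tmod <- eff / sqrt(post * (1 / n1 + 1 / n2))
  list(d0 = d0, s0_sq = s0, effect = eff, sg_sq = s2, t_mod = tmod,
       p = 2 * pt(-abs(tmod), df = d0 + dg))
}

# Storey q-values straight from the thresholding definition:
# q(p_i) = min over thresholds t >= p_i of pi0 * m * t / #{p <= t}.
oracle_storey <- function(p, lambda = 0.5) {
  m <- length(p)
  pi0 <- min(1, sum(p > lambda) / (m * (1 - lambda)))
  q <- vapply(p, function(pi) {
    ts <- sort(p[p >= pi - 1e-15])
    min(1, min(pi0 * m * ts / vapply(ts, function(t) sum(p <= t + 1e-15), 0)))
  }, 0)
  list(q = q, pi0 = pi0)
}

# Upper-tail hypergeometric probabilities by exhaustive subset enumeration:
# enumerate all size-n subsets of a universe of N genes of which the pathway
# holds the first K, tabulate the overlap, and return P(X >= k) for
# k = 0 .. min(K, n).
oracle_hyper_tails <- function(N, K, n) {
  sets <- utils::combn(N, n)
  overlap <- colSums(sets <= K)
  vapply(0:min(K, n), function(k) mean(overlap >= k), 0)
}

# Brute-force application of the four housekeeping criteria, written as a
# plain script against matrices (no shared code with select_hkgs).
oracle_hkg <- function(ct, ref_cols, tst_cols, median_max = 30, p_min = 0.1,
                       cv_mult = 2, fold = 5, r_min = 0.7) {
  ids <- rownames(ct)
  full <- !apply(is.na(ct), 1, any)
  i_pass <- full & apply(ct, 1, function(v) median(v, na.rm = TRUE)) < median_max
  ii_pass <- i_pass
  for (i in which(i_pass))
    ii_pass[i] <- oracle_mwu(ct[i, ref_cols], ct[i, tst_cols])$p > p_min
  lin <- 2^-ct
  cvs <- rep(NA_real_, length(ids))
  for (i in which(i_pass)) cvs[i] <- sd(lin[i, ]) / mean(lin[i, ])
  thr <- mean(cvs[i_pass]) + cv_mult * sd(cvs[i_pass])
  iii_pass <- ii_pass
  for (i in which(ii_pass)) {
    v <- lin[i, ]
    iii_pass[i] <- cvs[i] < thr &&
      !any(v < mean(v) / fold | v > mean(v) * fold)
  }
  cur <- ids[iii_pass]
  repeat {
    ref <- apply(ct[cur, , drop = FALSE], 2, mean)
    rs <- sapply(cur, function(a) {
      v <- ct[a, ]
      if (sd(v) == 0) 1 else if (sd(ref) == 0) 0 else cor(-v, -ref)
    })
    nxt <- cur[rs > r_min]
    if (identical(nxt, cur)) break
    cur <- nxt
    if (!length(cur)) break
  }
  cur
}
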