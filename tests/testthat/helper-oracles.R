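# Independent oracles used across the suite. Each one is written as the
# most literal, slow derivation of the quantity, deliberately sharing no
# code with the implementation it checks.

# Hardy-Weinberg exact p by full enumeration: list every genotype table
# (nAA', nAa', naa') compatible with the observed individual and allele
# counts, weight it by the number of distinct ways to realise it
# (multinomial x 2^het), normalise empirically, and sum the probabilities
# of tables no more probable than the observed one.
oracle_hwe_enum <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  hets <- integer(0)
  logw <- numeric(0)
  for (b in 0:n) {
    twoa <- nA - b
    if (twoa < 0 || twoa %% 2 != 0) next
    a <- twoa / 2
    cc <- n - a - b
    if (cc < 0) next
    hets <- c(hets, b)
    logw <- c(logw, lfactorial(n) - lfactorial(a) - lfactorial(b) -
                lfactorial(cc) + b * log(2))
  }
  w <- exp(logw - max(logw))
  probs <- w / sum(w)
  obs <- probs[hets == nAa]
  sum(probs[probs <= obs * (1 + 1e-9)])
}

# Brute-force sliding-window ROH oracle for one individual on one
# chromosome: enumerate every window and every SNP score with plain loops.
oracle_roh_instate <- function(g, params) {
  L <- length(g)
  w <- params$window_size
  if (L < w) return(logical(0))
  nwin <- L - w + 1
  ok <- logical(nwin)
  for (s in seq_len(nwin)) {
    win <- g[s:(s + w - 1)]
    ok[s] <- sum(win == 1L, na.rm = TRUE) <= params$max_opp_window &&
      sum(is.na(win)) <= params$max_miss_window
  }
  instate <- logical(L)
  for (j in seq_len(L)) {
    wins <- max(1, j - w + 1):min(nwin, j)
    instate[j] <- mean(ok[wins]) > params$threshold
  }
  instate
}

# ... and the maximal in-state stretches of at least min_snp SNPs.
oracle_roh_runs <- function(g, params) {
  st <- oracle_roh_instate(g, params)
  runs <- list()
  i <- 1
  while (i <= length(st)) {
    if (isTRUE(st[i])) {
      j <- i
      while (j < length(st) && isTRUE(st[j + 1])) j <- j + 1
      if (j - i + 1 >= params$min_snp)
        runs[[length(runs) + 1]] <- c(from = as.integer(i), to = as.integer(j))
      i <- j + 1
    } else i <- i + 1
  }
  runs
}

# Weir-Cockerham two-population theta evaluated step by step from the raw
# genotype vectors of one marker.
oracle_wc_theta <- function(g_high, g_low) {
  g1 <- g_high[!is.na(g_high)]
  g2 <- g_low[!is.na(g_low)]
  r <- 2
  n1 <- length(g1); n2 <- length(g2)
  p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
  h1 <- sum(g1 == 1L) / n1; h2 <- sum(g2 == 1L) / n2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  if (pbar == 0 || pbar == 1) return(NA_real_)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  a / (a + b + cc)
}
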