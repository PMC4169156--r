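# Independent oracles used to cross-check the package's implementations.
# These deliberately use different algorithms/code paths than the package.

# Brute-force finger enumeration: every placement of the C2H2 pattern,
# then the same greedy selection contract (leftmost start, shortest span,
# smallest gaps, non-overlapping).
oracle_find_fingers <- function(sequence, c_gap = c(2L, 4L),
                                ch_gap = c(11L, 14L), h_gap = c(3L, 5L)) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(ch)
  cand <- list()
  for (i in seq_len(n)) {
    if (ch[i] != "C") next
    for (g1 in c_gap[1]:c_gap[2]) for (g2 in ch_gap[1]:ch_gap[2]) for (g3 in h_gap[1]:h_gap[2]) {
      c2 <- i + g1 + 1L; h1 <- c2 + g2 + 1L; h2 <- h1 + g3 + 1L
      if (h2 > n) next
      if (ch[c2] == "C" && ch[h1] == "H" && ch[h2] == "H") {
        cand[[length(cand) + 1L]] <- c(cys1 = i, cys2 = c2, his1 = h1, his2 = h2)
      }
    }
  }
  chosen <- list()
  cursor <- 1L
  while (length(cand)) {
    ok <- Filter(function(m) m["cys1"] >= cursor, cand)
    if (!length(ok)) break
    starts <- vapply(ok, function(m) m[["cys1"]], integer(1))
    ok <- ok[starts == min(starts)]
    spans <- vapply(ok, function(m) m[["his2"]] - m[["cys1"]], integer(1))
    ok <- ok[spans == min(spans)]
    c2s <- vapply(ok, function(m) m[["cys2"]], integer(1))
    ok <- ok[c2s == min(c2s)]
    h1s <- vapply(ok, function(m) m[["his1"]], integer(1))
    pick <- ok[[which.min(h1s)]]
    chosen[[length(chosen) + 1L]] <- pick
    cursor <- pick[["his2"]] + 1L
  }
  if (!length(chosen)) {
    return(data.frame(cys1_pos = integer(), cys2_pos = integer(),
                      his1_pos = integer(), his2_pos = integer()))
  }
  m <- do.call(rbind, chosen)
  data.frame(cys1_pos = m[, "cys1"], cys2_pos = m[, "cys2"],
             his1_pos = m[, "his1"], his2_pos = m[, "his2"])
}

# Direct log-gamma evaluation of the conditional exact HWE distribution
# (no recurrence): P(nAB | n, nA) proportional to
# 2^nAB * n! / (nAA! nAB! naa!) * nA! na! / (2n)!
oracle_hwe_exact <- function(naa, nab, nbb) {
  n <- naa + nab + nbb
  na_cnt <- 2L * naa + nab
  n_rare <- min(na_cnt, 2L * n - na_cnt)
  if (n_rare == 0L) return(1)
  hets <- seq.int(n_rare %% 2L, n_rare, by = 2L)
  logp <- vapply(hets, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - hom_r - h
    h * log(2) + lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(h + 1) -
      lgamma(hom_c + 1) + lgamma(n_rare + 1) + lgamma(2 * n - n_rare + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  p_obs <- probs[match(nab, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Fixed-margin enumeration of the two-sided Fisher exact p-value for a
# 2x2 table (same tie rule as stats::fisher.test).
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  xs <- lo:hi
  d <- dhyper(xs, r1, r2, c1)
  sum(d[d <= d[match(tab[1, 1], xs)] * (1 + 1e-7)])
}

# Direct cell-by-cell KL evaluation with pseudocount + renormalization.
oracle_summed_kl <- function(r, s, pseudocount = 1e-6) {
  norm <- function(m) {
    m <- m + pseudocount
    for (j in seq_len(ncol(m))) m[, j] <- m[, j] / sum(m[, j])
    m
  }
  r <- norm(r); s <- norm(s)
  fwd <- 0; rev <- 0
  for (j in seq_len(ncol(r))) for (b in 1:4) {
    fwd <- fwd + unname(r[b, j] * log(r[b, j] / s[b, j]))
    rev <- rev + unname(s[b, j] * log(s[b, j] / r[b, j]))
  }
  c(forward = fwd, reverse = rev, summed = fwd + rev)
}

# Canonical test finger: C-PE-C-DRRFSRSDELTR-H-IRT-H (helix RSDELTR).
test_finger <- "CPECDRRFSRSDELTRHIRTH"

# A multi-finger protein with chosen linkers and motif-free flanks.
make_zf_protein <- function(linkers, flank = "MAGQSV") {
  paste0(flank, paste0(test_finger,
                       c(linkers, ""), collapse = ""), "GSAVQ")
}

random_pfm <- function(width = 3L) {
  m <- matrix(stats::rgamma(4L * width, shape = 0.7), nrow = 4L,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  sweep(m, 2L, colSums(m), "/")
}
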