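# Independent brute-force oracles used to cross-check the implementation.

# two-sided Fisher p by enumerating every table with the observed margins and
# summing hypergeometric probabilities <= observed (equal-prob ties included)
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- dhyper(lo:hi, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# two-sided Mann-Whitney p by full enumeration of group assignments (tie-free)
mw_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    xx <- pooled[idx]; yy <- pooled[-idx]
    sum(outer(xx, yy, ">"))
  }
  u_obs <- u_of(seq_len(n1))
  mid <- n1 * n2 / 2
  all_u <- combn(n1 + n2, n1, u_of)
  mean(abs(all_u - mid) >= abs(u_obs - mid))
}

# exhaustive gapless local alignment: every sub-window of a against every
# equal-length window of b
align_oracle <- function(a, b, M = neoscreen::blosum62()) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- 0
  for (i in seq_along(av)) for (j in i:length(av)) {
    w <- j - i
    if (w + 1 > length(bv)) next
    for (p in 1:(length(bv) - w)) {
      sc <- sum(M[cbind(av[i:j], bv[p:(p + w)])])
      if (sc > best) best <- sc
    }
  }
  best
}

# all substrings of lengths 8..12 that cover position mut_pos
spanning_oracle <- function(protein, mut_pos, lengths = 8:12) {
  L <- nchar(protein)
  out <- character(0)
  for (k in lengths) {
    if (k > L) next
    for (s in 1:(L - k + 1)) {
      if (s <= mut_pos && mut_pos <= s + k - 1) {
        out <- c(out, substr(protein, s, s + k - 1))
      }
    }
  }
  out
}

random_aa <- function(n) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V"),
               n, replace = TRUE), collapse = "")
}
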