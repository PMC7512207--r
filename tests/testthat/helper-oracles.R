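# Independent brute-force oracles. These deliberately mirror the printed
# definitions with naive double loops / explicit probability tables and share
# no code with the package implementations.

sampen_oracle <- function(x, m, r) {
  n <- length(x)
  nm <- n - m
  A <- 0L; B <- 0L
  for (i in 1:(nm - 1)) {
    for (j in (i + 1):nm) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) < r) {
        B <- B + 1L
        if (abs(x[i + m] - x[j + m]) < r) A <- A + 1L
      }
    }
  }
  if (A == 0L || B == 0L) return(NA_real_)
  -log(A / B)
}

fuzzyen_oracle <- function(x, m, r, nexp) {
  n <- length(x)
  nm <- n - m
  phi <- function(len) {
    tm <- matrix(0, nm, len)
    for (i in 1:nm) {
      v <- x[i:(i + len - 1)]
      tm[i, ] <- v - mean(v)
    }
    total <- 0
    for (i in 1:(nm - 1)) {
      for (j in (i + 1):nm) {
        d <- max(abs(tm[i, ] - tm[j, ]))
        total <- total + exp(-(d^nexp) / r)
      }
    }
    total / (nm * (nm - 1) / 2)
  }
  log(phi(m)) - log(phi(m + 1))
}

# Exhaustive Lempel-Ziv word parser: grows the current word until it no
# longer occurs in the prefix before its last symbol; the trailing
# incomplete word counts as one.
lzc_count_oracle <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  count <- 0L
  start <- 1L
  j <- 1L
  while (j <= n) {
    word <- substr(s, start, j)
    prefix <- substr(s, 1, j - 1)
    if (grepl(word, prefix, fixed = TRUE)) {
      j <- j + 1L
    } else {
      count <- count + 1L
      start <- j + 1L
      j <- start
    }
  }
  if (start <= n) count <- count + 1L
  count
}

# Recover the package's subsequence count from its normalized LZC.
lzc_count_from_value <- function(x) {
  round(eegdx::lempel_ziv_complexity(x) * length(x) / log2(length(x)))
}

# Pick a duplicate-column target whose name sorts after the source so the
# deterministic lexicographic tie-break keeps the original ranked first.
dup_target_after <- function(source, taken) {
  pool <- sort(setdiff(eegdx::feature_names(), taken))
  cand <- pool[pool > source]
  if (!length(cand)) NA_character_ else cand[1]
}

# Symmetrical uncertainty from an explicit joint probability table.
su_oracle <- function(counts) {
  p <- counts / sum(counts)
  h <- function(pv) { pv <- pv[pv > 0]; -sum(pv * log2(pv)) }
  ha <- h(rowSums(p)); hb <- h(colSums(p)); hab <- h(as.vector(p))
  if (ha + hb == 0) return(0)
  2 * (ha + hb - hab) / (ha + hb)
}

# Printed subject-level confusion matrices (actual rows HC, MCI, AD).
reference_confusions <- function() {
  list(
    lda = matrix(c(11, 4, 2, 4, 7, 6, 2, 3, 12), 3, 3, byrow = TRUE),
    qda = matrix(c(13, 3, 1, 4, 7, 6, 3, 3, 11), 3, 3, byrow = TRUE),
    mlp = matrix(c(12, 3, 2, 4, 8, 5, 2, 3, 12), 3, 3, byrow = TRUE))
}
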