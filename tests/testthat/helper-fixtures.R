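# Small in-code fixtures shared across test files.

tinyCube <- function(rows = 2, cols = 2, bands = 3, seed = 1,
                     wavelengths = seq(1000, by = 100,
                                       length.out = bands)) {
  vals <- array(0, c(rows, cols, bands))
  set.seed(seed)
  vals[] <- runif(length(vals))
  Hypercube(vals, wavelengths)
}

constCube <- function(value, rows = 1, cols = 1, bands = 2,
                      wavelengths = seq(1000, by = 100,
                                        length.out = bands)) {
  Hypercube(array(value, c(rows, cols, bands)), wavelengths)
}

# Bilinear factors with pure pixels (identity rows in C) and pure bands
# (zero columns in S rows), the identifiable regime for exact recovery.
pureFactorPair <- function(nPix = 20, nBands = 12, seed = 1) {
  set.seed(seed)
  S <- matrix(runif(2 * nBands, 0.2, 1), 2, nBands)
  S[1, seq(1, nBands, by = 4)] <- 0
  S[2, seq(3, nBands, by = 4)] <- 0
  C <- rbind(diag(2), matrix(runif((nPix - 2) * 2), nPix - 2, 2))
  list(C = C, S = S, D = C %*% S)
}

cosineSim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Best component-to-truth assignment by cosine similarity (permutation
# ambiguity is inherent to bilinear factorization).
bestCosines <- function(Shat, Strue) {
  k <- nrow(Strue)
  perms <- if (k == 2) list(1:2, 2:1) else
    lapply(seq_len(factorial(k)), function(i) {
      p <- seq_len(k)
      # enough for the k <= 3 uses here
      if (k == 3) list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1),
                       c(3,1,2), c(3,2,1))[[i]] else p
    })
  best <- -Inf
  for (p in perms) {
    cs <- vapply(seq_len(k), function(i) cosineSim(Shat[p[i], ], Strue[i, ]),
                 numeric(1))
    if (min(cs) > best) best <- min(cs)
  }
  best
}

# Brute-force Mann-Whitney U: count pairs with x > y, ties half.
bruteU <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}
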