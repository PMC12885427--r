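# Independent oracles used to cross-check the package's alignment code.
# These are deliberately separate implementations (plain dynamic programs in
# R), not calls into the package.

# semi-global (pattern-global, text-local) minimum edit distance; quadratic
# DP with the insertion chain resolved by a running-minimum transform
oracle_semiglobal_edits <- function(pattern, text) {
  p <- strsplit(pattern, "")[[1]]
  t <- strsplit(text, "")[[1]]
  m <- length(p); n <- length(t)
  prev <- rep(0, n + 1) # free start in text
  for (i in seq_len(m)) {
    sub <- prev[1:n] + ifelse(p[i] == t & p[i] != "N" & t != "N", 0, 1)
    del <- prev[2:(n + 1)] + 1
    base <- pmin(sub, del)
    cur <- numeric(n)
    run <- prev[1] + 1 # cur[0]
    for (k in seq_len(n)) {
      run <- min(base[k], run + 1) # insertion chain
      cur[k] <- run
    }
    prev <- c(prev[1] + 1, cur)
  }
  min(prev)
}

# global affine-gap alignment score (three-state Gotoh DP); gap of length L
# costs open + L * ext (both positive penalties)
oracle_affine_score <- function(a, b, submat, open = 10, ext = 1) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # x[i] aligned to y[j]
  X <- matrix(NEG, n + 1, m + 1)  # gap in y (x consumed)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in x (y consumed)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -open - ext * i
  for (j in seq_len(m)) Y[1, j + 1] <- -open - ext * j
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[x[i], y[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# global-alignment identity oracle: LCS length (match-maximising global
# alignment with free gaps/mismatches) over the shorter length
oracle_identity <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  d <- matrix(0L, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1, j + 1] <- if (x[i] == y[j]) d[i, j] + 1L else
        max(d[i, j + 1], d[i + 1, j])
    }
  }
  d[n + 1, m + 1] / min(n, m)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_aa <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}
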