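# Independent oracles used by the tests. These deliberately share no code
# with the implementation.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# position-by-position motif evaluation: for every start, walk the
# pattern one symbol at a time and apply the matching rules literally
oracle_scan <- function(seq, pattern, disc, hydrophobic, max_mismatch) {
  chars <- strsplit(seq, "")[[1]]
  syms <- strsplit(pattern, "")[[1]]
  L <- length(syms)
  hits <- NULL
  if (length(chars) < L) {
    return(data.frame(start = integer(), mismatches = integer()))
  }
  for (s in 1:(length(chars) - L + 1)) {
    mm <- 0
    valid <- TRUE
    for (p in 1:L) {
      r <- chars[s + p - 1]
      m <- if (r == "X") FALSE
           else if (syms[p] == "x") TRUE
           else if (syms[p] == "h") r %in% hydrophobic
           else r == syms[p]
      if (p %in% disc) {
        if (!m) { valid <- FALSE; break }
      } else if (!m) {
        mm <- mm + 1
      }
    }
    if (valid && mm <= max_mismatch) {
      hits <- rbind(hits, data.frame(start = s, mismatches = mm))
    }
  }
  if (is.null(hits)) data.frame(start = integer(), mismatches = integer())
  else hits[order(hits$mismatches, hits$start), , drop = FALSE]
}

# exhaustive affine-gap global alignment by dynamic programming over
# (score, max matches at that score); gap of length L costs open + L*ext
oracle_align <- function(a, b, sub, open, ext) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e18
  sc <- function(i, j) sub[A[i], B[j]]
  best2 <- function(...) {
    cands <- list(...)
    out <- cands[[1]]
    for (c2 in cands[-1]) {
      if (c2[1] > out[1] || (c2[1] == out[1] && c2[2] > out[2])) out <- c2
    }
    out
  }
  M <- X <- Y <- array(NEG, dim = c(n + 1, m + 1, 2))
  M[1, 1, ] <- c(0, 0)
  for (j in 1:m) Y[1, j + 1, ] <- c(-(open + j * ext), 0)
  for (i in 1:n) X[i + 1, 1, ] <- c(-(open + i * ext), 0)
  for (i in 1:n) for (j in 1:m) {
    d <- best2(M[i, j, ], X[i, j, ], Y[i, j, ])
    if (d[1] > NEG / 2) {
      M[i + 1, j + 1, ] <- c(d[1] + sc(i, j), d[2] + (A[i] == B[j]))
    }
    o <- best2(M[i, j + 1, ], Y[i, j + 1, ])
    X[i + 1, j + 1, ] <- best2(
      if (o[1] > NEG / 2) c(o[1] - open - ext, o[2]) else c(NEG, 0),
      if (X[i, j + 1, 1] > NEG / 2) c(X[i, j + 1, 1] - ext, X[i, j + 1, 2])
      else c(NEG, 0))
    o2 <- best2(M[i + 1, j, ], X[i + 1, j, ])
    Y[i + 1, j + 1, ] <- best2(
      if (o2[1] > NEG / 2) c(o2[1] - open - ext, o2[2]) else c(NEG, 0),
      if (Y[i + 1, j, 1] > NEG / 2) c(Y[i + 1, j, 1] - ext, Y[i + 1, j, 2])
      else c(NEG, 0))
  }
  fin <- best2(M[n + 1, m + 1, ], X[n + 1, m + 1, ], Y[n + 1, m + 1, ])
  list(score = fin[1], matches = fin[2])
}

# Benjamini-Hochberg step-up, written from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

rand_seq <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})
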