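# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Exhaustive enumeration over all gapped global alignments with affine gap
# scoring (gap run of length L costs go + (L-1)*ge). Plain recursion, no
# memoization: every alignment prefix is visited.
bf_align_score <- function(a, b, sub, go, ge) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca)
  m <- length(cb)
  rec <- function(i, j, last) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, sub[ca[i], cb[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= n) {
      cost <- if (identical(last, "X")) ge else go
      best <- max(best, cost + rec(i + 1, j, "X"))
    }
    if (j <= m) {
      cost <- if (identical(last, "Y")) ge else go
      best <- max(best, cost + rec(i, j + 1, "Y"))
    }
    best
  }
  rec(1, 1, "none")
}

# Column-by-column recount of identity and coverage from gapped strings.
recount_identity_coverage <- function(aligned_a, aligned_b) {
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  both <- ca != "-" & cb != "-"
  matches <- sum(both & ca == cb & ca != "X")
  cols <- sum(both)
  len_a <- sum(ca != "-")
  len_b <- sum(cb != "-")
  c(
    identity_pct = if (cols == 0) 0 else 100 * matches / cols,
    coverage_pct = min(100 * cols / len_a, 100 * cols / len_b)
  )
}

# Depth-first connected components on a logical adjacency matrix.
bf_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    stack <- s
    while (length(stack) > 0) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      nb <- which(adj[v, ] & is.na(comp))
      stack <- c(stack, nb)
    }
  }
  comp
}

# All set partitions of 1..n (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  rec <- function(assign, k) {
    i <- length(assign) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- assign
      return(invisible(NULL))
    }
    for (b in seq_len(k + 1)) rec(c(assign, b), max(k, b))
  }
  rec(integer(), 0L)
  out
}

# Welch's t-test recomputed from the textbook formulas.
welch_oracle <- function(x, y) {
  v1 <- var(x) / length(x)
  v2 <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  p <- 2 * pt(-abs(t), df)
  list(statistic = t, df = df, p_value = p)
}

# Per-base boolean recount of covered fraction.
covered_fraction_oracle <- function(kept, ref, len) {
  covered <- logical(len)
  r <- kept[!is.na(kept$ref_id) & kept$ref_id == ref, , drop = FALSE]
  if (nrow(r) > 0) {
    for (i in seq_len(nrow(r))) {
      lo <- r$ref_start[i]
      hi <- min(r$ref_start[i] + r$aligned_length[i] - 1, len)
      covered[lo:hi] <- TRUE
    }
  }
  100 * sum(covered) / len
}

# Adjusted Rand Index between two label vectors (NA treated as its own
# singleton class per element).
ari <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  a[is.na(a)] <- paste0(".na_a", seq_along(a)[is.na(a)])
  b[is.na(b)] <- paste0(".na_b", seq_along(b)[is.na(b)])
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# A tiny scoring scheme over a 3-letter alphabet for oracle tests.
toy_scheme <- function(match = 2, mismatch = -1, go = -5, ge = -2) {
  ab <- c("A", "B", "C")
  m <- matrix(mismatch, 3, 3, dimnames = list(ab, ab))
  diag(m) <- match
  scoring_scheme(m, go, ge)
}

random_toy_seq <- function(len) {
  paste(sample(c("A", "B", "C"), len, replace = TRUE), collapse = "")
}

# Small helper: random protein string over the 20 standard residues.
random_aa <- function(len) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(sample(aa, len, replace = TRUE), collapse = "")
}
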