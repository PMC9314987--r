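# Independent oracles used to freeze expected values.

# Full quadratic global-alignment identity oracle under unit
# match/mismatch/gap scoring, minimizing cost, then maximizing matches,
# then minimizing columns (same objective as pairwise_identity, computed
# by an independent full-matrix dynamic program in R).
identity_oracle <- function(s1, s2) {
  a <- strsplit(toupper(s1), "")[[1]]
  b <- strsplit(toupper(s2), "")[[1]]
  n1 <- length(a); n2 <- length(b)
  INF <- 1e9
  cost <- matrix(INF, n1 + 1, n2 + 1)
  mat <- matrix(0, n1 + 1, n2 + 1)
  col <- matrix(INF, n1 + 1, n2 + 1)
  cost[1, ] <- 0:n2; col[1, ] <- 0:n2
  cost[, 1] <- 0:n1; col[, 1] <- 0:n1
  better <- function(c1, m1, l1, c2, m2, l2)
    c1 < c2 || (c1 == c2 && (m1 > m2 || (m1 == m2 && l1 < l2)))
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    eq <- a[i] == b[j]
    bc <- cost[i, j] + !eq; bm <- mat[i, j] + eq; bl <- col[i, j] + 1
    c2 <- cost[i, j + 1] + 1; m2 <- mat[i, j + 1]; l2 <- col[i, j + 1] + 1
    if (better(c2, m2, l2, bc, bm, bl)) { bc <- c2; bm <- m2; bl <- l2 }
    c3 <- cost[i + 1, j] + 1; m3 <- mat[i + 1, j]; l3 <- col[i + 1, j] + 1
    if (better(c3, m3, l3, bc, bm, bl)) { bc <- c3; bm <- m3; bl <- l3 }
    cost[i + 1, j + 1] <- bc; mat[i + 1, j + 1] <- bm; col[i + 1, j + 1] <- bl
  }
  mat[n1 + 1, n2 + 1] / col[n1 + 1, n2 + 1]
}

# Closed-form normal-equation OLS oracle
ols_oracle <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  intercept <- yb - slope * xb
  res <- y - intercept - slope * x
  r2 <- if (sum((y - yb)^2) > 0) 1 - sum(res^2) / sum((y - yb)^2) else 0
  list(slope = slope, intercept = intercept, r_squared = r2,
       sigma2 = sum(res^2) / (length(x) - 2))
}

random_dna_string <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
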