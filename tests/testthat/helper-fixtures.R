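# Fixtures are built in code; no data files are read from disk except the
# shipped hand-encoded published critical-node table.

labels6 <- outcome_catalog()$labels

# A minimal wide cohort row
cohort_row <- function(id, group, dpf, PE = 0, YSE = 0, CM = 0, SD = 0,
                       SBI = 0, M = 0) {
  data.frame(individual_id = id, group = group, dpf = dpf, PE = PE,
             YSE = YSE, CM = CM, SD = SD, SBI = SBI, M = M,
             stringsAsFactors = FALSE)
}

# n individuals in one group, all endpoints zero, over timepoints tps
zero_cohort_df <- function(n = 10, group = "g", tps = 2:7) {
  do.call(rbind, lapply(seq_len(n), function(k) {
    do.call(rbind, lapply(tps, function(t) {
      cohort_row(sprintf("i%02d", k), group, t)
    }))
  }))
}

make_assoc <- function(p, group = "g", t = 2L) {
  dimnames(p) <- list(labels6, labels6)
  dynetox:::new_association_matrix(group, as.integer(t), p)
}

make_adj <- function(A, group = "g", t = 2L) {
  dimnames(A) <- list(labels6, labels6)
  dynetox:::new_adjacency_matrix(group, as.integer(t), A)
}

# symmetric p-value matrix with unit diagonal, off-diagonals drawn in (0,1]
rand_p_matrix <- function(K = 6) {
  p <- diag(K)
  vals <- stats::runif(choose(K, 2))
  p[upper.tri(p)] <- vals
  p <- p + t(p)
  diag(p) <- 1
  p
}

# random symmetric nonnegative weight matrix, zero diagonal, some zero links
rand_weight_matrix <- function(K = 6, density = 0.7, wmax = 100) {
  A <- matrix(0, K, K)
  m <- choose(K, 2)
  w <- ifelse(stats::runif(m) < density, stats::runif(m, 0, wmax), 0)
  A[upper.tri(A)] <- w
  A <- A + t(A)
  dimnames(A) <- list(labels6, labels6)
  A
}

# Independent exact-test oracle: enumerate all margin-consistent tables via
# stats::dhyper and apply the probability-mass rule.
oracle_fisher <- function(a, b, c, d, tie_tol = 1e-7) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (min(r1, r2, c1, b + d) == 0) return(1)
  supp <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(supp, r1, r2, c1)
  min(sum(probs[probs <= probs[supp == a] * (1 + tie_tol)]), 1)
}

random_table <- function(n = 30) {
  x <- stats::rmultinom(1, n, prob = stats::runif(4, 0.05, 1))
  as.integer(x)
}
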