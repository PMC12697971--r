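# Shared fixtures, all generated in code.

# Two well-separated Gaussian classes; feature 1 carries the signal.
make_sep_dataset <- function(n = 60, p = 20, sep = 8, seed = 1) {
  set.seed(seed)
  y <- rep(c("a", "b"), length.out = n)
  m <- matrix(rnorm(n * p), n, p)
  m[, 1] <- m[, 1] + sep * (y == "b")
  expression_dataset(m, y)
}

# Desk-scale control: small population/budget, coarse 2x2 SVM grid.
small_control <- function(iterations = 10, population = 8, k = 3, ...) {
  hmfw_control(population = population, iterations = iterations,
               beetle_swarm = 4, beetle_steps = 2,
               cv = cv_config(k = k, c_grid = c(1, 16),
                              gamma_grid = c(2^-4, 2^-1)),
               rf_trees = 200, ...)
}

# Independent plug-in MI oracle via the entropy identity
# MI = H(X) + H(Y) - H(X,Y), natural log.
oracle_mi <- function(x, y) {
  h <- function(v) {
    p <- as.numeric(table(v)) / length(v)
    -sum(p * log(p))
  }
  h(x) + h(y) - h(paste(x, y, sep = "\r"))
}

# Independent average-rank computation (no call to rank()).
oracle_avg_ranks <- function(v) {
  ord <- order(v)
  r <- numeric(length(v))
  pos <- seq_along(v)
  i <- 1
  while (i <= length(v)) {
    j <- i
    while (j < length(v) && v[ord[j + 1]] == v[ord[i]]) j <- j + 1
    r[ord[i:j]] <- mean(pos[i:j])
    i <- j + 1
  }
  r
}

oracle_spearman <- function(x, y) {
  d <- oracle_avg_ranks(x) - oracle_avg_ranks(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Independent brute-force scoring of the greedy relevance/redundancy
# recurrence: the score of `feature` given an already-selected set.
oracle_msmmi_score <- function(feature, selected, ds, s, y) {
  rel <- s * oracle_mi(ds$labels, ds$matrix[, feature])
  if (length(selected) == 0) return(rel)
  red <- min(sapply(selected, function(p)
    oracle_spearman(ds$matrix[, feature], ds$matrix[, p])))
  rel - y * red
}

# Verify a selection is greedy-optimal under the recurrence: every successive
# pick attains the maximum brute-force score over the remaining candidates
# (1e-9 tolerance absorbs last-bit differences between the two equivalent MI
# computations on exactly tied scores).
expect_greedy_optimal <- function(sel, candidates, ds, s, y) {
  selected <- integer(0)
  for (pick in sel) {
    rem <- setdiff(candidates, selected)
    scores <- sapply(rem, oracle_msmmi_score, selected = selected, ds = ds,
                     s = s, y = y)
    expect_gte(oracle_msmmi_score(pick, selected, ds, s, y),
               max(scores) - 1e-9)
    selected <- c(selected, pick)
  }
}
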