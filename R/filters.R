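#' Shannon entropy of a class-label vector (bits)
#'
#' \eqn{H(D) = -\sum_j (|D_j|/|D|) \log_2(|D_j|/|D|)} over the classes present.
#' Base-2 logarithm: this is the entropy used by the information-gain screen of
#' the random-forest pre-filter, not the natural-log entropy underlying the
#' mutual-information filter.
#'
#' @param labels non-empty vector of class codes.
#' @return Entropy in bits; 0 for a single class.
#' @export
entropy_bits <- function(labels) {
  if (length(labels) == 0) stop("empty label vector", call. = FALSE)
  p <- as.numeric(table(labels)) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information gain of a partition (bits)
#'
#' \eqn{IG = H(D) - \sum_i (|D_i|/|D|) H(D_i)}: the reduction in label entropy
#' when samples are split into the given parts.
#'
#' @param labels vector of class codes.
#' @param partition list of integer index vectors covering `seq_along(labels)`
#'   exactly once.
#' @return Information gain in bits (non-negative).
#' @export
information_gain <- function(labels, partition) {
  idx <- sort(unlist(partition, use.names = FALSE))
  if (!identical(as.integer(idx), seq_along(labels)))
    stop("partition must cover all samples exactly once", call. = FALSE)
  n <- length(labels)
  h <- entropy_bits(labels)
  cond <- sum(vapply(partition, function(part)
    length(part) / n * entropy_bits(labels[part]), numeric(1)))
  max(h - cond, 0)
}

#' Random-forest feature-importance pre-screen
#'
#' Module M1: trains an impurity-based random forest on the full (normalized)
#' matrix and returns the top `k1` features by mean impurity decrease. This is
#' the massive first-stage dimensionality reduction that cuts thousands of
#' features to the hundreds handed to the bivariate filter.
#'
#' @param ds an [expression_dataset()].
#' @param k1 number of features to keep (1..n_features).
#' @param seed integer seed (forest growing is deterministic under it).
#' @param num_trees number of trees (default 500).
#' @return A `"scored_features"` object: data frame with columns `feature`
#'   (column index), `score`, sorted by score descending, plus attribute
#'   `score_kind = "rf_importance"`.
#' @export
rf_fim_rank <- function(ds, k1, seed = 1, num_trees = 500) {
  p <- ncol(ds$matrix)
  k1 <- as.integer(k1)
  if (k1 < 1 || k1 > p) stop("k1 out of range [1, ", p, "]", call. = FALSE)
  df <- data.frame(ds$matrix, check.names = TRUE)
  df$.y <- ds$labels
  fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                        importance = "impurity", num.trees = num_trees,
                        seed = seed, num.threads = 1,
                        respect.unordered.factors = "order")
  imp <- as.numeric(fit$variable.importance)
  ord <- order(-imp, seq_along(imp))  # ties: lowest index first
  keep <- ord[seq_len(k1)]
  scored_features(keep, imp[keep], "rf_importance")
}

scored_features <- function(feature, score, kind) {
  structure(data.frame(feature = as.integer(feature), score = as.numeric(score)),
            score_kind = kind, class = c("scored_features", "data.frame"))
}

#' Plug-in mutual information (nats)
#'
#' Empirical-joint-distribution mutual information, by default treating each
#' distinct value as its own category, with the NATURAL logarithm:
#' \eqn{MI(X;Y) = \sum_{x,y} p(x,y) \log\frac{p(x,y)}{p(x)p(y)}}.
#' Distinct-value binning degenerates on continuous matrices where every value
#' is unique (MI collapses to the label entropy); `mode = "equal_width"`
#' discretizes each numeric input into `bins` equal-width intervals instead.
#'
#' @param x,y equal-length vectors (numeric or discrete codes), length >= 2.
#' @param mode `"distinct"` (default) or `"equal_width"`.
#' @param bins number of bins for equal-width discretization (default 10).
#' @return Mutual information in nats (symmetric, non-negative).
#' @export
mutual_information <- function(x, y, mode = c("distinct", "equal_width"), bins = 10) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 observations", call. = FALSE)
  mode <- match.arg(mode)
  if (mode == "equal_width") {
    x <- discretize_ew(x, bins)
    y <- discretize_ew(y, bins)
  }
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  pxy <- outer(px, py)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / pxy[nz]))
}

discretize_ew <- function(v, bins) {
  if (!is.numeric(v)) return(v)
  r <- range(v)
  if (r[1] == r[2]) return(rep(1L, length(v)))
  cut(v, breaks = seq(r[1], r[2], length.out = bins + 1L), include.lowest = TRUE,
      labels = FALSE)
}

#' Maximum mutual information with the label
#'
#' Returns the candidate feature most informative about the class label, i.e.
#' the argmax over candidates of `mutual_information(label, feature)`. Ties are
#' broken by the lowest feature index.
#'
#' @param candidates non-empty integer vector of feature column indices.
#' @param ds an [expression_dataset()].
#' @param ... passed to [mutual_information()] (`mode`, `bins`).
#' @return `list(feature = <index>, value = <MI in nats>)`.
#' @export
mmi <- function(candidates, ds, ...) {
  if (length(candidates) == 0) stop("empty candidate set", call. = FALSE)
  candidates <- sort(as.integer(candidates))
  vals <- vapply(candidates, function(j)
    mutual_information(ds$labels, ds$matrix[, j], ...), numeric(1))
  best <- which.max(vals)  # first maximum = lowest index after sort
  list(feature = candidates[best], value = vals[best])
}

#' Spearman coefficient, printed-formula form
#'
#' Ranks with AVERAGE ranks for ties, then evaluates
#' \eqn{\rho = 1 - 6\sum d^2 / (n(n^2-1))} exactly as printed, with no
#' tie-correction term. On tie-free input this equals the Pearson correlation
#' of the rank vectors; with ties it deliberately differs from
#' `cor(..., method = "spearman")`, which applies the tie correction.
#'
#' @param x,y equal-length numeric vectors, length >= 2.
#' @return The coefficient (in \[-1, 1\] for tie-free data).
#' @export
spearman_coef <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

#' Least-redundant candidate against one known feature
#'
#' Returns the candidate minimizing the Spearman coefficient with the known
#' feature (ties: lowest index).
#'
#' @param f_known feature column index (not among the candidates).
#' @param candidates non-empty integer vector of feature column indices.
#' @param ds an [expression_dataset()].
#' @return `list(feature = <index>, value = <coefficient>)`.
#' @export
ms1 <- function(f_known, candidates, ds) {
  if (length(candidates) == 0) stop("empty candidate set", call. = FALSE)
  if (f_known %in% candidates)
    stop("f_known must not be among the candidates", call. = FALSE)
  candidates <- sort(as.integer(candidates))
  vals <- vapply(candidates, function(j)
    spearman_coef(ds$matrix[, f_known], ds$matrix[, j]), numeric(1))
  best <- which.min(vals)
  list(feature = candidates[best], value = vals[best])
}

#' Least-redundant candidate against a selected set
#'
#' For each candidate its redundancy is the minimum Spearman coefficient
#' against the selected set; the returned candidate minimizes that redundancy
#' (ties: lowest index).
#'
#' @param selected non-empty integer vector of already-selected feature indices.
#' @param candidates non-empty integer vector, disjoint from `selected`.
#' @param ds an [expression_dataset()].
#' @return `list(feature = <index>, value = <coefficient>)`.
#' @export
ms2 <- function(selected, candidates, ds) {
  if (length(selected) == 0 || length(candidates) == 0)
    stop("selected and candidates must be non-empty", call. = FALSE)
  if (length(intersect(selected, candidates)))
    stop("selected and candidates must be disjoint", call. = FALSE)
  candidates <- sort(as.integer(candidates))
  vals <- vapply(candidates, function(j)
    min(vapply(selected, function(s)
      spearman_coef(ds$matrix[, j], ds$matrix[, s]), numeric(1))), numeric(1))
  best <- which.min(vals)
  list(feature = candidates[best], value = vals[best])
}

#' Relevance/redundancy weight schedule
#'
#' As the wrapper iterates from `i = 0` to `i = I`, the relevance weight
#' \eqn{s = \cos((i/I)\,\pi/2)} decreases from 1 to 0 and the redundancy weight
#' \eqn{y = \sin((i/I)\,\pi/2)} increases from 0 to 1, with \eqn{s^2+y^2 = 1}.
#'
#' @param i current wrapper iteration (0..I).
#' @param I maximum number of wrapper iterations (>= 1).
#' @return `c(s = , y = )`.
#' @export
sy_schedule <- function(i, I) {
  if (I < 1) stop("I must be >= 1", call. = FALSE)
  if (i < 0 || i > I) stop("require 0 <= i <= I", call. = FALSE)
  th <- (i / I) * pi / 2
  c(s = cos(th), y = sin(th))
}

#' Filter budget configuration
#'
#' Parameters of the stochastic feature-count formula
#' \eqn{K = RandnumA + (f\,\mathrm{rand}()/e)\cos(p\,e)}, where `f` is the
#' number of features and `e` the number of samples. `RandnumA` is drawn
#' uniformly from `[randnum_a_low, randnum_a_high]` for the bivariate-filter
#' stage (M2) and from ten times that range for the pre-screen stage (M1);
#' `rand()` is uniform on `(rand_low, rand_high)`. The result is rounded and
#' clamped to `[k_min, ceiling(k_max_fraction * available)]`.
#'
#' @param randnum_a_low,randnum_a_high baseline range for the M2 stage
#'   (defaults 10 and 20; M1 uses 10x these).
#' @param p cosine adjustment factor in (0, 1), default 0.8.
#' @param rand_low,rand_high range of the uniform multiplier, defaults 1 and 10.
#' @param k_min,k_max_fraction clamp bounds (defaults 5 and 1.0).
#' @return A `"filter_budget"` list.
#' @export
filter_budget <- function(randnum_a_low = 10, randnum_a_high = 20, p = 0.8,
                          rand_low = 1, rand_high = 10, k_min = 5,
                          k_max_fraction = 1.0) {
  stopifnot(randnum_a_low < randnum_a_high, rand_low < rand_high, k_min >= 2,
            p > 0, p < 1, k_max_fraction > 0, k_max_fraction <= 1)
  structure(list(randnum_a_low = randnum_a_low, randnum_a_high = randnum_a_high,
                 p = p, rand_low = rand_low, rand_high = rand_high,
                 k_min = as.integer(k_min), k_max_fraction = k_max_fraction),
            class = "filter_budget")
}

#' Draw a stage feature budget
#'
#' Evaluates the budget formula (see [filter_budget()]) for stage `"M1"`
#' (random-forest pre-screen; 10x baseline) or `"M2"` (bivariate filter),
#' consuming two uniform draws from the current RNG stream. The cosine term
#' couples the budget to the sample count, so it can be strongly negative for
#' some dataset sizes; the clamp absorbs all such pathologies.
#'
#' @param ds an [expression_dataset()] supplying `f` (features) and `e`
#'   (samples), or a length-2 vector `c(f, e)`.
#' @param budget a [filter_budget()].
#' @param stage `"M1"` or `"M2"`.
#' @param available number of features actually selectable at this stage (caps
#'   the upper clamp); defaults to `f`.
#' @return Integer feature count within the clamp bounds.
#' @export
feature_budget <- function(ds, budget, stage = c("M2", "M1"), available = NULL) {
  stage <- match.arg(stage)
  if (inherits(ds, "expression_dataset")) {
    f <- ncol(ds$matrix); e <- nrow(ds$matrix)
  } else {
    f <- ds[[1L]]; e <- ds[[2L]]
  }
  if (is.null(available)) available <- f
  mult <- if (stage == "M1") 10 else 1
  randnum_a <- stats::runif(1, budget$randnum_a_low * mult, budget$randnum_a_high * mult)
  r <- stats::runif(1, budget$rand_low, budget$rand_high)
  raw <- randnum_a + (f * r / e) * cos(budget$p * e)
  k <- as.integer(round(raw))
  hi <- as.integer(ceiling(budget$k_max_fraction * available))
  max(min(k, hi), min(budget$k_min, hi))
}

#' Greedy minimum-Spearman / maximum-MI feature selection
#'
#' The bivariate filter: the first pick maximizes `s * MI(label, f)`; with one
#' feature selected, subsequent candidates are scored
#' `s * MI(label, f) - y * rho(p1, f)`; with more, the redundancy term is the
#' candidate's minimum Spearman coefficient against the selected set. `s` and
#' `y` come from [sy_schedule()] at the current (global) wrapper iteration, so
#' relevance dominates early and redundancy avoidance dominates late. Ties are
#' broken by the lowest feature index.
#'
#' @param candidates integer vector of feature column indices.
#' @param ds an [expression_dataset()].
#' @param k2 number of features to select (`<= length(candidates)`).
#' @param schedule `c(s, y)` weights, e.g. from [sy_schedule()].
#' @param mi_mode,mi_bins passed to [mutual_information()].
#' @return Integer vector of `k2` feature indices, in selection order.
#' @export
msmmi_select <- function(candidates, ds, k2, schedule = sy_schedule(0, 1),
                         mi_mode = "distinct", mi_bins = 10) {
  candidates <- sort(unique(as.integer(candidates)))
  k2 <- as.integer(k2)
  if (k2 > length(candidates))
    stop("k2 (", k2, ") exceeds number of candidates (", length(candidates), ")",
         call. = FALSE)
  if (k2 < 1) stop("k2 must be >= 1", call. = FALSE)
  s <- schedule[[1L]]; y <- schedule[[2L]]
  mi_vals <- vapply(candidates, function(j)
    mutual_information(ds$labels, ds$matrix[, j], mode = mi_mode, bins = mi_bins),
    numeric(1))
  picked <- integer(0)
  remaining <- seq_along(candidates)
  # per-remaining-candidate running minimum Spearman against the selected set
  min_rho <- rep(Inf, length(candidates))
  for (step in seq_len(k2)) {
    if (step == 1L) {
      score <- s * mi_vals[remaining]
    } else {
      score <- s * mi_vals[remaining] - y * min_rho[remaining]
    }
    best <- remaining[which.max(score)]
    picked <- c(picked, best)
    remaining <- setdiff(remaining, best)
    if (length(remaining) && step < k2) {
      new_rho <- vapply(remaining, function(r)
        spearman_coef(ds$matrix[, candidates[r]], ds$matrix[, candidates[best]]),
        numeric(1))
      min_rho[remaining] <- pmin(min_rho[remaining], new_rho)
    }
  }
  candidates[picked]
}
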