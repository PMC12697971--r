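#' Cross-validation / grid-search configuration for the fitness function
#'
#' @param k number of folds (default 10).
#' @param nested if `TRUE`, hyperparameter search and normalization statistics
#'   are fitted strictly inside each outer training fold (leakage-free
#'   protocol); the default flat protocol tunes on the same folds it reports.
#' @param c_grid,gamma_grid SVM grids (coarse powers of two by default).
#' @param inner_k inner folds for the nested protocol (default 3).
#' @param seed seed for the fold split.
#' @return A `"cv_config"` list.
#' @export
cv_config <- function(k = 10, nested = FALSE, c_grid = 2^seq(-2, 8, by = 2),
                      gamma_grid = 2^seq(-8, 2, by = 2), inner_k = 3, seed = 1) {
  stopifnot(k >= 2, length(c_grid) >= 1, length(gamma_grid) >= 1)
  structure(list(k = as.integer(k), nested = isTRUE(nested),
                 c_grid = as.numeric(c_grid), gamma_grid = as.numeric(gamma_grid),
                 inner_k = as.integer(inner_k), seed = as.integer(seed)),
            class = "cv_config")
}

svm_fold_acc <- function(x, y, folds, C, gamma) {
  vapply(folds, function(fd) {
    fit <- e1071::svm(x[fd$train, , drop = FALSE], y[fd$train], scale = FALSE,
                      kernel = "radial", cost = C, gamma = gamma)
    mean(predict(fit, x[fd$test, , drop = FALSE]) == y[fd$test])
  }, numeric(1))
}

grid_search_acc <- function(x, y, folds, c_grid, gamma_grid) {
  best <- NULL
  for (C in c_grid) for (g in gamma_grid) {
    fa <- svm_fold_acc(x, y, folds, C, g)
    m <- mean(fa)
    if (is.null(best) || m > best$acc_mean + 1e-15) {
      best <- list(acc_mean = m, fold_accs = fa, C = C, gamma = g)
    }
  }
  best
}

#' Evaluate the fitness of a feature mask
#'
#' The wrapper's objective: cross-validated SVM (RBF kernel) accuracy on the
#' masked feature matrix, with `C` and `gamma` chosen by grid search. Under the
#' flat protocol one stratified `k`-fold split (from `cfg$seed`, or a
#' precomputed `folds` list) is used both to tune and to report. Under the
#' nested protocol the grid search runs on inner folds of each outer training
#' fold and, when min-max `ranges` are not supplied, normalization is fitted on
#' the training fold only; outer-fold accuracies are averaged.
#'
#' @param ds an [expression_dataset()] (already normalized in the flat
#'   protocol).
#' @param mask logical vector over features, or an integer vector of feature
#'   column indices; must select at least one feature.
#' @param cfg a [cv_config()].
#' @param folds optional precomputed [stratified_folds()] result (flat
#'   protocol), so repeated calls within one run share a single split.
#' @param hook optional function called as `hook(event, fold, rows)` on every
#'   preprocessing/tuning fit (events `"normalize_fit"`, `"grid_fit"`), for
#'   instrumentation of the nested protocol.
#' @return A `"fitness_result"`: list with `acc_mean`, `fold_accs`,
#'   `subset_length`, `feature_indices` (sorted), `chosen_c`, `chosen_gamma`.
#' @export
evaluate_fitness <- function(ds, mask, cfg = cv_config(), folds = NULL, hook = NULL) {
  idx <- if (is.logical(mask)) which(mask) else sort(unique(as.integer(mask)))
  if (length(idx) == 0) stop("mask selects no features", call. = FALSE)
  x <- ds$matrix[, idx, drop = FALSE]
  y <- ds$labels
  if (!cfg$nested) {
    if (is.null(folds)) folds <- stratified_folds(ds, cfg$k, cfg$seed)
    gs <- grid_search_acc(x, y, folds, cfg$c_grid, cfg$gamma_grid)
    res <- fitness_result(gs$acc_mean, gs$fold_accs, idx, gs$C, gs$gamma)
    return(res)
  }
  outer <- stratified_folds(ds, cfg$k, cfg$seed)
  fold_accs <- numeric(length(outer))
  chosen <- NULL
  for (i in seq_along(outer)) {
    tr <- outer[[i]]$train; te <- outer[[i]]$test
    lo <- apply(x[tr, , drop = FALSE], 2L, min)
    hi <- apply(x[tr, , drop = FALSE], 2L, max)
    if (!is.null(hook)) hook("normalize_fit", i, tr)
    span <- hi - lo; span[span == 0] <- 1
    xs <- sweep(sweep(x, 2L, lo, "-"), 2L, span, "/")
    inner <- stratified_folds(droplevels(y[tr]), cfg$inner_k, cfg$seed + i)
    inner <- lapply(inner, function(fd) list(train = tr[fd$train], test = tr[fd$test]))
    if (!is.null(hook)) hook("grid_fit", i, tr)
    gs <- grid_search_acc(xs, y, inner, cfg$c_grid, cfg$gamma_grid)
    fit <- e1071::svm(xs[tr, , drop = FALSE], y[tr], scale = FALSE,
                      kernel = "radial", cost = gs$C, gamma = gs$gamma)
    fold_accs[i] <- mean(predict(fit, xs[te, , drop = FALSE]) == y[te])
    chosen <- gs
  }
  fitness_result(mean(fold_accs), fold_accs, idx, chosen$C, chosen$gamma)
}

fitness_result <- function(acc_mean, fold_accs, idx, C, gamma) {
  structure(list(acc_mean = acc_mean, fold_accs = fold_accs,
                 subset_length = length(idx), feature_indices = idx,
                 chosen_c = C, chosen_gamma = gamma),
            class = "fitness_result")
}

#' @export
print.fitness_result <- function(x, ...) {
  cat(sprintf("fitness: ACC = %.4f over %d folds; LEN = %d (C = %g, gamma = %g)\n",
              x$acc_mean, length(x$fold_accs), x$subset_length, x$chosen_c,
              x$chosen_gamma))
  invisible(x)
}

#' Compare two fitness results
#'
#' Lexicographic ordering resolving the accuracy-versus-length trade-off:
#' higher mean accuracy wins; on an exact accuracy tie the smaller subset wins;
#' on a full tie the lexicographically smaller sorted feature-index vector wins
#' (determinism under a fixed seed).
#'
#' @param a,b `"fitness_result"` objects.
#' @return `1L` if `a` is better, `-1L` if `b` is better, `0L` if identical.
#' @export
compare_fitness <- function(a, b) {
  if (a$acc_mean != b$acc_mean) return(if (a$acc_mean > b$acc_mean) 1L else -1L)
  if (a$subset_length != b$subset_length)
    return(if (a$subset_length < b$subset_length) 1L else -1L)
  ia <- a$feature_indices; ib <- b$feature_indices
  for (i in seq_len(min(length(ia), length(ib)))) {
    if (ia[i] != ib[i]) return(if (ia[i] < ib[i]) 1L else -1L)
  }
  0L
}

fitness_better <- function(a, b) compare_fitness(a, b) > 0L

# Memoised fitness over global feature indices; cache valid for one fold split.
make_fitness_fun <- function(ds, cfg, folds, cache = new.env(parent = emptyenv())) {
  function(idx) {
    idx <- sort(unique(as.integer(idx)))
    key <- paste(idx, collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    res <- evaluate_fitness(ds, idx, cfg, folds = folds)
    cache[[key]] <- res
    res
  }
}
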