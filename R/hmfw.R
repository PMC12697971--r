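#' Control parameters for an HMF-W run
#'
#' Collects every tunable of the pipeline into one serializable object whose
#' canonical-JSON MD5 digest is embedded in reports, so silent default drift
#' between runs is detectable.
#'
#' @param population wrapper population size (default 30).
#' @param iterations total wrapper-iteration budget `T` across restarts
#'   (default 100); restarts never reset it, so every run costs the same
#'   number of wrapper iterations and the relevance/redundancy schedule of
#'   [sy_schedule()] advances on this global counter.
#' @param beetle_swarm,beetle_steps dung-beetle sub-swarm size and steps per
#'   leader per iteration (defaults 10 and 5).
#' @param bounds either `"draw"` (lower bound drawn uniformly from
#'   \[-1, -0.3\] and upper from \[0.3, 1\] once per run) or a numeric
#'   `c(lower, upper)`.
#' @param seed_param logistic-map parameter in (3, 4), default 3.9.
#' @param budget a [filter_budget()].
#' @param mi_mode,mi_bins mutual-information estimator settings (see
#'   [mutual_information()]); continuous expression data defaults to
#'   equal-width discretization.
#' @param cv a [cv_config()] (its `seed` field is overridden by the run seed).
#' @param rlif an [rlif_params()].
#' @param patience_min,patience_max,grid_points passed to [extrema_schedule()].
#' @param ec_up,ec_down extremum-control streak lengths (see [pom_step()]).
#' @param thresholds optional explicit integer patience schedule overriding
#'   the intensity-derived one.
#' @param rf_trees random-forest size for the pre-screen (default 500).
#' @return An `"hmfw_control"` list.
#' @export
hmfw_control <- function(population = 30, iterations = 100, beetle_swarm = 10,
                         beetle_steps = 5, bounds = "draw", seed_param = 3.9,
                         budget = filter_budget(), mi_mode = "equal_width",
                         mi_bins = 10, cv = cv_config(), rlif = rlif_params(),
                         patience_min = 3, patience_max = 12, grid_points = 4096,
                         ec_up = 3, ec_down = 2, thresholds = NULL,
                         rf_trees = 500) {
  stopifnot(population >= 4, iterations >= 1)
  structure(list(population = as.integer(population),
                 iterations = as.integer(iterations),
                 beetle_swarm = as.integer(beetle_swarm),
                 beetle_steps = as.integer(beetle_steps),
                 bounds = bounds, seed_param = seed_param, budget = budget,
                 mi_mode = mi_mode, mi_bins = as.integer(mi_bins), cv = cv,
                 rlif = rlif, patience_min = patience_min,
                 patience_max = patience_max, grid_points = grid_points,
                 ec_up = as.integer(ec_up), ec_down = as.integer(ec_down),
                 thresholds = thresholds, rf_trees = as.integer(rf_trees)),
            class = "hmfw_control")
}

config_digest <- function(control) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(control, tf, auto_unbox = TRUE, digits = 12, force = TRUE)
  unname(tools::md5sum(tf))
}

#' Hybrid multiple filter-wrapper feature selection
#'
#' Fits the full pipeline to an expression dataset: (1) min-max normalization;
#' (2) module M1 — random-forest impurity pre-screen to `K1` features, `K1`
#' drawn from the budget formula; (3) module M2 — a loop over the global
#' wrapper budget in which the bivariate filter ([msmmi_select()], `K2` from
#' the budget formula, weights from the global [sy_schedule()]) proposes a
#' candidate subset, a chaotically initialized wolf pack searches binary masks
#' over it ([hgw_cdbw_iterate()]) with cross-validated SVM accuracy as
#' fitness, and the process-optimization controller ([pom_step()]) watches the
#' average improvement rate, ordering a filter re-run and population
#' re-initialization whenever the search stagnates. The best mask ever seen is
#' kept in an elite archive outside the population, so the reported result is
#' monotone across restarts.
#'
#' @param x samples-by-features numeric matrix, or an [expression_dataset()].
#' @param y class labels (ignored when `x` is already a dataset).
#' @param control an [hmfw_control()].
#' @param seed master seed; every source of randomness (budget draws, forest,
#'   fold split, chaos streams, wolf updates) derives from it, so two runs
#'   with the same seed produce identical results.
#' @return An object of class `"hmfw"`; see Details.
#' @details The returned object carries `best` (the winning
#'   `"fitness_result"`), `feature_indices` / `feature_ids` (selected columns
#'   of the input matrix; `feature_indices_1based` is the same 1-based index
#'   vector, emitted for report comparability), `f1` (the M1 pre-screen),
#'   `trace` (per-iteration best accuracy/length, AIR, CAD, active threshold
#'   and restart flags), `restarts`, `filter_execs`, `seeds`, `digest`,
#'   `runtime_s`, and the fitted normalization ranges plus final SVM for
#'   [predict.hmfw()].
#' @seealso [hmfw_repeat()] for the repeated-runs protocol,
#'   [generate_synthetic_omics()] for test data.
#' @export
hmfw <- function(x, y = NULL, control = hmfw_control(), seed = 1) {
  t0 <- proc.time()[["elapsed"]]
  ds <- if (inherits(x, "expression_dataset")) x else expression_dataset(x, y)
  set.seed(seed)
  nds <- minmax_normalize(ds)
  ranges <- attr(nds, "ranges")
  n <- nrow(nds$matrix); p <- ncol(nds$matrix)
  T <- control$iterations

  # --- module M1: forest pre-screen ---------------------------------------
  k1 <- feature_budget(nds, control$budget, stage = "M1")
  rf_seed <- sample.int(.Machine$integer.max, 1)
  f1 <- rf_fim_rank(nds, k1, seed = rf_seed, num_trees = control$rf_trees)
  filter_execs <- 0L

  # one fold split per run, shared by every fitness evaluation (and the cache)
  cv <- control$cv
  cv$seed <- sample.int(.Machine$integer.max, 1)
  folds <- if (cv$nested) NULL else stratified_folds(nds, cv$k, cv$seed)
  cache <- new.env(parent = emptyenv())
  fit_fun <- make_fitness_fun(nds, cv, folds, cache)

  # search box: per-run draw unless given explicitly
  if (identical(control$bounds, "draw")) {
    lo <- stats::runif(1, -1, -0.3); hi <- stats::runif(1, 0.3, 1)
  } else {
    lo <- control$bounds[[1L]]; hi <- control$bounds[[2L]]
  }

  # controller
  sched <- if (is.null(control$thresholds)) {
    extrema_schedule(control$rlif, control$grid_points,
                     control$patience_min, control$patience_max)
  } else {
    structure(list(thresholds = sort(unique(as.integer(control$thresholds))),
                   cursor = 1L, extrema = numeric(0)),
              class = "extrema_schedule")
  }
  pst <- pom_state(sched, control$ec_up, control$ec_down)

  new_episode <- function(iter) {
    sy <- sy_schedule(iter, T)
    k2 <- feature_budget(c(p, n), control$budget, stage = "M2",
                         available = nrow(f1))
    k2 <- min(k2, nrow(f1))
    cand <- msmmi_select(f1$feature, nds, k2, sy,
                         mi_mode = control$mi_mode, mi_bins = control$mi_bins)
    filter_execs <<- filter_execs + 1L
    space <- search_space(length(cand), lo, hi)
    wolf_streams <- spawn_chaos_streams(control$population, control$seed_param)
    ip <- init_pack(space, control$population, wolf_streams, fit_fun, cand)
    list(candidates = cand, pack = ip$pack,
         beetle_streams = spawn_chaos_streams(control$beetle_swarm,
                                              control$seed_param))
  }

  ep <- new_episode(0L)
  best <- ep$pack$fitness[[ep$pack$leaders[1L]]]
  trace <- vector("list", T)
  restarts <- 0L

  for (iter in seq_len(T)) {
    it <- hgw_cdbw_iterate(ep$pack, iter, T, fit_fun, ep$candidates,
                           control$beetle_swarm, control$beetle_steps,
                           ep$beetle_streams)
    ep$pack <- it$pack
    ep$beetle_streams <- it$beetle_streams
    iter_best <- ep$pack$fitness[[ep$pack$leaders[1L]]]
    if (fitness_better(iter_best, best)) best <- iter_best
    ps <- pom_step(pst, max(iter_best$acc_mean, .Machine$double.eps))
    pst <- ps$state
    trace[[iter]] <- data.frame(
      iteration = iter,
      best_acc = best$acc_mean,
      best_len = best$subset_length,
      episode_acc = iter_best$acc_mean,
      air = if (length(pst$air_history)) pst$air_history[length(pst$air_history)] else NA_real_,
      cad = pst$cad,
      threshold = pst$schedule$thresholds[pst$schedule$cursor],
      s = sy_schedule(iter, T)[["s"]],
      y = sy_schedule(iter, T)[["y"]],
      restart = identical(ps$action, "restart"))
    if (identical(ps$action, "restart") && iter < T) {
      restarts <- restarts + 1L
      ep <- new_episode(iter)
    }
  }
  trace <- do.call(rbind, trace)

  idx <- best$feature_indices
  # final model on the selected features, for predict()
  final_svm <- e1071::svm(nds$matrix[, idx, drop = FALSE], nds$labels,
                          scale = FALSE, kernel = "radial",
                          cost = best$chosen_c, gamma = best$chosen_gamma)
  structure(list(best = best,
                 feature_indices = idx,
                 feature_indices_1based = idx,
                 feature_ids = ds$feature_ids[idx],
                 f1 = f1, trace = trace, restarts = restarts,
                 filter_execs = filter_execs,
                 n_samples = n, n_features = p,
                 levels = levels(ds$labels),
                 seeds = list(master = seed, rf = rf_seed, cv = cv$seed),
                 control = control, digest = config_digest(control),
                 ranges = ranges, svm = final_svm,
                 runtime_s = proc.time()[["elapsed"]] - t0),
            class = "hmfw")
}

#' @export
print.hmfw <- function(x, ...) {
  cat("HMF-W feature selection\n")
  cat(sprintf("  data: %d samples x %d features (%d classes)\n",
              x$n_samples, x$n_features, length(x$levels)))
  cat(sprintf("  ACC = %.4f (%d-fold CV), LEN = %d\n", x$best$acc_mean,
              length(x$best$fold_accs), x$best$subset_length))
  cat(sprintf("  restarts = %d, filter executions = %d, runtime = %.1fs\n",
              x$restarts, x$filter_execs, x$runtime_s))
  cat("  selected:", paste(utils::head(x$feature_ids, 10), collapse = ", "),
      if (length(x$feature_ids) > 10) "..." else "", "\n")
  invisible(x)
}

#' @export
summary.hmfw <- function(object, ...) {
  structure(list(fit = object), class = "summary.hmfw")
}

#' @export
print.summary.hmfw <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  SVM: C = %g, gamma = %g\n", f$best$chosen_c, f$best$chosen_gamma))
  cat("  fold accuracies:", paste(sprintf("%.3f", f$best$fold_accs), collapse = " "), "\n")
  cat(sprintf("  M1 pre-screen kept %d features; config digest %s\n",
              nrow(f$f1), f$digest))
  cat(sprintf("  final AIR = %.4g, final CAD = %d\n",
              utils::tail(stats::na.omit(f$trace$air), 1), utils::tail(f$trace$cad, 1)))
  invisible(x)
}

#' Selected features of a fitted HMF-W run
#'
#' @param object an `"hmfw"` fit.
#' @param ... unused.
#' @return Named integer vector: the selected (1-based) feature column
#'   indices, named by feature id.
#' @export
coef.hmfw <- function(object, ...) {
  stats::setNames(object$feature_indices, object$feature_ids)
}

#' Classify new samples with the selected feature subset
#'
#' Applies the stored min-max normalization (fitted on the training matrix) to
#' the selected columns of `newdata` and predicts with the final SVM.
#'
#' @param object an `"hmfw"` fit.
#' @param newdata matrix or data frame with the same feature columns as the
#'   training data (all of them, not just the selected subset).
#' @param ... unused.
#' @return Factor of predicted class labels.
#' @export
predict.hmfw <- function(object, newdata, ...) {
  nd <- as.matrix(newdata)
  if (ncol(nd) != object$n_features)
    stop("newdata must have ", object$n_features, " feature columns", call. = FALSE)
  xs <- apply_minmax(nd, object$ranges)[, object$feature_indices, drop = FALSE]
  predict(object$svm, xs)
}

#' Convergence and controller trace plot
#'
#' Two stacked base-graphics panels: best-so-far cross-validated accuracy per
#' wrapper iteration (restart iterations marked), and the controller's AIR and
#' CAD against the active patience threshold.
#'
#' @param x an `"hmfw"` fit.
#' @param ... unused.
#' @export
plot.hmfw <- function(x, ...) {
  tr <- x$trace
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  plot(tr$iteration, tr$best_acc, type = "s", lwd = 2, xlab = "wrapper iteration",
       ylab = "best CV accuracy", main = "HMF-W search trace")
  if (any(tr$restart))
    graphics::abline(v = tr$iteration[tr$restart], lty = 3, col = "grey40")
  plot(tr$iteration, tr$cad, type = "s", xlab = "wrapper iteration", ylab = "CAD",
       main = "controller")
  graphics::lines(tr$iteration, tr$threshold, lty = 2)
  graphics::par(new = TRUE)
  plot(tr$iteration, tr$air, type = "l", col = "red3", axes = FALSE,
       xlab = "", ylab = "")
  graphics::axis(4, col.axis = "red3")
  graphics::mtext("AIR", side = 4, line = 2.5, col = "red3")
  invisible(x)
}

#' Repeated HMF-W runs
#'
#' The evaluation protocol: `runs` independent fits with seeds
#' `master_seed, master_seed + 1, ...`, aggregated into mean and SD of
#' accuracy and subset length plus the best and worst run.
#'
#' @param x,y,control as in [hmfw()].
#' @param runs number of repeats (default 10).
#' @param master_seed seed of the first run.
#' @return An `"hmfw_runs"` object: list of fits plus a summary data frame.
#' @export
hmfw_repeat <- function(x, y = NULL, control = hmfw_control(), runs = 10,
                        master_seed = 1) {
  fits <- lapply(seq_len(runs), function(r)
    hmfw(x, y, control = control, seed = master_seed + r - 1L))
  accs <- vapply(fits, function(f) f$best$acc_mean, numeric(1))
  lens <- vapply(fits, function(f) f$best$subset_length, numeric(1))
  summ <- data.frame(run = seq_len(runs), seed = master_seed + seq_len(runs) - 1L,
                     acc = accs, len = lens,
                     restarts = vapply(fits, function(f) f$restarts, integer(1)),
                     runtime_s = vapply(fits, function(f) f$runtime_s, numeric(1)))
  structure(list(fits = fits, summary = summ,
                 acc_mean = mean(accs), acc_sd = stats::sd(accs),
                 len_mean = mean(lens), len_sd = stats::sd(lens),
                 best_run = which.max(accs), worst_run = which.min(accs),
                 digest = fits[[1L]]$digest, master_seed = master_seed),
            class = "hmfw_runs")
}

#' @export
print.hmfw_runs <- function(x, ...) {
  cat(sprintf("HMF-W, %d runs: ACC = %.2f +/- %.2f %%, LEN = %.1f +/- %.1f\n",
              nrow(x$summary), 100 * x$acc_mean, 100 * ifelse(is.na(x$acc_sd), 0, x$acc_sd),
              x$len_mean, ifelse(is.na(x$len_sd), 0, x$len_sd)))
  cat(sprintf("  best run %d (ACC %.4f, LEN %.0f); worst run %d (ACC %.4f, LEN %.0f)\n",
              x$best_run, x$summary$acc[x$best_run], x$summary$len[x$best_run],
              x$worst_run, x$summary$acc[x$worst_run], x$summary$len[x$worst_run]))
  invisible(x)
}

#' @export
as.data.frame.hmfw_runs <- function(x, ...) x$summary

#' Write a run report as JSON
#'
#' Serializes a fit's result, traces, seeds and config digest; wall-clock
#' runtime is reported but never part of any comparison.
#'
#' @param fit an `"hmfw"` object.
#' @param path output path.
#' @param dataset optional dataset identifier embedded in the report.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(fit, path, dataset = NA_character_) {
  rep <- list(dataset = dataset, seeds = fit$seeds, config_digest = fit$digest,
              trace = fit$trace, restarts = fit$restarts,
              filter_execs = fit$filter_execs,
              best = list(acc_mean = fit$best$acc_mean,
                          fold_accs = fit$best$fold_accs,
                          LEN = fit$best$subset_length,
                          feature_ids = fit$feature_ids,
                          feature_indices_1based = fit$feature_indices_1based,
                          chosen_c = fit$best$chosen_c,
                          chosen_gamma = fit$best$chosen_gamma),
              runtime_s = fit$runtime_s)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = 12, dataframe = "columns")
  invisible(path)
}

#' Write an aggregate CSV over repeated runs
#'
#' One row per run plus a trailing mean/SD row, mirroring the usual repeated-
#' runs summary table layout (ACC as a percentage).
#'
#' @param runs an `"hmfw_runs"` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_aggregate_csv <- function(runs, path) {
  s <- runs$summary
  out <- data.frame(run = as.character(s$run), seed = s$seed,
                    acc_pct = round(100 * s$acc, 4), len = s$len,
                    restarts = s$restarts)
  out <- rbind(out, data.frame(run = "mean_sd", seed = runs$master_seed,
                               acc_pct = round(100 * runs$acc_mean, 4),
                               len = round(runs$len_mean, 4),
                               restarts = NA))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
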