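#' Mean squared error between simulated and measured activities
#'
#' The unweighted goodness-of-fit term of the contextualization objective:
#' `(1/N) * sum_i (X_i - Xhat_i)^2` over all N (context, condition, measured
#' node) data points. Measurement SEMs are carried for plotting but do not
#' weight the fit.
#'
#' @param simulated either the data.frame returned by
#'   [simulate_experiments()] (columns `observed`, `simulated`) or a numeric
#'   vector aligned with the measurement rows of `table`.
#' @param table an [experiment_table()]; required when `simulated` is a bare
#'   numeric vector.
#' @return The MSE, a single non-negative number.
#' @export
mse <- function(simulated, table = NULL) {
  if (is.data.frame(simulated)) {
    obs <- simulated$observed
    sim <- simulated$simulated
  } else {
    if (is.null(table)) stop("table required when 'simulated' is a vector")
    obs <- table$measurements$mean
    sim <- as.numeric(simulated)
  }
  if (!length(obs)) stop("validation error: N = 0 data points")
  if (length(obs) != length(sim)) stop("simulated and observed lengths differ")
  mean((obs - sim)^2)
}

#' L1/2 semi-norm sparsity penalty
#'
#' `sum sqrt(k)` over every parameter instance (all interactions, all
#' contexts). Because each activator competition group is constrained to sum
#' to exactly 1, a plain L1 penalty is constant there; the fractional norm
#' still rewards concentrating weight on few interactions, which is what
#' prunes the network. The optimizer uses a smoothed version internally; this
#' function reports the exact value.
#'
#' @param params parameter matrix or named vector (values in \[0,1\]).
#' @return The penalty value.
#' @export
l_half_penalty <- function(params) {
  k <- as.numeric(if (is.matrix(params)) params else params)
  if (any(k < 0)) stop("domain error: negative parameter value")
  sum(sqrt(k))
}

#' Grouped L1 penalty across contexts
#'
#' For each interaction parameter, its per-context instances form one group
#' g with J^g members; the penalty is `sum_g sum_j |k_j^g - mean(k^g)|`.
#' It shrinks a reaction's context-specific values toward their mean, so
#' reactions that do not genuinely differ collapse to one shared value.
#' For a 2-member group the penalty equals `|k_1 - k_2|`.
#'
#' @param params parameter matrix (rows = parameters = groups, columns =
#'   contexts). A vector is treated as a single-context matrix (penalty 0).
#' @return The penalty value.
#' @export
grouped_l1_penalty <- function(params) {
  K <- if (is.matrix(params)) params else matrix(params, ncol = 1)
  sum(abs(K - rowMeans(K)))
}

#' The regularized contextualization objective
#'
#' `MSE + lambda1 * sum sqrt(k) + lambda2 * sum_g sum_j |k_j^g - mean(k^g)|`,
#' evaluated exactly (no smoothing) for a given network, parameter matrix and
#' experiment table. This is the quantity [dbn_fit()] minimizes over
#' `K in [0,1]^(P x contexts)` subject to the sum-to-one competition
#' constraints.
#'
#' @param net a [logic_network()].
#' @param params parameter matrix as in [simulate_experiments()].
#' @param table an [experiment_table()].
#' @param lambda1 L1/2 regularization strength (>= 0).
#' @param lambda2 grouped-L1 regularization strength (>= 0).
#' @param control a [dbn_sim_control()].
#' @return A number; equals the MSE exactly when both lambdas are 0.
#' @export
dbn_objective <- function(net, params, table, lambda1 = 0, lambda2 = 0,
                          control = dbn_sim_control()) {
  stopifnot(lambda1 >= 0, lambda2 >= 0)
  K <- as_param_matrix(params, table$contexts)
  sim <- simulate_experiments(net, K, table, control)
  mse(sim) + lambda1 * l_half_penalty(K) + lambda2 * grouped_l1_penalty(K)
}

#' Fit control settings
#'
#' @param restarts number of random multi-starts (>= 1). The scan functions
#'   lower this to 3 and warm-start along the regularization path.
#' @param seed integer seed for the start points; fits are reproducible given
#'   the seed.
#' @param maxit L-BFGS-B iteration budget per start.
#' @param factr L-BFGS-B relative tolerance factor (`factr * .Machine$double.eps`
#'   is the convergence tolerance on the objective).
#' @param eps smoothing constant for the non-smooth penalty terms inside the
#'   optimizer; reported penalty values are always exact.
#' @param sim a [dbn_sim_control()].
#' @param start optional warm-start parameter matrix used as the first start.
#' @return A list of class `dbn_control`.
#' @export
dbn_control <- function(restarts = 10, seed = 1L, maxit = 2000, factr = 1e4,
                        eps = 1e-8, sim = dbn_sim_control(), start = NULL) {
  stopifnot(restarts >= 1, eps > 0)
  structure(list(restarts = as.integer(restarts), seed = as.integer(seed),
                 maxit = as.integer(maxit), factr = factr, eps = eps,
                 sim = sim, start = start),
            class = "dbn_control")
}

# internal: index bookkeeping for the optimizer -------------------------------
# theta (length P*C, column-major by context) -> constrained K matrix:
# each competition group is renormalized to sum to 1 per context, which
# enforces the equality constraint exactly at every evaluation.
make_normalizer <- function(net, contexts) {
  pn <- net$interactions$parameter
  P <- length(pn)
  C <- length(contexts)
  gidx <- lapply(competition_groups(net), function(g) match(g, pn))
  function(theta) {
    K <- matrix(pmin(pmax(theta, 0), 1), nrow = P, ncol = C,
                dimnames = list(pn, contexts))
    for (g in gidx) {
      s <- colSums(K[g, , drop = FALSE])
      zero <- s < 1e-12
      if (any(zero)) {
        K[g, zero] <- 1 / length(g)
        s[zero] <- 1
      }
      K[g, ] <- sweep(K[g, , drop = FALSE], 2, s, "/")
    }
    K
  }
}

#' Contextualize a logic network against measurement data
#'
#' Jointly fits one parameter value per (interaction, context) by minimizing
#' the regularized objective of [dbn_objective()] over the box \[0,1\] with
#' the activator sum-to-one competition constraints enforced exactly
#' (normalization reparametrization). Optimization is multi-start L-BFGS-B
#' from uniformly drawn feasible points; the non-smooth penalty terms are
#' smoothed (`sqrt(k + eps)` and `sqrt((k - kbar)^2 + eps)`) inside the
#' optimizer only, and all reported values are exact.
#'
#' @param net a [logic_network()].
#' @param table an [experiment_table()]; all its contexts are fitted jointly
#'   with a single N (the total number of data points).
#' @param lambda1 L1/2 sparsity strength (>= 0).
#' @param lambda2 grouped-L1 cross-context strength (>= 0).
#' @param control a [dbn_control()].
#' @return An object of class `dbn_fit` with methods `print`, `summary`,
#'   `coef`, `fitted`, `residuals`, `predict`, `simulate`, `plot`, `AIC`,
#'   `BIC`.
#' @examples
#' net <- read_network(c("@node A input", "@node B measured", "A -> B k1"))
#' tab <- experiment_table(
#'   data.frame(context = "c1", condition = "on", node = "B",
#'              mean = 0.6, sem = 0.02, n = 5),
#'   data.frame(condition = "on", node = "A", value = 1))
#' fit <- dbn_fit(net, tab, control = dbn_control(restarts = 2, seed = 1))
#' coef(fit)  # k1 ~ 0.6
#' @export
dbn_fit <- function(net, table, lambda1 = 0, lambda2 = 0,
                    control = dbn_control()) {
  stopifnot(inherits(net, "logic_network"), inherits(table, "experiment_table"),
            lambda1 >= 0, lambda2 >= 0)
  contexts <- table$contexts
  P <- nrow(net$interactions)
  C <- length(contexts)
  b <- build_batch(net, table, contexts)
  obs <- table$measurements$mean
  ms <- if (is.null(control$sim$max_sweeps)) 100L * b$comp$n_nodes else
    control$sim$max_sweeps
  normalize <- make_normalizer(net, contexts)
  pn <- net$interactions$parameter
  # tighter fixed-point tolerance during optimization keeps the
  # finite-difference gradients clean for feedback loops
  spec_cpp <- list(P = as.integer(P), C = as.integer(C),
                   exp_ctx = b$exp_ctx,
                   clamp_idx = as.integer(b$clamp_idx),
                   clamp_vals = b$clamp_vals,
                   row_node = as.integer(b$row_node - 1L),
                   row_exp = as.integer(b$row_exp - 1L),
                   obs = as.numeric(obs),
                   groups = lapply(competition_groups(net),
                                   function(g) as.integer(match(g, pn) - 1L)),
                   lambda1 = lambda1, lambda2 = lambda2, eps = control$eps,
                   tol = min(control$sim$tolerance, 1e-9),
                   init = control$sim$init, max_sweeps = as.integer(ms))
  fn <- function(theta) cpp_objective(theta, b$comp, spec_cpp)
  gr <- function(theta) cpp_objective_grad(theta, b$comp, spec_cpp, 1e-5)

  set.seed(control$seed)
  starts <- lapply(seq_len(control$restarts), function(i) {
    if (i == 1L && !is.null(control$start)) {
      st <- as_param_matrix(control$start, contexts)
      as.numeric(st[net$interactions$parameter, contexts, drop = FALSE])
    } else stats::runif(P * C)
  })

  runs <- lapply(starts, function(u0) {
    stats::optim(u0, fn, gr, method = "L-BFGS-B", lower = 0, upper = 1,
                 control = list(maxit = control$maxit, factr = control$factr))
  })
  objs <- vapply(runs, `[[`, numeric(1), "value")
  best <- which.min(objs)
  K <- normalize(runs[[best]]$par)

  simdf <- simulate_experiments(net, K, table, control$sim)
  fit_mse <- mse(simdf)
  p1 <- l_half_penalty(K)
  p2 <- grouped_l1_penalty(K)
  structure(list(
    network = net, table = table, contexts = contexts,
    coefficients = K,
    mse = fit_mse,
    penalties = c(l_half = p1, grouped_l1 = p2),
    objective = fit_mse + lambda1 * p1 + lambda2 * p2,
    lambda1 = lambda1, lambda2 = lambda2,
    n = nrow(table$measurements),
    fitted = simdf,
    per_start = objs, best_start = best,
    converged = runs[[best]]$convergence == 0 && all(simdf$converged),
    seed = control$seed, control = control),
    class = "dbn_fit")
}

#' @export
print.dbn_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Contextualized logic network fit (%d parameters x %d contexts)\n",
              nrow(x$coefficients), ncol(x$coefficients)))
  cat(sprintf("  lambda1 = %g, lambda2 = %g; N = %d\n",
              x$lambda1, x$lambda2, x$n))
  cat(sprintf("  MSE = %.*g, objective = %.*g%s\n", digits, x$mse, digits,
              x$objective,
              if (x$converged) "" else "  [not converged]"))
  invisible(x)
}

#' @export
summary.dbn_fit <- function(object, threshold = 0.01, ...) {
  cls <- classify_reactions(object$coefficients, threshold)
  structure(list(fit = object, classification = cls,
                 counts = table(factor(cls, levels = c("shared", "inactive",
                                                       "context_specific"))),
                 p_eff = effective_params(object$coefficients, threshold),
                 aic = AIC(object, threshold = threshold),
                 bic = BIC(object, threshold = threshold),
                 threshold = threshold),
            class = "summary.dbn_fit")
}

#' @export
print.summary.dbn_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  effective parameters (threshold %g): %d; AIC = %.4g, BIC = %.4g\n",
              x$threshold, x$p_eff, x$aic, x$bic))
  cat("  reactions:",
      paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = ", "), "\n")
  k <- x$fit$coefficients
  df <- data.frame(round(k, 4), class = unname(x$classification))
  print(df)
  invisible(x)
}

#' @export
coef.dbn_fit <- function(object, ...) object$coefficients

#' @export
fitted.dbn_fit <- function(object, ...) object$fitted$simulated

#' @export
residuals.dbn_fit <- function(object, ...)
  object$fitted$observed - object$fitted$simulated

#' Information criteria of a contextualized fit
#'
#' `AIC = N log(MSE) + 2 P` and `BIC = N log(MSE) + log(N) P` (natural
#' logarithms), where N is the number of fitted data points and P the
#' effective parameter count: reactions pruned in all contexts count 0,
#' reactions with context-identical values count 1, context-specific
#' reactions count once per context (see [effective_params()]).
#'
#' @param object a [dbn_fit()].
#' @param ... unused.
#' @param k unused (AIC generic compatibility); the penalty is fixed at 2.
#' @param threshold pruning threshold for the effective count.
#' @return A single number.
#' @export
AIC.dbn_fit <- function(object, ..., k = 2, threshold = 0.01)
  aic(object$n, object$mse, effective_params(object$coefficients, threshold))

#' @rdname AIC.dbn_fit
#' @export
BIC.dbn_fit <- function(object, ..., threshold = 0.01)
  bic(object$n, object$mse, effective_params(object$coefficients, threshold))

#' @export
plot.dbn_fit <- function(x, ...) {
  f <- x$fitted
  graphics::plot(f$observed, f$simulated, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "measured (normalized)", ylab = "simulated",
                 pch = 19, col = factor(f$context), ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  graphics::legend("topleft", legend = levels(factor(f$context)),
                   col = seq_along(unique(f$context)), pch = 19, bty = "n")
  invisible(x)
}

#' Predict steady-state activities from a fit
#'
#' Simulates the fitted model for the table's conditions (or a new table) in
#' every context, optionally under interventions (see [intervention()]).
#'
#' @param object a [dbn_fit()].
#' @param table an [experiment_table()]; defaults to the fitting data.
#' @param interventions optional list of [intervention()] objects; predictions
#'   are produced for the unperturbed model and each intervention.
#' @param nodes which nodes to report; default all.
#' @param ... unused.
#' @return A long data.frame with columns `context`, `condition`,
#'   `intervention`, `node`, `activity`.
#' @export
predict.dbn_fit <- function(object, table = NULL, interventions = NULL,
                            nodes = NULL, ...) {
  if (is.null(table)) table <- object$table
  predict_interventions(object$network, object$coefficients, table,
                        interventions = interventions, nodes = nodes,
                        control = object$control$sim)
}

#' Simulate replicate measurement tables from a fitted model
#'
#' Draws `nsim` synthetic experiment tables whose replicate-level values are
#' the fitted steady states plus Gaussian noise (per-replicate sd
#' `noise_sem * sqrt(n)`), mirroring the generator used for ground-truth
#' studies.
#'
#' @param object a [dbn_fit()].
#' @param nsim number of tables.
#' @param seed integer seed.
#' @param noise_sem target standard error of the replicate mean.
#' @param replicates replicates per data point.
#' @param ... unused.
#' @return A list of [experiment_table()]s (length `nsim`).
#' @export
simulate.dbn_fit <- function(object, nsim = 1, seed = NULL, noise_sem = 0.02,
                             replicates = 5, ...) {
  if (!is.null(seed)) set.seed(seed)
  m <- object$table$measurements
  lapply(seq_len(nsim), function(i) {
    reps <- matrix(stats::rnorm(nrow(m) * replicates,
                                mean = rep(object$fitted$simulated, replicates),
                                sd = noise_sem * sqrt(replicates)),
                   nrow = nrow(m))
    reps <- pmax(reps, 0)
    m2 <- m
    m2$mean <- pmin(pmax(rowMeans(reps), 0), 1)
    m2$sem <- apply(reps, 1, stats::sd) / sqrt(replicates)
    m2$n <- replicates
    experiment_table(m2, object$table$conditions,
                     time_label = object$table$time_label)
  })
}

#' Export a fit report as JSON
#'
#' @param fit a [dbn_fit()].
#' @param file optional output path.
#' @return The JSON string, invisibly if written.
#' @export
fit_to_json <- function(fit, file = NULL) {
  obj <- list(contexts = fit$contexts,
              parameters = as.data.frame(fit$coefficients),
              mse = fit$mse,
              objective = fit$objective,
              penalties = as.list(fit$penalties),
              lambda1 = fit$lambda1, lambda2 = fit$lambda2,
              n = fit$n, converged = fit$converged, seed = fit$seed)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(file)) {
    writeLines(js, file)
    return(invisible(js))
  }
  js
}
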