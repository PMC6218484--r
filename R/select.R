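#' Half-log regularization grid
#'
#' Builds the axis of regularization strengths scanned during model
#' selection: `min * base^(0.5 * i)` up to `max` inclusive, optionally
#' prefixed by 0 (the unregularized model). The default range 1e-10 to 1e2
#' in base 10 yields 25 nonzero values, 26 with the leading zero, hence a
#' 26 x 26 = 676-cell scan when used on both axes.
#'
#' @param min,max positive range bounds, `min < max`.
#' @param base logarithm base for the half-log steps (default 10).
#' @param include_zero prepend 0 to the axis.
#' @return Numeric vector of grid values (non-negative, strictly increasing).
#' @examples
#' length(make_grid())            # 26
#' length(make_grid())^2          # 676 (lambda1, lambda2) cells
#' make_grid(1, 10, include_zero = FALSE)  # 1, sqrt(10), 10
#' @export
make_grid <- function(min = 1e-10, max = 1e2, base = 10, include_zero = TRUE) {
  if (!(min > 0 && min < max)) stop("need 0 < min < max")
  n <- floor(2 * log(max / min, base) + 1e-9) + 1L
  v <- min * base^(0.5 * (seq_len(n) - 1L))
  v <- v[v <= max * (1 + 1e-9)]
  if (include_zero) c(0, v) else v
}

#' Effective (non-null) parameter count
#'
#' Counts parameters the way the model-selection criteria penalize them: a
#' reaction whose values fall below the pruning threshold in every context is
#' inactive and contributes 0; a reaction whose per-context values differ by
#' less than the threshold is shared and contributes 1; any other reaction is
#' context-specific and contributes one parameter per context.
#'
#' @param params parameter matrix (rows = reactions, columns = contexts) or a
#'   named vector (single context).
#' @param threshold pruning threshold (> 0), default 0.01.
#' @return Integer count.
#' @examples
#' # 19 shared + 6 context-specific reactions in 2 contexts + 4 pruned = 31
#' K <- rbind(matrix(0.5, 19, 2), cbind(rep(0.2, 6), rep(0.8, 6)),
#'            matrix(0, 4, 2))
#' effective_params(K)
#' @export
effective_params <- function(params, threshold = 0.01) {
  stopifnot(threshold > 0)
  K <- if (is.matrix(params)) params else matrix(params, ncol = 1)
  per <- apply(K, 1, function(k) {
    if (all(k < threshold)) 0L
    else if (max(k) - min(k) < threshold) 1L
    else length(k)
  })
  as.integer(sum(per))
}

#' Classify reactions as inactive, shared, or context-specific
#'
#' Applies the [effective_params()] rules per reaction and returns the label
#' instead of the count. The labels partition the reaction set.
#'
#' @inheritParams effective_params
#' @return Named character vector (one label per reaction).
#' @export
classify_reactions <- function(params, threshold = 0.01) {
  stopifnot(threshold > 0)
  K <- if (is.matrix(params)) params else matrix(params, ncol = 1)
  lab <- apply(K, 1, function(k) {
    if (all(k < threshold)) "inactive"
    else if (max(k) - min(k) < threshold) "shared"
    else "context_specific"
  })
  stats::setNames(lab, rownames(K))
}

#' Akaike and Bayesian information criteria
#'
#' `aic(n, mse, p) = n * log(mse) + 2 * p` and
#' `bic(n, mse, p) = n * log(mse) + log(n) * p` (natural logarithms), the
#' scores used to compare knockout models and to select the best cell of a
#' regularization scan. A zero MSE is floored at machine epsilon with a
#' warning.
#'
#' @param n number of fitted data points (>= 1).
#' @param mse mean squared error (> 0; 0 is floored).
#' @param p effective parameter count.
#' @return A single number.
#' @export
aic <- function(n, mse, p) {
  stopifnot(n >= 1, mse >= 0)
  if (mse <= 0) {
    warning("MSE of 0 floored at machine epsilon for the information criterion")
    mse <- .Machine$double.eps
  }
  n * log(mse) + 2 * p
}

#' @rdname aic
#' @export
bic <- function(n, mse, p) {
  stopifnot(n >= 1, mse >= 0)
  if (mse <= 0) {
    warning("MSE of 0 floored at machine epsilon for the information criterion")
    mse <- .Machine$double.eps
  }
  n * log(mse) + log(n) * p
}

#' Scan a regularization grid and select the minimum-BIC model
#'
#' Fits the network at every (lambda1, lambda2) combination of the two axes,
#' warm-starting each cell from the previous cell's solution along the path
#' (which keeps neighbouring models similarly parametrized), scores every
#' cell by BIC with effective parameter counts, and selects the grid-minimal
#' BIC cell. Ties are broken toward the more strongly regularized cell later
#' in the scan order.
#'
#' @param net a [logic_network()].
#' @param table an [experiment_table()].
#' @param grid1 axis of lambda1 (L1/2) values, see [make_grid()].
#' @param grid2 axis of lambda2 (grouped-L1) values.
#' @param control a [dbn_control()]; scans default to 3 restarts per cell.
#' @param threshold pruning threshold for effective counts and
#'   classification.
#' @return An object of class `dbn_scan`: per-cell results (`cells`), the
#'   three landscape matrices (`bic`, `p_eff`, `log10_mse`; rows = lambda1,
#'   columns = lambda2), the selected cell (`best`), its refitted model
#'   (`best_fit`) and per-reaction classification (`classification`).
#' @export
dbn_scan <- function(net, table, grid1 = make_grid(), grid2 = make_grid(),
                     control = dbn_control(restarts = 3), threshold = 0.01) {
  stopifnot(all(grid1 >= 0), all(grid2 >= 0))
  n1 <- length(grid1)
  n2 <- length(grid2)
  Ks <- vector("list", n1 * n2)
  cells <- expand.grid(i = seq_len(n1), j = seq_len(n2))
  cells <- cells[order(cells$i, cells$j), ]
  rec <- data.frame(i = cells$i, j = cells$j,
                    lambda1 = grid1[cells$i], lambda2 = grid2[cells$j],
                    mse = NA_real_, p_eff = NA_integer_, bic = NA_real_,
                    converged = NA)
  col_first_K <- NULL
  prev_K <- NULL
  fit_objs <- vector("list", nrow(rec))
  for (r in seq_len(nrow(rec))) {
    i <- rec$i[r]; j <- rec$j[r]
    ctl <- control
    ctl$start <- if (j > 1) prev_K else col_first_K
    ctl$seed <- control$seed + r
    f <- tryCatch(dbn_fit(net, table, rec$lambda1[r], rec$lambda2[r], ctl),
                  error = function(e) e)
    if (inherits(f, "error")) {
      warning(sprintf("cell (lambda1=%g, lambda2=%g) failed: %s",
                      rec$lambda1[r], rec$lambda2[r], conditionMessage(f)))
      next
    }
    K <- coef(f)
    Ks[[(j - 1) * n1 + i]] <- K
    fit_objs[[r]] <- f
    rec$mse[r] <- f$mse
    rec$p_eff[r] <- effective_params(K, threshold)
    rec$bic[r] <- bic(f$n, f$mse, rec$p_eff[r])
    rec$converged[r] <- f$converged
    prev_K <- K
    if (j == 1) col_first_K <- K
  }
  ok <- which(!is.na(rec$bic))
  if (!length(ok)) stop("all scan cells failed")
  # ties toward stronger regularization: last minimum in scan order
  best_r <- ok[max(which(rec$bic[ok] <= min(rec$bic[ok]) + 0))]
  best_r <- ok[which(rec$bic[ok] == min(rec$bic[ok]))]
  best_r <- best_r[length(best_r)]
  best_fit <- fit_objs[[best_r]]
  land <- function(col) {
    m <- matrix(NA_real_, n1, n2, dimnames = list(signif(grid1, 6),
                                                  signif(grid2, 6)))
    m[cbind(rec$i, rec$j)] <- col
    m
  }
  structure(list(
    grid1 = grid1, grid2 = grid2, cells = rec,
    bic = land(rec$bic), p_eff = land(rec$p_eff),
    log10_mse = land(log10(pmax(rec$mse, .Machine$double.xmin))),
    params = Ks,
    best = rec[best_r, c("i", "j", "lambda1", "lambda2", "mse", "p_eff", "bic")],
    best_fit = best_fit,
    classification = classify_reactions(coef(best_fit), threshold),
    threshold = threshold),
    class = "dbn_scan")
}

#' @export
print.dbn_scan <- function(x, ...) {
  cat(sprintf("Regularization scan: %d x %d = %d models\n",
              length(x$grid1), length(x$grid2), nrow(x$cells)))
  b <- x$best
  cat(sprintf("  min-BIC cell: lambda1 = %g, lambda2 = %g (BIC = %.4g, MSE = %.4g, P = %d)\n",
              b$lambda1, b$lambda2, b$bic, b$mse, b$p_eff))
  cnt <- table(factor(x$classification,
                      levels = c("shared", "inactive", "context_specific")))
  cat("  selected model reactions:",
      paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.dbn_scan <- function(x, which = c("bic", "p_eff", "log10_mse"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  old <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(old))
  for (w in which) {
    m <- x[[w]]
    graphics::image(seq_along(x$grid1), seq_along(x$grid2), m,
                    xlab = "lambda1 index (L1/2)",
                    ylab = "lambda2 index (grouped L1)",
                    main = w, col = grDevices::hcl.colors(64, "viridis"), ...)
    graphics::points(x$best$i, x$best$j, pch = 0, cex = 2, col = "red", lwd = 2)
  }
  invisible(x)
}

#' Write the three scan landscape matrices as delimited tables
#'
#' @param scan a [dbn_scan()].
#' @param dir output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
write_landscapes <- function(scan, dir) {
  stopifnot(inherits(scan, "dbn_scan"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (w in c("bic", "p_eff", "log10_mse")) {
    p <- file.path(dir, paste0("landscape_", w, ".tsv"))
    utils::write.table(scan[[w]], p, sep = "\t", quote = FALSE,
                       col.names = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}

# internal: nodes reachable from the clamped set (for disconnection checks)
reachable_from_clamped <- function(net) {
  reach <- clamped_names(net)
  repeat {
    new <- net$interactions$target[vapply(net$interactions$sources,
                                          function(s) any(s %in% reach),
                                          logical(1))]
    add <- setdiff(new, reach)
    if (!length(add)) break
    reach <- c(reach, add)
  }
  reach
}

# internal: remove a node's incident interactions and clamp it to 0
knockout_network <- function(net, node) {
  ia <- net$interactions
  keep <- ia$target != node &
    !vapply(ia$sources, function(s) node %in% s, logical(1))
  net2 <- net
  net2$interactions <- ia[keep, , drop = FALSE]
  net2
}

#' Systematic in-silico knockout analysis
#'
#' For every non-input node, removes the node (all incident interactions
#' deleted, activity clamped to 0), refits the reduced model per context and
#' time point, and reports the change in AIC relative to the reference model,
#' whose AIC is scaled to 0. A positive delta-AIC means the network cannot
#' compensate for the loss of the node (it is essential for describing the
#' data); a negative delta-AIC means the node is dispensable. Knockout refits
#' are plain-MSE fits (lambda = 0) by default.
#'
#' @param net a [logic_network()].
#' @param tables a named list of [experiment_table()]s, one per time label,
#'   or a single table.
#' @param control a [dbn_control()].
#' @param lambda1,lambda2 regularization used for the reference and knockout
#'   refits (default 0).
#' @param threshold pruning threshold for effective parameter counts.
#' @return An object of class `dbn_knockout`: `report` with one row per
#'   (node, context, time_label) carrying `delta_aic` (NA with
#'   `disconnected = TRUE` when the knockout leaves no measured node
#'   reachable), and `reference` with the per-(context, time) reference AIC,
#'   exactly 0 on the reported scale.
#' @export
knockout_scan <- function(net, tables, control = dbn_control(restarts = 3),
                          lambda1 = 0, lambda2 = 0, threshold = 0.01) {
  if (inherits(tables, "experiment_table"))
    tables <- stats::setNames(list(tables),
                              tables$time_label %||% "t0")
  ko_nodes <- setdiff(net$nodes$name, input_names(net))
  rows <- list()
  refs <- list()
  for (tl in names(tables)) {
    tab <- tables[[tl]]
    for (ctx in tab$contexts) {
      ctab <- subset_contexts(tab, ctx)
      ref <- dbn_fit(net, ctab, lambda1, lambda2, control)
      ref_aic <- aic(ref$n, ref$mse, effective_params(coef(ref), threshold))
      refs[[length(refs) + 1L]] <- data.frame(
        context = ctx, time_label = tl, aic = 0, stringsAsFactors = FALSE)
      for (nd in ko_nodes) {
        net2 <- knockout_network(net, nd)
        # clamp the knocked-out node to 0 in every condition; a knockout
        # that leaves no measured node reachable from the clamped set is
        # flagged, and scored as the null model (all parameters gone)
        idx <- which(net2$nodes$name == nd)
        net2$nodes$constitutive[idx] <- FALSE
        net2$nodes$role[idx] <- "input"   # clampable in the reduced model
        cond2 <- ctab$conditions
        extra <- do.call(rbind, lapply(unique(cond2$condition), function(cc)
          data.frame(condition = cc, node = nd, value = 0,
                     stringsAsFactors = FALSE)))
        ctab2 <- ctab
        ctab2$conditions <- rbind(cond2[cond2$node != nd, , drop = FALSE], extra)
        disconnected <- nrow(net2$interactions) == 0L ||
          !any(measured_names(net2) %in% reachable_from_clamped(net2))
        if (nrow(net2$interactions) == 0L) {
          # null model: every unclamped node rests at 0
          m2 <- ctab2$measurements
          ko_aic <- aic(nrow(m2), mean(m2$mean^2), 0L)
        } else {
          f <- tryCatch(dbn_fit(net2, ctab2, lambda1, lambda2, control),
                        error = function(e) e)
          if (inherits(f, "error")) {
            rows[[length(rows) + 1L]] <- data.frame(
              node = nd, context = ctx, time_label = tl,
              delta_aic = NA_real_, disconnected = TRUE,
              stringsAsFactors = FALSE)
            next
          }
          ko_aic <- aic(f$n, f$mse, effective_params(coef(f), threshold))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          node = nd, context = ctx, time_label = tl,
          delta_aic = ko_aic - ref_aic, disconnected = disconnected,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(report = do.call(rbind, rows),
                 reference = do.call(rbind, refs)),
            class = "dbn_knockout")
}

#' @export
print.dbn_knockout <- function(x, ...) {
  r <- x$report
  cat(sprintf("In-silico knockout report: %d knockouts over %d (context, time) blocks\n",
              nrow(r), nrow(x$reference)))
  top <- r[order(-r$delta_aic), ]
  cat("  largest delta-AIC (least compensable):\n")
  print(utils::head(top[!is.na(top$delta_aic), ], 5), row.names = FALSE)
  invisible(x)
}

#' Write a knockout report as a long-format table
#'
#' @param ko a [knockout_scan()] result.
#' @param file output path.
#' @return `ko`, invisibly.
#' @export
write_knockout <- function(ko, file) {
  stopifnot(inherits(ko, "dbn_knockout"))
  utils::write.table(ko$report, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(ko)
}

#' Per-time-point differences between two contexts
#'
#' Profiles how strongly the normalized measurement profiles of two contexts
#' diverge over time: per (node, time) the signed difference of per-node
#' means (first context minus second, averaged over conditions), the per-time
#' sum of absolute differences, and the time labels ranked by that total.
#'
#' @param tables named list of [experiment_table()]s, one per time label,
#'   each containing both contexts.
#' @param contexts optionally, the two contexts to compare (defaults to the
#'   first two found).
#' @return An object of class `dbn_context_profile`: `diff` (node x time
#'   signed matrix), `total` (per-time sum of absolute differences) and
#'   `ranking` (time labels, most divergent first).
#' @export
context_difference_profile <- function(tables, contexts = NULL) {
  stopifnot(is.list(tables), length(tables) >= 1)
  if (is.null(names(tables)))
    names(tables) <- vapply(tables, function(t) t$time_label %||% "t0", "")
  if (is.null(contexts)) contexts <- tables[[1]]$contexts[1:2]
  if (length(contexts) != 2 || anyNA(contexts))
    stop("need two contexts to compare")
  cols <- lapply(names(tables), function(tl) {
    m <- tables[[tl]]$measurements
    a <- m[m$context == contexts[1], ]
    b <- m[m$context == contexts[2], ]
    am <- tapply(a$mean, a$node, mean)
    bm <- tapply(b$mean, b$node, mean)
    common <- intersect(names(am), names(bm))
    dropped <- setdiff(union(names(am), names(bm)), common)
    if (length(dropped))
      warning("node(s) missing in one context excluded: ",
              paste(dropped, collapse = ", "))
    am[common] - bm[common]
  })
  nodes <- sort(unique(unlist(lapply(cols, names))))
  D <- matrix(NA_real_, length(nodes), length(tables),
              dimnames = list(nodes, names(tables)))
  for (j in seq_along(cols)) D[names(cols[[j]]), j] <- cols[[j]]
  total <- colSums(abs(D), na.rm = TRUE)
  structure(list(diff = D, total = total,
                 ranking = names(sort(total, decreasing = TRUE)),
                 contexts = contexts),
            class = "dbn_context_profile")
}

#' @export
print.dbn_context_profile <- function(x, ...) {
  cat(sprintf("Context difference profile (%s - %s)\n",
              x$contexts[1], x$contexts[2]))
  cat("  time points ranked by total |difference|:",
      paste(x$ranking, collapse = " > "), "\n")
  print(round(x$diff, 3))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
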