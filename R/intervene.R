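#' Specify an in-silico intervention
#'
#' Three idioms are supported. `knockout` removes the node: its activity is
#' clamped to 0 and all incident interactions become inert (deleted).
#' `clamp` holds the node at a fixed activity for every sweep.
#' `remove_incoming` is the super-repressor idiom: the node's inhibitory
#' (degradation) inputs are removed while its activating (synthesis) inputs
#' are kept — a non-degradable IkBa mutant keeps being synthesized but no
#' longer responds to IKK. A node left with no incoming interactions at all
#' becomes a constitutive source held at its basal simulated activity.
#'
#' @param kind one of `"knockout"`, `"clamp"`, `"remove_incoming"`.
#' @param node node name.
#' @param clamp_value activity in \[0,1\]; required (and allowed) only for
#'   `kind = "clamp"`.
#' @return An object of class `dbn_intervention`.
#' @export
intervention <- function(kind = c("knockout", "clamp", "remove_incoming"),
                         node, clamp_value = NULL) {
  kind <- match.arg(kind)
  if (kind == "clamp") {
    if (is.null(clamp_value) || clamp_value < 0 || clamp_value > 1)
      stop("clamp_value in [0,1] required for kind = 'clamp'")
  } else if (!is.null(clamp_value)) {
    stop("clamp_value only applies to kind = 'clamp'")
  }
  structure(list(kind = kind, node = node, clamp_value = clamp_value),
            class = "dbn_intervention")
}

#' @export
print.dbn_intervention <- function(x, ...) {
  cat(sprintf("Intervention: %s(%s%s)\n", x$kind, x$node,
              if (!is.null(x$clamp_value)) paste0(", ", x$clamp_value) else ""))
  invisible(x)
}

# internal: label used in prediction reports
intervention_label <- function(iv) {
  if (iv$kind == "clamp") sprintf("clamp(%s=%g)", iv$node, iv$clamp_value)
  else sprintf("%s(%s)", iv$kind, iv$node)
}

# internal: drop the inhibitory incoming interactions of a node
remove_incoming_network <- function(net, node) {
  drop <- net$interactions$target == node &
    net$interactions$sign == "inhibition"
  net$interactions <- net$interactions[!drop, , drop = FALSE]
  net
}

# internal: does the node still receive any interaction?
has_incoming <- function(net, node) node %in% net$interactions$target

#' Apply an intervention to a network and parameter set
#'
#' Returns the modified model pieces for one context and one clamp setting:
#' the reduced network, the parameter matrix restricted to its surviving
#' interactions, and the clamp vector augmented with the intervention clamp.
#' For `remove_incoming` the basal activity is the node's steady state of the
#' unmodified model under the supplied clamps. Intervening on an input node
#' is an error (inputs are experimental handles, not intervention targets).
#'
#' @param net a [logic_network()].
#' @param params parameter matrix or named vector.
#' @param iv an [intervention()].
#' @param clamps named clamp vector covering the input nodes (used to compute
#'   the basal state for `remove_incoming`).
#' @param control a [dbn_sim_control()].
#' @return A list with elements `net`, `params`, `clamps`.
#' @export
apply_intervention <- function(net, params, iv, clamps = numeric(),
                               control = dbn_sim_control()) {
  stopifnot(inherits(iv, "dbn_intervention"))
  if (!iv$node %in% net$nodes$name)
    stop("schema error: unknown node '", iv$node, "'")
  if (iv$node %in% input_names(net))
    stop("cannot intervene on input node '", iv$node, "'")
  K <- if (is.matrix(params)) params else
    matrix(params, ncol = 1, dimnames = list(names(params), "ctx"))
  if (iv$kind == "knockout") {
    net2 <- knockout_network(net, iv$node)
    net2$nodes$constitutive[net2$nodes$name == iv$node] <- FALSE
    cl <- c(clamps[setdiff(names(clamps), iv$node)],
            stats::setNames(0, iv$node))
  } else if (iv$kind == "clamp") {
    net2 <- net
    cl <- c(clamps[setdiff(names(clamps), iv$node)],
            stats::setNames(iv$clamp_value, iv$node))
  } else {
    net2 <- remove_incoming_network(net, iv$node)
    if (!has_incoming(net2, iv$node)) {
      base <- steady_state(net, K[, 1], clamps, control)
      cl <- c(clamps[setdiff(names(clamps), iv$node)],
              stats::setNames(unname(base$activities[iv$node]), iv$node))
    } else cl <- clamps
  }
  keep <- net2$interactions$parameter
  list(net = net2, params = K[keep, , drop = FALSE], clamps = cl)
}

#' Predict intervention outcomes across contexts and conditions
#'
#' Simulates the full factorial of (context x condition x intervention,
#' including the unperturbed model) at steady state and reports node
#' activities. For `remove_incoming` interventions the basal clamp is
#' computed per (context, condition) from the unperturbed model. Duplicate
#' interventions are deduplicated with a warning. Activities are reported
#' raw in \[0,1\]; an optional linear calibration (see [percent_scale()])
#' maps a readout to percent — it is never applied silently.
#'
#' @param net a [logic_network()].
#' @param params parameter matrix (one column per context).
#' @param table an [experiment_table()] supplying contexts and conditions.
#' @param interventions list of [intervention()] objects (may be empty for a
#'   baseline-only report).
#' @param nodes nodes to report (default: readout nodes if any, else
#'   measured nodes).
#' @param percent optional function mapping activity to percent; adds a
#'   `percent` column.
#' @param control a [dbn_sim_control()].
#' @return A data.frame of class `dbn_prediction` with columns `context`,
#'   `condition`, `intervention`, `node`, `activity`, `converged` (and
#'   optionally `percent`). The attribute `"best_intervention"` records, per
#'   context, which intervention maximizes the mean reported activity.
#' @export
predict_interventions <- function(net, params, table, interventions = list(),
                                  nodes = NULL, percent = NULL,
                                  control = dbn_sim_control()) {
  stopifnot(inherits(net, "logic_network"), inherits(table, "experiment_table"))
  if (inherits(interventions, "dbn_intervention"))
    interventions <- list(interventions)
  labs <- vapply(interventions, intervention_label, "")
  if (anyDuplicated(labs)) {
    warning("duplicate intervention(s) removed: ",
            paste(unique(labs[duplicated(labs)]), collapse = ", "))
    interventions <- interventions[!duplicated(labs)]
  }
  K <- as_param_matrix(params, table$contexts)
  if (is.null(nodes)) {
    nodes <- net$nodes$name[net$nodes$role == "readout"]
    if (!length(nodes)) nodes <- measured_names(net)
  }
  conds <- unique(table$conditions$condition)
  grid <- expand.grid(condition = conds, context = table$contexts,
                      stringsAsFactors = FALSE)
  run_one <- function(net_i, K_i, extra_clamps_fun, label) {
    out <- lapply(seq_len(nrow(grid)), function(r) {
      ctx <- grid$context[r]
      cond <- grid$condition[r]
      cl <- condition_clamps(table, cond)
      ec <- extra_clamps_fun(ctx, cond, cl)
      st <- steady_state(net_i, K_i[, ctx], c(cl, ec), control)
      data.frame(context = ctx, condition = cond, intervention = label,
                 node = nodes,
                 activity = unname(st$activities[nodes]),
                 converged = st$converged, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  res <- list(run_one(net, K, function(...) numeric(), "none"))
  for (iv in interventions) {
    if (iv$kind == "remove_incoming") {
      if (iv$node %in% input_names(net))
        stop("cannot intervene on input node '", iv$node, "'")
      net2 <- remove_incoming_network(net, iv$node)
      K2 <- K[net2$interactions$parameter, , drop = FALSE]
      clamp_fun <- if (has_incoming(net2, iv$node)) {
        function(ctx, cond, cl) numeric()
      } else {
        # basal activity per (context, condition) from the unperturbed model
        function(ctx, cond, cl) {
          base <- steady_state(net, K[, ctx], cl, control)
          stats::setNames(unname(base$activities[iv$node]), iv$node)
        }
      }
      res[[length(res) + 1L]] <- run_one(net2, K2, clamp_fun,
                                         intervention_label(iv))
    } else {
      mod <- apply_intervention(net, K, iv, clamps = numeric(0), control)
      res[[length(res) + 1L]] <- run_one(
        mod$net, mod$params,
        function(ctx, cond, cl) mod$clamps,
        intervention_label(iv))
    }
  }
  df <- do.call(rbind, res)
  if (!is.null(percent)) df$percent <- percent(df$activity)
  agg <- stats::aggregate(activity ~ context + intervention, df, mean)
  best <- vapply(split(agg, agg$context),
                 function(d) d$intervention[which.max(d$activity)], "")
  structure(df, class = c("dbn_prediction", "data.frame"),
            best_intervention = best)
}

#' Linear activity-to-percent calibration
#'
#' Maps a readout activity in \[0,1\] linearly through two anchor points
#' supplied by the user (activity `a0` corresponds to `p0` percent, `a1` to
#' `p1`). A death-assay style preset in the spirit of "an enrichment factor
#' of 2 corresponds to 10% apoptosis" can be built by anchoring the measured
#' enrichment-equivalent activities; no calibration is ever applied unless
#' passed explicitly.
#'
#' @param a0,p0,a1,p1 anchor points.
#' @return A function mapping activity to percent.
#' @export
percent_scale <- function(a0 = 0, p0 = 0, a1 = 1, p1 = 100) {
  stopifnot(a1 != a0)
  function(a) p0 + (a - a0) * (p1 - p0) / (a1 - a0)
}

#' Write a prediction report as a long-format table
#'
#' @param pred a [predict_interventions()] result.
#' @param file output path.
#' @return `pred`, invisibly.
#' @export
write_predictions <- function(pred, file) {
  utils::write.table(as.data.frame(pred), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(pred)
}
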