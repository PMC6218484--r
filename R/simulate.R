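#' Simulation control settings
#'
#' @param tolerance convergence tolerance on the maximum per-node change
#'   between synchronous sweeps.
#' @param max_sweeps sweep budget; defaults to `100 * n_nodes` when a network
#'   is supplied to the simulator and `NULL` here.
#' @param init initial activity of unclamped nodes.
#' @return A list of class `dbn_sim_control`.
#' @export
dbn_sim_control <- function(tolerance = 1e-6, max_sweeps = NULL, init = 0) {
  stopifnot(tolerance > 0, is.null(max_sweeps) || max_sweeps >= 1,
            init >= 0, init <= 1)
  structure(list(tolerance = tolerance, max_sweeps = max_sweeps, init = init),
            class = "dbn_sim_control")
}

# internal: compile a logic_network into the integer encoding the C++
# simulator consumes (0-based indices, CSR source lists)
compile_network <- function(net) {
  stopifnot(inherits(net, "logic_network"))
  nm <- net$nodes$name
  idx <- stats::setNames(seq_along(nm) - 1L, nm)
  ia <- net$interactions
  gate_code <- c(single = 0L, AND = 1L, OR = 2L)
  src <- unlist(lapply(ia$sources, function(s) unname(idx[s])))
  src_ptr <- c(0L, cumsum(vapply(ia$sources, length, integer(1))))
  has_in <- as.integer(nm %in% ia$target)
  list(n_nodes = length(nm),
       node_names = nm,
       param_names = ia$parameter,
       ia_target = unname(idx[ia$target]),
       ia_gate = unname(gate_code[ia$gate]),
       ia_sign = as.integer(ia$sign == "activation"),
       ia_param = seq_len(nrow(ia)) - 1L,
       src = as.integer(if (is.null(src)) integer() else src),
       src_ptr = as.integer(src_ptr),
       has_in = has_in)
}

# internal: resolve clamp indices/values; constitutive nodes clamp to 1
# unless overridden by an explicit clamp
resolve_clamps <- function(net, clamps) {
  cv <- stats::setNames(rep(1, sum(net$nodes$constitutive)),
                        net$nodes$name[net$nodes$constitutive])
  cv[names(clamps)] <- clamps
  unknown <- setdiff(names(cv), net$nodes$name)
  if (length(unknown))
    stop("schema error: clamp on unknown node(s): ",
         paste(unknown, collapse = ", "))
  miss <- setdiff(input_names(net), names(cv))
  if (length(miss))
    stop("validation error: input node(s) without clamp: ",
         paste(miss, collapse = ", "))
  cv
}

#' Single-node update of the probabilistic logic model
#'
#' The building block of the simulator, exposed for inspection: activation
#' `a = sum_i k_i g_i` over the node's activating interactions, where the gate
#' value `g_i` is the source activity (single source), the product of source
#' activities (AND), or the probabilistic union `1 - prod(1 - x)` (OR); the
#' result is `a * prod_j (1 - h_j g_j)` over inhibitory interactions, clipped
#' to \[0,1\].
#'
#' @param net a [logic_network()].
#' @param target node name to update.
#' @param state named numeric vector of current activities in \[0,1\].
#' @param params named numeric vector of parameter values.
#' @return Updated activity of `target`, in \[0,1\].
#' @export
node_update <- function(net, target, state, params) {
  ia <- net$interactions[net$interactions$target == target, , drop = FALSE]
  gate_value <- function(sources, gate) {
    x <- state[sources]
    switch(gate, single = x[[1]], AND = prod(x), OR = 1 - prod(1 - x))
  }
  a <- 0
  inh <- 1
  for (i in seq_len(nrow(ia))) {
    g <- gate_value(ia$sources[[i]], ia$gate[i])
    kg <- params[[ia$parameter[i]]] * g
    if (ia$sign[i] == "activation") a <- a + kg
    else inh <- inh * (1 - min(max(kg, 0), 1))
  }
  min(max(a * inh, 0), 1)
}

#' Deterministic steady state of a logic network
#'
#' Runs synchronous sweeps of [node_update()] over all nodes from a fixed
#' initial state until the maximum per-node change drops below the tolerance.
#' Input nodes are held at their clamp values throughout; constitutive nodes
#' clamp to 1 unless overridden. Non-convergence (possible for feedback loops
#' at extreme parameters) is reported through the `converged` flag, not as an
#' error: the last state is returned and the caller decides.
#'
#' @param net a [logic_network()].
#' @param params named numeric vector of parameter values in \[0,1\], one per
#'   interaction (a single context).
#' @param clamps named numeric vector of clamped activities; must cover all
#'   input nodes.
#' @param control a [dbn_sim_control()].
#' @return A list of class `dbn_state`: `activities` (named, in \[0,1\]),
#'   `converged`, `sweeps`.
#' @examples
#' net <- read_network(c("@node A input", "A -> B k1", "B -> C k2"))
#' st <- steady_state(net, c(k1 = 0.8, k2 = 0.5), clamps = c(A = 1))
#' st$activities  # B = 0.8, C = 0.4
#' @export
steady_state <- function(net, params, clamps = numeric(),
                         control = dbn_sim_control()) {
  if (is.matrix(params))
    params <- stats::setNames(params[, 1], rownames(params))
  comp <- compile_network(net)
  k <- params[comp$param_names]
  if (anyNA(k))
    stop("validation error: missing parameter value(s): ",
         paste(setdiff(comp$param_names, names(params)), collapse = ", "))
  cv <- resolve_clamps(net, clamps)
  ci <- match(names(cv), comp$node_names) - 1L
  ms <- if (is.null(control$max_sweeps)) 100L * comp$n_nodes else control$max_sweeps
  st <- cpp_steady_state(comp, as.numeric(k), as.integer(ci), as.numeric(cv),
                         control$tolerance, as.integer(ms), control$init)
  structure(list(activities = stats::setNames(as.numeric(st), comp$node_names),
                 converged = attr(st, "converged"),
                 sweeps = attr(st, "sweeps")),
            class = "dbn_state")
}

#' @export
print.dbn_state <- function(x, ...) {
  cat(sprintf("Steady state (%s in %d sweeps)\n",
              if (x$converged) "converged" else "NOT converged", x$sweeps))
  print(round(x$activities, 4))
  invisible(x)
}

#' Export a steady state as a delimited table
#'
#' @param state a `dbn_state` from [steady_state()].
#' @param file output path.
#' @return `state`, invisibly.
#' @export
write_state <- function(state, file) {
  stopifnot(inherits(state, "dbn_state"))
  utils::write.table(
    data.frame(node = names(state$activities),
               activity = as.numeric(state$activities),
               converged = state$converged),
    file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(state)
}

# internal: batch description of an experiment table -------------------------
# experiments = unique (context, condition) pairs; returns the pieces the C++
# batch simulator needs plus the mapping from measurement rows to experiments
build_batch <- function(net, table, contexts) {
  comp <- compile_network(net)
  m <- table$measurements
  key <- paste(m$context, m$condition, sep = "\r")
  ukey <- unique(key)
  exp_ctx <- match(sub("\r.*$", "", ukey), contexts)
  if (anyNA(exp_ctx))
    stop("validation error: parameters not defined for context(s): ",
         paste(unique(sub("\r.*$", "", ukey)[is.na(exp_ctx)]), collapse = ", "))
  exp_cond <- sub("^.*\r", "", ukey)
  cl0 <- resolve_clamps(net, condition_clamps(table, exp_cond[1]))
  clamp_nodes <- names(cl0)
  clamp_vals <- vapply(exp_cond, function(cond) {
    cv <- resolve_clamps(net, condition_clamps(table, cond))
    cv[clamp_nodes]
  }, numeric(length(clamp_nodes)))
  clamp_vals <- matrix(clamp_vals, nrow = length(clamp_nodes))
  list(comp = comp,
       exp_ctx = as.integer(exp_ctx - 1L),
       clamp_idx = match(clamp_nodes, comp$node_names) - 1L,
       clamp_vals = clamp_vals,
       row_exp = match(key, ukey),
       row_node = match(m$node, comp$node_names))
}

#' Simulate a network for every row of an experiment table
#'
#' Computes the steady state of the network under every (context, condition)
#' pair occurring in the table, using the context's own parameter column, and
#' aligns the simulated activities with the measurement rows.
#'
#' @param net a [logic_network()].
#' @param params numeric matrix of parameter values, one row per interaction
#'   parameter (rownames = parameter names) and one column per context
#'   (colnames = context names); or, for a single context, a named vector.
#' @param table an [experiment_table()].
#' @param control a [dbn_sim_control()].
#' @return A data.frame aligned with `table$measurements`, with columns
#'   `context`, `condition`, `node`, `observed`, `simulated`, `converged`.
#' @export
simulate_experiments <- function(net, params, table,
                                 control = dbn_sim_control()) {
  stopifnot(inherits(table, "experiment_table"))
  K <- as_param_matrix(params, table$contexts)
  b <- build_batch(net, table, colnames(K))
  K <- K[b$comp$param_names, , drop = FALSE]
  ms <- if (is.null(control$max_sweeps)) 100L * b$comp$n_nodes else control$max_sweeps
  S <- cpp_simulate_batch(b$comp, K, b$exp_ctx, as.integer(b$clamp_idx),
                          b$clamp_vals, control$tolerance, as.integer(ms),
                          control$init)
  conv <- attr(S, "converged")
  m <- table$measurements
  data.frame(context = m$context, condition = m$condition, node = m$node,
             observed = m$mean,
             simulated = S[cbind(b$row_node, b$row_exp)],
             converged = conv[b$row_exp],
             stringsAsFactors = FALSE)
}

# internal: coerce parameter input to a P x n_contexts matrix
as_param_matrix <- function(params, contexts) {
  if (is.matrix(params)) {
    if (is.null(colnames(params)))
      colnames(params) <- contexts[seq_len(ncol(params))]
    miss <- setdiff(contexts, colnames(params))
    if (length(miss))
      stop("validation error: parameters not defined for context(s): ",
           paste(miss, collapse = ", "))
    return(params[, contexts, drop = FALSE])
  }
  if (is.null(names(params))) stop("parameters must be named")
  matrix(rep(as.numeric(params), length(contexts)),
         ncol = length(contexts),
         dimnames = list(names(params), contexts))
}

#' Validate a parameter matrix against a network
#'
#' Checks that every interaction parameter has a value in \[0,1\] for every
#' context and that each activator competition group sums to 1 (within 1e-9)
#' per context.
#'
#' @param net a [logic_network()].
#' @param params parameter matrix as in [simulate_experiments()].
#' @return `TRUE`, invisibly; otherwise an error.
#' @export
validate_params <- function(net, params) {
  K <- if (is.matrix(params)) params else
    matrix(params, dimnames = list(names(params), "ctx"))
  miss <- setdiff(net$interactions$parameter, rownames(K))
  if (length(miss))
    stop("validation error: missing parameter(s): ", paste(miss, collapse = ", "))
  if (any(K < -1e-12 | K > 1 + 1e-12))
    stop("validation error: parameter values must lie in [0,1]")
  for (g in competition_groups(net)) {
    s <- colSums(K[g, , drop = FALSE])
    if (any(abs(s - 1) > 1e-9))
      stop("validation error: competition group {",
           paste(g, collapse = ", "), "} does not sum to 1")
  }
  invisible(TRUE)
}
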