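#' Specification of a synthetic ground truth
#'
#' Describes the study design the generator emulates: a random connected
#' logic network with known parameters in several contexts, of which a given
#' number of reactions are inactive (zero in every context) and a given
#' number are context-specific (per-context values separated by at least
#' 0.3), the remainder shared. The default noise and replication mirror the
#' quantitative immunoblotting design the package targets: 5 replicates and
#' measurement SEMs on the normalized scale.
#'
#' @param n_nodes number of nodes.
#' @param n_reactions number of interactions (one parameter each).
#' @param n_contexts number of contexts (default 2).
#' @param n_zero reactions set to 0 in all contexts.
#' @param n_specific reactions with context-specific values.
#' @param noise_sem target SEM of the replicate mean on the \[0,1\] scale.
#' @param replicates replicates per data point (default 5).
#' @param feedback allow cycle-forming extra edges (default FALSE).
#' @param measured_frac fraction of non-input nodes that are measured
#'   (floored at 60% of all nodes). The default measures every non-input
#'   node: parameters of edges through unobserved nodes are structurally
#'   non-identifiable (only path products are), and a recovery benchmark
#'   needs a recoverable truth. Lower it to emulate latent nodes.
#' @param seed integer seed; everything downstream is reproducible from it.
#' @return A list of class `truth_spec`.
#' @export
truth_spec <- function(n_nodes, n_reactions, n_contexts = 2, n_zero = 0,
                       n_specific = 0, noise_sem = 0.02, replicates = 5,
                       feedback = FALSE, measured_frac = 1, seed = 1L) {
  stopifnot(n_nodes >= 3, n_zero + n_specific <= n_reactions,
            replicates >= 1, noise_sem >= 0, n_contexts >= 1,
            measured_frac >= 0, measured_frac <= 1)
  structure(list(n_nodes = n_nodes, n_reactions = n_reactions,
                 n_contexts = n_contexts, n_zero = n_zero,
                 n_specific = n_specific, noise_sem = noise_sem,
                 replicates = as.integer(replicates), feedback = feedback,
                 measured_frac = measured_frac, seed = as.integer(seed)),
            class = "truth_spec")
}

#' Generate a random ground-truth network and parameter set
#'
#' Builds a connected network (inputs first, every other node wired to an
#' earlier node so signal reaches everything; at least 60% of nodes
#' measured), draws shared parameters uniformly from \[0.2, 0.9\], zeroes
#' `n_zero` reactions in every context and resamples `n_specific` reactions
#' per context with a pairwise gap of at least 0.3, then renormalizes the
#' activator competition groups. Zero and context-specific reactions are
#' drawn from parameters outside competition groups, so renormalization
#' cannot silently reclassify a group partner; inactive reactions are
#' preferentially inhibitory edges, whose silencing does not disconnect the
#' network.
#'
#' @param spec a [truth_spec()].
#' @return A list of class `dbn_truth`: `network` (a [logic_network()]),
#'   `params` (matrix, reactions x contexts), `classes` (the true label per
#'   reaction) and `spec`.
#' @export
generate_truth <- function(spec) {
  stopifnot(inherits(spec, "truth_spec"))
  set.seed(spec$seed)
  n <- spec$n_nodes
  n_in <- max(1L, round(0.15 * n))
  n_span <- n - n_in
  if (spec$n_reactions < n_span)
    stop("infeasible spec: need at least ", n_span,
         " reactions to connect ", n, " nodes")
  mf <- spec$measured_frac %||% 1
  n_meas <- max(ceiling(0.6 * n), round(mf * (n - n_in)))
  n_meas <- min(n_meas, n - n_in)
  names_all <- sprintf("N%02d", seq_len(n))
  roles <- c(rep("input", n_in),
             sample(c(rep("measured", n_meas),
                      rep("latent", n - n_in - n_meas))))
  nodes <- data.frame(name = names_all, role = roles, constitutive = FALSE,
                      stringsAsFactors = FALSE)

  # spanning activation edges: node i (> inputs) fed from a random earlier node
  edges <- data.frame(src = names_all[vapply((n_in + 1):n, function(i)
                        sample.int(i - 1L, 1L), integer(1))],
                      tgt = names_all[(n_in + 1):n],
                      sign = "activation", stringsAsFactors = FALSE)
  need_free <- spec$n_zero + spec$n_specific
  n_extra <- spec$n_reactions - n_span
  n_extra_inh <- min(n_extra, max(spec$n_zero, ceiling(n_extra / 2)))
  pos <- stats::setNames(seq_len(n), names_all)
  tries <- 0L
  while (nrow(edges) < spec$n_reactions && tries < 1000L) {
    tries <- tries + 1L
    tgt <- sample(names_all[(n_in + 1):n], 1L)
    src_pool <- if (spec$feedback) setdiff(names_all, tgt) else
      names_all[seq_len(pos[tgt] - 1L)]
    if (!length(src_pool)) next
    src <- sample(src_pool, 1L)
    if (any(edges$src == src & edges$tgt == tgt)) next
    inh_left <- n_extra_inh - sum(edges$sign == "inhibition")
    extra_left <- spec$n_reactions - nrow(edges)
    sgn <- if (inh_left >= extra_left) "inhibition"
      else if (inh_left > 0 && stats::runif(1) < 0.6) "inhibition"
      else "activation"
    # keep enough non-competing parameters for the zero/specific labels
    if (sgn == "activation") {
      n_act_on_tgt <- sum(edges$sign == "activation" & edges$tgt == tgt)
      prospective <- rbind(edges, data.frame(src = src, tgt = tgt,
                                             sign = "activation",
                                             stringsAsFactors = FALSE))
      act_counts <- table(prospective$tgt[prospective$sign == "activation"])
      n_constrained <- sum(act_counts[act_counts >= 2])
      if (nrow(prospective) - n_constrained < need_free) sgn <- "inhibition"
      if (sgn == "inhibition" &&
          any(edges$src == src & edges$tgt == tgt)) next
    }
    edges <- rbind(edges, data.frame(src = src, tgt = tgt, sign = sgn,
                                     stringsAsFactors = FALSE))
  }
  if (nrow(edges) < spec$n_reactions)
    stop("infeasible spec: could not place ", spec$n_reactions,
         " distinct reactions on ", n, " nodes")

  ia <- data.frame(id = sprintf("r%d", seq_len(nrow(edges))),
                   target = edges$tgt, gate = "single", sign = edges$sign,
                   parameter = sprintf("k%02d", seq_len(nrow(edges))),
                   stringsAsFactors = FALSE)
  ia$sources <- as.list(edges$src)
  net <- logic_network(nodes, ia)

  cg <- unlist(competition_groups(net))
  free <- setdiff(ia$parameter, cg)
  if (length(free) < need_free)
    stop("infeasible spec: only ", length(free),
         " unconstrained parameters for ", need_free, " zero/specific labels")
  shared_val <- stats::runif(nrow(ia), 0.2, 0.9)
  K <- matrix(shared_val, nrow(ia), spec$n_contexts,
              dimnames = list(ia$parameter,
                              sprintf("ctx%d", seq_len(spec$n_contexts))))
  classes <- stats::setNames(rep("shared", nrow(ia)), ia$parameter)

  # inactive reactions come from inhibitory free parameters only: silencing
  # an activation edge can cut off a subtree and make downstream labels
  # unrecoverable by construction
  free_inh <- intersect(free, ia$parameter[ia$sign == "inhibition"])
  if (spec$n_zero > length(free_inh))
    stop("infeasible spec: ", spec$n_zero, " inactive reactions but only ",
         length(free_inh), " inhibitory parameters to silence")
  zero_pick <- free_inh[seq_len(spec$n_zero)]
  if (spec$n_zero > 0) {
    K[zero_pick, ] <- 0
    classes[zero_pick] <- "inactive"
  }
  spec_pool <- setdiff(free, zero_pick)
  spec_act <- intersect(spec_pool, ia$parameter[ia$sign == "activation"])
  spec_pick <- c(sample(spec_act), sample(setdiff(spec_pool, spec_act)))[
    seq_len(spec$n_specific)]
  for (p in spec_pick) {
    lo <- stats::runif(1, 0.05, 0.35)
    hi <- stats::runif(1, lo + 0.3, 0.95)
    v <- sample(c(lo, hi))
    K[p, ] <- rep_len(v, spec$n_contexts)
    classes[p] <- "context_specific"
  }
  for (g in competition_groups(net)) {
    s <- colSums(K[g, , drop = FALSE])
    K[g, ] <- sweep(K[g, , drop = FALSE], 2, s, "/")
  }
  structure(list(network = net, params = K, classes = classes, spec = spec),
            class = "dbn_truth")
}

#' @export
print.dbn_truth <- function(x, ...) {
  cat("Synthetic ground truth\n")
  print(x$network)
  cnt <- table(factor(x$classes, levels = c("shared", "inactive",
                                            "context_specific")))
  cat("  true classes:",
      paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "), "\n")
  invisible(x)
}

#' Factorial stimulation conditions for a network's inputs
#'
#' Enumerates input clamp combinations over \{0, 1\} (capped; beyond the cap
#' a random subset is drawn under the current RNG state).
#'
#' @param net a [logic_network()].
#' @param max_conditions cap on the number of conditions.
#' @return A conditions data.frame (`condition`, `node`, `value`).
#' @export
truth_conditions <- function(net, max_conditions = 16) {
  ins <- input_names(net)
  combos <- expand.grid(rep(list(c(0, 1)), length(ins)))
  names(combos) <- ins
  if (nrow(combos) > max_conditions)
    combos <- combos[sample.int(nrow(combos), max_conditions), , drop = FALSE]
  do.call(rbind, lapply(seq_len(nrow(combos)), function(i)
    data.frame(condition = sprintf("cond%02d", i), node = ins,
               value = as.numeric(combos[i, ]), stringsAsFactors = FALSE)))
}

#' Generate replicate-level raw measurements from a ground truth
#'
#' Simulates the network to steady state for every (context, condition) and
#' emits replicate-level values: steady-state activity plus Gaussian noise
#' with per-replicate standard deviation `noise_sem * sqrt(replicates)` (so
#' the replicate mean has standard error `noise_sem`), truncated at 0.
#'
#' @param net a [logic_network()].
#' @param params parameter matrix (reactions x contexts).
#' @param conditions conditions data.frame as from [truth_conditions()].
#' @param noise_sem target SEM of the replicate mean.
#' @param replicates replicates per cell.
#' @param seed integer seed.
#' @param control a [dbn_sim_control()].
#' @return A data.frame of class `raw_measurements` with columns `context`,
#'   `condition`, `node`, `replicate`, `value`.
#' @export
generate_data <- function(net, params, conditions, noise_sem = 0.02,
                          replicates = 5, seed = 1L,
                          control = dbn_sim_control()) {
  set.seed(seed)
  K <- if (is.matrix(params)) params else
    matrix(params, ncol = 1, dimnames = list(names(params), "ctx1"))
  meas <- measured_names(net)
  rows <- list()
  for (ctx in colnames(K)) {
    for (cond in unique(conditions$condition)) {
      cl <- conditions[conditions$condition == cond, ]
      st <- steady_state(net, K[, ctx], stats::setNames(cl$value, cl$node),
                         control)
      for (nd in meas) {
        v <- st$activities[[nd]] +
          stats::rnorm(replicates, 0, noise_sem * sqrt(replicates))
        rows[[length(rows) + 1L]] <- data.frame(
          context = ctx, condition = cond, node = nd,
          replicate = seq_len(replicates), value = pmax(v, 0),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(do.call(rbind, rows), class = c("raw_measurements", "data.frame"))
}

#' Min-max normalize raw measurements into an experiment table
#'
#' Emulates the normalization applied to quantitative immunoblot data:
#' independently for each protein, all raw values — pooled over contexts,
#' conditions and replicates — are min-max rescaled to \[0,1\] (the global
#' per-protein maximum maps to 1 and the minimum to 0), after which the mean
#' and standard error over replicates are computed per (context, condition,
#' node) cell. Set `average_first = TRUE` for the alternative
#' average-then-normalize order.
#'
#' @param raw a `raw_measurements` data.frame (see [generate_data()]), or any
#'   data.frame with columns `context`, `condition`, `node`, `replicate`,
#'   `value`.
#' @param conditions conditions data.frame defining the input clamps.
#' @param network optional [logic_network()] for validation.
#' @param average_first average replicates before rescaling.
#' @param time_label optional tag.
#' @return An [experiment_table()].
#' @export
normalize_measurements <- function(raw, conditions, network = NULL,
                                   average_first = FALSE, time_label = NULL) {
  stopifnot(all(c("context", "condition", "node", "replicate", "value") %in%
                  names(raw)))
  cellkey <- function(d) paste(d$context, d$condition, d$node, sep = "\r")
  if (average_first) {
    agg <- stats::aggregate(value ~ context + condition + node, raw, mean)
    sdv <- stats::aggregate(value ~ context + condition + node, raw, stats::sd)
    nrep <- stats::aggregate(value ~ context + condition + node, raw, length)
    rng <- tapply(agg$value, agg$node, range)
    span <- vapply(rng, diff, numeric(1))
    if (any(span <= 0))
      stop("zero range: constant protein(s): ",
           paste(names(span)[span <= 0], collapse = ", "))
    lo <- vapply(rng, `[`, numeric(1), 1)
    sem <- sdv$value / span[agg$node] / sqrt(nrep$value)
    m <- data.frame(context = agg$context, condition = agg$condition,
                    node = agg$node,
                    mean = (agg$value - lo[agg$node]) / span[agg$node],
                    sem = ifelse(is.na(sem), 0, sem),
                    n = nrep$value, stringsAsFactors = FALSE)
  } else {
    rng <- tapply(raw$value, raw$node, range)
    span <- vapply(rng, diff, numeric(1))
    if (any(span <= 0))
      stop("zero range: constant protein(s): ",
           paste(names(span)[span <= 0], collapse = ", "))
    lo <- vapply(rng, `[`, numeric(1), 1)
    norm <- (raw$value - lo[raw$node]) / span[raw$node]
    key <- cellkey(raw)
    mu <- tapply(norm, key, mean)
    sdv <- tapply(norm, key, stats::sd)
    nrep <- tapply(norm, key, length)
    parts <- strsplit(names(mu), "\r", fixed = TRUE)
    sem <- as.numeric(sdv) / sqrt(as.numeric(nrep))
    m <- data.frame(context = vapply(parts, `[`, "", 1),
                    condition = vapply(parts, `[`, "", 2),
                    node = vapply(parts, `[`, "", 3),
                    mean = as.numeric(mu),
                    sem = ifelse(is.na(sem), 0, sem),
                    n = as.numeric(nrep), stringsAsFactors = FALSE)
  }
  experiment_table(m, conditions, network = network, time_label = time_label)
}

#' Generate an experiment table directly on the model scale
#'
#' Convenience wrapper for ground-truth recovery studies: replicate values
#' are steady-state activities plus truncated Gaussian noise, averaged into
#' an [experiment_table()] without min-max rescaling (the data are already on
#' the model's \[0,1\] activity scale, and rescaling would deliberately
#' distort the parameters being recovered).
#'
#' @inheritParams generate_data
#' @param time_label optional tag.
#' @return An [experiment_table()].
#' @export
generate_table <- function(net, params, conditions, noise_sem = 0.02,
                           replicates = 5, seed = 1L,
                           control = dbn_sim_control(), time_label = NULL) {
  raw <- generate_data(net, params, conditions, noise_sem, replicates, seed,
                       control)
  key <- paste(raw$context, raw$condition, raw$node, sep = "\r")
  mu <- tapply(raw$value, key, mean)
  sdv <- tapply(raw$value, key, stats::sd)
  nrep <- tapply(raw$value, key, length)
  parts <- strsplit(names(mu), "\r", fixed = TRUE)
  m <- data.frame(context = vapply(parts, `[`, "", 1),
                  condition = vapply(parts, `[`, "", 2),
                  node = vapply(parts, `[`, "", 3),
                  mean = pmin(pmax(as.numeric(mu), 0), 1),
                  sem = as.numeric(sdv) / sqrt(as.numeric(nrep)),
                  n = as.numeric(nrep), stringsAsFactors = FALSE)
  m$sem[is.na(m$sem)] <- 0
  experiment_table(m, conditions, network = net, time_label = time_label)
}

#' The packaged melanoma signalling network fixture
#'
#' Loads the 19-node, 29-parameter TRAIL/NFkB/MAPK melanoma network shipped
#' with the package, together with its condition template: contexts
#' `parental` and `conditioned`, conditions `untreated` and `treated`
#' (TRAIL-receptor agonist on), and time labels 1, 2, 4, 8, 16, 24, 48 h.
#' The topology is a synthetic reconstruction around the documented
#' inhibitory reactions `FLIP -| Casp8cl`, `BCL2 -| Casp3cl` and
#' `XIAP -| Casp3cl`; seven nodes are measured (AKT, ERK, FLIP, XIAP, IkBa,
#' NFkB, PARPcl).
#'
#' @return A list: `network`, `conditions` (clamp template), `contexts`,
#'   `time_labels`, `measured`.
#' @export
melanoma_fixture <- function() {
  path <- system.file("extdata", "melanoma.net.tsv", package = "dbnlogic",
                      mustWork = TRUE)
  net <- read_network(path)
  conditions <- data.frame(
    condition = c("untreated", "treated"),
    node = "IZI1551", value = c(0, 1), stringsAsFactors = FALSE)
  list(network = net, conditions = conditions,
       contexts = c("parental", "conditioned"),
       time_labels = paste0(c(1, 2, 4, 8, 16, 24, 48), "h"),
       measured = measured_names(net))
}

#' Synthetic ground-truth parameters for the melanoma fixture
#'
#' A hand-set two-context parameter matrix emulating the resistance biology
#' the fixture models: the `XIAP -| Casp3cl` inhibition is near-absent in
#' parental cells (k = 0.0135) but strong in conditioned cells (k = 0.8715),
#' NFkB signalling is rewired toward the receptor-driven branch in
#' conditioned cells, and four reactions are inactive (< 0.01) in both
#' contexts. The matrix has 19 shared, 4 inactive and 6 context-specific
#' reactions — 31 effective parameters at the 0.01 threshold. These values
#' are synthetic anchors for testing and demonstration, not fitted estimates.
#'
#' @return A 29 x 2 parameter matrix (columns `parental`, `conditioned`).
#' @export
melanoma_truth_params <- function() {
  p <- c(
    k_izi_dr = 0.90, k_dr_c8 = 0.80, k_flip_c8 = 0.005,
    k_c8_c3 = 0.60, k_momp_c3 = 0.40, k_xiap_c3 = 0.0135,
    k_bcl2_c3 = 0.004, k_c8_momp = 0.70, k_bcl2_momp = 0.005,
    k_momp_smac = 0.80, k_smac_xiap = 0.008, k_c3_parp = 0.90,
    k_c3_apo = 0.90, k_akt_apo = 0.20, k_dr_ikk = 0.30,
    k_ikk_ikb = 0.70, k_nfkb_ikb = 0.60, k_ikb_nfkb = 0.70,
    k_ikk_nfkb = 0.50, k_akt_nfkb = 0.50, k_nfkb_flip = 0.60,
    k_erk_flip = 0.40, k_nfkb_xiap = 0.70, k_akt_xiap = 0.30,
    k_nfkb_bcl2 = 0.50, k_erk_bcl2 = 0.50, k_braf_mek = 0.90,
    k_mek_erk = 0.80, k_pi3k_akt = 0.70)
  K <- cbind(parental = p, conditioned = p)
  K["k_xiap_c3", "conditioned"] <- 0.8715
  K["k_dr_ikk", "conditioned"] <- 0.80
  K["k_akt_apo", "conditioned"] <- 0.40
  K["k_c8_momp", "conditioned"] <- 0.35
  K["k_ikk_nfkb", "conditioned"] <- 0.80
  K["k_akt_nfkb", "conditioned"] <- 0.20
  K
}

#' Synthetic measurement table for the melanoma fixture
#'
#' Generates a two-context experiment table from the fixture network and the
#' synthetic truth of [melanoma_truth_params()] (untreated and treated
#' conditions, 5 replicates), on the model's activity scale.
#'
#' @param noise_sem measurement noise (SEM scale).
#' @param replicates replicates per cell.
#' @param seed integer seed.
#' @param time_label optional tag.
#' @return An [experiment_table()].
#' @export
melanoma_synthetic_table <- function(noise_sem = 0.02, replicates = 5,
                                     seed = 1L, time_label = NULL) {
  fx <- melanoma_fixture()
  K <- melanoma_truth_params()
  generate_table(fx$network, K, fx$conditions, noise_sem = noise_sem,
                 replicates = replicates, seed = seed,
                 time_label = time_label)
}
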