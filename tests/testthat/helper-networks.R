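# Shared fixtures built in code, plus an independent reference simulator.

chain_net <- function() {
  read_network(c("@node A input",
                 "@node B measured",
                 "@node C measured",
                 "A -> B k1",
                 "B -> C k2"))
}

# two activators competing on C, one inhibitor on C
diamond_net <- function() {
  read_network(c("@node A input",
                 "@node B input",
                 "@node I input",
                 "@node C measured",
                 "A -> C k1",
                 "B -> C k2",
                 "I -| C k3"))
}

# independent brute-force fixed-point iterator, written directly from the
# gate definitions with none of the package's compiled machinery
ref_fixed_point <- function(net, params, clamps, tol = 1e-9,
                            max_iter = 10000, init = 0) {
  nodes <- net$nodes$name
  const <- net$nodes$name[net$nodes$constitutive]
  cl <- setNames(rep(1, length(const)), const)
  cl[names(clamps)] <- clamps
  x <- setNames(rep(init, length(nodes)), nodes)
  x[names(cl)] <- cl
  has_in <- nodes %in% net$interactions$target
  for (it in seq_len(max_iter)) {
    xn <- x
    for (nd in nodes) {
      if (nd %in% names(cl)) next
      if (!has_in[match(nd, nodes)]) next
      rows <- which(net$interactions$target == nd)
      a <- 0; inh <- 1
      for (r in rows) {
        srcs <- net$interactions$sources[[r]]
        g <- switch(net$interactions$gate[r],
                    single = x[[srcs]],
                    AND = prod(x[srcs]),
                    OR = 1 - prod(1 - x[srcs]))
        kg <- params[[net$interactions$parameter[r]]] * g
        if (net$interactions$sign[r] == "activation") a <- a + kg
        else inh <- inh * (1 - min(max(kg, 0), 1))
      }
      xn[nd] <- min(max(a * inh, 0), 1)
    }
    if (max(abs(xn - x)) < tol) return(xn)
    x <- xn
  }
  x
}

# random single-gate network on n nodes for oracle-equivalence sweeps;
# independent of the package's truth generator
random_small_net <- function(n = 6, p_extra = 0.5, p_inh = 0.3) {
  name <- sprintf("V%d", seq_len(n))
  lines <- c(sprintf("@node %s input", name[1]),
             sprintf("@node %s measured", name[-1]))
  k <- 0
  body <- character()
  for (i in 2:n) {
    k <- k + 1
    src <- name[sample.int(i - 1, 1)]
    body <- c(body, sprintf("%s -> %s k%02d", src, name[i], k))
  }
  for (i in 2:n) {
    if (runif(1) < p_extra) {
      src <- name[sample.int(i - 1, 1)]
      if (!any(grepl(sprintf("^%s .. %s ", src, name[i]), body))) {
        k <- k + 1
        arrow <- if (runif(1) < p_inh) "-|" else "->"
        body <- c(body, sprintf("%s %s %s k%02d", src, arrow, name[i], k))
      }
    }
  }
  net <- read_network(c(lines, body))
  params <- setNames(runif(nrow(net$interactions)),
                     net$interactions$parameter)
  for (g in competition_groups(net)) params[g] <- params[g] / sum(params[g])
  list(net = net, params = params)
}

# one-row-per-cell measurement table helper
tiny_table <- function(net, means, condition_clamps, context = "c1",
                       sem = 0.01, n = 5) {
  conds <- do.call(rbind, lapply(names(condition_clamps), function(cc)
    data.frame(condition = cc, node = names(condition_clamps[[cc]]),
               value = as.numeric(condition_clamps[[cc]]),
               stringsAsFactors = FALSE)))
  meas <- do.call(rbind, lapply(names(means), function(cc)
    data.frame(context = context, condition = cc,
               node = names(means[[cc]]), mean = as.numeric(means[[cc]]),
               sem = sem, n = n, stringsAsFactors = FALSE)))
  experiment_table(meas, conds, network = net)
}
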