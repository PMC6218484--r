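# simple two-context resistance motif: stimulus S drives readout R through D;
# inhibitor I (constitutively present) is strong only in context B
resistance_net <- function() {
  read_network(c("@node S input", "@node I latent constitutive",
                 "@node D latent", "@node R readout",
                 "S -> D k1", "D -> R k2", "I -| R k3"))
}

resistance_params <- function()
  cbind(A = c(k1 = 0.9, k2 = 0.9, k3 = 0.05),
        B = c(k1 = 0.9, k2 = 0.9, k3 = 0.9))

resistance_table <- function(net) {
  meas <- expand.grid(context = c("A", "B"), condition = c("off", "on"),
                      node = "R", stringsAsFactors = FALSE)
  meas$mean <- 0.5; meas$sem <- 0.02; meas$n <- 5
  cond <- data.frame(condition = c("off", "on"), node = "S", value = c(0, 1))
  experiment_table(meas, cond, network = net)
}

test_that("interventions validate their arguments", {
  expect_error(intervention("clamp", "X"), "clamp_value")
  expect_error(intervention("knockout", "X", clamp_value = 0.5),
               "only applies")
  net <- resistance_net()
  expect_error(apply_intervention(net, resistance_params(),
                                  intervention("knockout", "S")),
               "input node")
  expect_error(apply_intervention(net, resistance_params(),
                                  intervention("knockout", "Z")),
               "unknown node")
})

test_that("knockout clamps the node to zero and is idempotent", {
  net <- resistance_net()
  K <- resistance_params()
  iv <- intervention("knockout", "I")
  m1 <- apply_intervention(net, K, iv)
  m2 <- apply_intervention(m1$net, m1$params, iv, clamps = m1$clamps)
  st1 <- steady_state(m1$net, m1$params[, "B"], c(m1$clamps, S = 1))
  st2 <- steady_state(m2$net, m2$params[, "B"], c(m2$clamps, S = 1))
  expect_equal(st1$activities, st2$activities)
  expect_equal(unname(st1$activities["I"]), 0)

  # knocking out a node already at rest changes nothing
  netq <- read_network(c("@node A input", "@node Q latent",
                         "A -> B k1", "B -> Q k2"))
  Kq <- c(k1 = 0.5, k2 = 0.5)
  base <- steady_state(netq, Kq, c(A = 0))
  mq <- apply_intervention(netq, Kq, intervention("knockout", "Q"),
                           clamps = c(A = 0))
  after <- steady_state(mq$net, mq$params, mq$clamps)
  expect_equal(after$activities[c("A", "B")], base$activities[c("A", "B")])
  expect_equal(unname(after$activities["Q"]), unname(base$activities["Q"]))
})

test_that("clamped nodes hold their value at steady state", {
  net <- resistance_net()
  K <- resistance_params()
  m <- apply_intervention(net, K, intervention("clamp", "D", clamp_value = 1))
  st <- steady_state(m$net, m$params[, "A"], c(m$clamps, S = 0))
  expect_equal(unname(st$activities["D"]), 1)
})

test_that("remove_incoming strips degradation inputs, keeping synthesis", {
  net <- resistance_net()
  K <- resistance_params()
  # super-repressor on R: the inhibitory edge k3 goes, the activator stays
  m <- apply_intervention(net, K, intervention("remove_incoming", "R"),
                          clamps = c(S = 1))
  expect_false("k3" %in% rownames(m$params))
  expect_true("k2" %in% rownames(m$params))
  st <- steady_state(m$net, m$params[, "B"], c(m$clamps, S = 1))
  base <- steady_state(net, K[, "B"], c(S = 1))
  expect_gt(unname(st$activities["R"]), unname(base$activities["R"]))

  # a node left without any input is frozen at its basal activity
  net2 <- read_network(c("@node S input", "@node I latent constitutive",
                         "I -| W kW", "S -> R2 kR"))
  m2 <- apply_intervention(net2, c(kW = 0.5, kR = 0.5),
                           intervention("remove_incoming", "W"),
                           clamps = c(S = 1))
  base2 <- steady_state(net2, c(kW = 0.5, kR = 0.5), c(S = 1))
  expect_equal(unname(m2$clamps["W"]), unname(base2$activities["W"]))
})

test_that("knockout of the resistance inhibitor equalizes the contexts", {
  net <- resistance_net()
  K <- resistance_params()
  tab <- resistance_table(net)
  pred <- predict_interventions(net, K, tab,
                                list(intervention("knockout", "I")))
  on <- pred[pred$condition == "on" & pred$node == "R", ]
  base_gap <- abs(diff(on$activity[on$intervention == "none"]))
  ko_gap <- abs(diff(on$activity[on$intervention == "knockout(I)"]))
  expect_gt(base_gap, 0.5)
  expect_lt(ko_gap, 0.05)
})

test_that("in an activation-only acyclic network knockouts never raise a readout", {
  set.seed(71)
  for (i in 1:5) {
    rs <- random_small_net(p_inh = 0)
    base <- steady_state(rs$net, rs$params, c(V1 = 1))
    for (nd in setdiff(rs$net$nodes$name, "V1")) {
      m <- apply_intervention(rs$net, rs$params,
                              intervention("knockout", nd), clamps = c(V1 = 1))
      st <- steady_state(m$net, m$params[, 1], m$clamps)
      expect_true(all(st$activities <= base$activities + 1e-12))
    }
  }
})

test_that("prediction reports cover the factorial and deduplicate", {
  net <- resistance_net()
  K <- resistance_params()
  tab <- resistance_table(net)
  base_only <- predict_interventions(net, K, tab)
  expect_setequal(unique(base_only$intervention), "none")
  expect_equal(nrow(base_only), 4L)   # 2 contexts x 2 conditions x 1 node

  expect_warning(
    pred <- predict_interventions(net, K, tab,
                                  list(intervention("knockout", "I"),
                                       intervention("knockout", "I"))),
    "duplicate")
  expect_equal(sort(unique(pred$intervention)), c("knockout(I)", "none"))
  expect_named(attr(pred, "best_intervention"), c("A", "B"))

  scaled <- predict_interventions(net, K, tab, percent = percent_scale())
  expect_equal(scaled$percent, 100 * scaled$activity)
})

test_that("XIAP knockout re-sensitizes the conditioned melanoma model", {
  fx <- melanoma_fixture()
  K <- melanoma_truth_params()
  tab <- melanoma_synthetic_table(noise_sem = 0, seed = 1)
  pred <- predict_interventions(
    fx$network, K, tab,
    list(intervention("knockout", "XIAP"),
         intervention("remove_incoming", "IkBa")),
    nodes = "Apoptosis")
  g <- function(ctx, cond, ivn) pred$activity[pred$context == ctx &
                                                pred$condition == cond &
                                                pred$intervention == ivn]
  # conditioned cells are resistant at baseline
  expect_gt(g("parental", "treated", "none"),
            g("conditioned", "treated", "none") + 0.1)
  # XIAP knockout restores apoptosis beyond the untreated parental level
  expect_gte(g("conditioned", "treated", "knockout(XIAP)"),
             g("parental", "untreated", "none"))
  # ordering: super-repressor partial, knockout full re-sensitization
  expect_gt(g("conditioned", "treated", "remove_incoming(IkBa)"),
            g("conditioned", "treated", "none"))
  expect_gt(g("conditioned", "treated", "knockout(XIAP)"),
            g("conditioned", "treated", "remove_incoming(IkBa)"))
})
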