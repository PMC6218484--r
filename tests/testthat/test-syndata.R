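test_that("ground-truth generation is reproducible and correctly labelled", {
  sp <- truth_spec(12, 16, n_zero = 3, n_specific = 3, seed = 1)
  tr1 <- generate_truth(sp)
  tr2 <- generate_truth(sp)
  expect_identical(tr1$params, tr2$params)
  expect_identical(write_network(tr1$network), write_network(tr2$network))

  # no context-specific reactions: the contexts coincide
  tr0 <- generate_truth(truth_spec(10, 12, n_zero = 2, n_specific = 0,
                                   seed = 2))
  expect_equal(tr0$params[, 1], tr0$params[, 2])
})

test_that("the effective count of a generated truth matches its labels", {
  for (s in 1:50) {
    sp <- truth_spec(12, 16, n_zero = 3, n_specific = 3, seed = s)
    tr <- generate_truth(sp)
    expect_equal(effective_params(tr$params), (16 - 3) + 3)
    expect_equal(sum(tr$classes == "inactive"), 3L)
    expect_equal(sum(tr$classes == "context_specific"), 3L)
    # competition groups still sum to one after relabelling
    expect_true(validate_params(tr$network, tr$params))
  }
})

test_that("infeasible truth specifications are rejected", {
  expect_error(generate_truth(truth_spec(12, 5, seed = 1)), "infeasible")
  # more inactive labels than inhibitory parameters to silence
  expect_error(generate_truth(truth_spec(6, 5, n_zero = 4, seed = 1)),
               "infeasible")
})

test_that("generated replicates carry the requested noise", {
  tr <- generate_truth(truth_spec(10, 12, seed = 3))
  cond <- truth_conditions(tr$network)
  raw0 <- generate_data(tr$network, tr$params, cond, noise_sem = 0, seed = 4)
  spread <- tapply(raw0$value, paste(raw0$context, raw0$condition, raw0$node),
                   function(v) diff(range(v)))
  expect_true(all(spread == 0))

  # replicate SEM close to the requested level across many cells
  tr2 <- generate_truth(truth_spec(16, 20, seed = 30))
  cond <- truth_conditions(tr2$network)
  raw <- generate_data(tr2$network, tr2$params, cond, noise_sem = 0.05,
                       replicates = 5, seed = 5)
  sems <- tapply(raw$value, paste(raw$context, raw$condition, raw$node),
                 function(v) sd(v) / sqrt(length(v)))
  expect_gt(length(sems), 100)
  expect_lt(abs(mean(sems) - 0.05) / 0.05, 0.3)
  expect_true(all(raw$value >= 0))
})

test_that("all-zero inputs silence an activation-only network", {
  set.seed(81)
  rs <- random_small_net(p_inh = 0)
  cond <- data.frame(condition = "off", node = "V1", value = 0)
  raw <- generate_data(rs$net, rs$params, cond, noise_sem = 0, seed = 6)
  expect_true(all(raw$value == 0))
})

test_that("min-max normalization matches hand arithmetic and is scale invariant", {
  raw <- data.frame(context = "c1", condition = c("a", "b", "c"),
                    node = "P", replicate = 1,
                    value = c(10, 20, 30))
  cond <- data.frame(condition = c("a", "b", "c"), node = "S", value = c(0, 0.5, 1))
  tab <- normalize_measurements(raw, cond)
  expect_equal(sort(tab$measurements$mean), c(0, 0.5, 1))

  raw2 <- raw; raw2$value <- raw2$value * 7
  tab2 <- normalize_measurements(raw2, cond)
  expect_equal(tab2$measurements$mean, tab$measurements$mean)

  const <- raw; const$value <- 5
  expect_error(normalize_measurements(const, cond), "zero range")
})

test_that("normalization composes with the generator", {
  tr <- generate_truth(truth_spec(8, 10, seed = 7))
  cond <- truth_conditions(tr$network)
  raw <- generate_data(tr$network, tr$params, cond, noise_sem = 0, seed = 8)
  tab <- normalize_measurements(raw, cond)
  expect_true(all(tab$measurements$mean >= 0 & tab$measurements$mean <= 1))
  per_node_max <- tapply(tab$measurements$mean, tab$measurements$node, max)
  per_node_min <- tapply(tab$measurements$mean, tab$measurements$node, min)
  expect_true(all(abs(per_node_max - 1) < 1e-12))
  expect_true(all(abs(per_node_min) < 1e-12))

  # exact agreement with independently rescaled steady states
  key <- paste(raw$context, raw$condition, raw$node)
  states <- tapply(raw$value, key, mean)   # noiseless: replicates identical
  nodes_of <- sub("^.* ", "", names(states))
  lo <- tapply(states, nodes_of, min)[nodes_of]
  hi <- tapply(states, nodes_of, max)[nodes_of]
  rescaled <- as.numeric((states - lo) / (hi - lo))
  m <- tab$measurements
  got <- m$mean[match(names(states), paste(m$context, m$condition, m$node))]
  expect_equal(got, rescaled, tolerance = 1e-12)
})

test_that("average-then-normalize is available behind a flag", {
  tr <- generate_truth(truth_spec(8, 10, seed = 9))
  cond <- truth_conditions(tr$network)
  raw <- generate_data(tr$network, tr$params, cond, noise_sem = 0.03, seed = 10)
  t1 <- normalize_measurements(raw, cond)
  t2 <- normalize_measurements(raw, cond, average_first = TRUE)
  expect_equal(dim(t1$measurements), dim(t2$measurements))
  expect_false(isTRUE(all.equal(t1$measurements$mean, t2$measurements$mean)))
})

test_that("the melanoma fixture reproduces the published structure", {
  fx <- melanoma_fixture()
  expect_equal(nrow(fx$network$nodes), 19L)
  expect_equal(nrow(fx$network$interactions), 29L)
  expect_equal(length(unique(fx$network$interactions$parameter)), 29L)
  expect_setequal(fx$measured,
                  c("AKT", "ERK", "FLIP", "XIAP", "IkBa", "NFkB", "PARPcl"))
  expect_length(fx$measured, 7L)
  expect_length(fx$time_labels, 7L)
  ia <- fx$network$interactions
  named <- function(src, tgt) any(ia$sign == "inhibition" & ia$target == tgt &
                                    vapply(ia$sources, identical, TRUE, src))
  expect_true(named("FLIP", "Casp8cl"))
  expect_true(named("BCL2", "Casp3cl"))
  expect_true(named("XIAP", "Casp3cl"))
})

test_that("the synthetic melanoma truth encodes the resistance switch", {
  K <- melanoma_truth_params()
  expect_equal(K["k_xiap_c3", "parental"], 0.0135)
  expect_equal(K["k_xiap_c3", "conditioned"], 0.8715)
  cls <- classify_reactions(K)
  expect_equal(sum(cls == "shared"), 19L)
  expect_equal(sum(cls == "inactive"), 4L)
  expect_equal(sum(cls == "context_specific"), 6L)
  expect_equal(effective_params(K), 31L)
})
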