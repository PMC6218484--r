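test_that("half-log grids have the canonical sizes", {
  g <- make_grid()
  expect_length(g, 26L)
  expect_equal(g[1], 0)
  expect_equal(g[2], 1e-10)
  expect_equal(g[26], 1e2, tolerance = 1e-9)
  expect_equal(length(g)^2, 676L)
  expect_equal(make_grid(1, 10, include_zero = FALSE),
               c(1, 10^0.5, 10), tolerance = 1e-12)
  expect_error(make_grid(10, 1), "min < max")
  expect_true(all(diff(g) > 0))
})

test_that("effective parameter counting follows the pruning rules", {
  K <- rbind(matrix(0.5, 19, 2),
             cbind(rep(0.2, 6), rep(0.8, 6)),
             matrix(0.001, 4, 2))
  expect_equal(effective_params(K), 31L)
  expect_equal(effective_params(matrix(0, 10, 2)), 0L)
  expect_equal(effective_params(matrix(c(rep(0.2, 29), rep(0.8, 29)), 29, 2)),
               58L)
  # raising the threshold never increases the count
  set.seed(5)
  K2 <- matrix(runif(40), 20, 2)
  counts <- vapply(c(0.005, 0.01, 0.05, 0.1, 0.3),
                   function(th) effective_params(K2, th), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("reaction classification partitions the reaction set", {
  expect_equal(unname(classify_reactions(matrix(c(0.005, 0.003), 1))),
               "inactive")
  expect_equal(unname(classify_reactions(matrix(c(0.40, 0.41), 1))), "shared")
  expect_equal(unname(classify_reactions(matrix(c(0.0135, 0.8715), 1))),
               "context_specific")
  set.seed(6)
  K <- matrix(runif(30), 15, 2)
  cls <- classify_reactions(K)
  expect_length(cls, 15L)
  expect_true(all(cls %in% c("inactive", "shared", "context_specific")))
})

test_that("information criteria match their formulas", {
  expect_equal(aic(100, exp(-1), 0), -100)
  expect_equal(aic(50, 0.3, 4) - aic(50, 0.3, 3), 2)
  expect_equal(bic(exp(2), exp(-1), 1), -exp(2) + 2)
  set.seed(7)
  for (i in 1:20) {
    n <- sample(10:500, 1); m <- runif(1, 1e-6, 1); p <- sample(0:60, 1)
    expect_equal(aic(n, m, p), n * log(m) + 2 * p)
    expect_equal(bic(n, m, p), n * log(m) + log(n) * p)
  }
  # beyond n = e^2 the BIC penalizes parameters harder than the AIC
  expect_gt(bic(10, 0.1, 3) - bic(10, 0.1, 2), aic(10, 0.1, 3) - aic(10, 0.1, 2))
  expect_warning(aic(10, 0, 1), "floored")
})

test_that("degenerate single-cell scans reduce to one unregularized fit", {
  net <- chain_net()
  tab <- tiny_table(net, means = list(u = c(B = 0.5, C = 0.3)),
                    condition_clamps = list(u = c(A = 1)))
  sc <- dbn_scan(net, tab, 0, 0, dbn_control(restarts = 2, seed = 3))
  expect_equal(nrow(sc$cells), 1L)
  expect_equal(sc$best$lambda1, 0)
  f <- dbn_fit(net, tab, control = dbn_control(restarts = 2, seed = 4))
  expect_equal(sc$best$mse, f$mse, tolerance = 1e-6)
})

test_that("scan landscapes cover the full grid and select the min BIC", {
  set.seed(31)
  rs <- random_small_net(n = 6)
  cond <- truth_conditions(rs$net)
  tab <- generate_table(rs$net, rs$params, cond, noise_sem = 0.02, seed = 32)
  g <- c(0, 1e-4, 1e-2)
  sc <- dbn_scan(rs$net, tab, g, g, dbn_control(restarts = 2, seed = 33))
  expect_equal(nrow(sc$cells), 9L)
  expect_equal(dim(sc$bic), c(3L, 3L))
  expect_equal(min(sc$cells$bic, na.rm = TRUE), sc$best$bic)
  # selected model never uses more effective parameters than unregularized
  expect_lte(sc$best$p_eff, sc$cells$p_eff[sc$cells$lambda1 == 0 &
                                             sc$cells$lambda2 == 0])
  d <- tempfile()
  paths <- write_landscapes(sc, d)
  expect_true(all(file.exists(file.path(d, c("landscape_bic.tsv",
                                             "landscape_p_eff.tsv",
                                             "landscape_log10_mse.tsv")))))
  unlink(d, recursive = TRUE)
})

test_that("knockout of a bottleneck node is maximally destabilizing", {
  # S feeds hub H; H alone feeds every measured node
  net <- read_network(c("@node S input", "@node H latent",
                        paste("@node", sprintf("M%d", 1:5), "measured"),
                        "S -> H k0",
                        sprintf("H -> M%d k%d", 1:5, 1:5)))
  truth <- setNames(c(0.9, 0.8, 0.7, 0.75, 0.65, 0.85), sprintf("k%d", 0:5))
  cond <- truth_conditions(net)
  tab <- generate_table(net, truth, cond, noise_sem = 0.01, seed = 41)
  ko <- knockout_scan(net, tab, dbn_control(restarts = 2, seed = 42))
  rep <- ko$report
  # one row per non-input node per (context, time)
  expect_equal(nrow(rep), 6L)
  expect_equal(ko$reference$aic, 0)
  expect_equal(rep$node[which.max(rep$delta_aic)], "H")
  expect_true(rep$disconnected[rep$node == "H"])
  expect_gt(max(rep$delta_aic, na.rm = TRUE), 0)
})

test_that("removing a dispensable dangling node lowers the AIC by its parameters", {
  # L hangs off M1 and reaches no measured node: pure parameter cost
  net <- read_network(c("@node S input", "@node M1 measured",
                        "@node M2 measured", "@node L latent",
                        "S -> M1 k1", "M1 -> M2 k2", "M1 -> L k3"))
  truth <- c(k1 = 0.7, k2 = 0.6, k3 = 0.5)
  cond <- truth_conditions(net)
  # mild noise keeps log(MSE) away from the numerical floor, so the AIC
  # difference is dominated by the parameter count
  tab <- generate_table(net, truth, cond, noise_sem = 0.01, seed = 51)
  ko <- knockout_scan(net, tab, dbn_control(restarts = 3, seed = 52))
  ref <- dbn_fit(net, tab, control = dbn_control(restarts = 3, seed = 52))
  p_l <- as.integer(coef(ref)["k3", 1] >= 0.01)
  row_l <- ko$report[ko$report$node == "L", ]
  expect_false(row_l$disconnected)
  expect_equal(row_l$delta_aic, -2 * p_l, tolerance = 1)
  expect_lte(row_l$delta_aic, 0)
})

test_that("knockouts that silence every measured node are flagged", {
  net <- read_network(c("@node S input", "@node H latent",
                        "@node M1 measured",
                        "S -> H k0", "H -> M1 k1"))
  truth <- c(k0 = 0.9, k1 = 0.8)
  cond <- truth_conditions(net)
  tab <- generate_table(net, truth, cond, noise_sem = 0.01, seed = 61)
  ko <- knockout_scan(net, tab, dbn_control(restarts = 2, seed = 62))
  expect_true(ko$report$disconnected[ko$report$node == "M1"])
  # the flagged knockout is still scored, against the null model
  expect_true(is.finite(ko$report$delta_aic[ko$report$node == "M1"]))
})

test_that("context difference profiles rank divergent time points first", {
  fx <- melanoma_fixture()
  base <- melanoma_synthetic_table(noise_sem = 0, seed = 1)
  tables <- list()
  for (tl in fx$time_labels) {
    t2 <- base
    if (tl %in% c("4h", "16h", "48h")) {
      rows <- t2$measurements$context == "conditioned"
      t2$measurements$mean[rows] <-
        pmin(t2$measurements$mean[rows] + 0.3, 1)
    }
    tables[[tl]] <- t2
  }
  prof <- context_difference_profile(tables,
                                     contexts = c("parental", "conditioned"))
  expect_setequal(prof$ranking[1:3], c("4h", "16h", "48h"))
  expect_equal(dim(prof$diff), c(7L, 7L))

  same <- context_difference_profile(list(t0 = base, t1 = base)["t0"],
                                     contexts = c("parental", "parental"))
  expect_true(all(abs(same$diff) < 1e-12))

  solo <- base
  solo$measurements$mean[solo$measurements$context == "conditioned" &
                           solo$measurements$node == "AKT"] <- 0
  prof2 <- context_difference_profile(list(a = base, b = solo),
                                      contexts = c("parental", "conditioned"))
  expect_equal(prof2$ranking[1], "b")
})
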