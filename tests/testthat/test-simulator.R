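test_that("pattern maps generate the stated parent-child relationships", {
  net <- simulation_network()
  set.seed(41)
  # noiseless linear: child is an exact function of the parent
  x0 <- simulate_expression(500, net, "linear", noise_sd = 0)
  expect_equal(cor(x0[, "X1"], x0[, "X2"]), 1, tolerance = 1e-12)

  # linear with unit noise: population corr 0.5/sqrt(1.25) = 0.4472
  x <- simulate_expression(5000, net, "linear")
  expect_equal(cor(x[, "X1"], x[, "X2"]), 0.5 / sqrt(1.25), tolerance = 0.05)

  # quadratic: linear correlation vanishes, quadratic correlation remains
  xq <- simulate_expression(5000, net, "quadratic")
  expect_lt(abs(cor(xq[, "X1"], xq[, "X2"])), 0.05)
  expect_gt(cor(xq[, "X1"]^2, xq[, "X2"]), 0.05)

  # columns standardized; raw values preserved
  expect_equal(unname(colMeans(x)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(x, 2, sd)), rep(1, 10), tolerance = 1e-12)
  expect_equal(dim(attr(x, "raw")), dim(x))
})

test_that("cyclic orientations are rejected", {
  net <- gene_network(c("a", "b", "c"),
                      rbind(c("a", "b"), c("b", "c"), c("a", "c")),
                      orientation = rbind(c("a", "b"), c("b", "c"),
                                          c("c", "a")))
  expect_error(simulate_expression(10, net, "linear"), "cyclic")
})

test_that("true edge signal is the pattern transform times the child", {
  net <- simulation_network()
  set.seed(42)
  x <- simulate_expression(200, net, "quadratic")
  E <- true_edge_signal(x, net, "quadratic")
  expect_equal(E[, "X4_X5"], 0.1 * x[, "X4"]^2 * x[, "X5"])
  expect_equal(colnames(E), edge_names(net))
  xl <- simulate_expression(100, net, "linear")
  El <- true_edge_signal(xl, net, "linear")
  expect_equal(El[, "X7_X9"], 0.5 * xl[, "X7"] * xl[, "X9"])
  # zero child -> zero signal
  xz <- xl; xz[, "X5"] <- 0
  expect_true(all(true_edge_signal(xz, net, "linear")[, "X4_X5"] == 0))
})

test_that("Weibull generator inverts the survival function", {
  # U = exp(-1), w = 0, lam = 1, v = 0.5: T* = 1 exactly
  expect_equal(simulate_survival(0, v = 0.5, lam = 1, u = exp(-1)), 1)
  # theoretical median (log 2)^2 under S(t) = exp(-sqrt(t))
  set.seed(43)
  t5 <- simulate_survival(rep(0, 1e5), v = 0.5, lam = 1)
  expect_lt(abs(median(t5) - log(2)^2), 0.01)
  # proportional hazards direction: larger w, earlier event at fixed U
  u <- 0.37
  expect_lt(simulate_survival(1, u = u), simulate_survival(0, u = u))
  # KS against S(t) = exp(-sqrt(t)), i.e. sqrt(T) ~ Exp(1)
  ks <- suppressWarnings(ks.test(sqrt(t5), "pexp"))
  expect_gt(ks$p.value, 0.01)
})

test_that("censoring is exact in count and strictly informative-free in time", {
  set.seed(44)
  tstar <- simulate_survival(rep(0, 10))
  cens <- apply_censoring(tstar, 0.3)
  expect_equal(sum(cens$event == 0), 3L)
  expect_true(all(cens$time[cens$censored] < tstar[cens$censored]))
  expect_equal(cens$time[cens$event == 1], tstar[cens$event == 1])

  cens0 <- apply_censoring(tstar, 0)
  expect_true(all(cens0$event == 1))
  expect_equal(cens0$time, tstar)

  for (q in c(0.1, 0.25, 0.5)) {
    for (n in c(17, 100, 1001)) {
      cc <- apply_censoring(simulate_survival(rep(0, n)), q)
      expect_equal(sum(cc$event == 0), round(n * q))
    }
  }
})

test_that("scenario targets honour the effect-placement design", {
  cfg <- sim_config(n2 = 100, pattern = "linear", scenario = "node_only",
                    seed = 1)
  expect_equal(conet:::scenario_targets(cfg),
               list(node = "X6", edge = "X7_X9"))
  cfg$scenario <- "both_on_edge"
  tg <- conet:::scenario_targets(cfg)
  expect_equal(tg, list(node = "X4", edge = "X4_X5"))
  expect_true(tg$node %in% strsplit(tg$edge, "_")[[1]])
  cfg$scenario <- "both_off_edge"
  tg <- conet:::scenario_targets(cfg)
  expect_equal(tg$node, "X2")
  expect_false(tg$node %in% strsplit(tg$edge, "_")[[1]])

  # random placement respects the hanging/not-hanging constraint
  cfg$effect_placement <- "random"
  set.seed(9)
  for (i in 1:20) {
    tg <- conet:::scenario_targets(cfg)
    expect_false(tg$node %in% strsplit(tg$edge, "_")[[1]])
  }
})

test_that("simulated datasets wire effects into the hazard as configured", {
  cfg <- sim_config(n2 = 3000, pattern = "linear", scenario = "node_only",
                    eta = 2, gamma = 0, q = 0, seed = 5)
  set.seed(5)
  sim <- simulate_dataset(cfg)
  expect_equal(sum(sim$surv$event), 3000L)
  # strong node effect: higher expression, shorter survival
  expect_lt(cor(sim$expr[, "X6"], sim$surv$time, method = "spearman"), -0.3)
  # null nodes uncorrelated with survival
  expect_lt(abs(cor(sim$expr[, "X1"], sim$surv$time, method = "spearman")),
            0.1)
  expect_equal(colnames(sim$surv$covariates), c("z1", "z2"))
})

test_that("run_study is deterministic under a fixed seed", {
  cfg <- sim_config(n2 = 300, pattern = "linear", scenario = "node_only",
                    eta = 0, gamma = 0, n_reps = 4, seed = 99,
                    measures = c("pmi", "pm"))
  s1 <- run_study(cfg)
  s2 <- run_study(cfg)
  expect_identical(s1, s2)
  expect_true(all(s1$rejection_rate >= 0 & s1$rejection_rate <= 1))
  expect_equal(sort(unique(s1$method)), sort(c("CoNet", "CPNT")))
  p <- attr(s1, "pvalues")
  expect_equal(dim(p$pmi), c(4L, 2L))
  expect_true(all(p$pmi >= 0 & p$pmi <= 1))
})

test_that("simulation configs round-trip through key=value files", {
  f <- withr::local_tempfile(fileext = ".cfg")
  nf <- withr::local_tempfile(fileext = ".tsv")
  write_network(simulation_network(), nf)
  writeLines(c("# study cell", "n2 = 300", "pattern = sin2",
               "scenario = edge_only", "eta = 0", "gamma = 0.05",
               "q = 0.3", "n_reps = 7", "seed = 12",
               paste("network =", nf), "measures = pmi,pm"), f)
  cfg <- read_sim_config(f)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n2, 300L)
  expect_equal(cfg$pattern, "sin2")
  expect_equal(cfg$q, 0.3)
  expect_equal(cfg$measures, c("pmi", "pm"))
  expect_equal(cfg$seed, 12L)
  expect_length(cfg$network$nodes, 10L)
  # seed is mandatory
  writeLines("n2 = 100", f)
  expect_error(read_sim_config(f), "seed")
})
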