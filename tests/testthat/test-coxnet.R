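sim_small <- function(n = 40, seed = 1) {
  set.seed(seed)
  z <- cbind(z1 = rnorm(n), z2 = rbinom(n, 1, 0.5))
  tstar <- simulate_survival(0.3 * z[, 1])
  cens <- apply_censoring(tstar, 0.2)
  survival_data(cens$time, cens$event, covariates = z)
}

test_that("build_design orders columns covariates | nodes | edges", {
  set.seed(31)
  n <- 50
  surv <- sim_small(n)
  net <- simulation_network()
  expr <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, net$nodes))
  E <- edge_features(expr, net, "pm")
  d <- build_design(surv, expr, E)
  expect_equal(ncol(d$x), 22L)
  expect_equal(d$terms$kind, rep(c("covariate", "node", "edge"), c(2, 10, 10)))
  # node and edge columns standardized
  expect_equal(unname(colMeans(d$x[, -(1:2)])), rep(0, 20), tolerance = 1e-12)
  expect_equal(unname(apply(d$x[, -(1:2)], 2, sd)), rep(1, 20),
               tolerance = 1e-12)
  # zero edges: covariates + nodes only
  d2 <- build_design(surv, expr, NULL)
  expect_equal(ncol(d2$x), 12L)
})

test_that("build_design aligns rows by individual id", {
  set.seed(32)
  n <- 30
  surv <- sim_small(n)
  expr <- matrix(rnorm(n * 3), n, 3,
                 dimnames = list(surv$ids, c("a", "b", "c")))
  d <- build_design(surv, expr, NULL)
  perm <- sample(n)
  d2 <- build_design(surv, expr[perm, ], NULL)
  expect_equal(d$x, d2$x)
  expect_error(build_design(surv, expr[-1, , drop = FALSE], NULL), "missing")
})

test_that("constant design columns are dropped with a warning", {
  n <- 30
  surv <- sim_small(n)
  expr <- cbind(a = rnorm(n), flat = rep(1, n))
  expect_warning(d <- build_design(surv, expr, NULL), "flat")
  expect_equal(d$terms$name, c("z1", "z2", "a"))
})

test_that("fit_cox matches brute-force partial-likelihood maximization", {
  set.seed(33)
  n <- 20
  x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.5))
  tstar <- simulate_survival(0.5 * x[, 1] - 0.3 * x[, 2])
  surv <- survival_data(tstar, rep(1, n))   # no censoring, no ties
  d <- build_design(surv, x, NULL)
  fit <- fit_cox(d, surv)
  oracle <- oracle_cox_fit(surv$time, surv$event, d$x)
  expect_equal(fit$terms$coef, oracle$coef, tolerance = 1e-6)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-8)

  # censored instance with ties (Efron correction in both routes)
  set.seed(34)
  n <- 30
  x2 <- cbind(a = rnorm(n))
  t2 <- round(simulate_survival(0.4 * x2[, 1]), 1) + 0.1   # induce ties
  ev <- rbinom(n, 1, 0.8)
  surv2 <- survival_data(t2, ev)
  d2 <- build_design(surv2, x2, NULL)
  fit2 <- fit_cox(d2, surv2)
  oracle2 <- oracle_cox_fit(surv2$time, surv2$event, d2$x)
  expect_equal(fit2$terms$coef, oracle2$coef, tolerance = 1e-6)
})

test_that("partial-likelihood score at zero equals events minus risk-set means", {
  # 4 subjects, binary covariate alternating along ordered times
  time <- c(1, 2, 3, 4)
  event <- rep(1, 4)
  x <- matrix(c(1, 0, 1, 0), ncol = 1)
  # score at beta=0: sum over events of (x_event - mean of x over risk set)
  hand <- (1 - mean(x)) + (0 - mean(x[2:4])) + (1 - mean(x[3:4])) + (0 - 0)
  num <- (oracle_efron_loglik(1e-6, time, event, x) -
          oracle_efron_loglik(-1e-6, time, event, x)) / 2e-6
  expect_equal(num, hand, tolerance = 1e-6)
})

test_that("Cox invariances: shift leaves coefficients, scaling inverts them", {
  set.seed(35)
  n <- 60
  x <- cbind(a = rnorm(n), b = rnorm(n))
  tstar <- simulate_survival(0.5 * x[, 1])
  surv <- survival_data(tstar, rbinom(n, 1, 0.9))
  base <- list(x = x, terms = data.frame(name = c("a", "b"),
                                         kind = "covariate"),
               center = c(0, 0), scale = c(1, 1))
  f0 <- fit_cox(base, surv)
  shifted <- base; shifted$x[, 1] <- x[, 1] + 100
  f1 <- fit_cox(shifted, surv)
  expect_equal(f0$terms$coef, f1$terms$coef, tolerance = 1e-6)
  scaled <- base; scaled$x[, 2] <- 4 * x[, 2]
  f2 <- fit_cox(scaled, surv)
  expect_equal(f2$terms$coef[2], f0$terms$coef[2] / 4, tolerance = 1e-6)
})

test_that("degenerate fits raise informative errors", {
  n <- 40
  surv <- sim_small(n, seed = 36)
  set.seed(37)
  a <- rnorm(n)
  dup <- list(x = cbind(a = a, b = a),          # singular design
              terms = data.frame(name = c("a", "b"), kind = "covariate"),
              center = c(0, 0), scale = c(1, 1))
  expect_error(suppressWarnings(fit_cox(dup, surv)), "singular|undetermined")
  no_events <- survival_data(surv$time, rep(0L, n))
  d1 <- list(x = cbind(a = a), terms = data.frame(name = "a", kind = "covariate"),
             center = 0, scale = 1)
  expect_error(fit_cox(d1, no_events), "events")
})

test_that("wald_table applies BH within node and edge families separately", {
  fake <- structure(list(terms = data.frame(
    name = c("z1", paste0("n", 1:4), paste0("e", 1:3)),
    kind = rep(c("covariate", "node", "edge"), c(1, 4, 3)),
    coef = 0, se = 1, z = 0,
    p = c(0.001, 0.01, 0.02, 0.03, 0.04, 0.2, 0.1, 0.3),
    stringsAsFactors = FALSE)), class = "conet_fit")
  tab <- wald_table(fake, alpha = 0.05)
  # BH step-up on (0.01, 0.02, 0.03, 0.04): all adjusted to 0.04
  expect_equal(tab$p_adj[tab$kind == "node"], rep(0.04, 4))
  expect_equal(tab$p_adj[tab$kind == "node"],
               oracle_bh(c(0.01, 0.02, 0.03, 0.04)))
  expect_equal(tab$p_adj[tab$kind == "edge"],
               oracle_bh(c(0.2, 0.1, 0.3)))
  expect_true(is.na(tab$p_adj[tab$kind == "covariate"]))
  expect_true(all(tab$significant[tab$kind == "node"]))

  # single test: adjusted = raw; all-ones stay ones
  fake$terms <- data.frame(name = c("n1", "e1", "e2"),
                           kind = c("node", "edge", "edge"),
                           coef = 0, se = 1, z = 0, p = c(0.03, 1, 1))
  tab2 <- wald_table(fake)
  expect_equal(tab2$p_adj, c(0.03, 1, 1))
  expect_equal(sum(tab2$significant), 1L)
})

test_that("BH adjustment preserves the raw p-value ordering", {
  set.seed(38)
  p <- runif(20)
  adj <- oracle_bh(p)
  expect_equal(order(p), order(adj, p))
  fake <- structure(list(terms = data.frame(
    name = paste0("n", 1:20), kind = "node", coef = 0, se = 1, z = 0,
    p = p)), class = "conet_fit")
  expect_equal(wald_table(fake)$p_adj, adj)
  expect_equal(stats::p.adjust(p, "BH"), adj)  # oracle sanity
})

test_that("the one-call pipeline returns a full results table", {
  set.seed(39)
  net <- simulation_network()
  cfg <- sim_config(n2 = 400, pattern = "linear", scenario = "node_only",
                    eta = 0, gamma = 0, seed = 39)
  sim <- simulate_dataset(cfg)
  fit <- conet(sim$surv, sim$expr, net, measure = "pm")
  expect_s3_class(fit, "conet_fit")
  expect_equal(nrow(fit$results), 22L)
  expect_named(fit$results, c("term", "kind", "coef", "se", "z", "p",
                              "p_adj", "significant"))
  expect_true(all(fit$results$p_adj[!is.na(fit$results$p_adj)] >=
                  fit$results$p[!is.na(fit$results$p_adj)] - 1e-12))
})

test_that("Breslow baseline reproduces the exponential-type cumulative hazard", {
  # null model, Weibull v=0.5, lam=1: H0(t) = sqrt(t)
  set.seed(50)
  n <- 4000
  tstar <- simulate_survival(rep(0, n))
  surv <- survival_data(tstar, rep(1L, n))
  x <- cbind(a = rnorm(n))                     # a null covariate
  d <- build_design(surv, x, NULL)
  fit <- fit_cox(d, surv)
  bh <- breslow_baseline(fit, d, surv)
  expect_true(all(diff(bh$hazard) > 0))
  mid <- bh$time > 0.05 & bh$time < 2
  expect_lt(max(abs(bh$hazard[mid] - sqrt(bh$time[mid]))), 0.1)
})
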