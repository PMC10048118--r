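#' Simulation study configuration
#'
#' Collects every knob of the synthetic survival-TWAS study: sample size,
#' network, between-node correlation pattern, effect scenario, effect
#' sizes, Weibull baseline parameters and censoring rate. The defaults
#' are the study conditions of the method's evaluation design: node and
#' edge effects of 0.05 (when on), Weibull scale `v = 0.5` and shape
#' `lambda = 1`, covariate coefficients (0.5, 0.5), and censoring rates
#' drawn from \{0.1, 0.3, 0.5\}.
#'
#' @param n2 GWAS sample size per replicate (the study uses 5000, 10000,
#'   20000).
#' @param pattern between-node correlation pattern: `"linear"`
#'   (`x_k = 0.5 x_l + e`), `"quadratic"` (`x_k = 0.1 x_l^2 + e`),
#'   `"sine"` (`x_k = sin(x_l) + e`) or `"sin2"` (`x_k = sin^2(x_l) + e`),
#'   with `e ~ N(0, 1)`.
#' @param scenario effect placement: `"node_only"`, `"edge_only"`,
#'   `"both_on_edge"` (effecting node is an endpoint of the effecting
#'   edge) or `"both_off_edge"` (it is not).
#' @param eta node effect size (log-hazard per standardized expression
#'   unit); 0 under the null.
#' @param gamma edge effect size (log-hazard per unit of true edge
#'   signal); 0 under the null.
#' @param q censoring rate in `[0, 1)`; exactly `round(n2 * q)`
#'   individuals are censored.
#' @param v Weibull scale parameter of the baseline hazard (default 0.5).
#' @param lam Weibull shape parameter `lambda` (default 1).
#' @param covar_coefs coefficients of the two simulated covariates
#'   `z1 ~ N(0,1)` and `z2 ~ Bernoulli(0.5)`.
#' @param network the gene network; default [simulation_network()].
#' @param n_reps number of replicates for [run_study()].
#' @param seed integer seed; every replicate derives its own substream
#'   from it, so any replicate is regenerable in isolation.
#' @param effect_placement `"fixed"` uses the pre-specified targets (node
#'   `X6`, edge `X7_X9`, or `X4`/`X2` with `X4_X5` in the combined
#'   scenarios); `"random"` draws the effecting node/edge uniformly per
#'   replicate.
#' @param measures which edge measures to fit per replicate: any of
#'   `"pmi"` (the PMI-based model) and `"pm"` (the product-moment
#'   comparator).
#' @param alpha per-test significance level for rejection rates.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n2,
                       pattern = c("linear", "quadratic", "sine", "sin2"),
                       scenario = c("node_only", "edge_only",
                                    "both_on_edge", "both_off_edge"),
                       eta = 0.05, gamma = 0.05, q = 0.1,
                       v = 0.5, lam = 1, covar_coefs = c(0.5, 0.5),
                       network = simulation_network(),
                       n_reps = 1000L, seed = 1L,
                       effect_placement = c("fixed", "random"),
                       measures = "pmi", alpha = 0.05) {
  pattern <- match.arg(pattern)
  scenario <- match.arg(scenario)
  effect_placement <- match.arg(effect_placement)
  measures <- match.arg(measures, c("pmi", "pm"), several.ok = TRUE)
  stopifnot(n2 >= 4, q >= 0, q < 1, v > 0, lam > 0,
            length(covar_coefs) == 2L, n_reps >= 1, alpha > 0, alpha < 1,
            inherits(network, "gene_network"))
  structure(list(n2 = as.integer(n2), pattern = pattern, scenario = scenario,
                 eta = eta, gamma = gamma, q = q, v = v, lam = lam,
                 covar_coefs = covar_coefs, network = network,
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 effect_placement = effect_placement,
                 measures = measures, alpha = alpha),
            class = "sim_config")
}

pattern_transform <- function(pattern) {
  switch(pattern,
         linear = function(x) 0.5 * x,
         quadratic = function(x) 0.1 * x^2,
         sine = function(x) sin(x),
         sin2 = function(x) sin(x)^2,
         stop("unknown pattern: ", pattern))
}

#' Simulate network-structured expression
#'
#' Generates node values over a generative (forest) orientation of the
#' network: parentless nodes are i.i.d. N(0, 1); each child is the
#' pattern transform of its parent plus N(0, `noise_sd`^2) noise
#' (`noise_sd = 0` is a deterministic test hook). Edges outside the
#' forest orientation (cycle-closing edges) play no generative role.
#'
#' Every node symbol of the model denotes a standardized predicted
#' expression, so each column is standardized (mean 0, sd 1) as soon as
#' it is generated and children are generated from the parent's
#' standardized value; the pre-standardization child values are kept in
#' `attr(, "raw")`.
#'
#' @param n number of individuals.
#' @param net a [gene_network()]; must admit a forest orientation (a
#'   shipped orientation or BFS from the lowest-indexed node of each
#'   component).
#' @param pattern see [sim_config()].
#' @param noise_sd standard deviation of the child-node noise.
#' @return standardized expression matrix `n x m` with
#'   `attr(, "raw")` holding the unstandardized values.
#' @export
simulate_expression <- function(n, net, pattern, noise_sd = 1) {
  g <- pattern_transform(pattern)
  m <- length(net$nodes)
  ori <- network_orientation(net)
  parent_of <- rep(NA_integer_, m)
  parent_of[ori[, "child"]] <- ori[, "parent"]
  raw <- matrix(NA_real_, n, m, dimnames = list(NULL, net$nodes))
  x <- raw
  std <- function(v) if (noise_sd > 0) (v - mean(v)) / stats::sd(v) else v
  # generation order: parents before children
  done <- logical(m)
  repeat {
    ready <- !done & (is.na(parent_of) | done[ifelse(is.na(parent_of), 1L, parent_of)])
    if (!any(ready)) break
    for (j in which(ready)) {
      raw[, j] <- if (is.na(parent_of[j])) stats::rnorm(n) else
        g(x[, parent_of[j]]) + stats::rnorm(n, sd = noise_sd)
      x[, j] <- std(raw[, j])
      done[j] <- TRUE
    }
  }
  if (!all(done))
    stop("network orientation is cyclic; cannot generate nodes: ",
         paste(net$nodes[!done], collapse = ", "))
  if (noise_sd > 0) attr(x, "standardized") <- TRUE
  attr(x, "raw") <- raw
  x
}

#' True edge signal of a simulated dataset
#'
#' The generative edge variable entering the hazard when an edge carries
#' an effect: per edge with parent `l` and child `k`,
#' `E = g(x_l) * x_k` with `g` the pattern transform used in
#' [simulate_expression()] — e.g. `E = 0.1 * x_l^2 * x_k` for the
#' quadratic pattern — evaluated on the standardized node values, the
#' same scale on which every node symbol of the model lives. For a
#' cycle-closing edge without generative orientation the lower-position
#' node takes the parent role.
#'
#' @param expr matrix from [simulate_expression()].
#' @param net the generating [gene_network()].
#' @param pattern the pattern used at generation.
#' @return numeric matrix `n x |edges|` in [edge_index()] order, named as
#'   [edge_names()].
#' @export
true_edge_signal <- function(expr, net, pattern) {
  g <- pattern_transform(pattern)
  x <- as.matrix(expr)
  ori <- network_orientation(net)
  key <- paste(pmin(ori[, 1L], ori[, 2L]), pmax(ori[, 1L], ori[, 2L]))
  ei <- edge_index(net)
  E <- matrix(NA_real_, nrow(x), nrow(ei),
              dimnames = list(rownames(x), edge_names(net)))
  for (r in seq_len(nrow(ei))) {
    hit <- match(paste(ei[r, "l"], ei[r, "k"]), key)
    if (!is.na(hit)) {
      p <- ori[hit, "parent"]; ch <- ori[hit, "child"]
    } else {
      p <- ei[r, "l"]; ch <- ei[r, "k"]
    }
    E[, r] <- g(x[, p]) * x[, ch]
  }
  E
}

#' Simulate complete survival times from a Cox-Weibull model
#'
#' Inverse-transform simulation of event times under a Cox model with
#' Weibull baseline hazard:
#' \deqn{T^* = \left(\frac{-\log U}{\lambda \exp(w)}\right)^{1/v},
#'       \qquad U \sim \mathrm{Uniform}(0, 1),}
#' where `w` is the per-individual linear predictor. With `w = 0`,
#' `lam = 1`, `v = 0.5` the survival function is
#' `S(t) = exp(-sqrt(t))`.
#'
#' @param w numeric vector of linear predictors.
#' @param v Weibull scale parameter (> 0).
#' @param lam Weibull shape parameter (> 0).
#' @param u optional uniform draws (for reproducibility hooks); default
#'   fresh `runif(length(w))`.
#' @return positive complete event times, one per element of `w`.
#' @export
simulate_survival <- function(w, v = 0.5, lam = 1, u = NULL) {
  stopifnot(v > 0, lam > 0)
  if (is.null(u)) u <- stats::runif(length(w))
  (-log(u) / (lam * exp(w)))^(1 / v)
}

#' Apply exact uniform censoring
#'
#' Exactly `round(n * q)` individuals, chosen uniformly without
#' replacement, are censored: their observed time is drawn from
#' `Uniform(0, T*)` (so always below the complete time) and their event
#' indicator is 0; everyone else keeps `T*` with indicator 1.
#'
#' @param tstar complete event times.
#' @param q censoring rate in `[0, 1)`.
#' @return list with `time`, `event` (and `censored`, the censored
#'   indices).
#' @export
apply_censoring <- function(tstar, q) {
  stopifnot(q >= 0, q < 1)
  n <- length(tstar)
  n_cens <- round(n * q)
  time <- tstar
  event <- rep(1L, n)
  idx <- if (n_cens > 0) sample.int(n, n_cens) else integer(0)
  if (n_cens > 0) {
    time[idx] <- stats::runif(n_cens, min = 0, max = tstar[idx])
    event[idx] <- 0L
  }
  list(time = time, event = event, censored = sort(idx))
}

# Pre-specified effect targets per scenario (node name, edge name).
scenario_targets <- function(config) {
  net <- config$network
  pick <- switch(config$scenario,
                 node_only = list(node = "X6", edge = "X7_X9"),
                 edge_only = list(node = "X6", edge = "X7_X9"),
                 both_on_edge = list(node = "X4", edge = "X4_X5"),
                 both_off_edge = list(node = "X2", edge = "X4_X5"))
  en <- edge_names(net)
  if (config$effect_placement == "random") {
    pick$node <- sample(net$nodes, 1L)
    pick$edge <- sample(en, 1L)
    if (config$scenario == "both_on_edge") {
      pick$edge <- sample(en, 1L)
      pick$node <- sample(strsplit(pick$edge, "_")[[1L]], 1L)
    }
    if (config$scenario == "both_off_edge") {
      repeat {
        pick$edge <- sample(en, 1L)
        off <- setdiff(net$nodes, strsplit(pick$edge, "_")[[1L]])
        if (length(off)) { pick$node <- sample(off, 1L); break }
      }
    }
  } else if (!(pick$node %in% net$nodes) || !(pick$edge %in% en)) {
    # non-default network: fall back to the first node / first edge
    pick$node <- net$nodes[1L]
    pick$edge <- en[1L]
  }
  pick
}

#' Simulate one complete survival-TWAS dataset
#'
#' One replicate of the study generator: network-structured standardized
#' expression, the true edge signal, covariates `z1 ~ N(0,1)` and
#' `z2 ~ Bernoulli(0.5)`, the linear predictor
#' `w = 0.5 z1 + 0.5 z2 + eta * x_target + gamma * E_target`
#' (terms present according to the scenario), Weibull survival times and
#' exact uniform censoring.
#'
#' @param config a [sim_config()]. Its `seed` is NOT applied here; call
#'   `set.seed()` yourself or use [run_study()], which manages
#'   per-replicate substreams.
#' @return list with `expr` (standardized expression, raw values in its
#'   `"raw"` attribute), `edge_signal` (true generative edge variables),
#'   `surv` (a [survival_data()] with covariates `z1`, `z2`), `target`
#'   (list with `node`, `edge` names) and `truth` (logical: which target
#'   carries an effect).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n2
  net <- config$network
  expr <- simulate_expression(n, net, config$pattern)
  Etrue <- true_edge_signal(expr, net, config$pattern)
  z1 <- stats::rnorm(n)
  z2 <- stats::rbinom(n, 1L, 0.5)
  target <- scenario_targets(config)
  eta_on <- config$scenario %in% c("node_only", "both_on_edge", "both_off_edge")
  gamma_on <- config$scenario %in% c("edge_only", "both_on_edge", "both_off_edge")
  w <- config$covar_coefs[1L] * z1 + config$covar_coefs[2L] * z2
  if (eta_on && config$eta != 0)
    w <- w + config$eta * expr[, target$node]
  if (gamma_on && config$gamma != 0)
    w <- w + config$gamma * Etrue[, target$edge]
  tstar <- simulate_survival(w, v = config$v, lam = config$lam)
  cens <- apply_censoring(tstar, config$q)
  surv <- survival_data(cens$time, cens$event,
                        covariates = cbind(z1 = z1, z2 = z2))
  list(expr = expr, edge_signal = Etrue, surv = surv, target = target,
       truth = list(node = eta_on, edge = gamma_on))
}

#' Run a type-I-error / power study
#'
#' Repeats the full pipeline `n_reps` times — simulate a dataset, compute
#' edge features (PMI and/or product moment), assemble the design with
#' `z1`, `z2` as covariates, fit the network Cox model — and records, for
#' each measure, whether the Wald p-value of the pre-specified target
#' node and target edge falls below `alpha`. With zero effects the
#' rejection proportion estimates the type-I error; with effects on, the
#' power.
#'
#' Each replicate draws its RNG substream deterministically from
#' `config$seed`, so results are bit-reproducible and any replicate can
#' be regenerated in isolation. Replicates whose fit fails are logged and
#' excluded; more than 5\% failures is an error.
#'
#' @param config a [sim_config()].
#' @param ... passed to [edge_features()] for the PMI measure (e.g.
#'   `method = "exact"`).
#' @return data frame with one row per (measure, target kind): columns
#'   `method` (`CoNet` for PMI, `CPNT` for PM), `scenario`, `pattern`,
#'   `n2`, `censoring_rate`, `target_kind`, `target`, `rejection_rate`,
#'   `mc_se` (binomial Monte-Carlo standard error), `n_reps`, `n_failed`.
#'   The per-replicate p-values are attached as `attr(, "pvalues")` (a
#'   list, per measure, of `n_reps x 2` matrices with columns `node`,
#'   `edge`).
#' @export
run_study <- function(config, ...) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, config$n_reps)
  pvals <- lapply(config$measures, function(m)
    matrix(NA_real_, config$n_reps, 2L,
           dimnames = list(NULL, c("node", "edge"))))
  names(pvals) <- config$measures
  n_failed <- 0L
  for (r in seq_len(config$n_reps)) {
    set.seed(rep_seeds[r])
    ok <- tryCatch({
      sim <- simulate_dataset(config)
      for (meas in config$measures) {
        E <- if (meas == "pmi")
          edge_features(sim$expr, config$network, measure = "pmi", ...)
        else
          edge_features(sim$expr, config$network, measure = "pm")
        design <- build_design(sim$surv, sim$expr, E)
        fit <- fit_cox(design, sim$surv)
        tt <- fit$terms
        pvals[[meas]][r, "node"] <-
          tt$p[tt$kind == "node" & tt$name == sim$target$node]
        pvals[[meas]][r, "edge"] <-
          tt$p[tt$kind == "edge" & tt$name == sim$target$edge]
      }
      TRUE
    }, error = function(e) {
      message("replicate ", r, " failed: ", conditionMessage(e))
      FALSE
    })
    if (!ok) n_failed <- n_failed + 1L
  }
  if (n_failed > 0.05 * config$n_reps)
    stop("more than 5% of replicates failed (", n_failed, "/",
         config$n_reps, ")")
  rows <- list()
  for (meas in config$measures) {
    for (kind in c("node", "edge")) {
      p <- pvals[[meas]][, kind]
      p <- p[!is.na(p)]
      rate <- mean(p < config$alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        method = if (meas == "pmi") "CoNet" else "CPNT",
        scenario = config$scenario, pattern = config$pattern,
        n2 = config$n2, censoring_rate = config$q,
        target_kind = kind,
        target = if (kind == "node") scenario_targets_fixed(config)$node
                 else scenario_targets_fixed(config)$edge,
        rejection_rate = rate,
        mc_se = sqrt(rate * (1 - rate) / length(p)),
        n_reps = length(p), n_failed = n_failed,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "pvalues") <- pvals
  out
}

# fixed-placement target labels for reporting (random placement varies per
# replicate, so report the scenario's canonical label)
scenario_targets_fixed <- function(config) {
  cfg <- config
  cfg$effect_placement <- "fixed"
  scenario_targets(cfg)
}

#' Read a simulation configuration from a key=value file
#'
#' One `key = value` pair per line, keys matching the arguments of
#' [sim_config()] (`network` as a path to an edge-list file; `measures`
#' comma-separated). Lines starting with `#` are comments. A `seed` entry
#' is mandatory so that file-driven studies are reproducible by
#' construction.
#'
#' @param path path to the configuration file.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L])
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  if (!"seed" %in% keys) stop("config file must set a seed")
  args <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    args[[k]] <- switch(k,
      n2 = , n_reps = , seed = as.integer(v),
      eta = , gamma = , q = , v = , lam = , alpha = as.numeric(v),
      covar_coefs = as.numeric(strsplit(v, ",")[[1L]]),
      measures = trimws(strsplit(v, ",")[[1L]]),
      network = load_network(v),
      v)                                  # pattern, scenario, placement
  }
  do.call(sim_config, args)
}

#' Write a study results table as TSV
#' @param study data frame from [run_study()].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path) {
  utils::write.table(study, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
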