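#' Construct survival data
#'
#' Bundles observed times, event indicators and covariates for the Cox
#' network model.
#'
#' @param time positive observed times (event or censoring).
#' @param event 0/1 indicators (1 = event, 0 = censored).
#' @param covariates numeric matrix or data frame of covariates (may have
#'   zero columns); column names are kept for the results table.
#' @param ids individual identifiers; default `1..n`.
#' @return object of class `survival_data`.
#' @export
survival_data <- function(time, event, covariates = NULL, ids = NULL) {
  n <- length(time)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (length(event) != n || length(ids) != n)
    stop("time, event and ids must have equal length")
  if (any(!is.finite(time)) || any(time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("event indicators must be 0 or 1")
  if (is.null(covariates)) {
    covariates <- matrix(numeric(0), nrow = n, ncol = 0L)
  } else {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariates must have one row per individual")
    if (anyNA(covariates)) stop("missing covariate values")
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("Z", seq_len(ncol(covariates)))
  }
  structure(list(ids = as.character(ids), time = as.numeric(time),
                 event = as.integer(event), covariates = covariates),
            class = "survival_data")
}

#' Read survival phenotype and covariate TSVs
#'
#' The phenotype file has columns `id`, `time`, `event`; the optional
#' covariate file has `id` plus named covariate columns and is aligned to
#' the phenotype by id.
#'
#' @param phenotype_path TSV with `id`, `time`, `event`.
#' @param covariates_path optional TSV with `id` + covariate columns.
#' @return a [survival_data()].
#' @export
read_survival <- function(phenotype_path, covariates_path = NULL) {
  ph <- utils::read.delim(phenotype_path, stringsAsFactors = FALSE)
  if (!all(c("id", "time", "event") %in% names(ph)))
    stop("phenotype file must have columns id, time, event")
  covs <- NULL
  if (!is.null(covariates_path)) {
    cv <- utils::read.delim(covariates_path, stringsAsFactors = FALSE)
    idx <- match(as.character(ph$id), as.character(cv$id))
    if (anyNA(idx)) stop("covariate file missing id(s): ",
                         paste(ph$id[is.na(idx)], collapse = ", "))
    covs <- as.matrix(cv[idx, setdiff(names(cv), "id"), drop = FALSE])
  }
  survival_data(ph$time, ph$event, covs, ids = ph$id)
}

#' Assemble the network Cox design matrix
#'
#' Builds the design of the network Cox model: columns ordered
#' `[covariates | nodes | edges]`. Expression and edge-feature rows are
#' aligned to the survival data by individual id (an unmatched id is an
#' error). Node and edge columns are standardized to mean 0, sd 1 so that
#' node and edge effects are on comparable scales; the centring/scaling
#' constants are stored so raw-scale coefficients remain recoverable.
#' Constant columns are dropped with a warning and absent from results.
#'
#' @param surv a [survival_data()].
#' @param expr expression matrix (individuals x genes), rownames = ids
#'   (or ordered as `surv` when rownames are absent).
#' @param edges edge-feature matrix from [edge_features()] (may be `NULL`
#'   or have zero columns).
#' @return list with `x` (design matrix), `terms` (data frame `name`,
#'   `kind` in covariate/node/edge), `center`, `scale`.
#' @export
build_design <- function(surv, expr, edges = NULL) {
  stopifnot(inherits(surv, "survival_data"))
  expr <- as.matrix(expr)
  align <- function(m, what) {
    if (is.null(rownames(m))) {
      if (nrow(m) != length(surv$ids))
        stop(what, " has ", nrow(m), " rows for ", length(surv$ids),
             " individuals")
      return(m)
    }
    idx <- match(surv$ids, rownames(m))
    if (anyNA(idx))
      stop(what, " missing individual(s): ",
           paste(surv$ids[is.na(idx)], collapse = ", "))
    m[idx, , drop = FALSE]
  }
  expr <- align(expr, "expression matrix")
  if (is.null(edges))
    edges <- matrix(numeric(0), nrow = nrow(expr), ncol = 0L)
  edges <- align(as.matrix(edges), "edge-feature matrix")

  blocks <- list(covariate = surv$covariates, node = expr, edge = edges)
  xs <- list(); nm <- character(0); kind <- character(0)
  center <- numeric(0); scl <- numeric(0)
  for (b in names(blocks)) {
    m <- blocks[[b]]
    if (ncol(m) == 0L) next
    if (is.null(colnames(m))) colnames(m) <- paste0(b, seq_len(ncol(m)))
    mu <- colMeans(m)
    s <- apply(m, 2L, stats::sd)
    const <- s == 0 | !is.finite(s)
    if (any(const)) {
      warning("dropping constant ", b, " column(s): ",
              paste(colnames(m)[const], collapse = ", "))
      m <- m[, !const, drop = FALSE]
      mu <- mu[!const]; s <- s[!const]
      if (ncol(m) == 0L) next
    }
    if (b != "covariate") {
      m <- sweep(sweep(m, 2L, mu), 2L, s, "/")
    } else {
      mu <- rep(0, ncol(m)); s <- rep(1, ncol(m))
    }
    xs[[b]] <- m
    nm <- c(nm, colnames(m)); kind <- c(kind, rep(b, ncol(m)))
    center <- c(center, mu); scl <- c(scl, s)
  }
  if (length(xs) == 0L) stop("design has no usable columns")
  x <- do.call(cbind, xs)
  colnames(x) <- nm
  list(x = x,
       terms = data.frame(name = nm, kind = kind, stringsAsFactors = FALSE),
       center = center, scale = scl)
}

#' Fit the network Cox model by partial likelihood
#'
#' Maximizes the Cox partial likelihood for the assembled design (Efron
#' tie correction; Newton-Raphson with step-halving, up to 100
#' iterations). Standard errors come from the inverse observed
#' information; each coefficient gets a Wald statistic `z = coef/se` and a
#' two-sided normal p-value.
#'
#' The partial-likelihood maximization is delegated to
#' [survival::coxph()]. Non-convergence is an error carrying the last
#' iterate, and any coefficient exceeding 20 in absolute value is treated
#' as monotone-likelihood divergence with an error suggesting
#' penalization.
#'
#' @param design list from [build_design()].
#' @param surv the matching [survival_data()].
#' @return object of class `conet_fit`: list with `terms` (data frame
#'   `name`, `kind`, `coef`, `se`, `z`, `p`), `loglik` (partial
#'   log-likelihood at the optimum), `n`, `n_events`, `iter`.
#' @export
fit_cox <- function(design, surv) {
  stopifnot(inherits(surv, "survival_data"))
  x <- design$x
  if (sum(surv$event) < 2L) stop("need at least 2 events to fit")
  if (nrow(x) <= ncol(x))
    warning("fewer individuals than design columns; estimates unreliable")
  fit <- survival::coxph.fit(
    x, survival::Surv(surv$time, surv$event),
    strata = NULL, offset = NULL, init = NULL,
    control = survival::coxph.control(iter.max = 100L, eps = 1e-10),
    weights = NULL, method = "efron", rownames = NULL)
  if (fit$iter >= 100L)
    stop("partial-likelihood maximization did not converge after 100 ",
         "iterations; last coefficients: ",
         paste(signif(fit$coefficients, 4), collapse = ", "))
  beta <- unname(fit$coefficients)
  if (any(!is.finite(beta)))
    stop("undetermined coefficient(s) for: ",
         paste(design$terms$name[!is.finite(beta)], collapse = ", "),
         " (singular design)")
  if (any(abs(beta) > 20))
    stop("divergent coefficient (|beta| > 20) for: ",
         paste(design$terms$name[abs(beta) > 20], collapse = ", "),
         "; the partial likelihood is likely monotone - consider a ",
         "penalized fit or removing the offending column")
  se <- sqrt(diag(fit$var))
  z <- beta / se
  terms <- data.frame(design$terms,
                      coef = beta, se = se, z = z,
                      p = 2 * stats::pnorm(-abs(z)),
                      stringsAsFactors = FALSE)
  structure(list(terms = terms,
                 loglik = fit$loglik[2L],
                 n = length(surv$time),
                 n_events = sum(surv$event),
                 iter = fit$iter,
                 center = design$center,
                 scale = design$scale),
            class = "conet_fit")
}

#' @export
print.conet_fit <- function(x, ...) {
  cat("network Cox fit: n =", x$n, ", events =", x$n_events,
      ", log partial likelihood =", format(x$loglik), "\n")
  print(utils::head(x$terms, 15L), digits = 4)
  if (nrow(x$terms) > 15L) cat("... (", nrow(x$terms) - 15L, " more terms)\n")
  invisible(x)
}

#' Wald results table with BH-FDR adjustment
#'
#' Adds Benjamini-Hochberg adjusted p-values to the fit, applied
#' separately within the node family and within the edge family (the two
#' multiple-testing families of the method); covariate p-values are left
#' unadjusted (`p_adj = NA`). A term is flagged significant when its
#' adjusted p-value is below `alpha`.
#'
#' @param fit a `conet_fit` from [fit_cox()].
#' @param alpha FDR threshold; default 0.05.
#' @return data frame with columns `term`, `kind`, `coef`, `se`, `z`,
#'   `p`, `p_adj`, `significant`.
#' @export
wald_table <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "conet_fit"))
  t <- fit$terms
  p_adj <- rep(NA_real_, nrow(t))
  for (fam in c("node", "edge")) {
    idx <- t$kind == fam
    if (any(idx)) p_adj[idx] <- stats::p.adjust(t$p[idx], method = "BH")
  }
  data.frame(term = t$name, kind = t$kind, coef = t$coef, se = t$se,
             z = t$z, p = t$p, p_adj = p_adj,
             significant = !is.na(p_adj) & p_adj < alpha,
             stringsAsFactors = FALSE)
}

#' One-call network Cox regression
#'
#' The full second-stage pipeline: compute edge features over the network
#' (PMI by default, product moment for the linear comparator), assemble
#' the `[covariates | nodes | edges]` design, maximize the Cox partial
#' likelihood, and return the Wald table with BH-FDR adjustment within
#' the node and edge families.
#'
#' @param surv a [survival_data()].
#' @param expr expression matrix (individuals x genes) covering every
#'   network node. Standardization happens inside [build_design()].
#' @param net a [gene_network()].
#' @param measure `"pmi"` or `"pm"`.
#' @param alpha FDR threshold for the significance flag.
#' @param ... passed to [edge_features()].
#' @return a `conet_fit` whose `results` element is the [wald_table()].
#' @export
#' @examples
#' set.seed(1)
#' net <- simulation_network()
#' sim <- simulate_dataset(sim_config(n2 = 300, pattern = "linear",
#'                                    scenario = "node_only",
#'                                    eta = 0, gamma = 0, seed = 1))
#' fit <- conet(sim$surv, sim$expr, net)
#' head(fit$results)
conet <- function(surv, expr, net, measure = c("pmi", "pm"),
                  alpha = 0.05, ...) {
  measure <- match.arg(measure)
  E <- edge_features(expr, net, measure = measure, ...)
  design <- build_design(surv, expr, E)
  fit <- fit_cox(design, surv)
  fit$measure <- toupper(measure)
  fit$results <- wald_table(fit, alpha = alpha)
  fit
}

#' Breslow estimate of the cumulative baseline hazard
#'
#' Optional export: the step-function estimate
#' \eqn{\hat H_0(t) = \sum_{t_{(i)} \le t} d_i / \sum_{j \in R(t_{(i)})}
#' \exp(\hat\beta' x_j)} evaluated at the distinct event times. Not used
#' by any test statistic of the model; provided for survival-curve
#' summaries.
#'
#' @param fit a `conet_fit` from [fit_cox()].
#' @param design the [build_design()] list the fit was computed from.
#' @param surv the matching [survival_data()].
#' @return data frame with columns `time` (distinct event times,
#'   increasing) and `hazard` (cumulative baseline hazard).
#' @export
breslow_baseline <- function(fit, design, surv) {
  stopifnot(inherits(fit, "conet_fit"), inherits(surv, "survival_data"))
  r <- exp(as.vector(design$x %*% fit$terms$coef))
  times <- sort(unique(surv$time[surv$event == 1]))
  haz <- vapply(times, function(t) {
    sum(surv$event == 1 & surv$time == t) / sum(r[surv$time >= t])
  }, numeric(1))
  data.frame(time = times, hazard = cumsum(haz))
}

#' Write a results table as TSV
#' @param results data frame from [wald_table()] (or `fit$results`).
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  out <- results
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 10)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
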