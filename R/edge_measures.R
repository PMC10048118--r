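#' Normal-reference bandwidths for PMI estimation
#'
#' Selects the smoothing parameters used by [pmi_edge()]: a scalar
#' bandwidth for each marginal kernel density estimate and a diagonal
#' 2x2 bandwidth matrix `H` of squared bandwidths for the joint bivariate
#' estimate. The defaults follow the normal-reference (Silverman-type)
#' rules
#' \deqn{h = 1.06 \, \hat\sigma \, n^{-1/5}} for the marginals and
#' \deqn{H = \mathrm{diag}\big((\hat\sigma_x n^{-1/6})^2,
#'                             (\hat\sigma_y n^{-1/6})^2\big)}
#' for the joint density (the `-1/6` exponent is the optimal rate in two
#' dimensions).
#'
#' @param x,y numeric samples of equal length `n >= 2`, nonconstant.
#' @return an object of class `bandwidth_spec`: a list with elements
#'   `H` (2x2 diagonal matrix), `hx`, `hy` (marginal bandwidths) and
#'   `rule` (`"normal-reference"`), recorded for reproducibility.
#' @export
#' @examples
#' bw <- select_bandwidth(rnorm(100), rnorm(100))
#' bw$H
select_bandwidth <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 2L) stop("need at least 2 observations")
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (sx == 0 || sy == 0) stop("constant sample; bandwidth undefined")
  structure(list(
    H = diag(c((sx * n^(-1 / 6))^2, (sy * n^(-1 / 6))^2)),
    hx = 1.06 * sx * n^(-1 / 5),
    hy = 1.06 * sy * n^(-1 / 5),
    rule = "normal-reference"), class = "bandwidth_spec")
}

#' Univariate Gaussian kernel density estimate
#'
#' Evaluates \eqn{\hat p(q) = n^{-1} \sum_i \phi((q - x_i)/h)/h} with the
#' standard normal kernel \eqn{\phi}, exactly (full kernel sum, no
#' binning).
#'
#' @param sample numeric sample, length `n >= 2`.
#' @param h positive bandwidth (kernel standard deviation).
#' @param query points at which to evaluate the density.
#' @return nonnegative density values, one per query point.
#' @export
kde_univariate <- function(sample, h, query) {
  if (length(sample) < 2L) stop("need a sample of size >= 2")
  if (!is.numeric(h) || length(h) != 1L || h <= 0) stop("bandwidth h must be > 0")
  vapply(query, function(q) mean(stats::dnorm((q - sample) / h)) / h,
         numeric(1))
}

#' Bivariate kernel density estimate with a normal kernel
#'
#' Evaluates the bivariate kernel density estimate
#' \deqn{\hat p_H(z) = n^{-1} \sum_i K_H(z - Z_i), \qquad
#'       K_H(z) = (2\pi)^{-1} |H|^{-1/2}
#'                \exp\{-\tfrac12 z^\top H^{-1} z\},}
#' the bivariate normal kernel with symmetric positive-definite bandwidth
#' matrix `H` (entries are squared bandwidths). The kernel sum is exact.
#'
#' @param sample numeric matrix `n x 2` of observations, `n >= 2`.
#' @param H 2x2 symmetric positive-definite bandwidth matrix (e.g.
#'   `select_bandwidth(x, y)$H`).
#' @param query numeric matrix `m x 2` of evaluation points.
#' @return nonnegative density values, one per query row.
#' @export
bkde <- function(sample, H, query) {
  sample <- as.matrix(sample)
  query <- as.matrix(query)
  if (ncol(sample) != 2L || ncol(query) != 2L)
    stop("sample and query must have two columns")
  if (nrow(sample) < 2L) stop("need a sample of size >= 2")
  check_spd(H)
  Hinv <- solve(H)
  detH <- H[1, 1] * H[2, 2] - H[1, 2] * H[2, 1]
  norm_const <- 1 / (2 * pi * sqrt(detH))
  # quadratic form z' Hinv z expanded over all (query, sample) pairs
  dx <- outer(query[, 1L], sample[, 1L], "-")
  dy <- outer(query[, 2L], sample[, 2L], "-")
  qf <- Hinv[1, 1] * dx^2 + 2 * Hinv[1, 2] * dx * dy + Hinv[2, 2] * dy^2
  norm_const * rowMeans(exp(-0.5 * qf))
}

check_spd <- function(H) {
  H <- as.matrix(H)
  if (!all(dim(H) == 2L)) stop("H must be a 2x2 matrix")
  if (abs(H[1, 2] - H[2, 1]) > 1e-12 * max(abs(H)))
    stop("H must be symmetric")
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("H must be positive-definite")
  invisible(H)
}

#' Per-individual pointwise mutual information of an edge
#'
#' For two predicted-expression vectors, the pointwise mutual information
#' of individual `j` is
#' \deqn{E_j = \log \frac{\hat p_H(x_j, y_j)}{\hat p(x_j)\,\hat p(y_j)},}
#' the natural-log ratio of the joint density to the product of the
#' marginals, all estimated from the full sample by Gaussian kernel
#' density estimation and evaluated at the sample points themselves
#' (self-term included). Density values are floored at `floor` before the
#' ratio so far-tail points cannot produce infinities.
#'
#' Two evaluation paths give the same quantity: `"exact"` computes the
#' full kernel sums (`O(n^2)`), `"binned"` uses linear-binned FFT kernel
#' estimates on a fine grid (via \pkg{KernSmooth} and [stats::density()])
#' with bilinear/linear interpolation back to the sample points, which is
#' `O(n)` and accurate to well below the Monte-Carlo noise of any
#' downstream use. `"auto"` (default) picks `"exact"` for `n <= 2000`.
#' The binned path requires a diagonal `H`; a non-diagonal user-supplied
#' `H` falls back to exact evaluation.
#'
#' @param x,y numeric vectors of equal length `n >= 2`.
#' @param bw a `bandwidth_spec` from [select_bandwidth()]; default
#'   computed from the data.
#' @param method `"auto"`, `"exact"` or `"binned"`.
#' @param loo logical; drop the self-term (leave-one-out densities)?
#'   Exact path only. Default `FALSE`.
#' @param floor density floor before the log-ratio; default `1e-300`,
#'   below any attainable density for standardized data.
#' @param gridsize grid size per axis for the binned path.
#' @return numeric vector of per-individual PMI values, symmetric in the
#'   order of `x` and `y`.
#' @export
pmi_edge <- function(x, y, bw = NULL, method = c("auto", "exact", "binned"),
                     loo = FALSE, floor = 1e-300, gridsize = 201L) {
  method <- match.arg(method)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 2L) stop("need at least 2 observations")
  if (is.null(bw)) bw <- select_bandwidth(x, y)
  diagonal <- abs(bw$H[1, 2]) < 1e-15 && abs(bw$H[2, 1]) < 1e-15
  if (method == "auto") method <- if (n <= 2000L) "exact" else "binned"
  if (method == "binned" && (!diagonal || loo)) method <- "exact"

  if (method == "exact") {
    pj <- bkde(cbind(x, y), bw$H, cbind(x, y))
    px <- kde_univariate(x, bw$hx, x)
    py <- kde_univariate(y, bw$hy, y)
    if (loo) {
      # remove each point's own kernel contribution and renormalize
      detH <- bw$H[1, 1] * bw$H[2, 2]
      pj <- (n * pj - 1 / (2 * pi * sqrt(detH))) / (n - 1)
      px <- (n * px - stats::dnorm(0) / bw$hx) / (n - 1)
      py <- (n * py - stats::dnorm(0) / bw$hy) / (n - 1)
    }
  } else {
    hx2 <- sqrt(bw$H[1, 1])
    hy2 <- sqrt(bw$H[2, 2])
    rx <- range(x) + c(-4, 4) * hx2
    ry <- range(y) + c(-4, 4) * hy2
    f2 <- KernSmooth::bkde2D(cbind(x, y), bandwidth = c(hx2, hy2),
                             gridsize = c(gridsize, gridsize),
                             range.x = list(rx, ry))
    ix <- findInterval(x, f2$x1, all.inside = TRUE)
    iy <- findInterval(y, f2$x2, all.inside = TRUE)
    wx <- (x - f2$x1[ix]) / (f2$x1[2L] - f2$x1[1L])
    wy <- (y - f2$x2[iy]) / (f2$x2[2L] - f2$x2[1L])
    pj <- (1 - wx) * (1 - wy) * f2$fhat[cbind(ix, iy)] +
      wx * (1 - wy) * f2$fhat[cbind(ix + 1L, iy)] +
      (1 - wx) * wy * f2$fhat[cbind(ix, iy + 1L)] +
      wx * wy * f2$fhat[cbind(ix + 1L, iy + 1L)]
    dx <- stats::density(x, bw = bw$hx, n = 512L,
                         from = rx[1L], to = rx[2L])
    dy <- stats::density(y, bw = bw$hy, n = 512L,
                         from = ry[1L], to = ry[2L])
    px <- stats::approx(dx$x, dx$y, x, rule = 2)$y
    py <- stats::approx(dy$x, dy$y, y, rule = 2)$y
  }
  log(pmax(pj, floor)) - log(pmax(px, floor) * pmax(py, floor))
}

#' Per-individual product moment of an edge
#'
#' The comparator edge measure: the product of the two standardized node
#' values, \eqn{E_j = z(x_j)\, z(y_j)} with `z` the column
#' standardization (mean 0, sd 1, divisor `n - 1`). Its sample mean is
#' exactly the Pearson correlation of `x` and `y`, so each value can be
#' read as that individual's contribution to the linear correlation.
#'
#' @param x,y numeric vectors of equal length `n >= 2`, nonconstant.
#' @return numeric vector of per-individual products.
#' @export
pm_edge <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 2L) stop("need at least 2 observations")
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (sx == 0 || sy == 0) stop("constant input; product moment undefined")
  ((x - mean(x)) / sx) * ((y - mean(y)) / sy)
}

#' Edge-feature matrix over a network
#'
#' Computes the per-individual edge value for every edge of the network:
#' pointwise mutual information ([pmi_edge()], the default) or the
#' product moment ([pm_edge()], the linear comparator). Columns follow
#' [edge_index()] order and are named `geneA_geneB`.
#'
#' @param expr expression matrix (individuals x genes) containing every
#'   network node as a column.
#' @param net a [gene_network()].
#' @param measure `"pmi"` or `"pm"`.
#' @param ... passed to [pmi_edge()] (e.g. `method`, `bw`).
#' @return numeric matrix `n x |edges|` with
#'   `attr(, "measure")` set to the measure used.
#' @export
edge_features <- function(expr, net, measure = c("pmi", "pm"), ...) {
  measure <- match.arg(measure)
  expr <- as.matrix(expr)
  missing_genes <- setdiff(net$nodes, colnames(expr))
  if (length(missing_genes))
    stop("network gene(s) absent from expression matrix: ",
         paste(missing_genes, collapse = ", "))
  ei <- edge_index(net)
  E <- matrix(0, nrow = nrow(expr), ncol = nrow(ei),
              dimnames = list(rownames(expr), edge_names(net)))
  for (r in seq_len(nrow(ei))) {
    xl <- expr[, net$nodes[ei[r, "l"]]]
    xk <- expr[, net$nodes[ei[r, "k"]]]
    E[, r] <- if (measure == "pmi") pmi_edge(xl, xk, ...) else pm_edge(xl, xk)
  }
  attr(E, "measure") <- toupper(measure)
  E
}

#' Write an edge-feature matrix as TSV
#' @param E matrix from [edge_features()].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_features <- function(E, path) {
  d <- data.frame(id = if (is.null(rownames(E))) seq_len(nrow(E)) else rownames(E),
                  signif(as.matrix(E), 10), check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
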