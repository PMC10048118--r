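#' Read an eQTL weight table
#'
#' A weight table carries the estimated cis-SNP effect sizes on gene
#' expression from the first stage of a two-stage TWAS (e.g. produced by a
#' DPR- or BSLMM-style trainer, or by [train_weights_ridge()]). The file is
#' a TSV with a mandatory header and columns `snp_id`, `gene_id`,
#' `effect_allele`, `weight`.
#'
#' @param path path to the TSV file.
#' @return data frame with columns `snp_id`, `gene_id`, `effect_allele`,
#'   `weight`.
#' @export
read_weights <- function(path) {
  w <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_id", "gene_id", "effect_allele", "weight")
  if (!all(need %in% names(w)))
    stop("weight table must have columns: ", paste(need, collapse = ", "))
  w <- w[need]
  validate_weights(w)
  w
}

validate_weights <- function(w) {
  if (anyDuplicated(w[c("snp_id", "gene_id")]))
    stop("duplicate (snp_id, gene_id) pairs in weight table")
  if (!all(is.finite(w$weight))) stop("non-finite weights in weight table")
  invisible(w)
}

#' Write an eQTL weight table
#' @param weights data frame as returned by [read_weights()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  utils::write.table(weights, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix from TSV
#'
#' Individuals in rows, SNPs in columns; the first column holds individual
#' ids and the header holds SNP ids. Values are dosages (0-2) or
#' standardized genotypes. Missing dosages are mean-imputed per SNP.
#'
#' @param path path to the TSV file.
#' @param alleles optional data frame with columns `snp_id`,
#'   `effect_allele`, `other_allele` describing the allele coding of the
#'   dosage columns; enables allele harmonization in
#'   [predict_expression()].
#' @return numeric matrix with individual ids as rownames and SNP ids as
#'   colnames; allele information, when given, in `attr(, "alleles")`.
#' @export
read_genotypes <- function(path, alleles = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  g <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(g) <- "double"
  rownames(g) <- as.character(d[[1L]])
  impute_genotypes(g, alleles)
}

impute_genotypes <- function(g, alleles = NULL) {
  if (anyNA(g)) {
    for (j in seq_len(ncol(g))) {
      miss <- is.na(g[, j])
      if (any(miss)) g[miss, j] <- mean(g[!miss, j])
    }
  }
  if (!is.null(alleles)) attr(g, "alleles") <- alleles
  g
}

#' Read a genotype matrix from a VCF file
#'
#' Dosages are taken from the `DS` FORMAT field when present, otherwise
#' counted from `GT`. Requires the `vcfR` package.
#'
#' @param path path to an (uncompressed or bgzipped) VCF file.
#' @return as [read_genotypes()]: individuals x SNPs dosage matrix with
#'   REF/ALT alleles attached (effect allele = ALT).
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_genotypes_vcf requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  snp_id <- fix[, "ID"]
  nameless <- is.na(snp_id) | snp_id == "."
  snp_id[nameless] <- paste(fix[nameless, "CHROM"], fix[nameless, "POS"], sep = ":")
  if ("DS" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, 2, function(col) {
      vapply(strsplit(col, "[/|]"), function(a) sum(a == "1"), numeric(1))
    })
  }
  g <- t(ds)
  colnames(g) <- snp_id
  impute_genotypes(g, alleles = data.frame(
    snp_id = snp_id, effect_allele = fix[, "ALT"], other_allele = fix[, "REF"],
    stringsAsFactors = FALSE))
}

#' Predict gene expression from genotypes and eQTL weights
#'
#' Second-stage TWAS expression prediction: for each gene, the predicted
#' expression is the genotype matrix times the gene's SNP weight vector,
#' `x~ = G %*% beta`. Weights whose SNP is absent from the genotype matrix
#' are dropped (a message reports the count). When the genotype matrix
#' carries allele information, weights are harmonized: a weight whose
#' effect allele equals the genotype's other allele is negated;
#' strand-ambiguous (A/T, C/G) SNPs are kept with a warning.
#'
#' @param geno genotype matrix from [read_genotypes()] (individuals x
#'   SNPs).
#' @param weights weight table (see [read_weights()]).
#' @param genes gene ids to predict; default all genes in `weights`.
#' @return numeric matrix (individuals x genes). Genes whose SNPs were all
#'   dropped get an all-zero column, listed in `attr(, "empty_genes")`.
#'   Not yet standardized; see [standardize_columns()].
#' @export
predict_expression <- function(geno, weights, genes = NULL) {
  validate_weights(weights)
  if (is.null(genes)) genes <- unique(weights$gene_id)
  absent <- setdiff(genes, weights$gene_id)
  if (length(absent))
    stop("no weights for gene(s): ", paste(absent, collapse = ", "))
  w <- weights[weights$gene_id %in% genes, , drop = FALSE]

  in_geno <- w$snp_id %in% colnames(geno)
  if (any(!in_geno))
    message(sum(!in_geno), " weight SNP(s) absent from genotypes; dropped")
  w <- w[in_geno, , drop = FALSE]

  al <- attr(geno, "alleles")
  if (!is.null(al) && nrow(w)) {
    idx <- match(w$snp_id, al$snp_id)
    has <- !is.na(idx)
    ea <- toupper(al$effect_allele[idx[has]])
    oa <- toupper(al$other_allele[idx[has]])
    wa <- toupper(w$effect_allele[has])
    ambiguous <- (ea == comp_base(oa))
    if (any(ambiguous))
      warning(sum(ambiguous), " strand-ambiguous SNP(s) (A/T or C/G) kept as-is")
    flip <- wa == oa & !ambiguous
    w$weight[has][flip] <- -w$weight[has][flip]
  }

  x <- matrix(0, nrow = nrow(geno), ncol = length(genes),
              dimnames = list(rownames(geno), genes))
  empty <- character(0)
  for (gi in seq_along(genes)) {
    wg <- w[w$gene_id == genes[gi], , drop = FALSE]
    if (nrow(wg) == 0L) {
      empty <- c(empty, genes[gi])
      next
    }
    x[, gi] <- geno[, wg$snp_id, drop = FALSE] %*% wg$weight
  }
  if (length(empty)) {
    message("all SNPs dropped for gene(s): ", paste(empty, collapse = ", "),
            " (all-zero column)")
    attr(x, "empty_genes") <- empty
  }
  x
}

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

#' Standardize the columns of an expression matrix
#'
#' Centres each column to mean zero and scales to unit standard deviation
#' (divisor `n - 1`). Constant columns are an error naming the gene.
#'
#' @param x numeric matrix (individuals x genes).
#' @return matrix of the same shape with `attr(, "standardized") = TRUE`.
#' @export
standardize_columns <- function(x) {
  x <- as.matrix(x)
  s <- apply(x, 2L, stats::sd)
  if (any(s == 0 | !is.finite(s))) {
    bad <- colnames(x)[s == 0 | !is.finite(s)]
    if (is.null(bad)) bad <- which(s == 0 | !is.finite(s))
    stop("constant column(s), cannot standardize: ", paste(bad, collapse = ", "))
  }
  out <- scale(x, center = TRUE, scale = s)
  attributes(out)[c("scaled:center", "scaled:scale")] <- NULL
  attr(out, "standardized") <- TRUE
  out
}

#' Train eQTL weights by ridge regression
#'
#' A closed-form ridge trainer for the first TWAS stage: per gene it
#' solves `(G'G + penalty * I) beta = G'x`. It stands behind the same
#' weight-table contract as any external trainer, for users without
#' DPR/BSLMM output at hand.
#'
#' @param expr_train expression matrix (individuals x genes) from the
#'   eQTL study.
#' @param geno_train genotype matrix for the same individuals (see
#'   [read_genotypes()]).
#' @param penalty nonnegative ridge penalty. At `penalty = 0` a singular
#'   `G'G` is an error advising a positive penalty.
#' @return weight table (data frame `snp_id`, `gene_id`, `effect_allele`,
#'   `weight`) covering every SNP for every gene. Effect alleles come from
#'   the genotype allele attribute when present, `NA` otherwise.
#' @export
train_weights_ridge <- function(expr_train, geno_train, penalty = 0.1) {
  expr_train <- as.matrix(expr_train)
  geno_train <- as.matrix(geno_train)
  if (nrow(expr_train) != nrow(geno_train))
    stop("expression and genotype matrices must cover the same individuals")
  if (penalty < 0) stop("penalty must be nonnegative")
  p <- ncol(geno_train)
  gtg <- crossprod(geno_train) + diag(penalty, p)
  if (rcond(gtg) < 1e-12)
    stop("singular system; use a positive ridge penalty")
  ch <- chol(gtg)
  beta <- backsolve(ch, forwardsolve(t(ch), crossprod(geno_train, expr_train)))
  al <- attr(geno_train, "alleles")
  ea <- if (is.null(al)) rep(NA_character_, p) else
    al$effect_allele[match(colnames(geno_train), al$snp_id)]
  genes <- colnames(expr_train)
  if (is.null(genes)) genes <- paste0("gene", seq_len(ncol(expr_train)))
  data.frame(
    snp_id = rep(colnames(geno_train), times = length(genes)),
    gene_id = rep(genes, each = p),
    effect_allele = rep(ea, times = length(genes)),
    weight = as.vector(beta),
    stringsAsFactors = FALSE)
}

#' Write / read an expression matrix as TSV
#'
#' First column `id`, one column per gene; floats with 10 significant
#' digits.
#'
#' @param x expression matrix with individual rownames.
#' @param path TSV path.
#' @return `path` (write) or the matrix (read).
#' @export
write_expression <- function(x, path) {
  d <- data.frame(id = rownames(x), signif(as.matrix(x), 10),
                  check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  x <- as.matrix(d[, -1L, drop = FALSE])
  rownames(x) <- as.character(d[[1L]])
  x
}
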