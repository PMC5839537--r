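#' Sample-center a log-quantity matrix
#'
#' Subtracts the per-sample mean over genes from each column of the log2
#' relative-quantity matrix. This removes the shared per-sample loading
#' effect (total RNA input, RT yield) that all candidate reference genes
#' experience identically; every column of the result sums to zero. The
#' model-based decomposition downstream corrects for the gene-gene
#' correlation this centering induces, which requires at least 3 genes.
#'
#' @param y numeric matrix (genes x samples) of log2 relative quantities.
#' @return centered matrix z of the same shape.
#' @export
sample_center <- function(y) {
  stopifnot(is.matrix(y), is.numeric(y))
  if (anyNA(y)) stop("log-quantity matrix must be complete")
  if (nrow(y) < 3)
    stop("sample centering needs >= 3 genes (the variance correction is ",
         "undefined at k <= 2)")
  sweep(y, 2L, colMeans(y))
}

#' Moment-based intra-/inter-group variance decomposition
#'
#' Given the sample-centered matrix, estimates for each gene and group the
#' gene-specific technical variance sigma^2 (intra-group) and the raw
#' group-mean deviation d (inter-group). The naive per-group sample variance
#' of z is biased by the centering (each cell contains -1/k of every gene's
#' noise); the moment system is inverted per group as
#' `S_g = (k/(k-1)) * sum_i s2_ig`, then
#' `sigma2_ig = max((s2_ig - S_g/k^2) / (1 - 2/k), floor)`.
#' Deviations are taken about each gene's own across-group mean:
#' `d_ig = zbar_ig - mean_g'(zbar_ig')`, so they sum to zero over groups for
#' every gene (and over genes within every group, since columns of z sum to
#' zero).
#'
#' @param z centered matrix from [sample_center()].
#' @param groups character vector of group labels, one per column; every
#'   group needs >= 2 samples.
#' @param floor lower bound on the corrected variance estimates (default
#'   1e-8), preventing negative moment estimates from breaking downstream
#'   shrinkage ratios.
#' @return list with `intra_var` (genes x groups matrix of sigma^2-hat),
#'   `d` (genes x groups raw deviations), `n_g` (named group sizes),
#'   `groups` (ordered unique labels).
#' @export
variance_decomposition <- function(z, groups, floor = 1e-8) {
  stopifnot(is.matrix(z), length(groups) == ncol(z))
  k <- nrow(z)
  if (k < 3) stop("variance decomposition needs >= 3 genes")
  glev <- unique(as.character(groups))
  n_g <- stats::setNames(vapply(glev, function(g) sum(groups == g), 0L), glev)
  if (any(n_g < 2))
    stop("group(s) with fewer than 2 samples: ",
         paste(glev[n_g < 2], collapse = ", "))
  intra <- matrix(NA_real_, k, length(glev), dimnames = list(rownames(z), glev))
  zbar <- matrix(NA_real_, k, length(glev), dimnames = list(rownames(z), glev))
  for (g in glev) {
    zg <- z[, groups == g, drop = FALSE]
    s2 <- apply(zg, 1L, stats::var)
    S <- (k / (k - 1)) * sum(s2)
    intra[, g] <- pmax((s2 - S / k^2) / (1 - 2 / k), floor)
    zbar[, g] <- rowMeans(zg)
  }
  d <- zbar - rowMeans(zbar)
  list(intra_var = intra, d = d, n_g = n_g, groups = glev)
}

#' NormFinder-style model-based stability values
#'
#' Ranks candidate reference genes by a stability value rho that combines a
#' gene's estimated intra-group (within-tissue) variability with its
#' shrunken inter-group (between-tissue) expression deviation; lower rho is
#' more stable. With groups, the true between-group variance of each gene's
#' deviations is estimated as
#' `gamma2_i = max(0, (1/(G-1)) sum_g d_ig^2 - (1/G) sum_g sigma2_ig/n_g)`,
#' deviations are shrunk toward zero by the reliability ratio
#' `d~_ig = d_ig * gamma2_i / (gamma2_i + sigma2_ig/n_g)`, and
#' `rho_i = (1/G) sum_g (|d~_ig| + sqrt(sigma2_ig/n_g))`.
#' Without groups all samples form one group with d = 0, so
#' `rho_i = sqrt(sigma2_i)` — the gene's corrected technical SD.
#'
#' @param q an `rq_matrix` (groups carried along), a [cq_table], or a
#'   positive genes x samples matrix.
#' @param groups group labels per sample; defaults to the labels carried by
#'   `q`, or ungrouped mode if none exist.
#' @param floor variance floor, see [variance_decomposition()].
#' @return a `normfinder_result`: list with `stability` (gene -> rho),
#'   `rank` (ascending rho, ties share the smaller rank), `intra_var`,
#'   `inter_dev` (shrunken deviations; zero matrix in ungrouped mode),
#'   `groups`, `grouped` flag.
#' @export
normfinder_stability <- function(q, groups = NULL, floor = 1e-8) {
  if (is.null(groups)) {
    if (inherits(q, "rq_matrix")) groups <- q$groups
    else if (inherits(q, "cq_table")) groups <- q$groups
  }
  m <- as_q_matrix(q)
  if (any(m <= 0)) stop("relative quantities must be strictly positive")
  z <- sample_center(log2(m))
  genes <- rownames(z)
  if (is.null(groups)) {
    dec <- variance_decomposition(z, rep("all", ncol(z)), floor = floor)
    rho <- sqrt(dec$intra_var[, 1])
    inter <- matrix(0, nrow(z), 1, dimnames = list(genes, "all"))
    grouped <- FALSE
  } else {
    dec <- variance_decomposition(z, groups, floor = floor)
    G <- length(dec$groups)
    if (G < 2)
      stop("grouped mode needs >= 2 groups; omit `groups` for ungrouped mode")
    se2 <- sweep(dec$intra_var, 2L, dec$n_g[dec$groups], "/")  # sigma2/n per group
    gamma2 <- pmax(0, rowSums(dec$d^2) / (G - 1) - rowMeans(se2))
    shrink <- gamma2 / (gamma2 + se2)          # recycled per row via matrix ops
    shrink[gamma2 == 0, ] <- 0                 # exact limit: no group effect
    inter <- dec$d * shrink
    rho <- rowMeans(abs(inter) + sqrt(se2))
    grouped <- TRUE
  }
  rho <- stats::setNames(as.numeric(rho), genes)
  structure(list(
    stability = rho,
    rank = stats::setNames(rank(rho, ties.method = "min"), genes),
    intra_var = dec$intra_var,
    inter_dev = inter,
    groups = if (is.null(groups)) NULL else dec$groups,
    grouped = grouped
  ), class = "normfinder_result")
}

#' @export
print.normfinder_result <- function(x, ...) {
  ord <- order(x$rank)
  cat("normfinder_result (", length(x$stability), " genes, ",
      if (x$grouped) paste0(length(x$groups), " groups") else "ungrouped",
      ")\n", sep = "")
  print(data.frame(gene = names(x$stability)[ord],
                   stability = round(x$stability[ord], 4),
                   rank = x$rank[ord], row.names = NULL))
  invisible(x)
}
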