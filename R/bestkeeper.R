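#' BestKeeper descriptive statistics for one gene
#'
#' Crossing-point (Cq) descriptives computed on all non-missing values of a
#' single gene: geometric and arithmetic mean, extremes, dispersion (sample
#' SD by default, or the mean absolute deviation about the arithmetic mean),
#' the coefficient of variation on the Cq scale, and the x-fold expression
#' coefficients re-expressing the Cq range on the fold-change scale with the
#' BestKeeper sign convention: the fold at the minimum Cq (highest
#' expression) is negative, the fold at the maximum Cq positive, and
#' `sd_xfold = base^sd_cq`. Genes with Cq SD below 1 cycle are conventionally
#' considered consistently expressed.
#'
#' @param x a [cq_table].
#' @param gene gene identifier.
#' @param base amplification base used for the x-fold scale (default 2).
#' @param sd_method `"sample_sd"` (n-1 denominator, default) or `"mad"`
#'   (mean absolute deviation about the arithmetic mean).
#' @return a one-row data.frame with columns `gene, n, geo_mean_cq,
#'   ar_mean_cq, min_cq, max_cq, sd_cq, cv_pct, min_xfold, max_xfold,
#'   sd_xfold`.
#' @export
descriptive_stats <- function(x, gene, base = 2,
                              sd_method = c("sample_sd", "mad")) {
  sd_method <- match.arg(sd_method)
  stopifnot(inherits(x, "cq_table"))
  if (!gene %in% x$genes) stop("unknown gene: ", gene)
  if (base <= 1) stop("x-fold base must be > 1")
  v <- x$cq[gene, ]
  v <- v[!is.na(v)]
  if (length(v) < 3)
    stop("gene ", gene, " has fewer than 3 non-missing Cq values")
  if (any(v <= 0))
    stop("gene ", gene, " has non-positive Cq (geometric mean undefined)")
  geo <- exp(mean(log(v)))
  ar <- mean(v)
  s <- if (sd_method == "sample_sd") stats::sd(v) else mean(abs(v - ar))
  data.frame(
    gene = gene,
    n = length(v),
    geo_mean_cq = geo,
    ar_mean_cq = ar,
    min_cq = min(v),
    max_cq = max(v),
    sd_cq = s,
    cv_pct = 100 * s / ar,
    min_xfold = -(base^(geo - min(v))),
    max_xfold = base^(max(v) - geo),
    sd_xfold = base^s,
    stringsAsFactors = FALSE
  )
}

#' BestKeeper descriptive table for all genes
#'
#' @param x a [cq_table].
#' @param base single base, or an [efficiency_set] / named vector honoring
#'   per-gene amplification bases for the x-fold scale.
#' @param sd_method see [descriptive_stats()].
#' @return data.frame, one row per gene (Cq-table gene order).
#' @export
bestkeeper_stats <- function(x, base = 2, sd_method = c("sample_sd", "mad")) {
  sd_method <- match.arg(sd_method)
  bases <- rep(if (is.numeric(base) && length(base) == 1) base else 2,
               length(x$genes))
  names(bases) <- x$genes
  if (inherits(base, "efficiency_set") ||
      (is.numeric(base) && !is.null(names(base)))) {
    ev <- if (inherits(base, "efficiency_set")) base$efficiency else base
    hit <- intersect(names(ev), x$genes)
    bases[hit] <- ev[hit]
  }
  do.call(rbind, lapply(x$genes, function(g)
    descriptive_stats(x, g, base = bases[[g]], sd_method = sd_method)))
}

#' BestKeeper index
#'
#' Per-sample geometric mean of the selected genes' Cq values, computed on
#' the complete cases over those genes.
#'
#' @param x a [cq_table].
#' @param genes selected gene subset (>= 2 genes); default all.
#' @return named numeric vector, sample -> index Cq (cycles).
#' @export
bestkeeper_index <- function(x, genes = NULL) {
  stopifnot(inherits(x, "cq_table"))
  if (is.null(genes)) genes <- x$genes
  if (length(genes) < 2) stop("BestKeeper index needs >= 2 genes")
  cc <- complete_case_subset(x, genes)
  if (any(cc$cq <= 0)) stop("non-positive Cq: geometric mean undefined")
  stats::setNames(exp(colMeans(log(cc$cq))), cc$samples)
}

#' Pearson correlation with a two-sided p-value
#'
#' Pearson r plus the two-sided p-value from `t = r * sqrt((n-2)/(1-r^2))`
#' on n-2 degrees of freedom. A perfect correlation (|r| = 1) returns the
#' smallest positive double rather than p = 0.
#'
#' @param x,y numeric vectors of equal length n >= 3 with non-zero variance.
#' @return list with elements `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("correlation needs >= 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance: Pearson correlation undefined")
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- .Machine$double.xmin
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- max(2 * stats::pt(-abs(t), df = n - 2), .Machine$double.xmin)
  }
  list(r = r, p = min(p, 1), n = n)
}

#' Gene-vs-index and gene-vs-gene BestKeeper correlations
#'
#' @param x a [cq_table].
#' @param genes gene subset entering the index; default all.
#' @return list with `index` (sample -> index Cq), `gene_vs_index`
#'   (data.frame gene, r, p) and `pairwise` (data.frame gene_a, gene_b, r, p
#'   for each unordered pair).
#' @export
bestkeeper_correlations <- function(x, genes = NULL) {
  stopifnot(inherits(x, "cq_table"))
  if (is.null(genes)) genes <- x$genes
  cc <- complete_case_subset(x, genes)
  idx <- bestkeeper_index(cc, genes)
  gvi <- do.call(rbind, lapply(genes, function(g) {
    ct <- pearson_with_p(cc$cq[g, ], idx)
    data.frame(gene = g, r = ct$r, p = ct$p, stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(genes, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    ct <- pearson_with_p(cc$cq[a, ], cc$cq[b, ])
    data.frame(gene_a = a, gene_b = b, r = ct$r, p = ct$p,
               stringsAsFactors = FALSE)
  }))
  list(index = idx, gene_vs_index = gvi, pairwise = pw)
}

#' BestKeeper stability ranking
#'
#' Ranks genes by ascending Cq standard deviation (the primary BestKeeper
#' criterion), breaking ties by ascending sd_xfold and then input order.
#' Genes at or above 1 cycle of Cq SD are flagged `inconsistent` per the
#' SD < 1 consistency guideline but remain ranked. Ties (equal sd_cq and
#' sd_xfold) share the smaller rank. The correlation table, when supplied,
#' is attached as advisory information and never enters the sort.
#'
#' @param stats data.frame from [bestkeeper_stats()].
#' @param correlations optional list from [bestkeeper_correlations()].
#' @return a `bestkeeper_result`: list with `stats` (ranked data.frame incl.
#'   `rank` and `inconsistent` columns), `rank` (named vector in input gene
#'   order), `stability_order`, and `correlations`.
#' @export
bestkeeper_rank <- function(stats, correlations = NULL) {
  stopifnot(is.data.frame(stats), nrow(stats) >= 2)
  ord <- order(stats$sd_cq, stats$sd_xfold, seq_len(nrow(stats)))
  key <- paste(stats$sd_cq, stats$sd_xfold)
  rk <- integer(nrow(stats))
  rk[ord] <- seq_len(nrow(stats))
  # share the smaller rank on exact (sd_cq, sd_xfold) ties
  for (i in seq_along(ord)[-1]) {
    if (key[ord[i]] == key[ord[i - 1]]) rk[ord[i]] <- rk[ord[i - 1]]
  }
  out <- stats
  out$rank <- rk
  out$inconsistent <- out$sd_cq >= 1
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(list(
    stats = out,
    rank = stats::setNames(rk, stats$gene),
    stability_order = stats$gene[ord],
    correlations = correlations
  ), class = "bestkeeper_result")
}

#' Full BestKeeper analysis
#'
#' Convenience wrapper: descriptives on all non-missing Cq per gene, index
#' and correlations on the complete cases, and the SD-based ranking.
#'
#' @inheritParams bestkeeper_stats
#' @param x a [cq_table].
#' @return a `bestkeeper_result` (see [bestkeeper_rank()]).
#' @export
bestkeeper <- function(x, base = 2, sd_method = c("sample_sd", "mad")) {
  sd_method <- match.arg(sd_method)
  st <- bestkeeper_stats(x, base = base, sd_method = sd_method)
  bestkeeper_rank(st, bestkeeper_correlations(x))
}

#' @export
print.bestkeeper_result <- function(x, ...) {
  cat("bestkeeper_result (", nrow(x$stats), " genes)\n", sep = "")
  df <- x$stats[, c("gene", "n", "sd_cq", "cv_pct", "sd_xfold", "rank",
                    "inconsistent")]
  df[3:5] <- round(df[3:5], 2)
  print(df)
  invisible(x)
}
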