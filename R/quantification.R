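#' Amplification efficiency from a standard-curve slope
#'
#' For a dilution series, the fitted slope of Cq against log10(input) gives
#' the per-cycle amplification base `E = 10^(-1/slope)`. A slope of -3.3219
#' (= -1/log10(2)) corresponds to perfect doubling, E = 2 (100% efficiency,
#' reported as `(E - 1) * 100`).
#'
#' @param slope standard-curve slope, cycles per log10 dilution; must be < 0.
#' @return the amplification base E (> 1).
#' @seealso [slope_from_efficiency()], [fit_standard_curve()]
#' @export
efficiency_from_slope <- function(slope) {
  if (!is.numeric(slope) || anyNA(slope) || any(slope >= 0))
    stop("standard-curve slope must be negative (Cq decreases with input)")
  10^(-1 / slope)
}

#' Standard-curve slope implied by an amplification base
#' @param efficiency amplification base E; must be > 1.
#' @return the slope `-1/log10(E)`.
#' @export
slope_from_efficiency <- function(efficiency) {
  if (!is.numeric(efficiency) || anyNA(efficiency) || any(efficiency <= 1))
    stop("amplification base E must be > 1")
  -1 / log10(efficiency)
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of mean Cq against log10 relative input over a
#' dilution series (typically 5 points of five-fold serial dilutions).
#' Replicated Cq at the same dilution are averaged before fitting. R-squared
#' is the squared Pearson correlation of fitted vs observed Cq.
#'
#' @param log10_input log10 relative template input per point.
#' @param cq observed Cq per point (cycles).
#' @param gene optional gene identifier carried through for provenance.
#' @return a `standard_curve`: list with `gene`, `slope`, `intercept`, `r2`,
#'   `efficiency` (base E) and `efficiency_pct` (`(E-1)*100`).
#' @examples
#' sc <- fit_standard_curve(-(0:4) * log10(5), 30 + 3.3219 * (0:4) * log10(5))
#' sc$efficiency  # 2: perfect doubling
#' @export
fit_standard_curve <- function(log10_input, cq, gene = NULL) {
  stopifnot(is.numeric(log10_input), is.numeric(cq),
            length(log10_input) == length(cq))
  ok <- !is.na(log10_input) & !is.na(cq)
  x <- log10_input[ok]; y <- cq[ok]
  # average replicate Cq measured at the same dilution
  if (anyDuplicated(x)) {
    y <- tapply(y, x, mean)
    x <- as.numeric(names(y))
    y <- as.numeric(y)
  }
  if (length(unique(x)) < 3)
    stop("need >= 3 distinct dilution points to fit a standard curve")
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0)
    stop("fitted slope is non-negative (", signif(slope, 4),
         "); Cq must decrease with template input")
  structure(list(
    gene = gene,
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    r2 = stats::cor(y, stats::fitted(fit))^2,
    efficiency = efficiency_from_slope(slope),
    efficiency_pct = (efficiency_from_slope(slope) - 1) * 100
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("standard_curve", if (!is.null(x$gene)) paste0("[", x$gene, "]"),
      ": slope ", sprintf("%.4f", x$slope),
      ", E = ", sprintf("%.4f", x$efficiency),
      " (", sprintf("%.2f", x$efficiency_pct), "% efficiency), R2 = ",
      sprintf("%.4f", x$r2), "\n", sep = "")
  invisible(x)
}

#' Construct a per-gene efficiency set
#'
#' @param efficiency named numeric vector, gene -> amplification base E
#'   (each > 1; typical assays fall in 1.6-2.2).
#' @param slope optional named numeric vector of standard-curve slopes; when
#'   present, each must satisfy `E = 10^(-1/slope)` to within 1e-6.
#' @param r2 optional named numeric vector of standard-curve R-squared values.
#' @return an `efficiency_set`.
#' @export
efficiency_set <- function(efficiency, slope = NULL, r2 = NULL) {
  if (is.null(names(efficiency)) || anyDuplicated(names(efficiency)))
    stop("`efficiency` must be named by unique gene identifiers")
  if (any(!is.finite(efficiency)) || any(efficiency <= 1))
    stop("every amplification base E must be finite and > 1")
  if (!is.null(slope)) {
    slope <- slope[names(efficiency)]
    bad <- abs(efficiency - 10^(-1 / slope)) > 1e-6
    if (any(bad, na.rm = TRUE))
      stop("efficiency and slope disagree (|E - 10^(-1/slope)| > 1e-6) for: ",
           paste(names(efficiency)[which(bad)], collapse = ", "))
  }
  structure(list(efficiency = efficiency, slope = slope, r2 = r2),
            class = "efficiency_set")
}

#' Read per-gene efficiencies from CSV
#'
#' Accepts either columns `gene,efficiency` (base E) or `gene,slope`
#' (standard-curve slope, converted via `E = 10^(-1/slope)`).
#'
#' @param path CSV/TSV file path.
#' @return an [efficiency_set].
#' @export
read_efficiencies <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = infer_sep(path),
                          stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!"gene" %in% names(df)) stop("efficiency file needs a `gene` column")
  if ("efficiency" %in% names(df)) {
    e <- as.numeric(df$efficiency)
    # tolerate percent-style entries (e.g. 95 meaning E = 1.95)
    if (all(e > 10, na.rm = TRUE)) e <- 1 + e / 100
    eff <- stats::setNames(e, df$gene)
    efficiency_set(eff, r2 = if ("r2" %in% names(df)) stats::setNames(df$r2, df$gene))
  } else if ("slope" %in% names(df)) {
    sl <- stats::setNames(as.numeric(df$slope), df$gene)
    efficiency_set(efficiency_from_slope(sl), slope = sl,
                   r2 = if ("r2" %in% names(df)) stats::setNames(df$r2, df$gene))
  } else stop("efficiency file needs an `efficiency` or `slope` column")
}

#' Fit standard curves for every gene in a dilution-series file
#'
#' Expects columns `gene,log10_input,cq` (replicates allowed; averaged per
#' dilution before the fit).
#'
#' @param path CSV/TSV file path.
#' @return named list of `standard_curve` objects, plus an attached
#'   [efficiency_set] in attribute `"efficiency_set"`.
#' @export
read_standard_curves <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = infer_sep(path),
                          stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("gene", "log10_input", "cq")
  if (!all(need %in% names(df)))
    stop("standard-curve file needs columns: ", paste(need, collapse = ", "))
  curves <- lapply(split(df, factor(df$gene, levels = unique(df$gene))),
                   function(d) fit_standard_curve(as.numeric(d$log10_input),
                                                  as.numeric(d$cq), gene = d$gene[1]))
  eff <- efficiency_set(
    vapply(curves, `[[`, 0, "efficiency"),
    slope = vapply(curves, `[[`, 0, "slope"),
    r2 = vapply(curves, `[[`, 0, "r2")
  )
  attr(curves, "efficiency_set") <- eff
  curves
}

#' Comparative-Cq relative quantities
#'
#' Transforms Cq into relative expression quantities
#' `q_gs = E_g^(minCq_g - Cq_gs)`, referenced to each gene's minimum Cq so the
#' per-gene maximum quantity is exactly 1. Any common per-gene reference
#' cancels in every downstream log-ratio and variance, so the choice of
#' reference point is presentation-only. These quantities are the input to
#' the geNorm and NormFinder algorithms.
#'
#' @param x a complete-case [cq_table] (no missing cells; see
#'   [complete_case_subset()]).
#' @param eff optional [efficiency_set] (or named numeric vector of bases E);
#'   genes without a supplied efficiency fall back to `base`.
#' @param base default amplification base when no efficiency is given;
#'   2 assumes 100% efficiency.
#' @return an `rq_matrix`: list with `q` (genes x samples, each row max 1),
#'   `genes`, `samples`, `groups`, `base_of` (named vector of bases used).
#' @examples
#' m <- matrix(c(18, 19, 20), 1, dimnames = list("g", c("a", "b", "c")))
#' relative_quantities(cq_table(m))$q  # 1, 0.5, 0.25
#' @export
relative_quantities <- function(x, eff = NULL, base = 2) {
  stopifnot(inherits(x, "cq_table"))
  if (anyNA(x$cq))
    stop("Cq table has missing cells; run complete_case_subset() first")
  if (!is.null(x$replicates))
    stop("collapse technical replicates before quantification")
  bases <- rep(base, length(x$genes))
  names(bases) <- x$genes
  if (!is.null(eff)) {
    ev <- if (inherits(eff, "efficiency_set")) eff$efficiency else eff
    hit <- intersect(names(ev), x$genes)
    bases[hit] <- ev[hit]
  }
  if (any(!is.finite(bases)) || any(bases <= 1))
    stop("every amplification base must be finite and > 1")
  mins <- apply(x$cq, 1L, min)
  q <- bases^(mins - x$cq)  # recycles by row: bases and mins are per-gene
  dimnames(q) <- dimnames(x$cq)
  structure(list(q = q, genes = x$genes, samples = x$samples,
                 groups = x$groups, base_of = bases),
            class = "rq_matrix")
}

#' @export
print.rq_matrix <- function(x, ...) {
  cat("rq_matrix: ", nrow(x$q), " genes x ", ncol(x$q),
      " samples (comparative-Cq relative quantities, per-gene max = 1)\n", sep = "")
  invisible(x)
}

# Accept an rq_matrix, a cq_table (converted with base 2) or a plain positive
# matrix wherever a quantity matrix is expected.
as_q_matrix <- function(q) {
  if (inherits(q, "rq_matrix")) return(q$q)
  if (inherits(q, "cq_table")) return(relative_quantities(q)$q)
  if (is.matrix(q) && is.numeric(q)) return(q)
  stop("expected an rq_matrix, cq_table, or numeric matrix")
}
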