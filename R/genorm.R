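#' geNorm pairwise variation between two genes
#'
#' The building block of the geNorm stability measure: the sample standard
#' deviation (n-1 denominator) over samples of the log2 expression ratio
#' of two genes. Two ideal reference genes have a constant ratio across all
#' samples and hence V = 0; V grows as either gene is independently
#' regulated or noisy. Symmetric in its two arguments.
#'
#' @param q an `rq_matrix` (or positive genes x samples matrix).
#' @param gene_j,gene_k gene identifiers (or row indices); must differ.
#' @return V_jk, a dimensionless standard deviation of log2 ratios.
#' @export
pairwise_variation <- function(q, gene_j, gene_k) {
  m <- as_q_matrix(q)
  if (any(m <= 0)) stop("relative quantities must be strictly positive")
  if (ncol(m) < 3) stop("need >= 3 samples for a pairwise variation")
  if (identical(gene_j, gene_k)) stop("gene_j and gene_k must differ")
  stats::sd(log2(m[gene_j, ] / m[gene_k, ]))
}

#' geNorm gene-stability values (M)
#'
#' For each gene in the active subset, M is the arithmetic mean of its
#' pairwise variations V_jk against every other gene in the subset. Lower M
#' means more stable; geNorm's conventional acceptability guideline is
#' M < 1.5 for heterogeneous sample panels.
#'
#' @param q an `rq_matrix` (or positive genes x samples matrix).
#' @param genes active subset of gene identifiers; default all rows.
#' @return named numeric vector, gene -> M.
#' @export
m_values <- function(q, genes = NULL) {
  m <- as_q_matrix(q)
  if (any(m <= 0)) stop("relative quantities must be strictly positive")
  if (is.null(genes)) genes <- rownames(m)
  if (length(genes) < 2) stop("M values need an active subset of >= 2 genes")
  y <- log2(m[genes, , drop = FALSE])
  k <- length(genes)
  V <- matrix(0, k, k)
  for (j in seq_len(k - 1)) {
    for (l in (j + 1):k) {
      V[j, l] <- V[l, j] <- stats::sd(y[j, ] - y[l, ])
    }
  }
  stats::setNames(rowSums(V) / (k - 1), genes)
}

#' geNorm iterative stability ranking
#'
#' Implements the geNorm stepwise-exclusion procedure: compute M for every
#' gene in the active set, remove the single least-stable gene (highest M;
#' ties remove the later gene in input order, with a message), record the M
#' at which it was removed, and repeat until two genes remain. The final two
#' genes cannot be separated (each one's M equals their common pairwise V)
#' and share rank 1.
#'
#' @param q an `rq_matrix` (or positive genes x samples matrix) with
#'   >= 3 genes and >= 3 samples.
#' @param v_series compute the V(n/n+1) panel-size series as well
#'   (see [nf_pairwise_variation()]); default `TRUE`.
#' @return a `genorm_result`: list with
#'   \describe{
#'     \item{m_final}{gene -> M at the step the gene was excluded (the final
#'       pair shares its pairwise M).}
#'     \item{exclusion_order}{genes in removal order, least stable first.}
#'     \item{ranking}{gene -> rank, 1 = most stable; the final pair shares 1.}
#'     \item{stability_order}{genes most-stable first (ties: input order).}
#'     \item{m_trajectory}{per step, the remaining gene set and its mean M.}
#'     \item{v_series}{named vector V(n/n+1) for n = 2..k-1, or NULL.}
#'   }
#' @export
genorm_rank <- function(q, v_series = TRUE) {
  m <- as_q_matrix(q)
  if (nrow(m) < 3) stop("geNorm ranking needs >= 3 genes")
  if (ncol(m) < 3) stop("geNorm ranking needs >= 3 samples")
  input_order <- rownames(m)
  if (is.null(input_order)) input_order <- rownames(m) <- paste0("g", seq_len(nrow(m)))
  active <- input_order
  m_final <- stats::setNames(numeric(length(input_order)), input_order)
  exclusion_order <- character(0)
  trajectory <- list()
  while (length(active) > 2) {
    mv <- m_values(m, active)
    trajectory[[length(trajectory) + 1L]] <- list(genes = active,
                                                  mean_m = mean(mv))
    worst <- which(mv == max(mv))
    if (length(worst) > 1)
      message("geNorm: tie at M = ", format(max(mv)),
              " among ", paste(active[worst], collapse = ", "),
              "; removing the later gene in input order")
    drop_gene <- active[worst[length(worst)]]
    m_final[drop_gene] <- max(mv)
    exclusion_order <- c(exclusion_order, drop_gene)
    active <- setdiff(active, drop_gene)
  }
  pair_m <- m_values(m, active)  # identical by construction
  trajectory[[length(trajectory) + 1L]] <- list(genes = active,
                                                mean_m = mean(pair_m))
  m_final[active] <- pair_m
  # ranks: final pair shares 1; then 2, 3, ... walking back up the exclusions
  ranking <- stats::setNames(integer(length(input_order)), input_order)
  ranking[active] <- 1L
  ranking[rev(exclusion_order)] <- seq_along(exclusion_order) + 1L
  stability_order <- c(active, rev(exclusion_order))
  res <- structure(list(
    m_final = m_final,
    exclusion_order = exclusion_order,
    ranking = ranking,
    stability_order = stability_order,
    m_trajectory = trajectory,
    v_series = NULL
  ), class = "genorm_result")
  if (v_series) res$v_series <- nf_pairwise_variation(m, res)
  res
}

#' @export
print.genorm_result <- function(x, ...) {
  ord <- x$stability_order
  cat("genorm_result (", length(ord), " genes)\n", sep = "")
  df <- data.frame(gene = ord, M = round(x$m_final[ord], 4),
                   rank = x$ranking[ord], row.names = NULL)
  print(df)
  if (!is.null(x$v_series)) {
    cat("V(n/n+1):",
        paste(sprintf("V%s/%s=%.4f", names(x$v_series),
                      as.integer(names(x$v_series)) + 1L, x$v_series),
              collapse = "  "), "\n")
  }
  invisible(x)
}

#' Normalization-factor pairwise variation series V(n/n+1)
#'
#' For n = 2..k-1, builds the normalization factor NF_n(s) as the geometric
#' mean of the n most stable genes' relative quantities (geNorm order: the
#' tied top pair first, then ascending exclusion M) and reports
#' V(n/n+1) = sample SD over samples of log2(NF_n / NF_{n+1}). Small V means
#' adding the (n+1)-th gene barely changes the normalization factor, so n
#' genes suffice; the conventional suggestive cutoff is V <= 0.15.
#'
#' @param q an `rq_matrix` (or positive genes x samples matrix).
#' @param ranking a `genorm_result` for the same genes (see [genorm_rank()]).
#' @return named numeric vector; element `"n"` holds V(n/n+1).
#' @export
nf_pairwise_variation <- function(q, ranking) {
  m <- as_q_matrix(q)
  stopifnot(inherits(ranking, "genorm_result"))
  ord <- ranking$stability_order
  if (!setequal(ord, rownames(m)))
    stop("ranking and quantity matrix cover different gene sets")
  k <- length(ord)
  if (k < 3) stop("V(n/n+1) series needs >= 3 genes")
  logq <- log2(m[ord, , drop = FALSE])
  # log2 NF_n per sample = mean of the top-n genes' log2 quantities
  v <- stats::setNames(numeric(k - 2), as.character(2:(k - 1)))
  for (n in 2:(k - 1)) {
    lnf_n <- colMeans(logq[1:n, , drop = FALSE])
    lnf_n1 <- colMeans(logq[1:(n + 1), , drop = FALSE])
    v[as.character(n)] <- stats::sd(lnf_n - lnf_n1)
  }
  v
}

#' Per-group geNorm analysis
#'
#' Reruns the geNorm ranking and V series within each group (tissue),
#' mirroring tissue-wise stability workflows. Groups with fewer than 3
#' samples are skipped with a message (pairwise SDs would be degenerate).
#'
#' @param x a complete-case [cq_table] with group labels.
#' @param eff,base forwarded to [relative_quantities()].
#' @return named list of `genorm_result`, one per group analysed.
#' @export
genorm_by_group <- function(x, eff = NULL, base = 2) {
  stopifnot(inherits(x, "cq_table"))
  if (is.null(x$groups)) stop("per-group analysis requires group labels")
  out <- list()
  for (g in unique(x$groups)) {
    keep <- x$groups == g
    if (sum(keep) < 3) {
      message("genorm_by_group: skipping group `", g, "` (", sum(keep),
              " samples < 3)")
      next
    }
    sub <- cq_table(x$cq[, keep, drop = FALSE], samples = x$samples[keep],
                    groups = x$groups[keep])
    out[[g]] <- genorm_rank(relative_quantities(sub, eff = eff, base = base))
  }
  out
}
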