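#' Aggregate the three algorithms' rankings
#'
#' Combines geNorm, NormFinder and BestKeeper ranks into one consensus order
#' by the geometric mean of the three per-gene ranks. Ties within an
#' algorithm carry their shared (minimum) rank into the product; ties on the
#' aggregate score are broken by the better geNorm rank, then by input order
#' (the geNorm result's gene order). This total order is an artifact
#' convention for summarizing agreement — the algorithms themselves remain
#' the authoritative per-method rankings.
#'
#' @param genorm a `genorm_result` (see [genorm_rank()]).
#' @param normfinder a `normfinder_result` (see [normfinder_stability()]).
#' @param bestkeeper a `bestkeeper_result` (see [bestkeeper_rank()]).
#' @return a data.frame with one row per gene in consensus order: `gene`,
#'   `genorm_rank`, `normfinder_rank`, `bestkeeper_rank`, `aggregate_score`.
#' @export
aggregate_ranks <- function(genorm, normfinder, bestkeeper) {
  stopifnot(inherits(genorm, "genorm_result"),
            inherits(normfinder, "normfinder_result"),
            inherits(bestkeeper, "bestkeeper_result"))
  genes <- names(genorm$ranking)
  sets <- list(geNorm = genes, NormFinder = names(normfinder$stability),
               BestKeeper = names(bestkeeper$rank))
  for (nm in names(sets)[-1]) {
    if (!setequal(genes, sets[[nm]])) {
      diff <- c(setdiff(genes, sets[[nm]]), setdiff(sets[[nm]], genes))
      stop("gene sets differ between geNorm and ", nm, ": ",
           paste(unique(diff), collapse = ", "))
    }
  }
  r1 <- as.numeric(genorm$ranking[genes])
  r2 <- as.numeric(normfinder$rank[genes])
  r3 <- as.numeric(bestkeeper$rank[genes])
  score <- (r1 * r2 * r3)^(1 / 3)
  ord <- order(score, r1, seq_along(genes))
  data.frame(
    gene = genes[ord],
    genorm_rank = r1[ord],
    normfinder_rank = r2[ord],
    bestkeeper_rank = r3[ord],
    aggregate_score = score[ord],
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Recommend the normalization-panel size from a V series
#'
#' Applies the V(n/n+1) rule: the panel size is the smallest n whose
#' pairwise variation is at or below the threshold (the conventional
#' suggestive cutoff is 0.15, boundary inclusive). When no V meets the
#' threshold — common for heterogeneous panels spanning many tissue types —
#' the size at the minimum V is returned with `threshold_met = FALSE` and an
#' advisory message: the cutoff is suggestive, not universal, and the lowest
#' V(n/n+1) is then the pragmatic choice.
#'
#' @param v_series named numeric vector as returned by
#'   [nf_pairwise_variation()] (names are panel sizes n).
#' @param threshold V cutoff, default 0.15.
#' @return list with `panel_size`, `v_used`, `threshold_met`.
#' @export
recommend_panel_size <- function(v_series, threshold = 0.15) {
  stopifnot(is.numeric(v_series), length(v_series) >= 1)
  ns <- as.integer(names(v_series))
  if (anyNA(ns)) stop("v_series must be named by panel sizes n")
  o <- order(ns)
  ns <- ns[o]; vs <- as.numeric(v_series)[o]
  hit <- which(vs <= threshold)
  if (length(hit)) {
    list(panel_size = ns[hit[1]], v_used = vs[hit[1]], threshold_met = TRUE)
  } else {
    best <- which.min(vs)
    message("recommend_panel_size: no V(n/n+1) <= ", threshold,
            "; the cutoff is a suggestive criterion, not a universal one - ",
            "recommending the size with the lowest V (n = ", ns[best],
            ", V = ", format(round(vs[best], 4)), ")")
    list(panel_size = ns[best], v_used = vs[best], threshold_met = FALSE)
  }
}

#' Consensus result across the three algorithms
#'
#' Combines the per-algorithm rankings (see [aggregate_ranks()]) with the
#' panel-size recommendation from the geNorm V series. The recommended panel
#' itself is the top `panel_size` genes of the geNorm stability order, since
#' the V series is defined on that order (the normalization factor adds
#' genes in geNorm rank order).
#'
#' @inheritParams aggregate_ranks
#' @param v_threshold V(n/n+1) cutoff for [recommend_panel_size()].
#' @return a `consensus_result`: list with `table` (the aggregate data.frame),
#'   `consensus_order`, `panel`, `panel_size`, `v_used`, `threshold_met`.
#' @export
consensus_rank <- function(genorm, normfinder, bestkeeper, v_threshold = 0.15) {
  tab <- aggregate_ranks(genorm, normfinder, bestkeeper)
  if (is.null(genorm$v_series))
    stop("geNorm result carries no V series; rerun genorm_rank(v_series = TRUE)")
  rec <- recommend_panel_size(genorm$v_series, threshold = v_threshold)
  structure(list(
    table = tab,
    consensus_order = tab$gene,
    panel = genorm$stability_order[seq_len(rec$panel_size)],
    panel_size = rec$panel_size,
    v_used = rec$v_used,
    threshold_met = rec$threshold_met
  ), class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus_result\n")
  df <- x$table
  df$aggregate_score <- round(df$aggregate_score, 4)
  print(df)
  cat("recommended panel (n = ", x$panel_size, ", V = ",
      sprintf("%.4f", x$v_used),
      if (!x$threshold_met) ", above threshold - advisory", "): ",
      paste(x$panel, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Run the full stability pipeline on a Cq table
#'
#' Collapses technical replicates (mean), takes the complete-case subset,
#' converts Cq to comparative-Cq relative quantities, and runs geNorm,
#' NormFinder (grouped when group labels exist) and BestKeeper, returning
#' every per-algorithm result plus the consensus.
#'
#' @param x a [cq_table].
#' @param eff optional [efficiency_set] or named base vector.
#' @param base default amplification base (2 = 100% efficiency).
#' @param v_threshold V(n/n+1) cutoff for the panel-size rule.
#' @param sd_method BestKeeper dispersion estimator, see
#'   [descriptive_stats()].
#' @param algorithms subset of `c("genorm", "normfinder", "bestkeeper")`;
#'   the consensus needs all three.
#' @param per_group also rerun geNorm within each group
#'   (see [genorm_by_group()]).
#' @return a `refstab_result` list: `genorm`, `normfinder`, `bestkeeper`,
#'   `consensus`, `per_group`, `table` (the analysed complete-case table),
#'   `quantities`.
#' @export
run_stability <- function(x, eff = NULL, base = 2, v_threshold = 0.15,
                          sd_method = c("sample_sd", "mad"),
                          algorithms = c("genorm", "normfinder", "bestkeeper"),
                          per_group = FALSE) {
  sd_method <- match.arg(sd_method)
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  stopifnot(inherits(x, "cq_table"))
  collapsed <- collapse_replicates(x)
  cc <- complete_case_subset(collapsed)
  q <- relative_quantities(cc, eff = eff, base = base)
  res <- list(table = cc, quantities = q, genorm = NULL, normfinder = NULL,
              bestkeeper = NULL, consensus = NULL, per_group = NULL)
  if ("genorm" %in% algorithms) res$genorm <- genorm_rank(q)
  if ("normfinder" %in% algorithms) res$normfinder <- normfinder_stability(q)
  if ("bestkeeper" %in% algorithms) {
    bk_base <- if (!is.null(eff)) eff else base
    res$bestkeeper <- bestkeeper(collapsed, base = bk_base, sd_method = sd_method)
  }
  if (all(c("genorm", "normfinder", "bestkeeper") %in% algorithms))
    res$consensus <- consensus_rank(res$genorm, res$normfinder, res$bestkeeper,
                                    v_threshold = v_threshold)
  if (per_group)
    res$per_group <- genorm_by_group(cc, eff = eff, base = base)
  structure(res, class = "refstab_result")
}

#' @export
print.refstab_result <- function(x, ...) {
  cat("refstab_result: ", length(x$table$genes), " genes, ",
      length(x$table$samples), " samples\n\n", sep = "")
  for (nm in c("genorm", "normfinder", "bestkeeper", "consensus"))
    if (!is.null(x[[nm]])) { print(x[[nm]]); cat("\n") }
  invisible(x)
}
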