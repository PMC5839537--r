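# Deterministic serialization of pipeline results. Scores are fixed at 4
# decimal places and Cq-scale descriptives at 2, so identical inputs yield
# byte-identical reports in every format.

round4 <- function(x) round(as.numeric(x), 4)
round2 <- function(x) round(as.numeric(x), 2)

# Small deterministic checksum (djb2 mod 2^31-1) over a canonical text
# rendering of the Cq matrix; provenance only, not cryptographic.
input_digest <- function(x) {
  txt <- paste(c(x$genes, x$samples, sprintf("%.6g", x$cq)), collapse = "|")
  h <- 5381
  for (b in utf8ToInt(txt)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

report_payload <- function(res) {
  stopifnot(inherits(res, "refstab_result"))
  payload <- list(
    package = "refstab",
    version = as.character(utils::packageVersion("refstab")),
    input = list(
      genes = res$table$genes,
      n_samples = length(res$table$samples),
      n_groups = if (is.null(res$table$groups)) 0L
                 else length(unique(res$table$groups)),
      digest = input_digest(res$table)
    )
  )
  if (!is.null(res$genorm)) {
    g <- res$genorm
    ord <- g$stability_order
    payload$genorm <- list(
      ranking = data.frame(gene = ord, m = round4(g$m_final[ord]),
                           rank = unname(g$ranking[ord]),
                           stringsAsFactors = FALSE),
      exclusion_order = g$exclusion_order,
      v_series = data.frame(n = as.integer(names(g$v_series)),
                            v = round4(g$v_series))
    )
  }
  if (!is.null(res$normfinder)) {
    nf <- res$normfinder
    ord <- order(nf$rank, seq_along(nf$rank))
    payload$normfinder <- list(
      ranking = data.frame(gene = names(nf$stability)[ord],
                           stability = round4(nf$stability[ord]),
                           rank = unname(nf$rank[ord]),
                           stringsAsFactors = FALSE),
      grouped = nf$grouped
    )
    if (nf$grouped) {
      long <- expand.grid(gene = rownames(nf$intra_var),
                          group = colnames(nf$intra_var),
                          stringsAsFactors = FALSE)
      long$intra_sd <- round4(sqrt(nf$intra_var[as.matrix(long[1:2])]))
      long$inter_dev <- round4(nf$inter_dev[as.matrix(long[1:2])])
      payload$normfinder$group_variation <- long
    }
  }
  if (!is.null(res$bestkeeper)) {
    bk <- res$bestkeeper
    st <- bk$stats
    for (col in c("geo_mean_cq", "ar_mean_cq", "min_cq", "max_cq", "sd_cq",
                  "cv_pct", "min_xfold", "max_xfold", "sd_xfold"))
      st[[col]] <- round2(st[[col]])
    payload$bestkeeper <- list(stats = st)
    if (!is.null(bk$correlations)) {
      gvi <- bk$correlations$gene_vs_index
      gvi$r <- round4(gvi$r); gvi$p <- round4(gvi$p)
      pw <- bk$correlations$pairwise
      pw$r <- round4(pw$r); pw$p <- round4(pw$p)
      payload$bestkeeper$gene_vs_index <- gvi
      payload$bestkeeper$pairwise <- pw
    }
  }
  if (!is.null(res$consensus)) {
    cs <- res$consensus
    tab <- cs$table
    tab$aggregate_score <- round4(tab$aggregate_score)
    payload$consensus <- list(
      ranking = tab, panel = cs$panel, panel_size = cs$panel_size,
      v_used = round4(cs$v_used), threshold_met = cs$threshold_met
    )
  }
  if (!is.null(res$per_group)) {
    payload$per_group <- lapply(res$per_group, function(g) list(
      ranking = data.frame(gene = g$stability_order,
                           m = round4(g$m_final[g$stability_order]),
                           rank = unname(g$ranking[g$stability_order]),
                           stringsAsFactors = FALSE),
      v_series = data.frame(n = as.integer(names(g$v_series)),
                            v = round4(g$v_series))
    ))
  }
  payload
}

df_to_tsv <- function(df) {
  paste(c(paste(names(df), collapse = "\t"),
          apply(df, 1L, function(r) paste(trimws(r), collapse = "\t"))),
        collapse = "\n")
}

df_to_md <- function(df) {
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  rule <- paste0("|", paste(rep(" --- ", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1L, function(r)
    paste0("| ", paste(trimws(r), collapse = " | "), " |"))
  paste(c(header, rule, rows), collapse = "\n")
}

#' Render a stability report
#'
#' Serializes a [run_stability()] result deterministically: stable key
#' order, scores at 4 decimal places, Cq-scale descriptives at 2. The same
#' result always renders to a byte-identical string.
#'
#' @param res a `refstab_result`.
#' @param format `"json"` (default), `"tsv"` or `"markdown"`.
#' @return a single character string (the report).
#' @export
render_report <- function(res, format = "json") {
  if (length(format) != 1 || !format %in% c("json", "tsv", "markdown"))
    stop("unknown report format: ", paste(format, collapse = ", "),
         " (expected json, tsv or markdown)")
  payload <- report_payload(res)
  if (format == "json")
    return(as.character(jsonlite::toJSON(payload, dataframe = "rows",
                                         auto_unbox = TRUE, digits = NA,
                                         pretty = TRUE)))
  sections <- character(0)
  add <- function(title, body) sections <<- c(sections,
                                              paste0(if (format == "markdown") "## " else "# ",
                                                     title), body, "")
  add("metadata", if (format == "markdown")
        paste0("refstab ", payload$version, ", input digest ",
               payload$input$digest, ", ", length(payload$input$genes),
               " genes x ", payload$input$n_samples, " samples")
      else paste0("version\t", payload$version, "\ndigest\t",
                  payload$input$digest))
  fmt <- if (format == "markdown") df_to_md else df_to_tsv
  if (!is.null(payload$genorm)) {
    add("geNorm ranking", fmt(payload$genorm$ranking))
    add("geNorm V(n/n+1)", fmt(payload$genorm$v_series))
  }
  if (!is.null(payload$normfinder))
    add("NormFinder ranking", fmt(payload$normfinder$ranking))
  if (!is.null(payload$bestkeeper))
    add("BestKeeper statistics", fmt(payload$bestkeeper$stats))
  if (!is.null(payload$consensus)) {
    add("Consensus ranking", fmt(payload$consensus$ranking))
    add("Recommended panel",
        paste0(paste(payload$consensus$panel, collapse = ", "),
               " (n = ", payload$consensus$panel_size,
               ", V = ", sprintf("%.4f", payload$consensus$v_used),
               ", threshold_met = ", payload$consensus$threshold_met, ")"))
  }
  if (!is.null(payload$per_group)) {
    for (g in names(payload$per_group))
      add(paste0("geNorm ranking [", g, "]"),
          fmt(payload$per_group[[g]]$ranking))
  }
  paste(sections, collapse = "\n")
}

#' Write a stability report to disk
#'
#' @param res a `refstab_result`.
#' @param path output file path.
#' @param format see [render_report()].
#' @return `path`, invisibly.
#' @export
write_report <- function(res, path, format = "json") {
  txt <- render_report(res, format)
  con <- file(path, open = "wb")  # binary: byte-identical across platforms
  on.exit(close(con))
  writeBin(charToRaw(txt), con)
  invisible(path)
}
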