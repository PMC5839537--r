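#' Construct a Cq table
#'
#' A `cq_table` is the single input currency of the pipeline: a genes x wells
#' matrix of quantification-cycle (Cq) values with per-well sample, group
#' (tissue), optional biological-subject and optional technical-replicate
#' labels. Before technical replicates are collapsed a sample may own several
#' wells; each (sample, replicate) pair must be unique.
#'
#' @param cq numeric matrix, one row per gene, one column per well; rownames
#'   are gene identifiers.
#' @param samples character vector of sample identifiers, one per column.
#'   Defaults to `colnames(cq)`.
#' @param groups optional character vector of group (tissue) labels per column.
#' @param subjects optional character vector of biological-subject labels per
#'   column.
#' @param replicates optional character vector of technical-replicate labels
#'   per column; when present, sample identifiers may repeat across columns.
#' @return an object of class `cq_table` with fields `cq`, `genes`, `samples`,
#'   `groups`, `subjects`, `replicates`.
#' @examples
#' m <- matrix(c(20.1, 19.8, 20.5, 20.0), nrow = 2,
#'             dimnames = list(c("ACTB", "GAPDH"), c("s1", "s2")))
#' tab <- cq_table(m, groups = c("liver", "heart"))
#' @export
cq_table <- function(cq, samples = colnames(cq), groups = NULL,
                     subjects = NULL, replicates = NULL) {
  if (!is.matrix(cq) || !is.numeric(cq))
    stop("`cq` must be a numeric matrix (genes x samples)")
  if (is.null(rownames(cq)))
    stop("`cq` must have gene identifiers as rownames")
  if (is.null(samples))
    stop("sample identifiers are required (colnames(cq) or `samples`)")
  samples <- as.character(samples)
  x <- structure(list(
    cq = cq,
    genes = rownames(cq),
    samples = samples,
    groups = if (!is.null(groups)) as.character(groups),
    subjects = if (!is.null(subjects)) as.character(subjects),
    replicates = if (!is.null(replicates)) as.character(replicates)
  ), class = "cq_table")
  colnames(x$cq) <- well_ids(x)
  validate_cq_table(x)
}

well_ids <- function(x) {
  if (is.null(x$replicates)) x$samples else paste(x$samples, x$replicates, sep = ":")
}

#' Validate a Cq table
#'
#' Checks the structural invariants: dimensions, unique gene identifiers,
#' unique (sample, replicate) pairs, metadata lengths, and that all
#' non-missing Cq are finite and positive. Cq values above 45 cycles are
#' implausible for standard qPCR programs and trigger a warning.
#'
#' @param x a `cq_table`.
#' @return `x`, invisibly unchanged, or an error.
#' @export
validate_cq_table <- function(x) {
  stopifnot(inherits(x, "cq_table"))
  k <- nrow(x$cq); n <- ncol(x$cq)
  if (anyDuplicated(x$genes))
    stop("duplicate gene identifiers: ",
         paste(unique(x$genes[duplicated(x$genes)]), collapse = ", "))
  if (length(x$samples) != n)
    stop("`samples` length (", length(x$samples), ") != number of columns (", n, ")")
  ids <- well_ids(x)
  if (anyDuplicated(ids))
    stop("duplicate (sample, replicate) identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (field in c("groups", "subjects", "replicates")) {
    v <- x[[field]]
    if (!is.null(v) && length(v) != n)
      stop("`", field, "` length (", length(v), ") != number of columns (", n, ")")
  }
  v <- x$cq[!is.na(x$cq)]
  if (any(!is.finite(v)))
    stop("non-finite Cq values present")
  if (any(v <= 0))
    stop("non-positive Cq values present (Cq must be > 0 cycles)")
  if (any(v > 45))
    warning(sum(v > 45), " Cq value(s) exceed 45 cycles (implausible)")
  x
}

#' @export
print.cq_table <- function(x, ...) {
  cat("cq_table: ", nrow(x$cq), " genes x ", ncol(x$cq), " wells",
      if (!is.null(x$replicates)) " (with technical replicates)", "\n", sep = "")
  cat("  genes:   ", paste(utils::head(x$genes, 8), collapse = ", "),
      if (length(x$genes) > 8) ", ...", "\n", sep = "")
  if (!is.null(x$groups))
    cat("  groups:  ", paste(unique(x$groups), collapse = ", "), "\n", sep = "")
  cat("  missing: ", sum(is.na(x$cq)), " of ", length(x$cq), " cells\n", sep = "")
  invisible(x)
}

# Infer field separator: explicit > extension > sniff the header line.
infer_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.tsv$|\\.tab$", path, ignore.case = TRUE)) return("\t")
  header <- readLines(path, n = 1L)
  if (!grepl(",", header) && grepl("\t", header)) "\t" else ","
}

#' Read a Cq table from CSV/TSV
#'
#' Long layout expects columns `sample_id` (or `sample`), `gene`, `cq` and
#' optionally `group`, `subject_id`, `replicate`. Wide layout expects the
#' first column to hold gene identifiers and the remaining columns one sample
#' each, with group labels supplied through a sidecar CSV (`groups_file`,
#' columns `sample_id,group`). Unparseable Cq cells become missing with a
#' warning; duplicate (gene, sample, replicate) triples are a hard error.
#' Gene and sample order is first-seen order.
#'
#' @param path path to a CSV or TSV file.
#' @param layout `"long"` or `"wide"`.
#' @param groups_file optional sidecar CSV with columns `sample_id,group`
#'   (wide layout, or to override long-layout groups).
#' @param column_map optional named character vector remapping canonical
#'   column names (`sample_id`, `gene`, `cq`, `group`, `subject_id`,
#'   `replicate`) to the names actually present in the file.
#' @param sep field separator; inferred from the extension/content if `NULL`.
#' @return a validated [cq_table].
#' @export
read_cq_table <- function(path, layout = c("long", "wide"), groups_file = NULL,
                          column_map = NULL, sep = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- infer_sep(path, sep)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           fileEncoding = "UTF-8")
  tab <- if (layout == "long") parse_long_cq(raw, path) else parse_wide_cq(raw)
  if (!is.null(groups_file)) {
    side <- utils::read.table(groups_file, header = TRUE, sep = infer_sep(groups_file),
                              colClasses = "character", stringsAsFactors = FALSE)
    names(side) <- tolower(names(side))
    if (!all(c("sample_id", "group") %in% names(side)))
      stop("groups sidecar must have columns sample_id, group")
    idx <- match(tab$samples, side$sample_id)
    if (anyNA(idx))
      stop("groups sidecar missing sample(s): ",
           paste(unique(tab$samples[is.na(idx)]), collapse = ", "))
    tab$groups <- side$group[idx]
  }
  validate_cq_table(tab)
}

canonical_names <- function(nms, column_map) {
  nms <- trimws(nms)
  out <- tolower(nms)
  out[out == "sample"] <- "sample_id"
  out[out == "subject"] <- "subject_id"
  if (!is.null(column_map)) {
    for (canon in names(column_map)) out[nms == column_map[[canon]]] <- canon
  }
  out
}

parse_cq_numeric <- function(cells, context) {
  cq <- suppressWarnings(as.numeric(cells))
  bad <- is.na(cq) & !is.na(cells) & nzchar(trimws(cells)) &
    !toupper(trimws(cells)) %in% c("NA", "NAN", "UNDETERMINED")
  if (any(bad))
    warning(sum(bad), " unparseable Cq cell(s) set to missing in ", context,
            " (e.g. \"", cells[which(bad)[1]], "\")")
  cq
}

parse_long_cq <- function(raw, path) {
  names(raw) <- canonical_names(names(raw), NULL)
  for (col in c("sample_id", "gene", "cq"))
    if (!col %in% names(raw)) stop("missing mandatory column `", col, "` in ", path)
  has_rep <- "replicate" %in% names(raw)
  triple <- paste(raw$gene, raw$sample_id,
                  if (has_rep) raw$replicate else "", sep = "\r")
  if (anyDuplicated(triple)) {
    d <- strsplit(triple[duplicated(triple)][1], "\r")[[1]]
    stop("duplicate (gene, sample", if (has_rep) ", replicate", ") entry: (",
         paste(d[nzchar(d) | seq_along(d) <= 2], collapse = ", "), ")")
  }
  cqv <- parse_cq_numeric(raw$cq, path)
  genes <- unique(raw$gene)
  wells <- unique(paste(raw$sample_id, if (has_rep) raw$replicate else "", sep = "\r"))
  wkey <- paste(raw$sample_id, if (has_rep) raw$replicate else "", sep = "\r")
  m <- matrix(NA_real_, length(genes), length(wells),
              dimnames = list(genes, NULL))
  m[cbind(match(raw$gene, genes), match(wkey, wells))] <- cqv
  first <- match(wells, wkey)  # first-seen row per well, for metadata
  parts <- strsplit(wells, "\r")
  cq_table(
    m,
    samples = vapply(parts, `[`, "", 1L),
    groups = if ("group" %in% names(raw)) raw$group[first],
    subjects = if ("subject_id" %in% names(raw)) raw$subject_id[first],
    replicates = if (has_rep) raw$replicate[first]
  )
}

parse_wide_cq <- function(raw) {
  if (ncol(raw) < 2) stop("wide layout needs a gene column plus sample columns")
  genes <- raw[[1]]
  samples <- names(raw)[-1]
  if (anyDuplicated(genes))
    stop("duplicate (gene, sample) entry: gene ", genes[duplicated(genes)][1],
         " appears twice")
  m <- sapply(seq_along(samples), function(j)
    parse_cq_numeric(raw[[j + 1]], paste0("column ", samples[j])))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(genes))
  dimnames(m) <- list(genes, samples)
  cq_table(m)
}

#' Write a Cq table to CSV
#'
#' Inverse of [read_cq_table()]: `layout = "long"` writes
#' `sample_id[,group][,subject_id][,replicate],gene,cq`; `layout = "wide"`
#' writes `gene,<sample1>,...` plus an optional group sidecar. Round-tripping
#' preserves genes, samples, Cq values, and metadata.
#'
#' @param x a [cq_table].
#' @param path output file path.
#' @param layout `"long"` or `"wide"`.
#' @param groups_file optional sidecar path for wide-layout group labels.
#' @return `path`, invisibly.
#' @export
write_cq_table <- function(x, path, layout = c("long", "wide"), groups_file = NULL) {
  layout <- match.arg(layout)
  stopifnot(inherits(x, "cq_table"))
  if (layout == "long") {
    n <- ncol(x$cq)
    df <- data.frame(
      sample_id = rep(x$samples, each = nrow(x$cq)),
      gene = rep(x$genes, times = n),
      cq = as.vector(x$cq),
      stringsAsFactors = FALSE
    )
    if (!is.null(x$groups)) df$group <- rep(x$groups, each = nrow(x$cq))
    if (!is.null(x$subjects)) df$subject_id <- rep(x$subjects, each = nrow(x$cq))
    if (!is.null(x$replicates)) df$replicate <- rep(x$replicates, each = nrow(x$cq))
    df <- df[c("sample_id", intersect(c("group", "subject_id", "replicate"), names(df)),
               "gene", "cq")]
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    if (!is.null(x$replicates))
      stop("wide layout cannot represent technical replicates; collapse first")
    df <- data.frame(gene = x$genes, x$cq, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- c("gene", x$samples)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
    if (!is.null(groups_file) && !is.null(x$groups))
      utils::write.csv(data.frame(sample_id = x$samples, group = x$groups),
                       groups_file, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Collapse technical replicates
#'
#' Reduces a replicate-level table to one Cq per (gene, sample) by the
#' arithmetic mean (default) or median of non-missing replicate Cq. A cell
#' whose replicates are all missing stays missing. Replicate spreads above
#' 0.5 cycles are flagged with a QC warning (duplicates that disagree by more
#' than half a cycle usually indicate a pipetting or threshold problem).
#' Collapsing a table without replicate labels is the identity.
#'
#' @param x a [cq_table].
#' @param method `"mean"` or `"median"`.
#' @param qc_spread spread (max - min, cycles) above which a QC warning is
#'   emitted; default 0.5.
#' @return a [cq_table] with one column per sample and no replicate labels.
#' @export
collapse_replicates <- function(x, method = c("mean", "median"), qc_spread = 0.5) {
  method <- match.arg(method)
  stopifnot(inherits(x, "cq_table"))
  if (is.null(x$replicates)) return(x)
  fun <- if (method == "mean") mean else stats::median
  samples <- unique(x$samples)
  m <- matrix(NA_real_, length(x$genes), length(samples),
              dimnames = list(x$genes, samples))
  n_wide <- 0L
  for (j in seq_along(samples)) {
    cols <- which(x$samples == samples[j])
    sub <- x$cq[, cols, drop = FALSE]
    m[, j] <- apply(sub, 1L, function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) NA_real_ else fun(v)
    })
    spread <- apply(sub, 1L, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2) 0 else max(v) - min(v)
    })
    n_wide <- n_wide + sum(spread > qc_spread)
  }
  if (n_wide > 0)
    warning(n_wide, " (gene, sample) cell(s) have replicate spread > ",
            qc_spread, " cycles")
  first <- match(samples, x$samples)
  cq_table(m, samples = samples,
           groups = if (!is.null(x$groups)) x$groups[first],
           subjects = if (!is.null(x$subjects)) x$subjects[first])
}

#' Complete-case subset of a Cq table
#'
#' Restricts the table to the requested genes and to the samples with no
#' missing Cq in any of those genes. geNorm's log-ratio matrix and the
#' NormFinder decomposition require rectangular, fully observed data
#' (listwise deletion per analysis); BestKeeper descriptives do not and use
#' all non-missing values per gene.
#'
#' @param x a [cq_table] (replicates collapsed).
#' @param genes subset of gene identifiers; default all.
#' @return a [cq_table] with the surviving samples; a message reports any
#'   dropped samples.
#' @export
complete_case_subset <- function(x, genes = NULL) {
  stopifnot(inherits(x, "cq_table"))
  if (!is.null(x$replicates))
    stop("collapse technical replicates before taking complete cases")
  if (is.null(genes)) genes <- x$genes
  missing_genes <- setdiff(genes, x$genes)
  if (length(missing_genes))
    stop("unknown gene(s): ", paste(missing_genes, collapse = ", "))
  sub <- x$cq[genes, , drop = FALSE]
  keep <- colSums(is.na(sub)) == 0L
  if (any(!keep))
    message("complete_case_subset: dropped ", sum(!keep), " sample(s): ",
            paste(x$samples[!keep], collapse = ", "))
  if (sum(keep) < 3L)
    stop("fewer than 3 complete-case samples remain (", sum(keep),
         "); downstream standard deviations would be degenerate")
  cq_table(sub[, keep, drop = FALSE],
           samples = x$samples[keep],
           groups = if (!is.null(x$groups)) x$groups[keep],
           subjects = if (!is.null(x$subjects)) x$subjects[keep])
}
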