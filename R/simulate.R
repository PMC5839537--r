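#' Simulation configuration for synthetic Cq tables
#'
#' Encodes the statistical world the stability analysis assumes: each well's
#' Cq is a gene baseline plus an optional group-specific regulation shift,
#' plus a per-sample loading effect shared by all genes (template amount,
#' RT yield), plus gene-specific technical noise — all Normal on the Cq
#' scale (multiplicative on quantities). Optionally, technical duplicates
#' add independent well noise.
#'
#' @param genes character vector of gene identifiers.
#' @param group_sizes named integer vector, group -> number of biological
#'   samples (unbalanced allowed; each >= 2).
#' @param baseline_cq named numeric vector, gene -> mean Cq (cycles).
#' @param noise_sd named numeric vector, gene -> technical noise SD (cycles,
#'   >= 0).
#' @param loading_sd shared per-sample loading SD (cycles, >= 0).
#' @param regulation optional data.frame with columns `gene, group, delta`:
#'   Cq shift (cycles) applied to that gene in that group (regulated =
#'   unstable expression).
#' @param replicate_sd optional technical-duplicate SD (cycles); when set,
#'   two replicate wells per sample are emitted.
#' @param seed integer RNG seed. Mandatory: simulations are never silently
#'   seeded.
#' @return a validated `sim_config`.
#' @export
sim_config <- function(genes, group_sizes, baseline_cq, noise_sd,
                       loading_sd = 0, regulation = NULL,
                       replicate_sd = NULL, seed) {
  if (missing(seed) || is.null(seed) || is.na(suppressWarnings(as.integer(seed))))
    stop("`seed` is mandatory and must be an integer")
  if (anyDuplicated(genes)) stop("gene identifiers must be unique")
  if (is.null(names(group_sizes)))
    stop("`group_sizes` must be named by group labels")
  if (any(group_sizes < 2)) stop("every group needs >= 2 samples")
  for (nm in c("baseline_cq", "noise_sd")) {
    v <- get(nm)
    if (!all(genes %in% names(v)))
      stop("`", nm, "` must cover every gene")
  }
  if (any(noise_sd < 0) || loading_sd < 0 ||
      (!is.null(replicate_sd) && replicate_sd < 0))
    stop("all SDs must be >= 0")
  if (any(baseline_cq <= 0)) stop("baseline Cq must be positive cycles")
  if (!is.null(regulation)) {
    stopifnot(is.data.frame(regulation),
              all(c("gene", "group", "delta") %in% names(regulation)))
    if (!all(regulation$gene %in% genes))
      stop("regulation refers to unknown gene(s)")
    if (!all(regulation$group %in% names(group_sizes)))
      stop("regulation refers to unknown group(s)")
  }
  structure(list(
    genes = as.character(genes),
    group_sizes = group_sizes,
    baseline_cq = baseline_cq[genes],
    noise_sd = noise_sd[genes],
    loading_sd = loading_sd,
    regulation = regulation,
    replicate_sd = replicate_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a Cq table with planted ground truth
#'
#' Draws `Cq_g,s = mu_g + delta_g,group(s) + L_s + eps_g,s` with
#' `L_s ~ N(0, loading_sd^2)` once per sample and
#' `eps ~ N(0, noise_sd_g^2)` per cell; with `replicate_sd` set, each sample
#' yields two wells with additional independent `N(0, replicate_sd^2)`
#' noise. Bit-for-bit reproducible for a fixed seed; the caller's RNG state
#' is left untouched.
#'
#' The truth sidecar records the realized loading effects and the planted
#' stability order: genes ascending by effective instability
#' `sqrt(noise_sd^2 + population variance of the regulation shifts over the
#' sample layout)`.
#'
#' @param config a [sim_config].
#' @return list with `table` (a [cq_table]; samples carry group and subject
#'   labels) and `truth` (a `sim_truth`: the config, `loading` per sample,
#'   `effective_sd` per gene, `stability_order`, and `regulated` flags).
#' @export
simulate_cq <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  groups_vec <- rep(names(config$group_sizes), times = config$group_sizes)
  subj <- unlist(lapply(config$group_sizes, seq_len), use.names = FALSE)
  samples <- paste0(groups_vec, "_s", subj)
  k <- length(config$genes); n <- length(samples)
  delta <- matrix(0, k, n, dimnames = list(config$genes, samples))
  if (!is.null(config$regulation)) {
    for (i in seq_len(nrow(config$regulation))) {
      r <- config$regulation[i, ]
      delta[r$gene, groups_vec == r$group] <-
        delta[r$gene, groups_vec == r$group] + r$delta
    }
  }
  out <- with_seed(config$seed, {
    loading <- stats::rnorm(n, 0, config$loading_sd)
    eps <- matrix(stats::rnorm(k * n), k, n) * config$noise_sd
    cq <- config$baseline_cq + delta +
      matrix(loading, k, n, byrow = TRUE) + eps
    if (!is.null(config$replicate_sd)) {
      well <- matrix(stats::rnorm(k * 2 * n, 0, config$replicate_sd), k, 2 * n)
      rep_idx <- rep(seq_len(n), each = 2)
      cq2 <- cq[, rep_idx, drop = FALSE] + well
      rownames(cq2) <- config$genes
      list(cq = cq2, loading = loading,
           samples = samples[rep_idx], groups = groups_vec[rep_idx],
           subjects = paste0("a", subj)[rep_idx],
           replicates = rep(c("r1", "r2"), times = n))
    } else {
      rownames(cq) <- config$genes
      list(cq = cq, loading = loading, samples = samples,
           groups = groups_vec, subjects = paste0("a", subj),
           replicates = NULL)
    }
  })
  tab <- cq_table(out$cq, samples = out$samples, groups = out$groups,
                  subjects = out$subjects, replicates = out$replicates)
  # planted instability: technical noise plus across-sample regulation spread
  reg_var <- apply(delta, 1L, function(d) mean((d - mean(d))^2))
  eff_sd <- sqrt(config$noise_sd^2 + reg_var)
  truth <- structure(list(
    config = config,
    loading = stats::setNames(out$loading, samples),
    effective_sd = eff_sd,
    regulated = stats::setNames(reg_var > 0, config$genes),
    stability_order = config$genes[order(eff_sd, seq_len(k))]
  ), class = "sim_truth")
  list(table = tab, truth = truth)
}

#' Paper-scale preset configuration
#'
#' A checked-in simulation world shaped like a multi-tissue reference-gene
#' survey in livestock: 10 candidate genes over 12 tissue groups and 54
#' usable samples (unbalanced: sex-specific and scarce tissues contribute
#' fewer animals). Baseline Cq spans ~19-26 cycles; per-gene technical noise
#' is graded so four genes (the UXT/RPS9/RPL4/RPS23 namesakes) are clearly
#' most stable and two (the B2M and RPS15 namesakes) clearly least stable,
#' with the B2M namesake additionally regulated (+1.5 cycles) in spleen,
#' liver and intestine. With loading SD 0.7 the total per-gene Cq SDs span
#' about 0.75-1.9 cycles. Gene names are synthetic namesakes of commonly
#' assayed candidates, not measured data.
#'
#' @param seed integer RNG seed passed through to the config (mandatory).
#' @return a [sim_config].
#' @export
preset_paper_like <- function(seed) {
  genes <- c("UXT", "RPS9", "RPS23", "RPL4", "EEF1A1", "ACTB", "GAPDH",
             "HMBS", "B2M", "RPS15")
  baseline <- c(UXT = 24.0, RPS9 = 19.8, RPS23 = 19.3, RPL4 = 20.9,
                EEF1A1 = 20.0, ACTB = 20.7, GAPDH = 20.4, HMBS = 25.6,
                B2M = 19.8, RPS15 = 22.8)
  noise <- c(UXT = 0.30, RPS9 = 0.27, RPS23 = 0.35, RPL4 = 0.40,
             EEF1A1 = 0.75, ACTB = 0.85, GAPDH = 0.90, HMBS = 1.00,
             B2M = 1.35, RPS15 = 1.80)
  sizes <- c(mammary_gland = 4L, kidney = 5L, spleen = 5L, liver = 5L,
             heart = 5L, intestine = 5L, ovary = 3L, lung = 5L, muscle = 5L,
             brain = 5L, subcutaneous_fat = 5L, testis = 2L)
  reg <- data.frame(gene = "B2M",
                    group = c("spleen", "liver", "intestine"),
                    delta = 1.5, stringsAsFactors = FALSE)
  sim_config(genes = genes, group_sizes = sizes, baseline_cq = baseline,
             noise_sd = noise, loading_sd = 0.7, regulation = reg,
             seed = seed)
}

#' Write a simulated dataset to disk
#'
#' Emits the long-layout Cq CSV, the group sidecar CSV, and a JSON truth
#' sidecar (planted parameters, loading effects and stability order) for
#' recovery experiments.
#'
#' @param sim result of [simulate_cq()].
#' @param dir output directory (created if needed).
#' @return character vector of the three file paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(is.list(sim), inherits(sim$table, "cq_table"),
            inherits(sim$truth, "sim_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cq_path <- file.path(dir, "cq_long.csv")
  grp_path <- file.path(dir, "groups.csv")
  truth_path <- file.path(dir, "truth.json")
  write_cq_table(sim$table, cq_path, layout = "long")
  first <- !duplicated(sim$table$samples)
  utils::write.csv(data.frame(sample_id = sim$table$samples[first],
                              group = sim$table$groups[first]),
                   grp_path, row.names = FALSE, quote = FALSE)
  cfg <- sim$truth$config
  jsonlite::write_json(list(
    seed = cfg$seed,
    genes = cfg$genes,
    group_sizes = as.list(cfg$group_sizes),
    baseline_cq = as.list(cfg$baseline_cq),
    noise_sd = as.list(cfg$noise_sd),
    loading_sd = cfg$loading_sd,
    replicate_sd = cfg$replicate_sd,
    regulation = cfg$regulation,
    loading = as.list(round(sim$truth$loading, 6)),
    effective_sd = as.list(round(sim$truth$effective_sd, 6)),
    stability_order = sim$truth$stability_order
  ), truth_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(cq_path, grp_path, truth_path))
}
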