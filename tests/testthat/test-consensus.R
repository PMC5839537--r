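# minimal hand-built algorithm results for consensus tests
fake_results <- function(genes, r1, r2, r3) {
  g <- structure(list(
    ranking = setNames(as.integer(r1), genes),
    m_final = setNames(seq_along(genes) / 10, genes),
    stability_order = genes[order(r1, seq_along(genes))],
    exclusion_order = rev(genes[order(r1)])[seq_len(length(genes) - 2)],
    v_series = c(`2` = 0.2, `3` = 0.1),
    m_trajectory = list()
  ), class = "genorm_result")
  nf <- structure(list(
    stability = setNames(r2 / 10, genes),
    rank = setNames(as.integer(r2), genes),
    grouped = FALSE, groups = NULL,
    intra_var = NULL, inter_dev = NULL
  ), class = "normfinder_result")
  bk <- structure(list(
    rank = setNames(as.integer(r3), genes),
    stability_order = genes[order(r3, seq_along(genes))],
    stats = data.frame(gene = genes, sd_cq = r3 / 4),
    correlations = NULL
  ), class = "bestkeeper_result")
  list(genorm = g, normfinder = nf, bestkeeper = bk)
}

test_that("aggregate_ranks: unanimity, hand arithmetic, sort oracle", {
  genes <- paste0("g", 1:4)
  fr <- fake_results(genes, 1:4, 1:4, 1:4)
  tab <- aggregate_ranks(fr$genorm, fr$normfinder, fr$bestkeeper)
  expect_equal(tab$gene, genes)
  expect_equal(tab$aggregate_score, 1:4)

  # ranks (1, 4, 2) -> (8)^(1/3) = 2
  fr <- fake_results(genes, c(1, 2, 3, 4), c(4, 1, 2, 3), c(2, 3, 1, 4))
  tab <- aggregate_ranks(fr$genorm, fr$normfinder, fr$bestkeeper)
  expect_equal(tab$aggregate_score[tab$gene == "g1"], 2)

  # random rankings match a brute-force sort on the triple product
  for (seed in 1:10) {
    set.seed(seed)
    genes <- paste0("g", 1:10)
    r1 <- sample(10); r2 <- sample(10); r3 <- sample(10)
    fr <- fake_results(genes, r1, r2, r3)
    tab <- aggregate_ranks(fr$genorm, fr$normfinder, fr$bestkeeper)
    expect_equal(tab$gene, genes[order((r1 * r2 * r3)^(1 / 3), r1)])
  }

  # gene-set mismatch names the symmetric difference
  fr2 <- fake_results(paste0("h", 1:10), r1, r2, r3)
  expect_error(aggregate_ranks(fr$genorm, fr2$normfinder, fr$bestkeeper),
               "h1")
})

test_that("consensus is invariant to internal gene order of the inputs", {
  genes <- paste0("g", 1:6)
  set.seed(5)
  r1 <- sample(6); r2 <- sample(6); r3 <- sample(6)
  fr <- fake_results(genes, r1, r2, r3)
  perm <- sample(6)
  fr$normfinder$rank <- fr$normfinder$rank[perm]
  fr$normfinder$stability <- fr$normfinder$stability[perm]
  fr$bestkeeper$rank <- fr$bestkeeper$rank[rev(perm)]
  tab1 <- aggregate_ranks(fr$genorm, fr$normfinder, fr$bestkeeper)
  fr0 <- fake_results(genes, r1, r2, r3)
  tab0 <- aggregate_ranks(fr0$genorm, fr0$normfinder, fr0$bestkeeper)
  expect_equal(tab1, tab0)
})

test_that("recommend_panel_size applies the inclusive V <= threshold rule", {
  # heterogeneous-panel shape: nothing under 0.15, minimum wins, advisory
  expect_message(
    rec <- recommend_panel_size(c(`2` = 0.304, `3` = 0.228, `4` = 0.26)),
    "suggestive")
  expect_equal(rec$panel_size, 3)
  expect_equal(rec$v_used, 0.228)
  expect_false(rec$threshold_met)

  # single-tissue shape: two genes suffice
  rec2 <- recommend_panel_size(c(`2` = 0.051))
  expect_equal(rec2$panel_size, 2)
  expect_true(rec2$threshold_met)

  # inclusive boundary
  rec3 <- recommend_panel_size(c(`2` = 0.15))
  expect_equal(rec3$panel_size, 2)
  expect_true(rec3$threshold_met)

  # first size under threshold wins even if a later V is lower
  rec4 <- recommend_panel_size(c(`2` = 0.2, `3` = 0.12, `4` = 0.05))
  expect_equal(rec4$panel_size, 3)
})

test_that("well-separated planted stabilities are recovered by all routes", {
  agree <- 0L
  for (seed in 1:20) {
    cq <- plant_loading_world(k = 6, n = 24,
                              noise_sd = c(rep(0.2, 3), rep(1.8, 3)),
                              loading_sd = 0.8, seed = seed + 600)
    tab <- cq_table(cq, groups = rep(c("a", "b", "c"), each = 8))
    res <- suppressMessages(run_stability(tab))
    top3 <- list(
      genorm = names(sort(res$genorm$ranking))[1:3],
      normfinder = names(sort(res$normfinder$rank))[1:3],
      bestkeeper = res$bestkeeper$stability_order[1:3],
      consensus = res$consensus$consensus_order[1:3]
    )
    agree <- agree + all(vapply(top3, setequal, TRUE, y = c("g1", "g2", "g3")))
  }
  expect_gte(agree, 19)
})

test_that("reports are deterministic and structurally faithful", {
  sim <- simulate_cq(preset_paper_like(3))
  res <- suppressMessages(run_stability(sim$table, per_group = TRUE))

  for (fmt in c("json", "tsv", "markdown")) {
    expect_identical(render_report(res, fmt), render_report(res, fmt))
  }
  expect_error(render_report(res, "xml"), "unknown report format")

  # JSON round-trip preserves values at formatting precision
  parsed <- jsonlite::fromJSON(render_report(res, "json"))
  expect_equal(parsed$genorm$ranking$m,
               unname(round(res$genorm$m_final[res$genorm$stability_order], 4)))
  expect_equal(parsed$consensus$panel_size, res$consensus$panel_size)
  expect_equal(parsed$bestkeeper$stats$sd_cq,
               round(res$bestkeeper$stats$sd_cq, 2))
  expect_equal(parsed$normfinder$ranking$gene[1],
               names(sort(res$normfinder$rank))[1])

  # markdown carries one ranking table per algorithm plus consensus
  md <- render_report(res, "markdown")
  for (h in c("## geNorm ranking", "## NormFinder ranking",
              "## BestKeeper statistics", "## Consensus ranking",
              "## Recommended panel"))
    expect_match(md, h, fixed = TRUE)
})

test_that("the CLI wires files to reports with spec exit codes", {
  out <- withr::local_tempdir()
  simdir <- file.path(out, "sim")
  code <- suppressMessages(refstab_main(
    c("simulate", "--preset", "paper-like", "--seed", "7", "--out", simdir)))
  expect_identical(code, 0L)
  expect_true(all(file.exists(file.path(simdir,
    c("cq_long.csv", "groups.csv", "truth.json")))))

  rundir <- file.path(out, "run")
  code <- suppressMessages(refstab_main(
    c("run", "--cq", file.path(simdir, "cq_long.csv"), "--layout", "long",
      "--v-threshold", "0.15", "--format", "markdown", "--out", rundir)))
  expect_identical(code, 0L)
  report <- readLines(file.path(rundir, "stability_report.md"))
  expect_true(any(grepl("Consensus ranking", report)))

  # exit code 1: input error (file unreadable)
  expect_identical(suppressMessages(refstab_main(
    c("run", "--cq", file.path(out, "nope.csv"), "--out", rundir))), 1L)
  # exit code 2: configuration errors
  expect_identical(suppressMessages(refstab_main(
    c("run", "--cq", file.path(simdir, "cq_long.csv"), "--out", rundir,
      "--format", "yaml"))), 2L)
  expect_identical(suppressMessages(refstab_main(c("frobnicate"))), 2L)
  expect_identical(suppressMessages(refstab_main(
    c("simulate", "--out", simdir))), 2L)
})
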