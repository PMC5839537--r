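test_that("pairwise_variation is the SD of log2 ratios", {
  q <- rand_q(2, 8, seed = 1)
  q <- rbind(q, copy = q[1, ])
  expect_equal(pairwise_variation(q, "g1", "copy"), 0)

  ratios <- matrix(c(1, 2, 4, 1, 1, 1), 2, 3, byrow = TRUE,
                   dimnames = list(c("a", "b"), NULL))
  expect_equal(pairwise_variation(ratios, "a", "b"), 1)

  for (seed in 1:10) {
    q <- rand_q(2, 8, seed = seed)
    v <- pairwise_variation(q, "g1", "g2")
    expect_equal(v, oracle_sd(log2(q[1, ] / q[2, ])), tolerance = 1e-12)
    expect_equal(v, pairwise_variation(q, "g2", "g1"))  # symmetry
  }

  expect_error(pairwise_variation(q, "g1", "g1"), "differ")
  q[1, 1] <- -1
  expect_error(pairwise_variation(q, "g1", "g2"), "positive")
})

test_that("m_values equals the exhaustive pairwise oracle", {
  # duplicate-gene structure: M_B = M_C = V_AB/2, M_A = V_AB
  q <- rand_q(2, 10, seed = 2, genes = c("A", "B"))
  q <- rbind(q, C = q["B", ])
  vab <- oracle_sd(log2(q["A", ] / q["B", ]))
  m <- m_values(q)
  expect_equal(unname(m["A"]), vab, tolerance = 1e-12)
  expect_equal(unname(m["B"]), vab / 2, tolerance = 1e-12)
  expect_equal(unname(m["C"]), vab / 2, tolerance = 1e-12)

  # all genes identical -> all zero
  same <- matrix(rep(rand_q(1, 6, seed = 3), each = 4), 4, 6,
                 dimnames = list(paste0("g", 1:4), NULL))
  expect_true(all(m_values(same) == 0))

  for (seed in 1:10) {
    q <- rand_q(6, 10, seed = seed + 50)
    expect_equal(m_values(q), oracle_m_values(q), tolerance = 1e-12)
  }
  expect_error(m_values(rand_q(3, 5, seed = 1), genes = "g1"), ">= 2")
})

test_that("genorm_rank: minimal k, tied final pair, ranking structure", {
  q <- rand_q(3, 8, seed = 7)
  res <- genorm_rank(q)
  expect_length(res$exclusion_order, 1)
  pair <- setdiff(rownames(q), res$exclusion_order)
  expect_equal(unname(res$ranking[pair]), c(1L, 1L))
  # final pair M equals their common pairwise variation
  expect_equal(unname(res$m_final[pair[1]]),
               pairwise_variation(q, pair[1], pair[2]), tolerance = 1e-12)
  expect_equal(unname(res$m_final[pair[1]]), unname(res$m_final[pair[2]]))
  # v_series covers n = 2..k-1
  expect_named(res$v_series, "2")
})

test_that("genorm_rank excludes a planted noisy gene first", {
  hits <- 0L
  for (seed in 1:20) {
    cq <- plant_loading_world(k = 6, n = 20,
                              noise_sd = c(2, rep(0.05, 5)),
                              loading_sd = 1, seed = seed)
    res <- genorm_rank(relative_quantities(cq_table(cq)))
    hits <- hits + (res$exclusion_order[1] == "g1")
  }
  expect_gte(hits, 19)
})

test_that("iterative ranking equals the brute-force oracle on small matrices", {
  for (seed in 1:25) {
    set.seed(seed)
    k <- sample(3:6, 1); n <- sample(4:8, 1)
    q <- rand_q(k, n, seed = seed + 1000)
    res <- genorm_rank(q)
    orc <- oracle_genorm(q)
    expect_identical(res$exclusion_order, orc$exclusion_order)
    expect_identical(res$ranking, orc$ranking)
    expect_equal(res$m_final, orc$m_final, tolerance = 1e-12)
    expect_equal(res$v_series, oracle_v_series(q, orc$stability_order),
                 tolerance = 1e-12)
  }
})

test_that("exact duplicate genes trigger the documented tie-break", {
  base <- rand_q(2, 6, seed = 4, genes = c("A", "C"))
  # two duplicate pairs: every gene's M ties at the first step
  q <- rbind(A = base["A", ], A2 = base["A", ],
             C = base["C", ], C2 = base["C", ])
  expect_message(res <- genorm_rank(q, v_series = FALSE), "tie")
  # later gene in input order (C2) goes first, then C; A/A2 survive at rank 1
  expect_equal(res$exclusion_order, c("C2", "C"))
  expect_equal(unname(res$ranking[c("A", "A2")]), c(1L, 1L))
})

test_that("nf_pairwise_variation: degenerate, hand-set, and invariance cases", {
  # identical genes -> zero series
  same <- matrix(rep(rand_q(1, 6, seed = 5), each = 4), 4, 6,
                 dimnames = list(paste0("g", 1:4), NULL))
  res <- suppressMessages(genorm_rank(same))
  expect_true(all(res$v_series == 0))

  # k=3 hand-set oracle
  q <- rand_q(3, 7, seed = 6)
  res <- genorm_rank(q)
  top <- res$stability_order
  nf2 <- sqrt(q[top[1], ] * q[top[2], ])
  nf3 <- (q[top[1], ] * q[top[2], ] * q[top[3], ])^(1 / 3)
  expect_equal(unname(res$v_series["2"]), oracle_sd(log2(nf2 / nf3)),
               tolerance = 1e-12)

  # per-sample scalar factor cancels throughout the series
  fac <- 2^seq(-1, 2, length.out = 7)
  q2 <- sweep(q, 2, fac, `*`)
  res2 <- genorm_rank(q2)
  expect_equal(res2$v_series, res$v_series, tolerance = 1e-9)
})

test_that("loading and gene-scale invariances hold to 1e-9", {
  for (seed in 1:10) {
    q <- rand_q(5, 9, seed = seed + 300)
    res <- genorm_rank(q)
    # per-sample loading (multiply each column by a constant)
    set.seed(seed)
    q_load <- sweep(q, 2, 2^rnorm(9), `*`)
    # per-gene scale (multiply each row by a constant)
    q_scale <- sweep(q, 1, 2^rnorm(5), `*`)
    for (qq in list(q_load, q_scale)) {
      res2 <- genorm_rank(qq)
      expect_equal(res2$m_final, res$m_final, tolerance = 1e-9)
      expect_equal(res2$v_series, res$v_series, tolerance = 1e-9)
      expect_identical(res2$ranking, res$ranking)
    }
    # V_jk itself
    expect_equal(pairwise_variation(q_load, "g1", "g2"),
                 pairwise_variation(q, "g1", "g2"), tolerance = 1e-9)
  }
})

test_that("raising one gene's noise never lowers its expected M", {
  sds <- c(0.2, 0.6, 1.2, 2.0)
  mean_m <- vapply(sds, function(s) {
    mean(vapply(1:20, function(seed) {
      cq <- plant_loading_world(k = 5, n = 16,
                                noise_sd = c(s, rep(0.4, 4)),
                                loading_sd = 1, seed = seed)
      m_values(relative_quantities(cq_table(cq)))[["g1"]]
    }, 0))
  }, 0)
  expect_true(all(diff(mean_m) > 0))
})

test_that("genorm_by_group reruns the ranking within each tissue", {
  sim <- simulate_cq(preset_paper_like(5))
  cc <- suppressMessages(complete_case_subset(sim$table))
  per <- suppressMessages(genorm_by_group(cc))
  # groups with >= 3 samples are analysed (testis has 2 and is skipped)
  expect_false("testis" %in% names(per))
  expect_equal(length(per), 11)
  kid <- per$kidney
  expect_s3_class(kid, "genorm_result")
  # result matches running genorm on the kidney slice directly
  keep <- cc$groups == "kidney"
  direct <- genorm_rank(relative_quantities(
    cq_table(cc$cq[, keep], samples = cc$samples[keep])))
  expect_equal(kid$m_final, direct$m_final, tolerance = 1e-12)
})
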