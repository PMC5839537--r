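# Fixture builders and independent brute-force oracles. The oracles are
# written as plain nested loops over the defining formulas, deliberately
# sharing no code with the package internals.

rand_q <- function(k, n, seed, genes = paste0("g", seq_len(k))) {
  set.seed(seed)
  m <- matrix(2^stats::rnorm(k * n, sd = 1.5), k, n,
              dimnames = list(genes, paste0("s", seq_len(n))))
  m
}

rand_cq_table <- function(k, n, seed, missing_frac = 0, groups = NULL) {
  set.seed(seed)
  m <- matrix(stats::rnorm(k * n, mean = 22, sd = 2), k, n,
              dimnames = list(paste0("g", seq_len(k)), paste0("s", seq_len(n))))
  if (missing_frac > 0) {
    idx <- which(stats::runif(k * n) < missing_frac)
    m[idx] <- NA_real_
  }
  cq_table(m, groups = groups)
}

# sample SD with explicit n-1 formula
oracle_sd <- function(v) sqrt(sum((v - mean(v))^2) / (length(v) - 1))

# geNorm M by explicit double loop
oracle_m_values <- function(q, genes = rownames(q)) {
  out <- numeric(length(genes))
  names(out) <- genes
  for (j in genes) {
    acc <- 0
    for (k in setdiff(genes, j)) {
      acc <- acc + oracle_sd(log2(q[j, ] / q[k, ]))
    }
    out[j] <- acc / (length(genes) - 1)
  }
  out
}

# full iterative exclusion recomputed from scratch each step
oracle_genorm <- function(q) {
  active <- rownames(q)
  excl <- character(0)
  m_final <- stats::setNames(numeric(length(active)), active)
  while (length(active) > 2) {
    m <- oracle_m_values(q, active)
    worst_idx <- which(m == max(m))
    drop <- active[worst_idx[length(worst_idx)]]  # later in input order on ties
    m_final[drop] <- max(m)
    excl <- c(excl, drop)
    active <- setdiff(active, drop)
  }
  m_final[active] <- oracle_m_values(q, active)
  rk <- stats::setNames(integer(length(m_final)), names(m_final))
  rk[active] <- 1L
  rk[rev(excl)] <- seq_along(excl) + 1L
  list(m_final = m_final, exclusion_order = excl, ranking = rk,
       stability_order = c(active, rev(excl)))
}

# V(n/n+1) by explicit geometric means
oracle_v_series <- function(q, stability_order) {
  k <- length(stability_order)
  v <- stats::setNames(numeric(k - 2), as.character(2:(k - 1)))
  for (n in 2:(k - 1)) {
    nf_n <- apply(q[stability_order[1:n], , drop = FALSE], 2,
                  function(col) prod(col)^(1 / n))
    nf_n1 <- apply(q[stability_order[1:(n + 1)], , drop = FALSE], 2,
                   function(col) prod(col)^(1 / (n + 1)))
    v[as.character(n)] <- oracle_sd(log2(nf_n / nf_n1))
  }
  v
}

# simulate the loading + gene-noise world directly (independent of sim_config)
plant_loading_world <- function(k, n, noise_sd, loading_sd = 1, seed = 1,
                                baseline = rep(22, k)) {
  set.seed(seed)
  loading <- stats::rnorm(n, 0, loading_sd)
  cq <- outer(baseline, loading, `+`) +
    matrix(stats::rnorm(k * n), k, n) * noise_sd
  dimnames(cq) <- list(paste0("g", seq_len(k)), paste0("s", seq_len(n)))
  cq
}
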