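make_counts <- function(mu, n_per_group, seed, dispersion = 0.1) {
  set.seed(seed)
  G <- nrow(mu)
  cnt <- matrix(stats::rnbinom(G * 2 * n_per_group, size = 1 / dispersion, mu = mu),
                G, 2 * n_per_group,
                dimnames = list(rownames(mu), sprintf("S%02d", 1:(2 * n_per_group))))
  expression_matrix(cnt, "counts")
}

test_that("a strong planted gene passes the quadruple filter and tops the ranking", {
  mu <- matrix(100, 50, 12, dimnames = list(sprintf("G%02d", 1:50), NULL))
  mu[1, 7:12] <- 20         # 5-fold drop in group B
  ex <- make_counts(mu[, 1:12, drop = FALSE], 6, seed = 2, dispersion = 0.05)
  de <- differential_expression(ex, rep(c("A", "B"), each = 6))
  expect_identical(de$gene[which.min(de$p_value)], "G01")
  expect_gte(abs(de$log2_fc[de$gene == "G01"]), 1)
  expect_error(differential_expression(ex, rep(c("A", "B", "C"), each = 4)), "two groups")
  expect_error(differential_expression(ex, c("A", rep("B", 11))), ">= 2 samples")
})

test_that("a group facing a permuted copy of itself passes zero genes", {
  # group B holds the same samples as group A in shuffled order, so the
  # two group multisets are identical per gene and nothing can pass the
  # stringent quadruple filter
  set.seed(10)
  mu <- matrix(2^runif(300 * 10, 5, 9), 300, 10,
               dimnames = list(sprintf("G%03d", 1:300), NULL))
  a <- matrix(rnbinom(length(mu), size = 1 / 0.3, mu = mu), 300, 10)
  set.seed(42)
  for (rep in 1:20) {
    b <- a[, sample(10)]
    cnt <- cbind(a, b)
    dimnames(cnt) <- list(sprintf("G%03d", 1:300), sprintf("S%02d", 1:20))
    de <- differential_expression(expression_matrix(cnt, "counts"),
                                  rep(c("A", "B"), each = 10))
    expect_identical(sum(de$pass), 0L)
  }
})

test_that("planted 4-fold genes are recovered with controlled false discoveries", {
  set.seed(3)
  G <- 2000
  base <- 2^stats::runif(G, 5, 10)
  mu <- matrix(base, G, 20, dimnames = list(sprintf("G%04d", 1:G), NULL))
  mu[1:50, 11:20] <- mu[1:50, 11:20] * 4
  ex <- make_counts(mu, 10, seed = 3, dispersion = 0.1)
  de <- differential_expression(ex, rep(c("B", "A"), each = 10))
  sens <- mean(de$pass[match(sprintf("G%04d", 1:50), de$gene)])
  fdp <- sum(de$pass[-(1:50)]) / max(sum(de$pass), 1)
  expect_gte(sens, 0.8)
  expect_lte(fdp, 0.1)
})

test_that("hypergeometric ORA matches the exact summation oracle", {
  # universe 54, set 13, query 20, overlap 10
  universe <- sprintf("U%02d", 1:54)
  set_genes <- universe[1:13]
  query <- c(universe[1:10], universe[14:23])
  sigs <- signature_collection(list(S = set_genes), "t")
  res <- ora_hypergeometric(query, sigs, universe, min_overlap = 3)
  p_oracle <- sum(vapply(10:13, oracle_table_prob, 0, r1 = 13, r2 = 41, c1 = 20))
  expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
  expect_equal(round(res$p_value, 4), 0.0011)
  expect_identical(res$overlap, 10L)

  # query = universe forces p = 1 for every set
  res_all <- ora_hypergeometric(universe, sigs, universe)
  expect_equal(res_all$p_value, 1)

  # sets under the overlap floor are excluded before testing
  res_min <- ora_hypergeometric(query, sigs, universe, min_overlap = 11)
  expect_identical(nrow(res_min), 0L)
  expect_error(ora_hypergeometric(c(query, "ELSEWHERE"), sigs, universe), "universe")
})

test_that("ORA p-values decrease as the overlap grows at fixed margins", {
  universe <- sprintf("U%02d", 1:60)
  sigs <- signature_collection(list(S = universe[1:15]), "t")
  ps <- vapply(5:15, function(ov) {
    query <- c(universe[1:ov], universe[16:(16 + 20 - ov - 1)])
    ora_hypergeometric(query, sigs, universe, min_overlap = 1)$p_value
  }, 0)
  expect_true(all(diff(ps) < 0))
})

test_that("GSEA hits its limit cases and flips sign with the ranking", {
  scores <- stats::setNames(c(rep(10, 10), stats::runif(990)), sprintf("G%04d", 1:1000))
  sigs <- signature_collection(list(top = sprintf("G%04d", 1:10)), "t")
  res <- gsea_preranked(scores, sigs, n_perm = 200, seed = 1)
  expect_gt(res$es, 0.9)
  expect_lte(res$es, 1)
  neg <- gsea_preranked(-scores, sigs, n_perm = 200, seed = 1)
  expect_equal(neg$es, -res$es, tolerance = 1e-12)
  expect_error(gsea_preranked(scores, sigs, n_perm = 50, seed = 1), "100")
})

test_that("GSEA empirical p matches exhaustive enumeration on a 10-gene ranking", {
  set.seed(6)
  scores <- stats::setNames(sort(stats::rnorm(10), decreasing = TRUE),
                            paste0("G", 1:10))
  sigs <- signature_collection(list(S = c("G1", "G2", "G5")), "t")
  res <- gsea_preranked(scores, sigs, n_perm = 200, seed = 9)
  expect_equal(res$n_perm, choose(10, 3))   # exhaustive branch taken
  combs <- utils::combn(10, 3)
  es_null <- apply(combs, 2, function(idx) oracle_gsea_es(scores, idx))
  es_obs <- oracle_gsea_es(scores, c(1, 2, 5))
  expect_equal(res$es, es_obs, tolerance = 1e-12)
  same <- es_null[sign(es_null) == sign(es_obs) | es_null == 0]
  p_exact <- mean(abs(same) >= abs(es_obs))
  expect_lte(abs(res$p_value - p_exact), 1 / length(same) + 1e-12)
})

test_that("GSEA p-values are uniform under a random ranking", {
  set.seed(99)
  scores <- stats::setNames(stats::rnorm(500), paste0("G", 1:500))
  sets <- stats::setNames(lapply(1:200, function(i) paste0("G", sample(500, 15))),
                          paste0("R", 1:200))
  res <- gsea_preranked(scores, signature_collection(sets, "null"),
                        n_perm = 400, seed = 5)
  expect_true(all(res$es >= -1 & res$es <= 1))
  ks <- suppressWarnings(stats::ks.test(res$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
  # BH q-values are monotone in the sorted p-values and bounded by 1
  o <- order(res$p_value)
  expect_true(all(diff(res$fdr[o]) >= -1e-12))
  expect_true(all(res$fdr >= 0 & res$fdr <= 1))
})
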