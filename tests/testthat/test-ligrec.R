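toy_expr <- function(values, platform = "counts", probe_map = NULL) {
  expression_matrix(values, platform, probe_map)
}

test_that("pair correlation is Spearman on genes and probe-max on probes", {
  x <- c(1, 4, 9, 16, 25, 36)
  m <- rbind(LIGA = x, RECA = x^3, OTHER = c(3, 1, 4, 1, 5, 9))
  colnames(m) <- paste0("S", 1:6)
  db <- lr_database("LIGA", "RECA")
  res <- pair_correlation(toy_expr(m), db)
  expect_equal(res$rho, 1)           # monotone transform of the same vector

  # absent gene is reported missing, never zero
  res2 <- pair_correlation(toy_expr(m), lr_database("LIGA", "NOPE"))
  expect_true(is.na(res2$rho))

  expect_error(pair_correlation(toy_expr(m[, 1:4]), db), "5 samples")
})

test_that("probe-max equals brute-force max over probe combinations", {
  set.seed(4)
  m <- matrix(rnorm(32, 8), 4, 8,
              dimnames = list(c("L_p1", "L_p2", "R_p1", "R_p2"), paste0("S", 1:8)))
  pm <- data.frame(probe = rownames(m), gene = c("LG", "LG", "RG", "RG"))
  ex <- toy_expr(m, "intensity", pm)
  res <- pair_correlation(ex, lr_database("LG", "RG"))
  brute <- max(vapply(1:2, function(i) {
    vapply(3:4, function(j) oracle_spearman(m[i, ], m[j, ]), 0)
  }, numeric(2)))
  expect_equal(res$rho, brute, tolerance = 1e-12)

  # one probe per gene degenerates to plain gene-level Spearman
  pm1 <- data.frame(probe = c("L_p1", "R_p1"), gene = c("LG", "RG"))
  ex1 <- toy_expr(m[c(1, 3), ], "intensity", pm1)
  res1 <- pair_correlation(ex1, lr_database("LG", "RG"))
  expect_equal(res1$rho, oracle_spearman(m[1, ], m[3, ]), tolerance = 1e-12)

  # intensity without a probe map is refused
  expect_error(pair_correlation(toy_expr(m, "intensity"), lr_database("LG", "RG")),
               "probe map")
})

test_that("correlation is invariant under strictly monotone transforms", {
  set.seed(11)
  m <- matrix(rexp(20, 0.1), 2, 10,
              dimnames = list(c("LA", "RA"), paste0("S", 1:10)))
  db <- lr_database("LA", "RA")
  base <- pair_correlation(toy_expr(m), db)$rho
  m2 <- m; m2["LA", ] <- m2["LA", ]^3
  expect_equal(pair_correlation(toy_expr(m2), db)$rho, base, tolerance = 1e-12)
})

test_that("confident selection uses a closed threshold and tolerates noise", {
  df <- data.frame(ligand = c("A", "B", "C"), receptor = c("X", "Y", "Z"),
                   rho = c(0.5, 0.49999, NA))
  sel <- select_confident(df, 0.5)
  expect_identical(sel$ligand, "A")       # rho exactly tau is included
  expect_error(select_confident(df, 1.2), "tau")

  set.seed(3)
  noisy <- data.frame(ligand = paste0("L", 1:50), receptor = paste0("R", 1:50),
                      rho = stats::runif(50, -0.4, 0.6))
  expect_lte(nrow(select_confident(noisy, 0.999)), 1L)
})

test_that("planted pairs are recovered and background pairs are not", {
  sens <- bg_fp <- numeric(10)
  for (s in 1:10) {
    co <- generate_cohort(cohort_config(seed = s))
    rho <- pair_correlation(co$expr, co$lr_db)
    sel <- select_confident(rho, 0.5)
    keys <- pair_key(sel$ligand, sel$receptor)
    planted <- pair_key(co$truth$planted_pairs$ligand, co$truth$planted_pairs$receptor)
    bg <- pair_key(co$truth$background_pairs$ligand, co$truth$background_pairs$receptor)
    sens[s] <- mean(planted %in% keys)
    bg_fp[s] <- mean(bg %in% keys)
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(bg_fp), 0.1)
})

test_that("consensus intersects, removes background, and logs the funnel", {
  a <- data.frame(ligand = paste0("L", 1:12), receptor = paste0("R", 1:12))
  b <- a
  bg <- a[1:4, ]
  res <- consensus_and_filter(a, b, bg)
  expect_identical(unname(res$funnel),
                   c(12L, 12L, 12L, 4L, 8L))
  expect_identical(nrow(res$retained), 8L)

  ident <- consensus_and_filter(a, a, NULL)
  expect_identical(ident$retained$ligand, a$ligand)
  disj <- consensus_and_filter(a[1:6, ], a[7:12, ], NULL)
  expect_identical(nrow(disj$retained), 0L)
  # funnel monotonicity
  expect_lte(res$funnel[["n_retained"]], res$funnel[["n_consensus"]])
  expect_lte(res$funnel[["n_consensus"]],
             min(res$funnel[["n_a"]], res$funnel[["n_b"]]))
})

test_that("L-R score follows the regularized geometric mean", {
  # matrix engineered so the global mean of the normalized values is 2
  m <- rbind(LIG = c(0, 2, 8), REC = c(0, 2, 2), PAD = c(0, 2, 2))
  colnames(m) <- paste0("S", 1:3)
  ex <- toy_expr(m, "intensity")
  expect_equal(mean(m), 2)
  s <- lr_score(ex, "LIG", "REC")
  expect_equal(unname(s[1]), 0)                    # L = R = 0
  expect_equal(unname(s[2]), 0.5)                  # sqrt(L R) = mu
  expect_true(all(s >= 0 & s < 1))
  expect_error(lr_score(ex, "LIG", "NOPE"), "NOPE")

  # monotone in the ligand at fixed receptor and fixed matrix mean: the
  # padding row compensates so mu stays at 11 across the grid
  grid <- seq(0, 50, by = 2.5)
  svals <- vapply(grid, function(L) {
    mm <- rbind(LIG = c(L, 4), REC = c(4, 4), PAD = c((54 - L) / 2, (54 - L) / 2))
    colnames(mm) <- c("A", "B")
    unname(lr_score(toy_expr(mm, "intensity"), "LIG", "REC")["A"])
  }, 0)
  expect_true(all(diff(svals) > 0))
})

test_that("L-R scores are scale- and sample-permutation-invariant", {
  set.seed(9)
  m <- matrix(rexp(30, 0.2), 3, 10,
              dimnames = list(c("LA", "RA", "PAD"), paste0("S", 1:10)))
  ex <- toy_expr(m, "intensity")
  base <- lr_score(ex, "LA", "RA")
  scaled <- lr_score(toy_expr(3.7 * m, "intensity"), "LA", "RA")
  expect_equal(scaled, base, tolerance = 1e-12)
  perm <- sample(10)
  permuted <- lr_score(toy_expr(m[, perm], "intensity"), "LA", "RA")
  expect_equal(permuted, base[perm], tolerance = 1e-12)
})

test_that("infiltration screen flags driven pairs and skips degenerate ones", {
  set.seed(2)
  infil <- stats::runif(20, -2, 2)
  scores <- rbind(driven = (infil - min(infil)) / (max(infil) - min(infil)) * 0.8,
                  flat = rep(0.4, 20),
                  noise = stats::runif(20))
  colnames(scores) <- paste0("S", 1:20)
  res <- infiltration_screen(scores, infil)
  expect_equal(res$rho[res$pair == "driven"], 1)
  expect_true(res$flagged[res$pair == "driven"])
  expect_true(is.na(res$rho[res$pair == "flat"]))
  expect_false(res$flagged[res$pair == "flat"])
})

test_that("screen recovers infiltration-driven pairs on a planted cohort", {
  co <- generate_cohort(cohort_config(seed = 1))
  sc <- score_signatures(zscore_matrix(co$expr), co$signatures)
  infil <- infiltration_score(sc, synthetic_immune_signatures())
  pairs <- rbind(co$truth$planted_pairs, co$truth$background_pairs)
  sm <- lr_score_matrix(co$expr, pairs)
  res <- infiltration_screen(sm, infil)
  n_planted <- nrow(co$truth$planted_pairs)
  expect_gte(mean(res$flagged[seq_len(n_planted)]), 0.8)
  expect_lte(mean(res$flagged[-seq_len(n_planted)]), 0.1)
})
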