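# Shared clean fixture: fully informative bin genotypes (hets left in place
# are handled by the coding/prior rules).
scan_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_bin_population(2, 15, 160, 60, seed = 50)
    cache
  }
})

test_that("stepwise selection finds an exact marker signal", {
  d <- scan_fixture()
  X <- rilmap:::code_genotypes(d$binset$geno)
  y <- X[, 7]
  sel <- stepwise_select(X, y, pin = 0.001)
  expect_true(7 %in% sel$index)
  fit <- lm(y ~ X[, sel$index])
  expect_gt(suppressWarnings(summary(fit)$r.squared), 1 - 1e-9)
  expect_error(stepwise_select(X, rep(1, nrow(X))), "variance")
})

test_that("stepwise selection stays near-empty under the null", {
  d <- make_bin_population(2, 100, 175, 80, seed = 51)
  X <- rilmap:::code_genotypes(d$binset$geno)
  set.seed(52)
  counts <- vapply(1:5, function(i)
    length(stepwise_select(X, rnorm(175), pin = 0.001)$index), numeric(1))
  expect_true(all(counts <= 2))
})

test_that("phenotype adjustment subtracts non-released cofactors only", {
  X <- cbind(c(1, -1, 1, -1, 0), c(1, 1, -1, -1, 1))
  y <- c(3, 1, 2, 0, 1.5)
  cof <- list(index = 1:2, coef = c(0.5, -0.25))
  expect_equal(as.vector(adjust_phenotype(y, cof, X)),
               y - 0.5 * X[, 1] + 0.25 * X[, 2])
  expect_equal(as.vector(adjust_phenotype(y, cof, X, released = 1:2)), y)
  one <- list(index = 2L, coef = -0.25)
  expect_equal(as.vector(adjust_phenotype(y, one, X, released = 2L)), y)
  expect_equal(as.vector(adjust_phenotype(y, one, X)), y + 0.25 * X[, 2])
  none <- list(index = integer(0), coef = numeric(0))
  expect_identical(adjust_phenotype(y, none, X), y)
})

test_that("marker-coincident scan positions reproduce single-marker regression LOD", {
  d <- scan_fixture()
  keep <- apply(d$binset$geno != 2L, 1, all)     # no residual hets
  bs <- d$binset
  bs$geno <- bs$geno[keep, , drop = FALSE]
  bs$line_ids <- bs$line_ids[keep]
  map <- build_map(bs)
  set.seed(53)
  n <- nrow(bs$geno)
  y <- rnorm(n) + 0.8 * rilmap:::code_genotypes(bs$geno)[, 4]
  prof <- interval_scan(map, bs, y, scan_params(step_cM = 1))
  for (gn in names(map$groups)) {
    g <- map$groups[[gn]]
    for (k in seq_len(nrow(g))) {
      x <- rilmap:::code_genotypes(bs$geno)[, match(g$marker[k], bs$bins$id)]
      rss1 <- sum(lm.fit(cbind(1, x), y)$residuals^2)
      rss0 <- sum((y - mean(y))^2)
      lod_reg <- n / 2 * log10(rss0 / rss1)
      lod_scan <- prof$lod[prof$lg == gn &
                             abs(prof$pos_cM - g$pos_cM[k]) < 1e-9]
      expect_equal(lod_scan, lod_reg, tolerance = 1e-6)
    }
  }
})

test_that("a noise-free marker phenotype gives an overwhelming peak at the marker", {
  d <- scan_fixture()
  bs <- d$binset
  keep <- apply(bs$geno != 2L, 1, all)
  bs$geno <- bs$geno[keep, , drop = FALSE]
  bs$line_ids <- bs$line_ids[keep]
  map <- build_map(bs)
  y <- rilmap:::code_genotypes(bs$geno)[, 5]
  prof <- interval_scan(map, bs, y, scan_params(step_cM = 0.5))
  target <- map$groups[["1"]]
  pos5 <- target$pos_cM[match(bs$bins$id[5], target$marker)]
  peak <- prof[which.max(prof$lod), ]
  expect_gte(peak$lod, 10)
  expect_equal(peak$lg, "1")
  expect_lte(abs(peak$pos_cM - pos5), 0.5)
})

test_that("LOD is invariant to phenotype location/scale; the effect scales", {
  d <- scan_fixture()
  map <- build_map(d$binset)
  set.seed(54)
  y <- rnorm(160) + 0.6 * rilmap:::code_genotypes(d$binset$geno)[, 9]
  p1 <- interval_scan(map, d$binset, y, scan_params(step_cM = 2))
  p2 <- interval_scan(map, d$binset, 5 + 3 * y, scan_params(step_cM = 2))
  expect_equal(p2$lod, p1$lod, tolerance = 1e-6)
  expect_equal(p2$additive, 3 * p1$additive, tolerance = 1e-3)
  expect_true(all(p1$lod >= 0))
})

test_that("permutation thresholds are deterministic order statistics", {
  d <- scan_fixture()
  map <- build_map(d$binset)
  set.seed(55)
  y <- rnorm(160)
  sp <- scan_params(step_cM = 2, n_permutations = 40, seed = 99)
  t1 <- permutation_threshold(map, d$binset, y, sp)
  t2 <- permutation_threshold(map, d$binset, y, sp)
  expect_identical(as.numeric(t1), as.numeric(t2))
  maxima <- attr(t1, "max_lods")
  expect_equal(as.numeric(t1), sort(maxima)[ceiling(0.95 * 40)])
  sp_all <- scan_params(step_cM = 2, n_permutations = 40, alpha = 1, seed = 99)
  t_all <- permutation_threshold(map, d$binset, y, sp_all)
  expect_equal(as.numeric(t_all), min(maxima))
  expect_equal(attr(t2, "max_lods"), maxima)
})

test_that("QTL calling handles empty and multi-QTL profiles", {
  d <- make_bin_population(
    2, 15, 175, 60, seed = 56,
    qtl_specs = list(qtl_spec(1, 30, target_pve = 30, trait = "R"),
                     qtl_spec(2, 30, target_pve = 30, trait = "R")))
  ph <- simulate_phenotypes(d$pop)
  map <- build_map(d$binset)
  sp <- scan_params(step_cM = 0.5, n_permutations = 60, seed = 57)
  sc <- icim_scan(map, d$binset, ph[["R"]], sp, trait = "R")
  expect_setequal(unique(sc$qtl$lg), c("1", "2"))
  # flanking markers bracket each peak
  for (i in seq_len(nrow(sc$qtl))) {
    g <- map$groups[[sc$qtl$lg[i]]]
    pl <- g$pos_cM[match(sc$qtl$left_marker[i], g$marker)]
    pr <- g$pos_cM[match(sc$qtl$right_marker[i], g$marker)]
    expect_lte(pl, sc$qtl$peak_cM[i] + 1e-9)
    expect_gte(pr, sc$qtl$peak_cM[i] - 1e-9)
  }
  empty <- call_qtl(sc$profile, max(sc$profile$lod) + 1, map, d$binset)
  expect_equal(nrow(empty), 0)
})

test_that("PVE is 100 for a noise-free marker phenotype and matches targets", {
  d <- scan_fixture()
  bs <- d$binset
  keep <- apply(bs$geno != 2L, 1, all)
  bs$geno <- bs$geno[keep, , drop = FALSE]
  bs$line_ids <- bs$line_ids[keep]
  x <- rilmap:::code_genotypes(bs$geno)[, 5]
  fit <- list(mu1 = 1, mu2 = -1, p = as.numeric(x == 1))
  expect_equal(compute_pve(fit, x), 100)

  big <- make_bin_population(
    1, 3, 10000, 10, seed = 58,
    qtl_specs = list(qtl_spec(1, 5, target_pve = 50, trait = "Q")))
  ph <- simulate_phenotypes(big$pop)
  y <- ph[["Q"]]
  g <- attr(ph, "genetic_values")[, "Q"]
  p <- as.numeric(g > 0); p[g == 0] <- 0.5
  mu1 <- mean(y[g > 0]); mu2 <- mean(y[g < 0])
  expect_equal(compute_pve(list(mu1 = mu1, mu2 = mu2, p = p), y), 50,
               tolerance = 3)
  expect_error(compute_pve(fit, rep(1, sum(keep))), "variance")
})
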