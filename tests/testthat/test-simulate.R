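test_that("meiosis copies a parent at negligible length and rejects bad input", {
  h1 <- list(breaks = numeric(0), origins = 1L)
  h2 <- list(breaks = numeric(0), origins = 2L)
  set.seed(1)
  for (i in 1:50) {
    g <- simulate_meiosis(h1, h2, 1e-4)
    expect_length(g$breaks, 0)
  }
  expect_error(simulate_meiosis(h1, h2, 0), "positive")
  expect_error(simulate_meiosis(h1, h2, -5), "positive")
})

test_that("crossover count is Poisson with mean length/100", {
  h1 <- list(breaks = numeric(0), origins = 1L)
  h2 <- list(breaks = numeric(0), origins = 2L)
  set.seed(42)
  counts <- vapply(seq_len(10000), function(i)
    length(simulate_meiosis(h1, h2, 100)$breaks), numeric(1))
  se <- sqrt(1 / 10000)       # Poisson(1): var 1
  expect_lt(abs(mean(counts) - 1), 3 * se)
})

test_that("gamete from identical haplotypes is that haplotype", {
  h <- list(breaks = c(20, 60), origins = c(1L, 2L, 1L))
  set.seed(3)
  for (i in 1:20) {
    g <- simulate_meiosis(h, h, 100)
    expect_identical(g$breaks, h$breaks)
    expect_identical(g$origins, h$origins)
  }
})

test_that("F2 genotype frequencies are 1:2:1", {
  cfg <- sim_config(n_chromosomes = 1, chrom_lengths_cM = 1,
                    chrom_lengths_bp = 1e6, n_snps_per_chrom = 1,
                    n_lines = 10000, n_generations = 2, seed = 11)
  pop <- breed_ril_population(cfg)
  fr <- tabulate(pop$geno, 3) / 10000
  expect_lt(abs(fr[1] - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))
  expect_lt(abs(fr[2] - 0.50), 3 * sqrt(0.50 * 0.50 / 10000))
  expect_lt(abs(fr[3] - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))
})

test_that("heterozygosity decays to 0.5^(t-1) and aa/bb stay symmetric", {
  cfg <- sim_config(n_chromosomes = 1, chrom_lengths_cM = 50,
                    chrom_lengths_bp = 1e7, n_snps_per_chrom = 1,
                    n_lines = 3000, n_generations = 8, seed = 2)
  pop <- breed_ril_population(cfg)
  p_ab <- 0.5^7
  expect_lt(abs(mean(pop$geno == 2) - p_ab), 3 * sqrt(p_ab * (1 - p_ab) / 3000))
  n_aa <- sum(pop$geno == 1); n_bb <- sum(pop$geno == 3)
  expect_lt(abs(n_aa - n_bb) / (n_aa + n_bb),
            3 * sqrt(0.25 / (n_aa + n_bb)) * 2)
  expect_error(breed_ril_population(
    sim_config(n_chromosomes = 1, chrom_lengths_cM = 50,
               chrom_lengths_bp = 1e7, n_snps_per_chrom = 1,
               n_lines = 10, n_generations = 1)), "n_generations")
})

test_that("markers fit 1:1 segregation at nearly every locus", {
  cfg <- sim_config(n_chromosomes = 2, chrom_lengths_cM = rep(80, 2),
                    chrom_lengths_bp = rep(2e7, 2), n_snps_per_chrom = 300,
                    n_lines = 400, seed = 1)
  pop <- breed_ril_population(cfg)
  p <- segregation_chisq(colSums(pop$geno == 1), colSums(pop$geno == 3))$p
  expect_gte(mean(p >= 0.01), 0.99)
})

test_that("noise-free observation reproduces the truth exactly", {
  cfg <- sim_config(n_chromosomes = 1, chrom_lengths_cM = 60,
                    chrom_lengths_bp = 1e7, n_snps_per_chrom = 100,
                    n_lines = 40, mean_depth = 30, error_rate = 0,
                    missing_rate = 0, contaminated_line_fraction = 0, seed = 4)
  pop <- breed_ril_population(cfg)
  calls <- observe_genotypes(pop)
  expect_identical(unname(calls$geno), unname(pop$geno))
  expect_error(observe_genotypes(pop, mean_depth = -1), "non-negative")
})

test_that("missing-call fraction follows missing_rate", {
  cfg <- sim_config(n_chromosomes = 1, chrom_lengths_cM = 60,
                    chrom_lengths_bp = 1e7, n_snps_per_chrom = 200,
                    n_lines = 50, mean_depth = 30, error_rate = 0,
                    missing_rate = 0.1, contaminated_line_fraction = 0,
                    seed = 5)
  pop <- breed_ril_population(cfg)
  calls <- observe_genotypes(pop)
  n <- length(calls$geno)
  expect_lt(abs(mean(is.na(calls$geno)) - 0.1), 3 * sqrt(0.1 * 0.9 / n) + 1e-3)
})

test_that("contaminated lines exceed the 2% abnormal threshold, clean ones do not", {
  # study geometry: 11 chromosomes, 190 lines, 15 contaminated
  cfg <- sim_config(n_snps_per_chrom = 150, n_lines = 190, seed = 6)
  pop <- breed_ril_population(cfg)
  calls <- observe_genotypes(pop)
  cs <- select_aaxbb(calls)
  kept <- filter_lines(cs)
  rem <- attr(kept, "removed_lines")
  expect_equal(nrow(kept$geno), 175)
  expect_setequal(rem$line_id, pop$line_ids[attr(calls, "contaminated")])
  expect_true(all(rem$abnormal_fraction > 0.02))
})

test_that("identical config and seed reproduce identical studies", {
  cfg <- sim_config(n_chromosomes = 2, chrom_lengths_cM = rep(50, 2),
                    chrom_lengths_bp = rep(1e7, 2), n_snps_per_chrom = 50,
                    n_lines = 30, seed = 9,
                    qtl_specs = list(qtl_spec(1, 25, 30, trait = "Q")))
  a <- simulate_ril_study(cfg)
  b <- simulate_ril_study(cfg)
  expect_identical(a$truth$geno, b$truth$geno)
  expect_identical(a$calls$geno, b$calls$geno)
  expect_identical(a$phenotypes, b$phenotypes)
})

test_that("QTL drives the target share of phenotypic variance", {
  cfg <- sim_config(n_chromosomes = 1, chrom_lengths_cM = 10,
                    chrom_lengths_bp = 1e6, n_snps_per_chrom = 3,
                    n_lines = 10000, seed = 12,
                    qtl_specs = list(qtl_spec(1, 5, target_pve = 50,
                                              trait = "R")))
  pop <- breed_ril_population(cfg)
  ph <- simulate_phenotypes(pop)
  g <- attr(ph, "genetic_values")[, "R"]
  r2 <- cor(g, ph[["R"]])^2
  expect_lt(abs(r2 - 0.5), 0.03)
})

test_that("noise-free phenotypes are two-valued across homozygous lines", {
  cfg <- sim_config(n_chromosomes = 1, chrom_lengths_cM = 20,
                    chrom_lengths_bp = 1e6, n_snps_per_chrom = 3,
                    n_lines = 200, seed = 13,
                    qtl_specs = list(qtl_spec(1, 10, target_pve = 50,
                                              trait = "Q")))
  pop <- breed_ril_population(cfg)
  ph <- simulate_phenotypes(pop, noise_sd = 0)
  g <- attr(ph, "genetic_values")[, "Q"]
  hom <- g != 0
  expect_length(unique(ph[["Q"]][hom]), 2L)
  expect_error(qtl_spec(1, 10, target_pve = 0), "between")
  expect_error(qtl_spec(1, 10, target_pve = 100), "between")
})

test_that("adjacent-marker recombination recovers simulated cM gaps", {
  cfg <- sim_config(n_chromosomes = 1, chrom_lengths_cM = 45,
                    chrom_lengths_bp = 1e7, n_snps_per_chrom = 9,
                    n_lines = 500, seed = 14, snp_placement = "even")
  pop <- breed_ril_population(cfg)
  gaps <- diff(pop$markers$pos_cM)
  d_est <- vapply(seq_len(8), function(i) {
    rf <- estimate_rf(pop$geno[, i], pop$geno[, i + 1])
    100 * rf$r            # small-r map distance from the meiotic fraction
  }, numeric(1))
  expect_lt(abs(mean(d_est) - mean(gaps)) / mean(gaps), 0.2)
})
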