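test_that("only aa x bb parental patterns are retained, with recoding", {
  geno <- matrix(c(1L, 3L, 2L, 1L, 3L,
                   3L, 1L, 2L, 1L, 1L), 2, 5, byrow = TRUE)
  cs <- make_callset(p1 = c(1L, 2L, 1L, NA, 3L),
                     p2 = c(3L, 3L, 1L, 3L, 1L),
                     geno = geno)
  out <- select_aaxbb(cs)
  # kept: SNP1 (aa x bb) and SNP5 (bb x aa, flipped)
  expect_equal(out$snps$id, c("s1", "s5"))
  expect_true(all(out$snps$parent1 == 1L & out$snps$parent2 == 3L))
  # SNP5 calls re-oriented: parent-1-like becomes aa
  expect_equal(out$geno[, 2], c(4L - 3L, 4L - 1L))
  rem <- attr(out, "removed_snps")
  expect_equal(rem$n[rem$reason == "parent_missing"], 1)
  expect_equal(rem$n[rem$reason == "parent_heterozygous"], 1)
  expect_equal(rem$n[rem$reason == "parent_monomorphic"], 1)
})

test_that("depth filter is strict at the boundary", {
  geno <- matrix(1L, 2, 4)
  depth <- rbind(c(3L, 4L, 5L, 0L), rep(99L, 4))
  cs <- make_callset(p1 = rep(1L, 4), p2 = rep(3L, 4), geno = geno,
                     depth = depth)
  out <- apply_depth_filter(cs, 4)
  expect_equal(unname(is.na(out$geno[1, ])), c(TRUE, FALSE, FALSE, TRUE))
  ident <- apply_depth_filter(cs, 0)
  expect_identical(ident$geno, cs$geno)
  # a one-line call set drops SNPs that end up missing everywhere
  solo <- make_callset(p1 = rep(1L, 4), p2 = rep(3L, 4),
                       geno = matrix(1L, 1, 4),
                       depth = matrix(c(3L, 4L, 5L, 0L), 1, 4))
  expect_equal(ncol(apply_depth_filter(solo, 4)$geno), 2L)
})

test_that("window typing matches the brute-force >threshold rule", {
  # one full window; missing calls count towards neither homozygote
  type_of <- function(n_aa, n_bb, n_ab = 0L, n_na = 0L) {
    g <- rep(c(1L, 3L, 2L, NA), c(n_aa, n_bb, n_ab, n_na))
    cs <- make_callset(p1 = rep(1L, 15), p2 = rep(3L, 15),
                       geno = matrix(g, 1))
    unique(call_line_genotypes(cs)[1, ])
  }
  expect_equal(type_of(15, 0), 1L)
  expect_equal(type_of(12, 3), 1L)
  expect_equal(type_of(11, 4), 2L)
  expect_equal(type_of(3, 12), 3L)
  expect_equal(type_of(12, 0, 0, 3), 1L)   # missing neither helps nor hurts
  expect_equal(type_of(11, 0, 0, 4), 2L)
})

test_that("centre-window smoothing buffers and breakpoint resolution recover a clean switch", {
  g <- rep(c(1L, 3L), each = 15L)
  cs <- make_callset(p1 = rep(1L, 30), p2 = rep(3L, 30),
                     geno = matrix(g, 1))
  sm <- call_line_genotypes(cs)[1, ]
  # symmetric rule: an 8-SNP ab run centred on the exchange
  expect_equal(sum(sm == 2L), 8L)
  expect_equal(range(which(sm == 2L)), c(12L, 19L))
  res <- resolve_breakpoints(call_line_genotypes(cs))[1, ]
  expect_identical(unname(res), g)
  bp <- find_breakpoints(call_line_genotypes(cs))
  expect_equal(nrow(bp), 1L)
  expect_equal(bp$mid_marker, 15.5)
})

test_that("bin merging matches run enumeration", {
  sm <- matrix(1L, 3, 4)
  attr(sm, "snps") <- data.frame(chrom = 1L, pos_bp = c(10, 20, 30, 40),
                                 id = paste0("s", 1:4))
  expect_equal(nrow(merge_into_bins(sm)$bins), 1L)

  sm2 <- sm
  sm2[2, 3:4] <- 3L                      # one line switches between SNP2 and 3
  expect_equal(nrow(merge_into_bins(sm2)$bins), 2L)
  b2 <- merge_into_bins(sm2)$bins
  expect_equal(b2$start_bp, c(10, 30))
  expect_equal(b2$end_bp, c(20, 40))

  sm3 <- matrix(c(1L, 3L, 1L, 3L), 1, 4)
  attr(sm3, "snps") <- attr(sm, "snps")
  expect_equal(nrow(merge_into_bins(sm3)$bins), 4L)

  # random matrices agree with the independent oracle
  set.seed(8)
  for (i in 1:20) {
    m <- matrix(sample(c(1L, 2L, 3L), 60, TRUE), 5, 12)
    chrom <- rep(1:2, each = 6)
    attr(m, "snps") <- data.frame(chrom = chrom, pos_bp = rep(1:6 * 100, 2),
                                  id = paste0("s", 1:12))
    expect_equal(nrow(merge_into_bins(m)$bins), oracle_bin_count(m, chrom))
  }
})

test_that("re-merging bin-level vectors is a no-op", {
  set.seed(21)
  m <- matrix(sample(c(1L, 3L), 80, TRUE), 4, 20)
  attr(m, "snps") <- data.frame(chrom = 1L, pos_bp = 1:20 * 1e5,
                                id = paste0("s", 1:20))
  bins <- merge_into_bins(m)
  again <- merge_into_bins(bins$geno,
                           snps = data.frame(chrom = bins$bins$chrom,
                                             pos_bp = bins$bins$start_bp,
                                             id = bins$bins$id))
  expect_equal(nrow(again$bins), nrow(bins$bins))
  expect_identical(unname(again$geno), unname(bins$geno))
})

test_that("1:1 chi-square test matches closed forms", {
  r <- segregation_chisq(50, 50)
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)
  r2 <- segregation_chisq(120, 55)
  expect_equal(r2$chi2, 65^2 / 175)
  expect_lt(r2$p, 0.01)
  expect_error(segregation_chisq(0, 0), "zero")
})

test_that("bin filters apply the span and distortion rules", {
  bins <- data.frame(id = c("b1", "b2", "b3", "b4"),
                     chrom = 1L,
                     start_bp = c(1, 1, 1, 1),
                     end_bp = c(8000, 10001, 10000, 50000),
                     n_snps = 1L)
  geno <- matrix(rep(c(1L, 3L), 2 * 4), 4, 4)   # balanced aa/bb everywhere
  bs <- structure(list(bins = bins, geno = geno,
                       line_ids = paste0("L", 1:4)), class = "bin_set")
  out <- filter_bins(bs, genotyper_params())
  expect_setequal(out$bins$id, c("b2", "b4"))   # 10,001 bp kept, 10,000 not
  rem <- attr(out, "removed_bins")
  expect_true(all(rem$reason == "short"))

  # distorted bin: 120 aa vs 55 bb
  geno2 <- cbind(rep(c(1L, 3L), c(120, 55)), rep(c(1L, 3L), c(88, 87)))
  bs2 <- structure(list(bins = data.frame(id = c("d1", "d2"), chrom = 1L,
                                          start_bp = c(1, 1),
                                          end_bp = c(50000, 50000),
                                          n_snps = 1L),
                        geno = geno2, line_ids = paste0("L", 1:175)),
                   class = "bin_set")
  out2 <- filter_bins(bs2, genotyper_params())
  expect_equal(out2$bins$id, "d2")
  expect_equal(attr(out2, "removed_bins")$reason, "distorted")
})

test_that("line filter drops lines with scattered heterozygous calls", {
  l1 <- rep(1L, 100); l1[c(10, 40, 80)] <- 2L        # 3% scattered: dropped
  l2 <- rep(1L, 100)                                 # clean: kept
  l3 <- rep(3L, 100); l3[c(20, 70)] <- 2L            # 2% exactly: kept (strict >)
  l4 <- rep(1L, 100); l4[30:39] <- 2L                # 10% in one het tract: kept
  cs <- make_callset(p1 = rep(1L, 100), p2 = rep(3L, 100),
                     geno = rbind(l1, l2, l3, l4))
  out <- filter_lines(cs)
  expect_equal(out$line_ids, c("L02", "L03", "L04"))
  expect_equal(attr(out, "removed_lines")$line_id, "L01")
  cs_bad <- make_callset(p1 = rep(1L, 10), p2 = rep(3L, 10),
                         geno = rbind(rep(c(2L, 1L), 5), rep(c(1L, 2L), 5)))
  expect_error(filter_lines(cs_bad), "all lines")
})

test_that("smoothing corrects isolated errors at realistic depth", {
  cfg <- sim_config(n_chromosomes = 2, chrom_lengths_cM = rep(60, 2),
                    chrom_lengths_bp = rep(2e7, 2), n_snps_per_chrom = 600,
                    n_lines = 80, mean_depth = 10, error_rate = 0.01,
                    missing_rate = 0.02, contaminated_line_fraction = 0,
                    seed = 5)
  pop <- breed_ril_population(cfg)
  cs <- apply_depth_filter(select_aaxbb(observe_genotypes(pop)), 4)
  sm <- resolve_breakpoints(call_line_genotypes(cs))
  truth <- pop$geno[, match(cs$snps$id, pop$markers$id)]
  expect_gte(mean(sm == truth), 0.99)
})

test_that("genotype_bins report reconciles inputs and outputs", {
  cfg <- sim_config(n_chromosomes = 2, chrom_lengths_cM = rep(50, 2),
                    chrom_lengths_bp = rep(2e7, 2), n_snps_per_chrom = 150,
                    n_lines = 60, seed = 17)
  sim <- simulate_ril_study(cfg)
  bins <- genotype_bins(sim$calls)
  rep_ <- attr(bins, "report")
  expect_equal(rep_$n_snps_in,
               rep_$n_snps_used + sum(rep_$removed_snps$n))
  expect_equal(rep_$n_lines_in,
               rep_$n_lines_used + nrow(rep_$removed_lines))
  expect_equal(rep_$n_bins_kept,
               rep_$n_bins_raw - nrow(rep_$removed_bins))
})
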