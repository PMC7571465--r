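# Shared fixture builders. Bin-level populations skip the SNP observation
# layer: the truth genotypes at evenly spaced markers stand in for clean bin
# markers, which is the regime the ordering/scanning studies assume.

make_bin_population <- function(n_lg, bins_per_lg, n_lines, length_cM, seed,
                                n_generations = 8L, qtl_specs = list()) {
  cfg <- sim_config(n_chromosomes = n_lg,
                    chrom_lengths_cM = rep(length_cM, n_lg),
                    chrom_lengths_bp = rep(3e7, n_lg),
                    n_snps_per_chrom = bins_per_lg, n_lines = n_lines,
                    n_generations = n_generations, seed = seed,
                    snp_placement = "even", qtl_specs = qtl_specs)
  pop <- breed_ril_population(cfg)
  bins <- data.frame(id = pop$markers$id, chrom = pop$markers$chrom,
                     start_bp = pop$markers$pos_bp,
                     end_bp = pop$markers$pos_bp, n_snps = 1L)
  binset <- structure(list(bins = bins, geno = pop$geno,
                           line_ids = pop$line_ids), class = "bin_set")
  list(pop = pop, binset = binset, config = cfg)
}

# Minimal hand-built call set for genotyper unit tests.
make_callset <- function(p1, p2, geno, depth = NULL, pos_bp = NULL,
                         chrom = NULL) {
  m <- length(p1)
  n <- nrow(geno)
  if (is.null(depth)) depth <- matrix(99L, n, m)
  if (is.null(pos_bp)) pos_bp <- seq_len(m) * 1000
  if (is.null(chrom)) chrom <- rep(1L, m)
  snps <- data.frame(chrom = chrom, pos_bp = pos_bp,
                     id = sprintf("s%d", seq_len(m)),
                     parent1 = p1, parent2 = p2)
  structure(list(snps = snps, geno = geno, depth = depth,
                 line_ids = sprintf("L%02d", seq_len(n))),
            class = "snp_callset")
}

# Independent run-enumeration oracle: number of maximal runs of identical
# genotype columns, per chromosome, via string keys.
oracle_bin_count <- function(geno, chrom) {
  sum(vapply(unique(chrom), function(cc) {
    keys <- apply(geno[, chrom == cc, drop = FALSE], 2L, paste, collapse = ",")
    length(rle(keys)$lengths)
  }, numeric(1)))
}

# Independent permutation enumeration (insertion method, distinct from the
# package's lexicographic generator).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(pos) {
    left <- sub[, seq_len(pos - 1L), drop = FALSE]
    right <- if (pos <= n - 1L) sub[, pos:(n - 1L), drop = FALSE]
             else sub[, 0, drop = FALSE]
    cbind(left, n, right)
  }))
}

# SARF of an order under a recombination-fraction matrix (test-local copy).
sarf_of <- function(ord, r) sum(r[cbind(ord[-length(ord)], ord[-1L])])
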