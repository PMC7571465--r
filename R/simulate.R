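#' Simulation configuration for a single-seed-descent RIL population
#'
#' Describes an F1 -> RIL population advanced by single seed descent (SSD):
#' one selfed plant per line per generation, no selection, no mortality.
#' Generation 1 is the fully heterozygous F1, so `n_generations = 8` gives an
#' RIL8 population with expected residual heterozygosity 0.5^7 per locus.
#'
#' @param n_chromosomes number of chromosomes (the mung bean study has 11).
#' @param chrom_lengths_cM per-chromosome genetic lengths in centimorgan.
#' @param chrom_lengths_bp per-chromosome physical lengths in basepairs.
#' @param n_snps_per_chrom number of aa x bb SNPs simulated per chromosome.
#' @param n_lines number of RIL lines (190 in the study before line filtering).
#' @param n_generations SSD generation count; F1 = 1, RIL8 = 8.
#' @param mean_depth expected sequencing reads per genotype call (Poisson).
#' @param error_rate per-read miscall probability.
#' @param missing_rate probability that a call is absent independent of depth.
#' @param contaminated_line_fraction fraction of lines given inflated
#'   heterozygous-call rates (emulating the study's 15/190 "abnormal" lines).
#' @param contam_ab_rate per-call probability, in contaminated lines, that the
#'   observed call is replaced by a heterozygous call.
#' @param snp_placement `"random"` (positions drawn uniformly) or `"even"`
#'   (equally spaced along the chromosome, as for idealized bin markers).
#' @param qtl_specs list of [qtl_spec()] objects driving the phenotypes.
#' @param seed RNG seed; identical configs (including seed) reproduce
#'   byte-identical populations.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 11L,
                       chrom_lengths_cM = rep(96, n_chromosomes),
                       chrom_lengths_bp = rep(30e6, n_chromosomes),
                       n_snps_per_chrom = 300L,
                       n_lines = 190L,
                       n_generations = 8L,
                       mean_depth = 10,
                       error_rate = 0.01,
                       missing_rate = 0.02,
                       contaminated_line_fraction = 15 / 190,
                       contam_ab_rate = 0.06,
                       snp_placement = c("random", "even"),
                       qtl_specs = list(),
                       seed = 1L) {
  stopifnot_scalar(n_chromosomes, "n_chromosomes", min = 1, integer = TRUE)
  stopifnot_scalar(n_snps_per_chrom, "n_snps_per_chrom", min = 1, integer = TRUE)
  stopifnot_scalar(n_lines, "n_lines", min = 1, integer = TRUE)
  stopifnot_scalar(n_generations, "n_generations", min = 2, integer = TRUE)
  stopifnot_scalar(mean_depth, "mean_depth", min = 0)
  stopifnot_scalar(error_rate, "error_rate", min = 0, max = 1)
  stopifnot_scalar(missing_rate, "missing_rate", min = 0, max = 1)
  stopifnot_scalar(contaminated_line_fraction, "contaminated_line_fraction",
                   min = 0, max = 1)
  stopifnot_scalar(contam_ab_rate, "contam_ab_rate", min = 0, max = 1)
  if (length(chrom_lengths_cM) != n_chromosomes ||
      length(chrom_lengths_bp) != n_chromosomes)
    stop("chromosome length vectors must have one entry per chromosome")
  if (any(chrom_lengths_cM <= 0) || any(chrom_lengths_bp <= 0))
    stop("chromosome lengths must be positive")
  if (n_snps_per_chrom > min(chrom_lengths_bp))
    stop("more SNPs than basepairs on a chromosome")
  snp_placement <- match.arg(snp_placement)
  for (q in qtl_specs) {
    if (!inherits(q, "qtl_spec")) stop("qtl_specs must be a list of qtl_spec()")
    if (q$chromosome > n_chromosomes ||
        q$position_cM > chrom_lengths_cM[q$chromosome])
      stop("QTL position outside the simulated genome")
  }
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_lengths_cM = as.numeric(chrom_lengths_cM),
    chrom_lengths_bp = as.numeric(chrom_lengths_bp),
    n_snps_per_chrom = as.integer(n_snps_per_chrom),
    n_lines = as.integer(n_lines),
    n_generations = as.integer(n_generations),
    mean_depth = mean_depth,
    error_rate = error_rate,
    missing_rate = missing_rate,
    contaminated_line_fraction = contaminated_line_fraction,
    contam_ab_rate = contam_ab_rate,
    snp_placement = snp_placement,
    qtl_specs = qtl_specs,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Specification of one simulated QTL
#'
#' @param chromosome chromosome index the QTL sits on.
#' @param position_cM genetic position along that chromosome.
#' @param target_pve percent of phenotypic variance the QTL should explain,
#'   strictly between 0 and 100.
#' @param trait which phenotype the QTL drives: `"NA"` (apex count),
#'   `"R"` (lobed-area ratio) or `"Q"` (length ratio).
#' @param additive_effect phenotype units per allele substitution (+a for aa
#'   lines, -a for bb, 0 for ab).
#' @return an object of class `qtl_spec`.
#' @export
qtl_spec <- function(chromosome, position_cM, target_pve, trait = "R",
                     additive_effect = 1) {
  stopifnot_scalar(chromosome, "chromosome", min = 1, integer = TRUE)
  stopifnot_scalar(position_cM, "position_cM", min = 0)
  if (target_pve <= 0 || target_pve >= 100)
    stop("target_pve must be strictly between 0 and 100")
  trait <- match.arg(trait, c("NA", "R", "Q"))
  structure(list(chromosome = as.integer(chromosome),
                 position_cM = position_cM,
                 target_pve = target_pve,
                 trait = trait,
                 additive_effect = additive_effect),
            class = "qtl_spec")
}

## ---- haplotype mosaics -----------------------------------------------------
## A haplotype is a parental-origin mosaic along one chromosome:
## list(breaks, origins) where segment j covers (breaks[j-1], breaks[j]] in cM
## and origins[j] is 1 (parent 1) or 2 (parent 2); length(origins) =
## length(breaks) + 1 and breaks are strictly increasing.

hap_founder <- function(origin) list(breaks = numeric(0), origins = origin)

hap_origin_at <- function(hap, pos) {
  hap$origins[findInterval(pos, hap$breaks) + 1L]
}

#' Simulate one meiosis for a chromosome pair
#'
#' Crossover count is Poisson with mean `length_cM / 100` (no interference,
#' i.e. a Haldane process per meiosis); crossover positions are uniform. The
#' returned gamete is a parental-origin mosaic alternating between the two
#' input haplotypes at each crossover, starting from a randomly chosen
#' chromatid.
#'
#' @param hap1,hap2 the plant's two haplotype mosaics
#'   (`list(breaks, origins)`).
#' @param length_cM chromosome genetic length, > 0.
#' @return a haplotype mosaic.
#' @export
simulate_meiosis <- function(hap1, hap2, length_cM) {
  if (!is.numeric(length_cM) || length_cM <= 0)
    stop("chromosome length must be positive")
  n_xo <- rpois(1L, length_cM / 100)
  src <- if (runif(1) < 0.5) 1L else 2L
  if (n_xo == 0L) return(if (src == 1L) hap1 else hap2)
  xs <- sort(runif(n_xo, 0, length_cM))
  haps <- list(hap1, hap2)
  seg_start <- numeric(0)
  seg_orig <- integer(0)
  bounds <- c(0, xs, length_cM)
  for (i in seq_len(n_xo + 1L)) {
    a <- bounds[i]; b <- bounds[i + 1L]
    h <- haps[[src]]
    inner <- h$breaks[h$breaks > a & h$breaks < b]
    starts <- c(a, inner)
    seg_start <- c(seg_start, starts)
    seg_orig <- c(seg_orig, h$origins[findInterval(starts, h$breaks) + 1L])
    src <- 3L - src
  }
  keep <- c(TRUE, seg_orig[-1L] != seg_orig[-length(seg_orig)])
  list(breaks = seg_start[keep][-1L], origins = seg_orig[keep])
}

#' Breed an SSD RIL population with full ground truth
#'
#' Starts from a fully heterozygous F1 (generation 1) and advances each line
#' by selfing a single plant per generation. After `n_generations` the
#' expected per-locus heterozygosity is `0.5^(n_generations - 1)`.
#'
#' @param config a [sim_config()].
#' @return an object of class `true_population`: marker table (`markers` with
#'   chrom, pos_bp, pos_cM), `geno` (lines x markers truth matrix coded
#'   1/2/3 = aa/ab/bb), `haplotypes` (per line, per chromosome, the two
#'   parental-origin mosaics) and `line_ids`.
#' @export
breed_ril_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_generations < 2L) stop("n_generations must be at least 2")
  set.seed(config$seed)
  nc <- config$n_chromosomes
  markers <- do.call(rbind, lapply(seq_len(nc), function(cc) {
    pos_bp <- if (config$snp_placement == "even") {
      round(seq_len(config$n_snps_per_chrom) * config$chrom_lengths_bp[cc] /
              (config$n_snps_per_chrom + 1))
    } else {
      sort(sample.int(config$chrom_lengths_bp[cc], config$n_snps_per_chrom))
    }
    data.frame(chrom = cc, pos_bp = pos_bp,
               pos_cM = pos_bp / config$chrom_lengths_bp[cc] *
                 config$chrom_lengths_cM[cc])
  }))
  markers$id <- sprintf("snp_c%d_%d", markers$chrom,
                        ave(markers$chrom, markers$chrom, FUN = seq_along))
  n <- config$n_lines
  haplotypes <- vector("list", n)
  geno <- matrix(NA_integer_, n, nrow(markers))
  pos_by_chrom <- split(markers$pos_cM, markers$chrom)
  col_by_chrom <- split(seq_len(nrow(markers)), markers$chrom)
  for (li in seq_len(n)) {
    line_haps <- vector("list", nc)
    for (cc in seq_len(nc)) {
      L <- config$chrom_lengths_cM[cc]
      hA <- hap_founder(1L); hB <- hap_founder(2L)       # F1
      for (g in seq_len(config$n_generations - 1L)) {    # selfing rounds
        nA <- simulate_meiosis(hA, hB, L)
        nB <- simulate_meiosis(hA, hB, L)
        hA <- nA; hB <- nB
      }
      line_haps[[cc]] <- list(hA, hB)
      pos <- pos_by_chrom[[as.character(cc)]]
      g2 <- hap_origin_at(hA, pos) + hap_origin_at(hB, pos)
      geno[li, col_by_chrom[[as.character(cc)]]] <- g2 - 1L   # 2/3/4 -> 1/2/3
    }
    haplotypes[[li]] <- line_haps
  }
  line_ids <- sprintf("RIL%03d", seq_len(n))
  rownames(geno) <- line_ids
  colnames(geno) <- markers$id
  structure(list(markers = markers, geno = geno, haplotypes = haplotypes,
                 line_ids = line_ids, config = config),
            class = "true_population")
}

# True genotype of each line at an arbitrary genetic position (used to place
# QTL between markers).
true_genotype_at <- function(pop, chromosome, pos_cM) {
  vapply(pop$haplotypes, function(lh) {
    h <- lh[[chromosome]]
    hap_origin_at(h[[1L]], pos_cM) + hap_origin_at(h[[2L]], pos_cM) - 1L
  }, integer(1))
}

## ---- observation model -----------------------------------------------------

# Genotype-call heuristic shared by parents and progeny: depth ~ Poisson;
# a call is heterozygous only when both alleles are covered by >= 2 reads,
# otherwise it collapses to the majority-allele homozygote. This is what makes
# low-depth heterozygotes and read errors produce the "abnormal" calls the
# 2%-line filter and the depth floor exist for.
call_from_reads <- function(truth, depth, error_rate) {
  n <- length(truth)
  obs <- integer(n)
  hom <- !is.na(truth) & truth != GENO_AB
  # homozygotes: miscalled reads ~ Binomial(depth, error_rate)
  if (any(hom)) {
    d <- depth[hom]
    nerr <- rbinom(sum(hom), d, error_rate)
    minor <- pmin(nerr, d - nerr)
    call <- ifelse(minor >= 2L, GENO_AB,
                   ifelse(nerr > d - nerr, 4L - truth[hom], truth[hom]))
    obs[hom] <- call
  }
  het <- !is.na(truth) & truth == GENO_AB
  if (any(het)) {
    d <- depth[het]
    k <- rbinom(sum(het), d, 0.5)          # reads carrying the parent-1 allele
    coin <- rbinom(sum(het), 1L, 0.5)
    call <- ifelse(pmin(k, d - k) >= 2L, GENO_AB,
                   ifelse(k > d - k, GENO_AA,
                          ifelse(k < d - k, GENO_BB,
                                 ifelse(coin == 1L, GENO_AA, GENO_BB))))
    obs[het] <- call
  }
  obs[is.na(truth)] <- NA_integer_
  obs
}

#' Observe a true population through a sequencing depth/error model
#'
#' @param pop a [breed_ril_population()] result.
#' @param mean_depth,error_rate,missing_rate observation parameters (defaults
#'   from `pop$config`).
#' @param contaminated_line_fraction,contam_ab_rate contamination model: the
#'   chosen lines have each call replaced by a heterozygous call with
#'   probability `contam_ab_rate`, giving them an abnormal-call fraction well
#'   above the 2% line-filter threshold.
#' @return an object of class `snp_callset`: SNP table with observed parental
#'   calls, lines x SNP genotype (`geno`) and depth (`depth`) matrices, and
#'   the indices of contaminated lines as attribute `"contaminated"`.
#' @export
observe_genotypes <- function(pop,
                              mean_depth = pop$config$mean_depth,
                              error_rate = pop$config$error_rate,
                              missing_rate = pop$config$missing_rate,
                              contaminated_line_fraction =
                                pop$config$contaminated_line_fraction,
                              contam_ab_rate = pop$config$contam_ab_rate) {
  stopifnot(inherits(pop, "true_population"))
  if (mean_depth < 0) stop("mean_depth must be non-negative")
  if (error_rate < 0 || error_rate > 1 || missing_rate < 0 || missing_rate > 1)
    stop("rates must lie in [0, 1]")
  n <- nrow(pop$geno); m <- ncol(pop$geno)

  # parents: true homozygotes observed through the same model
  pdepth <- matrix(rpois(2L * m, mean_depth), 2L, m)
  pdepth[pdepth == 0L] <- 1L   # parents are sequenced deeply in practice
  p_truth <- rbind(rep(GENO_AA, m), rep(GENO_BB, m))
  p_obs <- rbind(call_from_reads(p_truth[1L, ], pdepth[1L, ], error_rate),
                 call_from_reads(p_truth[2L, ], pdepth[2L, ], error_rate))

  depth <- matrix(rpois(n * m, mean_depth), n, m)
  obs <- matrix(call_from_reads(as.vector(pop$geno), as.vector(depth),
                                error_rate), n, m)
  miss <- matrix(runif(n * m) < missing_rate, n, m) | depth == 0L
  obs[miss] <- NA_integer_

  n_contam <- round(contaminated_line_fraction * n)
  contaminated <- if (n_contam > 0L) sort(sample.int(n, n_contam)) else integer(0)
  if (n_contam > 0L) {
    sel <- matrix(FALSE, n, m)
    sel[contaminated, ] <- runif(n_contam * m) < contam_ab_rate
    sel[is.na(obs)] <- FALSE
    obs[sel] <- GENO_AB
  }
  dimnames(obs) <- dimnames(depth) <- list(pop$line_ids, pop$markers$id)

  snps <- pop$markers
  snps$parent1 <- p_obs[1L, ]
  snps$parent2 <- p_obs[2L, ]
  snps$parent1_depth <- pdepth[1L, ]
  snps$parent2_depth <- pdepth[2L, ]
  structure(list(snps = snps, geno = obs, depth = depth,
                 line_ids = pop$line_ids),
            class = "snp_callset",
            contaminated = contaminated)
}

#' @exportS3Method base::print
print.snp_callset <- function(x, ...) {
  cat(sprintf("snp_callset: %d lines x %d SNPs on %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$snps$chrom))))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * mean(is.na(x$geno))))
  invisible(x)
}

## ---- phenotypes ------------------------------------------------------------

#' Simulate QTL-driven phenotypes for a population
#'
#' Each trait value is `trait mean + sum of additive QTL contributions +
#' Gaussian noise`; a line contributes `+a` when it is aa at the QTL, `-a`
#' when bb, and 0 when (residually) heterozygous. The noise variance is set
#' from the realized genetic variance so that the total genetic contribution
#' matches the summed target PVE in expectation. Apex counts ("NA") are
#' rounded to non-negative integers.
#'
#' @param pop a [breed_ril_population()] result.
#' @param qtl_specs list of [qtl_spec()]; default taken from the population's
#'   config.
#' @param trait_means named baseline values for the three traits.
#' @param noise_sd optional named override of the per-trait noise standard
#'   deviation (bypasses the PVE-derived value; `0` gives noise-free traits).
#' @return a `data.frame` (class `phenotype_table`) with columns `line_id`,
#'   `NA`, `R`, `Q`, `class`; the true per-line genetic values are kept in
#'   attribute `"genetic_values"`.
#' @export
simulate_phenotypes <- function(pop, qtl_specs = pop$config$qtl_specs,
                                trait_means = c("NA" = 10, R = 70, Q = 60),
                                noise_sd = NULL) {
  stopifnot(inherits(pop, "true_population"))
  n <- length(pop$line_ids)
  traits <- c("NA", "R", "Q")
  vals <- matrix(0, n, 3L, dimnames = list(pop$line_ids, traits))
  gvals <- matrix(0, n, 3L, dimnames = list(pop$line_ids, traits))
  for (tr in traits) {
    specs <- Filter(function(q) q$trait == tr, qtl_specs)
    g <- rep(0, n)
    f_target <- 0
    for (q in specs) {
      if (q$target_pve <= 0 || q$target_pve >= 100)
        stop("target_pve must be strictly inside (0, 100)")
      geno <- true_genotype_at(pop, q$chromosome, q$position_cM)
      score <- c(1, 0, -1)[geno]              # aa = +1, ab = 0, bb = -1
      g <- g + q$additive_effect * score
      f_target <- f_target + q$target_pve / 100
    }
    gvals[, tr] <- g
    if (length(specs) > 0L && f_target >= 1)
      stop("summed target PVE for one trait must stay below 100")
    sd_override <- if (is.null(noise_sd)) NA_real_
      else if (is.null(names(noise_sd))) as.numeric(noise_sd[1L])
      else as.numeric(noise_sd[tr])
    sdv <- if (!is.na(sd_override)) {
      sd_override
    } else if (length(specs) == 0L) {
      1
    } else {
      vg <- var(g) * (n - 1) / n
      if (vg <= 0) stop("QTL genetic variance is zero; cannot set noise from PVE")
      sqrt(vg * (1 - f_target) / f_target)
    }
    vals[, tr] <- trait_means[tr] + g + rnorm(n, 0, sdv)
  }
  vals[, "NA"] <- pmax(0, round(vals[, "NA"]))
  # synthetic class labels: lobed when the lobed-area ratio drops well below
  # the unlobed parent's value, indented when the apex count is elevated
  lobed <- vals[, "R"] < trait_means["R"]
  indented <- vals[, "NA"] > trait_means["NA"]
  cls <- ifelse(lobed & indented, "mixed",
                ifelse(lobed, "lobed", ifelse(indented, "indented", "ovate")))
  out <- data.frame(line_id = pop$line_ids, check.names = FALSE)
  out[["NA"]] <- vals[, "NA"]
  out[["R"]] <- vals[, "R"]
  out[["Q"]] <- vals[, "Q"]
  out[["class"]] <- cls
  attr(out, "genetic_values") <- gvals
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Run the full simulator: population, observed calls and phenotypes
#'
#' @param config a [sim_config()].
#' @return list (class `ril_sim`) with elements `truth`, `calls`, `phenotypes`
#'   and `config`.
#' @export
simulate_ril_study <- function(config = sim_config()) {
  truth <- breed_ril_population(config)
  calls <- observe_genotypes(truth)
  phenotypes <- simulate_phenotypes(truth)
  structure(list(truth = truth, calls = calls, phenotypes = phenotypes,
                 config = config), class = "ril_sim")
}

#' @exportS3Method base::print
print.ril_sim <- function(x, ...) {
  cat(sprintf("ril_sim: %d lines, %d chromosomes, %d SNPs/chromosome, F%d\n",
              x$config$n_lines, x$config$n_chromosomes,
              x$config$n_snps_per_chrom, x$config$n_generations))
  cat(sprintf("  %d QTL spec(s); seed %d\n", length(x$config$qtl_specs),
              x$config$seed))
  invisible(x)
}
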