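#' Parameters of the sliding-window bin genotyper
#'
#' Defaults follow the resequencing-RIL workflow: a 15-SNP window typed
#' homozygous only when more than 11 of its calls agree, a read-depth floor of
#' 4, bins kept only when longer than 10 kb, segregation distortion tested at
#' P < 0.01 and lines dropped when more than 2% of their calls are abnormal
#' (heterozygous among non-missing).
#'
#' @param window_size SNPs per sliding window.
#' @param window_threshold a window is typed aa (or bb) when the aa (bb) count
#'   is strictly greater than this; otherwise ab.
#' @param min_depth calls with fewer reads are set to missing.
#' @param min_bin_length bins whose inclusive bp span is not strictly greater
#'   than this are removed.
#' @param distortion_alpha 1:1 segregation chi-square significance level below
#'   which a bin is removed as distorted.
#' @param max_abnormal_fraction lines whose abnormal-call fraction exceeds
#'   this are removed.
#' @param min_het_run heterozygous calls in runs of at least this many
#'   consecutive non-missing calls are treated as residual heterozygosity
#'   (legitimate in an RIL) rather than abnormal calls.
#' @return object of class `genotyper_params`.
#' @export
genotyper_params <- function(window_size = 15L, window_threshold = 11L,
                             min_depth = 4L, min_bin_length = 10000L,
                             distortion_alpha = 0.01,
                             max_abnormal_fraction = 0.02,
                             min_het_run = 3L) {
  stopifnot_scalar(window_size, "window_size", min = 1, integer = TRUE)
  stopifnot_scalar(window_threshold, "window_threshold", min = 0, integer = TRUE)
  if (window_threshold >= window_size)
    stop("window_threshold must be smaller than window_size")
  stopifnot_scalar(min_depth, "min_depth", min = 0, integer = TRUE)
  stopifnot_scalar(min_bin_length, "min_bin_length", min = 0)
  if (distortion_alpha <= 0 || distortion_alpha >= 1)
    stop("distortion_alpha must lie in (0, 1)")
  stopifnot_scalar(max_abnormal_fraction, "max_abnormal_fraction",
                   min = 0, max = 1)
  stopifnot_scalar(min_het_run, "min_het_run", min = 1, integer = TRUE)
  structure(list(window_size = as.integer(window_size),
                 window_threshold = as.integer(window_threshold),
                 min_depth = as.integer(min_depth),
                 min_bin_length = min_bin_length,
                 distortion_alpha = distortion_alpha,
                 max_abnormal_fraction = max_abnormal_fraction,
                 min_het_run = as.integer(min_het_run)),
            class = "genotyper_params")
}

#' Keep only SNPs with the aa x bb parental pattern
#'
#' Retains SNPs where both parents are observed homozygous for different
#' alleles and recodes progeny calls so that `aa` means "parent-1-like". SNPs
#' with a missing parent call, monomorphic parents or a heterozygous parent
#' are dropped; removal counts by reason are attached as attribute
#' `"removed_snps"`.
#'
#' @param callset a `snp_callset`.
#' @return the filtered, recoded `snp_callset`.
#' @export
select_aaxbb <- function(callset) {
  stopifnot(inherits(callset, "snp_callset"))
  p1 <- callset$snps$parent1
  p2 <- callset$snps$parent2
  miss <- is.na(p1) | is.na(p2)
  het <- !miss & (p1 == GENO_AB | p2 == GENO_AB)
  mono <- !miss & !het & p1 == p2
  keep <- !miss & !het & !mono          # homozygous and different = aa x bb
  removed <- data.frame(reason = c("parent_missing", "parent_heterozygous",
                                   "parent_monomorphic"),
                        n = c(sum(miss), sum(het), sum(mono)))
  out <- callset
  out$snps <- callset$snps[keep, , drop = FALSE]
  out$geno <- callset$geno[, keep, drop = FALSE]
  out$depth <- callset$depth[, keep, drop = FALSE]
  # re-orient SNPs where the observed parent calls are flipped relative to
  # the stored coding, so aa is always the parent-1 allele
  flip <- out$snps$parent1 == GENO_BB
  if (any(flip)) {
    out$geno[, flip] <- 4L - out$geno[, flip]
    out$snps$parent1[flip] <- GENO_AA
    out$snps$parent2[flip] <- GENO_BB
  }
  attr(out, "removed_snps") <- removed
  attr(out, "contaminated") <- attr(callset, "contaminated")
  out
}

#' Set calls below a read-depth floor to missing
#'
#' Calls with depth strictly less than `min_depth` become missing (a depth of
#' exactly `min_depth` is kept); SNPs left missing in every line are dropped.
#'
#' @param callset a `snp_callset`.
#' @param min_depth read-count floor (default 4).
#' @return filtered `snp_callset` with attribute `"removed_snps"` updated.
#' @export
apply_depth_filter <- function(callset, min_depth = 4L) {
  stopifnot(inherits(callset, "snp_callset"))
  g <- callset$geno
  g[callset$depth < min_depth] <- NA_integer_
  all_missing <- colSums(!is.na(g)) == 0L
  out <- callset
  out$geno <- g[, !all_missing, drop = FALSE]
  out$depth <- callset$depth[, !all_missing, drop = FALSE]
  out$snps <- callset$snps[!all_missing, , drop = FALSE]
  attr(out, "removed_snps") <- rbind(
    attr(callset, "removed_snps"),
    data.frame(reason = "all_calls_below_depth", n = sum(all_missing)))
  attr(out, "contaminated") <- attr(callset, "contaminated")
  out
}

#' Drop lines with an excess of abnormal (scattered heterozygous) calls
#'
#' In an RIL population from an aa x bb cross, heterozygous calls are either
#' residual heterozygosity - which survives as contiguous tracts - or noise:
#' contamination and systematic miscalling scatter isolated het calls across
#' the genome. A call is counted abnormal when it is heterozygous and not
#' part of a run of at least `min_het_run` consecutive non-missing het calls
#' on its chromosome; a line is removed when its abnormal fraction among
#' non-missing calls exceeds `max_abnormal_fraction`.
#'
#' @param callset a `snp_callset` (recoded by [select_aaxbb()]).
#' @param max_abnormal_fraction threshold fraction (default 0.02).
#' @param min_het_run run length from which het calls count as residual
#'   heterozygosity instead.
#' @return filtered `snp_callset`; removed line ids and their abnormal
#'   fractions in attribute `"removed_lines"`.
#' @export
filter_lines <- function(callset, max_abnormal_fraction = 0.02,
                         min_het_run = 3L) {
  stopifnot(inherits(callset, "snp_callset"))
  g <- callset$geno
  abn <- matrix(FALSE, nrow(g), ncol(g))
  for (cc in unique(callset$snps$chrom)) {
    cols <- which(callset$snps$chrom == cc)
    for (li in seq_len(nrow(g))) {
      obs <- cols[!is.na(g[li, cols])]
      if (length(obs) == 0L) next
      rr <- rle(g[li, obs] == GENO_AB)
      short_het <- rr$values & rr$lengths < min_het_run
      if (any(short_het)) {
        ends <- cumsum(rr$lengths)
        starts <- ends - rr$lengths + 1L
        for (k in which(short_het)) abn[li, obs[starts[k]:ends[k]]] <- TRUE
      }
    }
  }
  frac <- rowSums(abn) / pmax(1L, rowSums(!is.na(g)))
  drop <- frac > max_abnormal_fraction
  if (all(drop)) stop("all lines exceed the abnormal-call threshold")
  out <- callset
  out$geno <- g[!drop, , drop = FALSE]
  out$depth <- callset$depth[!drop, , drop = FALSE]
  out$line_ids <- callset$line_ids[!drop]
  attr(out, "removed_lines") <- data.frame(
    line_id = callset$line_ids[drop], abnormal_fraction = frac[drop])
  attr(out, "removed_snps") <- attr(callset, "removed_snps")
  attr(out, "contaminated") <- attr(callset, "contaminated")
  out
}

# Type one window from its aa and bb counts (missing calls count for
# neither): aa when the aa count is strictly above the threshold, bb
# symmetrically, otherwise ab.
window_type <- function(n_aa, n_bb, threshold = 11L) {
  ifelse(n_aa > threshold, GENO_AA,
         ifelse(n_bb > threshold, GENO_BB, GENO_AB))
}

#' Sliding-window smoothing of line genotypes
#'
#' For each line and chromosome a window of `window_size` SNPs slides one SNP
#' at a time; each window is typed aa/bb when the corresponding homozygote
#' count strictly exceeds `window_threshold`, else ab. Each SNP takes the type
#' of the window centred on it; the first and last `floor(window_size / 2)`
#' SNPs take the type of the first/last full window. Chromosomes with fewer
#' SNPs than the window are typed as a single window.
#'
#' @param callset a `snp_callset` (aa x bb recoded, depth filtered).
#' @param params a [genotyper_params()].
#' @return lines x SNPs integer matrix of smoothed genotypes (no missing
#'   values), with the SNP table attached as attribute `"snps"`.
#' @export
call_line_genotypes <- function(callset, params = genotyper_params()) {
  stopifnot(inherits(callset, "snp_callset"))
  w <- params$window_size
  thr <- params$window_threshold
  g <- callset$geno
  out <- matrix(NA_integer_, nrow(g), ncol(g), dimnames = dimnames(g))
  for (cc in unique(callset$snps$chrom)) {
    cols <- which(callset$snps$chrom == cc)
    m <- length(cols)
    if (m == 0L) { warning(sprintf("chromosome %s has no SNPs", cc)); next }
    sub <- g[, cols, drop = FALSE]
    isA <- !is.na(sub) & sub == GENO_AA
    isB <- !is.na(sub) & sub == GENO_BB
    if (m < w) {            # whole chromosome is one window
      out[, cols] <- window_type(rowSums(isA), rowSums(isB), thr)
      next
    }
    half <- (w - 1L) %/% 2L
    nw <- m - w + 1L
    for (li in seq_len(nrow(sub))) {
      csA <- c(0L, cumsum(isA[li, ]))
      csB <- c(0L, cumsum(isB[li, ]))
      cntA <- csA[(w + 1L):(m + 1L)] - csA[1L:nw]
      cntB <- csB[(w + 1L):(m + 1L)] - csB[1L:nw]
      wt <- window_type(cntA, cntB, thr)
      smoothed <- wt[pmin(pmax(seq_len(m) - half, 1L), nw)]
      out[li, cols] <- smoothed
    }
  }
  attr(out, "snps") <- callset$snps
  attr(out, "line_ids") <- callset$line_ids
  out
}

#' Merge runs of identical SNP genotype vectors into bin markers
#'
#' Adjacent SNPs (within a chromosome) whose genotype vectors across all
#' lines are identical carry no recombination information individually and
#' are merged into one bin marker spanning their physical range.
#'
#' @param smoothed a smoothed genotype matrix from [call_line_genotypes()]
#'   (or any lines x SNPs matrix with a `"snps"` attribute).
#' @param snps optional SNP table overriding the attribute.
#' @return object of class `bin_set`: `bins` data.frame (id, chrom, start_bp,
#'   end_bp, n_snps) and `geno` lines x bins matrix.
#' @export
merge_into_bins <- function(smoothed, snps = attr(smoothed, "snps")) {
  if (is.null(snps)) stop("SNP table required (attribute 'snps')")
  stopifnot(nrow(snps) == ncol(smoothed))
  bin_of <- integer(nrow(snps))
  nbin <- 0L
  for (cc in unique(snps$chrom)) {
    cols <- which(snps$chrom == cc)
    sub <- smoothed[, cols, drop = FALSE]
    if (length(cols) == 1L) {
      changed <- logical(0)
    } else {
      changed <- colSums(sub[, -1L, drop = FALSE] !=
                           sub[, -length(cols), drop = FALSE]) > 0L
    }
    bin_of[cols] <- nbin + cumsum(c(TRUE, changed))
    nbin <- max(bin_of[cols])
  }
  first <- which(!duplicated(bin_of))
  last <- c(first[-1L] - 1L, nrow(snps))
  bins <- data.frame(
    id = sprintf("Block%d", seq_along(first)),
    chrom = snps$chrom[first],
    start_bp = snps$pos_bp[first],
    end_bp = snps$pos_bp[last],
    n_snps = as.integer(last - first + 1L))
  geno <- smoothed[, first, drop = FALSE]
  colnames(geno) <- bins$id
  structure(list(bins = bins, geno = geno,
                 line_ids = attr(smoothed, "line_ids") %||% rownames(smoothed)),
            class = "bin_set")
}

#' @exportS3Method base::print
print.bin_set <- function(x, ...) {
  cat(sprintf("bin_set: %d bins x %d lines on %d chromosome(s)\n",
              nrow(x$bins), nrow(x$geno), length(unique(x$bins$chrom))))
  invisible(x)
}

#' Upper-tail probability of a 1-df chi-square statistic
#'
#' The p-value convention shared by every segregation test in the package.
#'
#' @param chi2 chi-square statistic(s).
#' @return upper-tail probability at 1 degree of freedom.
#' @export
chisq_1df_p <- function(chi2) pchisq(chi2, df = 1, lower.tail = FALSE)

#' Chi-square test of 1:1 segregation for homozygote counts
#'
#' `chi2 = (aa - bb)^2 / (aa + bb)`, tested against the upper tail of a
#' 1-df chi-square distribution.
#'
#' @param aa_count,bb_count homozygote class counts (heterozygous and missing
#'   calls are excluded beforehand).
#' @return list with `chi2` and `p`.
#' @export
segregation_chisq <- function(aa_count, bb_count) {
  total <- aa_count + bb_count
  if (any(total <= 0)) stop("both counts are zero: test undefined")
  chi2 <- (aa_count - bb_count)^2 / total
  list(chi2 = chi2, p = chisq_1df_p(chi2))
}

#' Filter bin markers by physical span and segregation distortion
#'
#' Removes bins whose inclusive span `end_bp - start_bp + 1` is not strictly
#' greater than `min_bin_length`, and bins whose aa:bb ratio departs from 1:1
#' at `p < distortion_alpha`.
#'
#' @param binset a `bin_set`.
#' @param params a [genotyper_params()].
#' @return filtered `bin_set`; per-bin removals (id, reason) in attribute
#'   `"removed_bins"`.
#' @export
filter_bins <- function(binset, params = genotyper_params()) {
  stopifnot(inherits(binset, "bin_set"))
  span <- binset$bins$end_bp - binset$bins$start_bp + 1
  short <- span <= params$min_bin_length
  aa <- colSums(binset$geno == GENO_AA, na.rm = TRUE)
  bb <- colSums(binset$geno == GENO_BB, na.rm = TRUE)
  p <- rep(1, length(aa))
  ok <- aa + bb > 0
  p[ok] <- segregation_chisq(aa[ok], bb[ok])$p
  distorted <- p < params$distortion_alpha
  drop <- short | distorted
  removed <- data.frame(
    id = binset$bins$id[drop],
    reason = ifelse(short[drop] & distorted[drop], "short+distorted",
                    ifelse(short[drop], "short", "distorted")))
  out <- binset
  out$bins <- binset$bins[!drop, , drop = FALSE]
  out$geno <- binset$geno[, !drop, drop = FALSE]
  attr(out, "removed_bins") <- removed
  out
}

#' Resolve window-caller transition buffers into clean breakpoints
#'
#' The symmetric sliding-window rule surrounds every clean crossover with a
#' deterministic run of ab calls (while the window straddles the exchange,
#' neither homozygote count clears the threshold). Because the rule is
#' symmetric, the midpoint of that run is an unbiased estimate of the
#' crossover position. This step replaces each ab run flanked by opposite
#' homozygotes with a clean switch at the run midpoint (the left genotype
#' takes the extra SNP when the run length is odd). Runs flanked by equal
#' homozygotes - the signature of a residual heterozygous tract, not of a
#' crossover - and runs touching a chromosome end are left as ab.
#'
#' @param smoothed smoothed genotype matrix from [call_line_genotypes()].
#' @param snps optional SNP table overriding the `"snps"` attribute.
#' @return the resolved genotype matrix (same shape and attributes).
#' @export
resolve_breakpoints <- function(smoothed, snps = attr(smoothed, "snps")) {
  if (is.null(snps)) stop("SNP table required (attribute 'snps')")
  out <- smoothed
  for (cc in unique(snps$chrom)) {
    cols <- which(snps$chrom == cc)
    for (li in seq_len(nrow(out))) {
      gg <- out[li, cols]
      rr <- rle(gg)
      ends <- cumsum(rr$lengths)
      starts <- ends - rr$lengths + 1L
      for (k in seq_along(rr$values)) {
        if (rr$values[k] != GENO_AB) next
        if (k == 1L || k == length(rr$values)) next
        left <- rr$values[k - 1L]; right <- rr$values[k + 1L]
        if (left == GENO_AB || right == GENO_AB || left == right) next
        len <- rr$lengths[k]
        n_left <- ceiling(len / 2)
        gg[starts[k]:(starts[k] + n_left - 1L)] <- left
        if (n_left < len) gg[(starts[k] + n_left):ends[k]] <- right
      }
      out[li, cols] <- gg
    }
  }
  out
}

#' Infer recombination breakpoints from smoothed genotypes
#'
#' The sliding-window caller surrounds every clean homozygote crossover with
#' a deterministic, symmetric run of ab calls (both homozygote counts drop
#' below the threshold while the window straddles the exchange), so the
#' crossover itself is best estimated by the midpoint of the non-homozygous
#' run separating two opposite homozygote segments. For every line this
#' returns those transition intervals.
#'
#' @param smoothed smoothed genotype matrix from [call_line_genotypes()].
#' @param snps optional SNP table overriding the `"snps"` attribute.
#' @return data.frame with `line`, `chrom`, `left_snp`, `right_snp` (indices
#'   of the flanking homozygous SNPs within the chromosome), `left_bp`,
#'   `right_bp`, `mid_marker` (the midpoint on the marker-index scale) and
#'   `from`, `to` genotype codes.
#' @export
find_breakpoints <- function(smoothed, snps = attr(smoothed, "snps")) {
  if (is.null(snps)) stop("SNP table required (attribute 'snps')")
  out <- list()
  line_ids <- attr(smoothed, "line_ids") %||% rownames(smoothed) %||%
    as.character(seq_len(nrow(smoothed)))
  for (cc in unique(snps$chrom)) {
    cols <- which(snps$chrom == cc)
    pos <- snps$pos_bp[cols]
    for (li in seq_len(nrow(smoothed))) {
      gg <- smoothed[li, cols]
      homo <- which(gg != GENO_AB)
      if (length(homo) < 2L) next
      gh <- gg[homo]
      sw <- which(gh[-1L] != gh[-length(gh)])
      for (s in sw) {
        l <- homo[s]; r <- homo[s + 1L]
        out[[length(out) + 1L]] <- data.frame(
          line = line_ids[li], chrom = cc, left_snp = l, right_snp = r,
          left_bp = pos[l], right_bp = pos[r], mid_marker = (l + r) / 2,
          from = gh[s], to = gh[s + 1L])
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(line = character(0), chrom = integer(0),
                      left_snp = integer(0), right_snp = integer(0),
                      left_bp = numeric(0), right_bp = numeric(0),
                      mid_marker = numeric(0), from = integer(0),
                      to = integer(0)))
  do.call(rbind, out)
}

#' Run the whole genotyping stage: filters, smoothing, binning
#'
#' Convenience wrapper chaining [select_aaxbb()], [apply_depth_filter()],
#' [filter_lines()], [call_line_genotypes()], [resolve_breakpoints()],
#' [merge_into_bins()] and [filter_bins()], keeping the removal reports of
#' every step.
#'
#' @param callset a raw `snp_callset`.
#' @param params a [genotyper_params()].
#' @param resolve apply [resolve_breakpoints()] to the smoothed matrix before
#'   binning (recommended; see that function's help).
#' @return a filtered `bin_set` with attribute `"report"` (list of removal
#'   tables and input/output counts).
#' @export
genotype_bins <- function(callset, params = genotyper_params(),
                          resolve = TRUE) {
  n_snps_in <- ncol(callset$geno)
  n_lines_in <- nrow(callset$geno)
  cs <- select_aaxbb(callset)
  cs <- apply_depth_filter(cs, params$min_depth)
  cs <- filter_lines(cs, params$max_abnormal_fraction, params$min_het_run)
  smoothed <- call_line_genotypes(cs, params)
  if (resolve) smoothed <- resolve_breakpoints(smoothed)
  bins <- merge_into_bins(smoothed)
  out <- filter_bins(bins, params)
  attr(out, "report") <- list(
    n_snps_in = n_snps_in, n_snps_used = ncol(cs$geno),
    n_lines_in = n_lines_in, n_lines_used = nrow(cs$geno),
    n_bins_raw = nrow(bins$bins), n_bins_kept = nrow(out$bins),
    removed_snps = attr(cs, "removed_snps"),
    removed_lines = attr(cs, "removed_lines"),
    removed_bins = attr(out, "removed_bins"))
  out
}
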