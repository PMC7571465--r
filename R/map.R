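#' Kosambi mapping function and its inverse
#'
#' `kosambi_cM(r) = 25 * ln((1 + 2r) / (1 - 2r))` converts a meiotic
#' recombination fraction into a map distance allowing partial interference;
#' `kosambi_inv(d) = tanh(d / 50) / 2` inverts it.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @param d map distance(s) in centimorgan.
#' @return distances in cM / recombination fractions.
#' @export
kosambi_cM <- function(r) {
  if (any(r < 0 | r >= 0.5)) stop("r must lie in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_cM
#' @export
kosambi_inv <- function(d) {
  if (any(d < 0)) stop("d must be non-negative")
  tanh(d / 50) / 2
}

# Haldane-Waddington relation for selfed RILs: observed recombinant fraction
# across lines R = 2r / (1 + 2r) for meiotic fraction r, and its inverse.
ril_R_from_r <- function(r) 2 * r / (1 + 2 * r)
ril_r_from_R <- function(R) pmin(R / (2 * (1 - R)), 0.4999)

#' Pairwise recombination fraction and linkage LOD between two markers
#'
#' Only homozygous (aa/bb) calls are informative in an RIL. The observed
#' recombinant fraction `R = recombinants / informative lines` is transformed
#' to the meiotic scale by the Haldane-Waddington inverse `r = R / (2(1 - R))`
#' (clipped to `[0, 0.5)`), and the LOD is the base-10 likelihood ratio of
#' linkage at `R` against independence.
#'
#' @param g1,g2 integer genotype vectors (codes 1/2/3, NA missing).
#' @param min_informative minimum informative lines, below which the pair is
#'   flagged uninformative (`r = 0.5`, `LOD = 0`).
#' @return list with `R` (observed), `r` (meiotic), `lod`, `n_informative`,
#'   `informative` (logical).
#' @export
estimate_rf <- function(g1, g2, min_informative = 20L) {
  use <- !is.na(g1) & !is.na(g2) & g1 != GENO_AB & g2 != GENO_AB
  n <- sum(use)
  if (n < min_informative)
    return(list(R = 0.5, r = 0.5, lod = 0, n_informative = n,
                informative = FALSE))
  nrec <- sum(g1[use] != g2[use])
  R <- nrec / n
  r <- if (R >= 0.5) 0.5 else ril_r_from_R(R)
  Rc <- min(max(R, 1e-12), 1 - 1e-12)
  lod <- max(0, (n - nrec) * log10(2 * (1 - Rc)) + nrec * log10(2 * Rc))
  list(R = R, r = r, lod = lod, n_informative = n, informative = TRUE)
}

# All-pairs RF/LOD matrices for a genotype matrix (lines x markers).
rf_matrices <- function(geno, min_informative = 20L) {
  A <- !is.na(geno) & geno == GENO_AA
  B <- !is.na(geno) & geno == GENO_BB
  storage.mode(A) <- "numeric"; storage.mode(B) <- "numeric"
  npar <- crossprod(A) + crossprod(B)
  nrec <- crossprod(A, B) + crossprod(B, A)
  n <- npar + nrec
  R <- matrix(0.5, ncol(geno), ncol(geno))
  ok <- n >= min_informative
  R[ok] <- (nrec / pmax(n, 1))[ok]
  Rc <- pmin(pmax(R, 1e-12), 1 - 1e-12)
  lod <- pmax(npar * log10(2 * (1 - Rc)) + nrec * log10(2 * Rc), 0)
  lod[!ok] <- 0
  r <- ifelse(R >= 0.5, 0.5, ril_r_from_R(R))
  diag(R) <- 0; diag(r) <- 0
  dimnames(R) <- dimnames(r) <- dimnames(lod) <-
    list(colnames(geno), colnames(geno))
  list(R = R, r = r, lod = lod, n = n, informative = ok)
}

#' Group bin markers by reference chromosome
#'
#' Linkage groups are preset to the reference chromosomes; within-group
#' connectivity at a LOD threshold is checked diagnostically (markers whose
#' best within-group linkage LOD falls below the threshold are flagged, not
#' re-assigned).
#'
#' @param binset a `bin_set`.
#' @param min_lod linkage LOD threshold for the connectivity check.
#' @return named list of per-chromosome bin index vectors, with a
#'   `"connectivity"` attribute listing flagged markers.
#' @export
group_markers <- function(binset, min_lod = 3) {
  stopifnot(inherits(binset, "bin_set"))
  groups <- split(seq_len(nrow(binset$bins)), binset$bins$chrom)
  flagged <- list()
  for (gn in names(groups)) {
    idx <- groups[[gn]]
    if (length(idx) < 3L) {
      warning(sprintf("linkage group %s has fewer than 3 markers", gn))
      next
    }
    lod <- rf_matrices(binset$geno[, idx, drop = FALSE])$lod
    diag(lod) <- 0
    best <- apply(lod, 1L, max)
    if (any(best < min_lod))
      flagged[[gn]] <- binset$bins$id[idx][best < min_lod]
  }
  attr(groups, "connectivity") <- flagged
  groups
}

# Sum of adjacent recombination fractions along a marker order.
sarf <- function(order, r) {
  if (length(order) < 2L) return(0)
  sum(r[cbind(order[-length(order)], order[-1L])])
}

#' Order markers by nearest-neighbour tour construction plus 2-opt
#'
#' Builds a path seeded from the marker pair with the smallest recombination
#' fraction, greedily extending whichever end has the closer unplaced marker,
#' then improves it with 2-opt segment reversals until no reversal strictly
#' lowers the SARF (sum of adjacent recombination fractions). All tie-breaks
#' take the lowest marker index, so the result is deterministic.
#'
#' @param r symmetric recombination-fraction matrix (uninformative pairs
#'   imputed to 0.5).
#' @return integer marker ordering.
#' @export
order_nn_two_opt <- function(r) {
  m <- nrow(r)
  if (m < 2L) return(seq_len(m))
  rr <- r
  diag(rr) <- Inf
  # seed: smallest r, lowest indices first
  seed <- which(rr == min(rr), arr.ind = TRUE)
  seed <- seed[order(seed[, 1L], seed[, 2L]), , drop = FALSE][1L, ]
  path <- as.integer(sort(seed))
  unplaced <- setdiff(seq_len(m), path)
  while (length(unplaced) > 0L) {
    d1 <- rr[path[1L], unplaced]
    d2 <- rr[path[length(path)], unplaced]
    if (min(d1) <= min(d2)) {
      nxt <- unplaced[which.min(d1)]
      path <- c(nxt, path)
    } else {
      nxt <- unplaced[which.min(d2)]
      path <- c(path, nxt)
    }
    unplaced <- setdiff(unplaced, nxt)
  }
  two_opt(path, r)
}

# 2-opt improvement on a path under SARF; best-improvement steps, lowest
# (i, j) tie-break, strictly decreasing acceptance.
two_opt <- function(path, r) {
  m <- length(path)
  if (m < 3L) return(path)
  repeat {
    best_delta <- -1e-12
    best_ij <- NULL
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        if (i == 1L && j == m) next            # whole-path reversal: no change
        a <- if (i > 1L) r[path[i - 1L], path[j]] - r[path[i - 1L], path[i]] else 0
        b <- if (j < m) r[path[i], path[j + 1L]] - r[path[j], path[j + 1L]] else 0
        delta <- a + b
        if (delta < best_delta) {
          best_delta <- delta
          best_ij <- c(i, j)
        }
      }
    }
    if (is.null(best_ij)) break
    path[best_ij[1L]:best_ij[2L]] <- rev(path[best_ij[1L]:best_ij[2L]])
  }
  path
}

#' Ripple an ordering with a sliding permutation window (SARF criterion)
#'
#' Slides a window (default 5 markers) along the order; within each window
#' every permutation is tried and accepted only if it strictly lowers the
#' total SARF. Passes repeat until a full pass makes no change.
#'
#' @param order integer marker ordering.
#' @param r recombination-fraction matrix.
#' @param window window size (5 as in SARF rippling).
#' @return improved ordering.
#' @export
ripple_sarf <- function(order, r, window = 5L) {
  m <- length(order)
  if (m <= 2L) return(order)
  window <- min(window, m)
  pp <- perms_n(window)
  repeat {
    changed <- FALSE
    for (s in seq_len(m - window + 1L)) {
      idx <- s:(s + window - 1L)
      seg <- order[idx]
      lo <- if (s > 1L) order[s - 1L] else NA_integer_
      hi <- if (s + window <= m) order[s + window] else NA_integer_
      local_cost <- function(perm) {
        o <- seg[perm]
        cost <- sum(r[cbind(o[-window], o[-1L])])
        if (!is.na(lo)) cost <- cost + r[lo, o[1L]]
        if (!is.na(hi)) cost <- cost + r[o[window], hi]
        cost
      }
      costs <- apply(pp, 1L, local_cost)
      cur <- costs[1L]                       # pp's first row is the identity
      best <- which.min(costs)
      if (costs[best] < cur - 1e-12) {
        order[idx] <- seg[pp[best, ]]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  order
}

#' Assemble a genetic map from grouped, ordered bins
#'
#' Map positions are cumulative Kosambi distances over adjacent-pair meiotic
#' recombination fractions, starting at 0; each group is oriented so the
#' first marker has the smaller physical position.
#'
#' @param binset a filtered `bin_set`.
#' @param min_informative minimum informative lines per pair for
#'   [estimate_rf()].
#' @param ripple_window window size for [ripple_sarf()].
#' @return object of class `genetic_map`: list of per-group data.frames
#'   (`marker`, `chrom`, `pos_cM`, `start_bp`, `end_bp`, `n_snps`).
#' @export
build_map <- function(binset, min_informative = 20L, ripple_window = 5L) {
  stopifnot(inherits(binset, "bin_set"))
  groups <- group_markers(binset)
  out <- list()
  for (gn in names(groups)) {
    idx <- groups[[gn]]
    sub <- binset$geno[, idx, drop = FALSE]
    bins <- binset$bins[idx, , drop = FALSE]
    if (length(idx) == 1L) {
      out[[gn]] <- data.frame(marker = bins$id, chrom = bins$chrom,
                              pos_cM = 0, start_bp = bins$start_bp,
                              end_bp = bins$end_bp, n_snps = bins$n_snps)
      next
    }
    rf <- rf_matrices(sub, min_informative)
    ord <- ripple_sarf(order_nn_two_opt(rf$r), rf$r, ripple_window)
    if (bins$start_bp[ord[1L]] > bins$start_bp[ord[length(ord)]])
      ord <- rev(ord)
    radj <- rf$r[cbind(ord[-length(ord)], ord[-1L])]
    pos <- cumsum(c(0, kosambi_cM(pmin(radj, 0.49))))
    out[[gn]] <- data.frame(marker = bins$id[ord], chrom = bins$chrom[ord],
                            pos_cM = pos, start_bp = bins$start_bp[ord],
                            end_bp = bins$end_bp[ord], n_snps = bins$n_snps[ord])
  }
  structure(list(groups = out, connectivity = attr(groups, "connectivity")),
            class = "genetic_map")
}

#' Summarize a genetic map, linkage group by linkage group
#'
#' Per group: marker count, total length, average adjacent spacing
#' `total / (count - 1)`, largest gap and number of gaps over `gap_threshold`.
#' The `Total` row reports the summed length; its average-distance column
#' follows the whole-map convention `total length / total marker count`
#' (the adjacent-spacing convention `total / (markers - groups)` is attached
#' as attribute `"overall_avg_adjacent"`). A census of gaps larger than 10 cM
#' is attached as attribute `"gaps_over_10"`.
#'
#' @param map a `genetic_map`, or a list of per-group data.frames with a
#'   `pos_cM` column.
#' @param gap_threshold gap size (cM) counted in the last column.
#' @return data.frame shaped like a linkage-map summary table.
#' @export
map_summary <- function(map, gap_threshold = 5) {
  groups <- if (inherits(map, "genetic_map")) map$groups else map
  rows <- lapply(names(groups), function(gn) {
    g <- groups[[gn]]
    n <- nrow(g)
    len <- max(g$pos_cM) - min(g$pos_cM)
    gaps <- diff(g$pos_cM)
    data.frame(LG = paste0("LG", gn), n_markers = n, total_cM = len,
               avg_cM = if (n > 1L) round(len / (n - 1L), 2L) else NA_real_,
               max_gap_cM = if (n > 1L) max(gaps) else NA_real_,
               gaps_over = if (n > 1L) sum(gaps > gap_threshold) else 0L)
  })
  out <- do.call(rbind, rows)
  total_len <- sum(out$total_cM)
  total_n <- sum(out$n_markers)
  total <- data.frame(LG = "Total", n_markers = total_n, total_cM = total_len,
                      avg_cM = round(total_len / total_n, 2L),
                      max_gap_cM = NA_real_, gaps_over = sum(out$gaps_over))
  res <- rbind(out, total)
  attr(res, "overall_avg_adjacent") <-
    round(total_len / max(1L, total_n - length(groups)), 2L)
  attr(res, "gaps_over_10") <- sum(vapply(groups, function(g)
    if (nrow(g) > 1L) sum(diff(g$pos_cM) > 10) else 0L, numeric(1)))
  attr(res, "mean_group_length") <- round(total_len / length(groups), 2L)
  res
}

#' @exportS3Method base::print
print.genetic_map <- function(x, ...) {
  s <- map_summary(x)
  cat(sprintf("genetic_map: %d linkage group(s), %d markers, %.2f cM\n",
              length(x$groups), s$n_markers[nrow(s)], s$total_cM[nrow(s)]))
  invisible(x)
}

#' @export
summary.genetic_map <- function(object, ...) map_summary(object, ...)

#' @exportS3Method graphics::plot
plot.genetic_map <- function(x, ...) {
  ng <- length(x$groups)
  maxlen <- max(vapply(x$groups, function(g) max(g$pos_cM), numeric(1)))
  graphics::plot(NULL, xlim = c(0.5, ng + 0.5), ylim = c(maxlen, 0),
                 xlab = "linkage group", ylab = "position (cM)",
                 xaxt = "n", ...)
  graphics::axis(1, at = seq_len(ng), labels = names(x$groups))
  for (i in seq_len(ng)) {
    g <- x$groups[[i]]
    graphics::segments(i, 0, i, max(g$pos_cM))
    graphics::segments(i - 0.2, g$pos_cM, i + 0.2, g$pos_cM)
  }
  invisible(x)
}
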