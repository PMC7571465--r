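#' Parameters of the ICIM QTL scan
#'
#' Defaults follow the study protocol: a 0.1-cM walking step, stepwise entry
#' probability 0.001 (removal probability twice that), and a genome-wide LOD
#' threshold from 1000 phenotype permutations at P = 0.05.
#'
#' @param step_cM scan grid step in centimorgan.
#' @param pin stepwise entry probability (partial-F p-value to enter).
#' @param pout stepwise removal probability (defaults to `2 * pin`).
#' @param n_permutations permutation count for the LOD threshold.
#' @param alpha genome-wide significance level.
#' @param seed RNG seed for the permutations.
#' @return object of class `scan_params`.
#' @export
scan_params <- function(step_cM = 0.1, pin = 0.001, pout = 2 * pin,
                        n_permutations = 1000L, alpha = 0.05, seed = 1L) {
  stopifnot_scalar(step_cM, "step_cM")
  if (step_cM <= 0) stop("step_cM must be positive")
  if (pin <= 0 || pin >= pout || pout >= 1)
    stop("need 0 < pin < pout < 1")
  stopifnot_scalar(n_permutations, "n_permutations", min = 1, integer = TRUE)
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  structure(list(step_cM = step_cM, pin = pin, pout = pout,
                 n_permutations = as.integer(n_permutations), alpha = alpha,
                 seed = as.integer(seed)),
            class = "scan_params")
}

# Numeric marker coding for regression: aa = +1, bb = -1, ab and missing = 0
# (the midpoint, equivalent to mean imputation for a balanced RIL).
code_genotypes <- function(geno) {
  x <- matrix(0, nrow(geno), ncol(geno), dimnames = dimnames(geno))
  x[!is.na(geno) & geno == GENO_AA] <- 1
  x[!is.na(geno) & geno == GENO_BB] <- -1
  x
}

#' Forward-backward stepwise marker selection
#'
#' Linear-model stepwise regression of the phenotype on all bin markers: in
#' each forward step the candidate with the smallest partial-F p-value enters
#' if `p < pin` (lowest index on ties); backward steps remove the worst
#' selected marker while its p-value exceeds `pout`. The final coefficients
#' come from the joint least-squares fit of the selected markers.
#'
#' @param X coded marker matrix (lines x markers, from [code_genotypes()]).
#' @param y phenotype vector (variance must be positive).
#' @param pin,pout entry/removal probabilities.
#' @return list with `index` (selected columns), `coef` (their joint-fit
#'   coefficients) and `intercept`.
#' @export
stepwise_select <- function(X, y, pin = 0.001, pout = 2 * pin) {
  n <- length(y)
  if (var(y) <= 0) stop("phenotype variance is zero")
  stopifnot(nrow(X) == n)
  sel <- integer(0)
  forward_p <- function(sel) {
    Q <- qr.Q(qr(cbind(1, X[, sel, drop = FALSE])))
    ry <- y - Q %*% crossprod(Q, y)
    RX <- X - Q %*% crossprod(Q, X)
    ssx <- colSums(RX^2)
    ssy <- sum(ry^2)
    df <- n - length(sel) - 2L
    if (df <= 0 || ssy <= 0) return(rep(1, ncol(X)))
    r2 <- as.vector(crossprod(RX, ry))^2 / (pmax(ssx, 1e-300) * ssy)
    r2[ssx < 1e-10] <- 0                  # aliased with current model
    fstat <- r2 * df / pmax(1 - r2, 1e-300)
    p <- pf(fstat, 1, df, lower.tail = FALSE)
    p[sel] <- 1
    p
  }
  backward_p <- function(sel) {
    Xs <- cbind(1, X[, sel, drop = FALSE])
    fit <- lm.fit(Xs, y)
    df <- n - length(sel) - 1L
    if (df <= 0) return(rep(0, length(sel)))
    s2 <- sum(fit$residuals^2) / df
    xtxi <- chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE])
    se <- sqrt(diag(xtxi) * s2)
    tt <- fit$coefficients / se
    pf(tt[-1L]^2, 1, df, lower.tail = FALSE)
  }
  repeat {
    changed <- FALSE
    p <- forward_p(sel)
    if (min(p) < pin) {
      sel <- c(sel, which.min(p))
      changed <- TRUE
    }
    while (length(sel) > 0L) {
      bp <- backward_p(sel)
      if (max(bp) > pout) {
        worst <- which(bp == max(bp))
        sel <- sel[-worst[length(worst)]]    # drop the highest index on ties
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  sel <- sort(sel)
  if (length(sel) == 0L)
    return(list(index = integer(0), coef = numeric(0), intercept = mean(y)))
  fit <- lm.fit(cbind(1, X[, sel, drop = FALSE]), y)
  list(index = sel, coef = unname(fit$coefficients[-1L]),
       intercept = unname(fit$coefficients[1L]))
}

#' Adjust a phenotype for background cofactors, releasing the scanned interval
#'
#' The ICIM phenotype adjustment subtracts each selected cofactor's
#' contribution `coef * marker code`, except cofactors that are flanking (or
#' inside) the interval currently being scanned, which are released.
#'
#' @param y phenotype vector.
#' @param cofactors result of [stepwise_select()].
#' @param X coded marker matrix the cofactors refer to.
#' @param released indices (columns of `X`) of cofactors to release.
#' @return adjusted phenotype vector.
#' @export
adjust_phenotype <- function(y, cofactors, X, released = integer(0)) {
  if (length(cofactors$index) == 0L) return(y)
  keep <- !(cofactors$index %in% released)
  if (!any(keep)) return(y)
  y - X[, cofactors$index[keep], drop = FALSE] %*% cofactors$coef[keep]
}

# Per-line prior P(QTL genotype = aa) at a scan position, conditioned on the
# flanking-marker genotypes through the line-level Markov chain whose
# adjacent transition probability is the RIL-scale recombination fraction
# R = 2r/(1+2r), r = Kosambi-inverse of the cM gap.
interval_priors <- function(gl, gr, d_left, d_right) {
  RL <- ril_R_from_r(kosambi_inv(d_left))
  RR <- ril_R_from_r(kosambi_inv(d_right))
  a1 <- ifelse(is.na(gl), 1, ifelse(gl > 0, 1 - RL, RL))
  a2 <- ifelse(is.na(gl), 1, ifelse(gl > 0, RL, 1 - RL))
  b1 <- ifelse(is.na(gr), 1, ifelse(gr > 0, 1 - RR, RR))
  b2 <- ifelse(is.na(gr), 1, ifelse(gr > 0, RR, 1 - RR))
  p1 <- a1 * b1
  p2 <- a2 * b2
  p1 / (p1 + p2)
}

# Precompute, per linkage group, the scan grid, flanking-marker indices and
# prior matrix; reused across permutations since it only depends on the map
# and genotypes.
prepare_scan <- function(map, binset, step_cM) {
  stopifnot(inherits(map, "genetic_map"), inherits(binset, "bin_set"))
  prep <- list()
  for (gn in names(map$groups)) {
    g <- map$groups[[gn]]
    cols <- match(g$marker, binset$bins$id)
    if (anyNA(cols)) stop("map marker absent from bin set")
    geno <- binset$geno[, cols, drop = FALSE]
    gg <- matrix(NA_real_, nrow(geno), ncol(geno))
    gg[!is.na(geno) & geno == GENO_AA] <- 1
    gg[!is.na(geno) & geno == GENO_BB] <- -1
    pos <- g$pos_cM
    L <- max(pos)
    grid <- sort(unique(c(seq(0, L, by = step_cM), pos)))
    iL <- pmin(findInterval(grid, pos), length(pos) - 1L)
    iL <- pmax(iL, 1L)
    P <- matrix(0.5, nrow(geno), length(grid))
    for (j in seq_along(grid)) {
      P[, j] <- interval_priors(gg[, iL[j]], gg[, iL[j] + 1L],
                                grid[j] - pos[iL[j]], pos[iL[j] + 1L] - grid[j])
    }
    prep[[gn]] <- list(grid = grid, iL = iL, pos = pos,
                       markers = g$marker, cols = cols, P = P)
  }
  prep
}

# Core scan over the precomputed grid; X/cofactors drive the per-interval
# phenotype adjustment, var_total scales the PVE column.
scan_engine <- function(prep, y, cofactors, X, var_total, maxit = 50L,
                        tol = 1e-8) {
  res <- list()
  n <- length(y)
  for (gn in names(prep)) {
    pr <- prep[[gn]]
    ncof <- length(cofactors$index)
    if (ncof > 0L) {
      # which cofactors are flanking markers of each grid interval
      flank_left <- pr$cols[pr$iL]
      flank_right <- pr$cols[pr$iL + 1L]
      rel_key <- character(length(pr$grid))
      released <- vector("list", length(pr$grid))
      for (j in seq_along(pr$grid)) {
        rel <- cofactors$index[cofactors$index %in%
                                 c(flank_left[j], flank_right[j])]
        released[[j]] <- rel
        rel_key[j] <- paste(rel, collapse = ",")
      }
      groups <- split(seq_along(pr$grid), rel_key)
    } else {
      groups <- list(all = seq_along(pr$grid))
      released <- NULL
    }
    lod <- additive <- pve <- numeric(length(pr$grid))
    for (gset in groups) {
      rel <- if (is.null(released)) integer(0) else released[[gset[1L]]]
      yadj <- as.vector(adjust_phenotype(y, cofactors, X, rel))
      fit <- em_scan_cpp(yadj, pr$P[, gset, drop = FALSE], maxit, tol)
      lod[gset] <- fit[, "lod"]
      additive[gset] <- fit[, "additive"]
      pve[gset] <- 100 * fit[, "gvar"] / var_total
    }
    res[[gn]] <- data.frame(lg = gn, pos_cM = pr$grid, lod = lod,
                            additive = additive, pve = pve)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Additive ICIM interval scan
#'
#' Scans every linkage group on a `step_cM` grid (marker positions are always
#' included). At each position the per-line probability of carrying the aa
#' QTL genotype is computed from the flanking-marker genotypes via
#' Kosambi-inverted, RIL-scale recombination fractions; a two-component
#' normal mixture is fitted to the cofactor-adjusted phenotype by EM, and the
#' LOD is the base-10 likelihood ratio against the single-normal null on the
#' same adjusted phenotype. Cofactors flanking the scanned interval are
#' released from the adjustment.
#'
#' @param map a `genetic_map`.
#' @param binset the `bin_set` the map was built from.
#' @param phenotype numeric phenotype vector (one value per line).
#' @param params a [scan_params()].
#' @param cofactors optional [stepwise_select()] result; `NULL` scans the raw
#'   phenotype.
#' @return data.frame LOD profile: `lg`, `pos_cM`, `lod`, `additive`, `pve`.
#' @export
interval_scan <- function(map, binset, phenotype, params = scan_params(),
                          cofactors = NULL) {
  X <- code_genotypes(binset$geno)
  prep <- prepare_scan(map, binset, params$step_cM)
  if (is.null(cofactors))
    cofactors <- list(index = integer(0), coef = numeric(0))
  var_total <- var(phenotype) * (length(phenotype) - 1) / length(phenotype)
  scan_engine(prep, phenotype, cofactors, X, var_total)
}

#' Genome-wide LOD threshold by phenotype permutation
#'
#' Permutes the phenotype across lines `n_permutations` times; each
#' permutation re-runs the full ICIM procedure (stepwise cofactor selection
#' and interval scan) and records the genome-wide maximum LOD. The cutoff is
#' the `ceiling((1 - alpha) * N)`-th smallest maximum (an order statistic, so
#' the result is bit-reproducible for a fixed seed).
#'
#' @inheritParams interval_scan
#' @return the LOD cutoff, with the permutation maxima as attribute
#'   `"max_lods"`.
#' @export
permutation_threshold <- function(map, binset, phenotype,
                                  params = scan_params()) {
  X <- code_genotypes(binset$geno)
  prep <- prepare_scan(map, binset, params$step_cM)
  n <- length(phenotype)
  set.seed(params$seed)
  maxlod <- numeric(params$n_permutations)
  for (b in seq_len(params$n_permutations)) {
    yp <- phenotype[sample.int(n)]
    cof <- stepwise_select(X, yp, params$pin, params$pout)
    vt <- var(yp) * (n - 1) / n
    prof <- scan_engine(prep, yp, cof, X, vt)
    maxlod[b] <- max(prof$lod)
  }
  srt <- sort(maxlod)
  cutoff <- srt[max(1L, ceiling((1 - params$alpha) * params$n_permutations))]
  attr(cutoff, "max_lods") <- maxlod
  cutoff
}

#' Call QTL from a LOD profile
#'
#' Each maximal run of scan positions at or above the threshold yields one
#' QTL at the run's LOD maximum. Flanking markers are the nearest mapped bins
#' left and right of the peak, the physical interval is their combined bp
#' span, and a 1.5-LOD-drop support interval is reported alongside.
#'
#' @param profile LOD profile from [interval_scan()].
#' @param threshold LOD cutoff (e.g. from [permutation_threshold()]).
#' @param map the `genetic_map` scanned.
#' @param binset the `bin_set` (for physical coordinates).
#' @return data.frame with one row per QTL (possibly zero rows).
#' @export
call_qtl <- function(profile, threshold, map, binset) {
  out <- list()
  for (gn in unique(profile$lg)) {
    pf_ <- profile[profile$lg == gn, , drop = FALSE]
    above <- pf_$lod >= threshold & pf_$lod > 0
    if (!any(above)) next
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    g <- map$groups[[gn]]
    for (ri in which(runs$values)) {
      seg <- starts[ri]:ends[ri]
      peak <- seg[which.max(pf_$lod[seg])]
      peak_cM <- pf_$pos_cM[peak]
      li <- max(which(g$pos_cM <= peak_cM + 1e-9))
      ri2 <- min(which(g$pos_cM >= peak_cM - 1e-9))
      if (li == ri2) {                 # peak exactly at a marker
        if (ri2 < nrow(g)) ri2 <- ri2 + 1L else if (li > 1L) li <- li - 1L
      }
      bl <- binset$bins[match(g$marker[li], binset$bins$id), ]
      br <- binset$bins[match(g$marker[ri2], binset$bins$id), ]
      # 1.5-LOD-drop support interval
      drop_lvl <- pf_$lod[peak] - 1.5
      lo <- peak; while (lo > 1L && pf_$lod[lo - 1L] >= drop_lvl) lo <- lo - 1L
      hi <- peak; while (hi < nrow(pf_) && pf_$lod[hi + 1L] >= drop_lvl) hi <- hi + 1L
      out[[length(out) + 1L]] <- data.frame(
        lg = gn, peak_cM = peak_cM, lod = pf_$lod[peak],
        additive = pf_$additive[peak], pve = pf_$pve[peak],
        left_marker = g$marker[li], right_marker = g$marker[ri2],
        phys_start_bp = min(bl$start_bp, br$start_bp),
        phys_end_bp = max(bl$end_bp, br$end_bp),
        ci_lo_cM = pf_$pos_cM[lo], ci_hi_cM = pf_$pos_cM[hi],
        threshold = as.numeric(threshold))
    }
  }
  if (length(out) == 0L)
    return(data.frame(lg = character(0), peak_cM = numeric(0),
                      lod = numeric(0), additive = numeric(0),
                      pve = numeric(0), left_marker = character(0),
                      right_marker = character(0), phys_start_bp = numeric(0),
                      phys_end_bp = numeric(0), ci_lo_cM = numeric(0),
                      ci_hi_cM = numeric(0), threshold = numeric(0)))
  res <- do.call(rbind, out)
  res$qtl_name <- sprintf("q%s.%d", res$lg, ave(seq_len(nrow(res)), res$lg,
                                                FUN = seq_along))
  res[, c("qtl_name", setdiff(names(res), "qtl_name"))]
}

#' Percent of phenotypic variance explained by a fitted QTL
#'
#' `PVE = 100 * genetic variance / total phenotypic variance`, with the
#' genetic variance of the two-point effect distribution taken over the
#' per-line genotype probabilities.
#'
#' @param fit list with `mu1`, `mu2` (class means) and `p` (per-line
#'   probability of the aa genotype).
#' @param phenotype the unadjusted trait values.
#' @return PVE in percent.
#' @export
compute_pve <- function(fit, phenotype) {
  vtot <- var(phenotype) * (length(phenotype) - 1) / length(phenotype)
  if (vtot <= 0) stop("phenotype variance is zero")
  eg <- mean(fit$p * fit$mu1 + (1 - fit$p) * fit$mu2)
  eg2 <- mean(fit$p * fit$mu1^2 + (1 - fit$p) * fit$mu2^2)
  100 * max(0, eg2 - eg^2) / vtot
}

#' Inclusive composite interval mapping of one trait
#'
#' The full ICIM procedure: stepwise cofactor selection on all bin markers,
#' cofactor-adjusted interval scan, permutation LOD threshold and QTL
#' calling.
#'
#' @param map a `genetic_map`.
#' @param binset the `bin_set` the map was built from.
#' @param phenotype numeric vector, one value per line (order matching
#'   `binset$line_ids`).
#' @param params a [scan_params()].
#' @param threshold optional fixed LOD threshold; when `NULL` it is computed
#'   by [permutation_threshold()].
#' @param trait trait label carried into the results.
#' @return object of class `icim_scan` with elements `profile`, `threshold`,
#'   `qtl`, `cofactors`, `params`, `trait`.
#' @export
icim_scan <- function(map, binset, phenotype, params = scan_params(),
                      threshold = NULL, trait = "trait") {
  stopifnot(length(phenotype) == nrow(binset$geno))
  X <- code_genotypes(binset$geno)
  cof <- stepwise_select(X, phenotype, params$pin, params$pout)
  profile <- interval_scan(map, binset, phenotype, params, cof)
  if (is.null(threshold))
    threshold <- permutation_threshold(map, binset, phenotype, params)
  qtl <- call_qtl(profile, threshold, map, binset)
  if (nrow(qtl) > 0L) qtl$trait <- trait
  structure(list(profile = profile, threshold = as.numeric(threshold),
                 qtl = qtl, cofactors = cof, params = params, trait = trait),
            class = "icim_scan")
}

#' @exportS3Method base::print
print.icim_scan <- function(x, ...) {
  cat(sprintf("icim_scan of '%s': %d positions, threshold %.2f, %d QTL\n",
              x$trait, nrow(x$profile), x$threshold, nrow(x$qtl)))
  if (nrow(x$qtl) > 0L)
    print(x$qtl[, c("qtl_name", "lg", "peak_cM", "lod", "pve", "additive",
                    "left_marker", "right_marker")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.icim_scan <- function(object, ...) {
  list(trait = object$trait, threshold = object$threshold, qtl = object$qtl,
       n_cofactors = length(object$cofactors$index),
       max_lod = max(object$profile$lod))
}

#' @exportS3Method graphics::plot
plot.icim_scan <- function(x, ...) {
  prof <- x$profile
  lgs <- unique(prof$lg)
  offs <- 0
  xs <- numeric(nrow(prof))
  mids <- numeric(length(lgs))
  for (i in seq_along(lgs)) {
    sel <- prof$lg == lgs[i]
    xs[sel] <- prof$pos_cM[sel] + offs
    mids[i] <- offs + max(prof$pos_cM[sel]) / 2
    offs <- offs + max(prof$pos_cM[sel]) + 5
  }
  graphics::plot(xs, prof$lod, type = "l", xlab = "linkage group",
                 ylab = "LOD", xaxt = "n", ...)
  graphics::axis(1, at = mids, labels = lgs)
  graphics::abline(h = x$threshold, lty = 2)
  invisible(x)
}
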