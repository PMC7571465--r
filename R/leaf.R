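#' Specification of a parametric lobed/indented leaf outline
#'
#' The generated leaflet is a simple polygon, symmetric about the main vein
#' (the segment from the base at the origin to the tip at unit height, so all
#' lengths are in main-vein units; the shape indices R and Q are scale-free).
#' Margin apexes sit on a smooth ovate envelope; between consecutive apexes a
#' sinus vertex is pulled towards the vein, and the area between each sinus
#' and the chord joining its two neighbouring apexes is the "lobed" area cut
#' out of the blade.
#'
#' @param lobe_depth fraction in [0, 1): how far sinus vertices are pulled in
#'   from the apex-to-apex chord towards the vein. 0 gives an unlobed
#'   (convex-margin) leaf with R = 100.
#' @param n_apexes odd count >= 3 of margin apexes (the tip plus an equal
#'   number per side).
#' @param notch_position fraction in (0, 1]: height along the main vein of the
#'   deepest concave-point pair, so Q = 100 * notch_position by construction.
#' @return object of class `leaf_shape_spec`.
#' @export
leaf_shape_spec <- function(lobe_depth = 0.3, n_apexes = 7L,
                            notch_position = 0.5) {
  if (!is.numeric(lobe_depth) || lobe_depth < 0 || lobe_depth >= 1)
    stop("lobe_depth must lie in [0, 1)")
  stopifnot_scalar(n_apexes, "n_apexes", min = 3, integer = TRUE)
  if (n_apexes %% 2 == 0)
    stop("n_apexes must be odd (tip plus an equal number per side)")
  if (notch_position <= 0 || notch_position > 1)
    stop("notch_position must lie in (0, 1]")
  structure(list(lobe_depth = lobe_depth, n_apexes = as.integer(n_apexes),
                 notch_position = notch_position), class = "leaf_shape_spec")
}

# Envelope half-width of the blade at height y (y in [0, 1]).
leaf_envelope_width <- function(y) 0.35 * sin(pi * y)^0.8

#' Generate a leaf outline polygon with landmarks and analytic measurements
#'
#' @param spec a [leaf_shape_spec()].
#' @return object of class `leaf_shape`: `outline` (vertex matrix, counter-
#'   clockwise, base first), indices `base`, `tip`, `apex_indices`,
#'   `concave_pairs` (list of `c(right, left)` vertex-index pairs, one per
#'   sinus height), and `analytic` = list(V, lobed_area, L1, L2) recorded at
#'   generation time.
#' @export
generate_leaf_polygon <- function(spec) {
  stopifnot(inherits(spec, "leaf_shape_spec"))
  k <- (spec$n_apexes - 1L) %/% 2L          # lateral apexes per side
  np <- spec$notch_position
  # the deepest sinus sits midway between two apexes placed around the notch;
  # remaining apexes are spread below and above that pair
  if (k == 1L) {
    if (np <= 0.5)
      stop("notch_position must exceed 0.5 with a single lateral apex pair")
    y_apex <- 2 * np - 1
    notch_idx <- 1L                         # sinus between the apex and tip
  } else {
    h <- min(0.15, np / 2, (1 - np) / 2)
    a_lo <- np - h; a_hi <- np + h
    n_extra <- k - 2L
    n_below <- min(n_extra, max(0L, floor(n_extra * np)))
    if (n_below > 0L && a_lo - 0.08 <= 0.06) n_below <- 0L
    n_above <- n_extra - n_below
    below <- if (n_below > 0L)
      seq(max(0.06, a_lo - 0.08 - 0.12 * n_below), a_lo - 0.08,
          length.out = n_below) else numeric(0)
    above <- if (n_above > 0L)
      seq(a_hi + 0.08, min(0.95, a_hi + 0.08 + 0.12 * n_above),
          length.out = n_above) else numeric(0)
    y_apex <- c(below, a_lo, a_hi, above)
    notch_idx <- n_below + 1L
  }
  if (any(diff(c(0, y_apex, 1)) <= 0))
    stop("notch_position incompatible with the apex layout")

  apex_xy <- cbind(leaf_envelope_width(y_apex), y_apex)
  upper_xy <- rbind(apex_xy[-1L, , drop = FALSE], c(0, 1))
  depth <- rep(0.6 * spec$lobe_depth, k)
  depth[notch_idx] <- spec$lobe_depth
  mid_xy <- (apex_xy + upper_xy) / 2
  sinus_xy <- cbind(mid_xy[, 1] * (1 - depth), mid_xy[, 2])

  # right side bottom->top: base, A1, S1, A2, S2, ..., Ak, Sk, tip
  right <- matrix(0, 2L * k, 2L)
  right[seq(1L, 2L * k, by = 2L), ] <- apex_xy
  right[seq(2L, 2L * k, by = 2L), ] <- sinus_xy
  left <- right[rev(seq_len(nrow(right))), , drop = FALSE]
  left[, 1] <- -left[, 1]
  outline <- rbind(c(0, 0), right, c(0, 1), left)

  base <- 1L
  tip <- 2L + 2L * k
  apex_r <- 1L + seq(1L, 2L * k, by = 2L)
  sinus_r <- 1L + seq(2L, 2L * k, by = 2L)
  nv <- nrow(outline)
  # left-side index of right-side vertex i: reflection about the tip
  mirror <- function(i) if (i == 1L) 1L else nv + 2L - i
  apex_indices <- c(apex_r, tip, vapply(rev(apex_r), mirror, integer(1)))
  concave_pairs <- lapply(sinus_r, function(i) c(i, mirror(i)))

  tri_area <- function(a, b, c)
    abs((b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])) / 2
  lobed <- 2 * sum(vapply(seq_len(k), function(j) {
    tri_area(apex_xy[j, ], sinus_xy[j, ], upper_xy[j, ])
  }, numeric(1)))
  structure(list(outline = outline, base = base, tip = tip,
                 apex_indices = apex_indices, concave_pairs = concave_pairs,
                 analytic = list(V = shoelace_area(outline),
                                 lobed_area = lobed,
                                 L1 = spec$notch_position, L2 = 1),
                 spec = spec),
            class = "leaf_shape")
}

#' Lobed-area ratio R
#'
#' `R = V / (V + lobed_area) * 100`, where V is the actual blade area and the
#' lobed area is the area missing between the outline and the chords closing
#' each marginal sinus. R = 100 exactly when the leaf is unlobed.
#'
#' @param V actual leaflet area, > 0.
#' @param lobed_area total lobed (cut-out) area, >= 0.
#' @return percent in (0, 100].
#' @export
compute_R <- function(V, lobed_area) {
  if (!is.numeric(V) || any(V <= 0)) stop("V must be positive")
  if (any(lobed_area < 0)) stop("lobed_area must be non-negative")
  V / (V + lobed_area) * 100
}

#' Length ratio Q
#'
#' `Q = L1 / L2 * 100`, where L1 is the distance from the leaf base to the
#' point where the chord of the deepest concave-point pair crosses the main
#' vein and L2 is the base-to-tip distance.
#'
#' @param L1,L2 lengths with `0 < L1 <= L2`.
#' @return percent in (0, 100].
#' @export
compute_Q <- function(L1, L2) {
  if (any(L1 <= 0)) stop("L1 must be positive")
  if (any(L1 > L2)) stop("L1 cannot exceed L2 (inconsistent landmarks)")
  L1 / L2 * 100
}

# Intersection of segment p1-p2 with segment q1-q2; NULL if none.
segment_intersection <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-14) return(NULL)
  t <- ((q1[1] - p1[1]) * d2[2] - (q1[2] - p1[2]) * d2[1]) / den
  u <- ((q1[1] - p1[1]) * d1[2] - (q1[2] - p1[2]) * d1[1]) / den
  if (t < -1e-9 || t > 1 + 1e-9 || u < -1e-9 || u > 1 + 1e-9) return(NULL)
  p1 + t * d1
}

#' Measure blade area, lobed area and landmark lengths from a leaf polygon
#'
#' V is the shoelace area of the outline; the lobed area closes each annotated
#' concave vertex with the chord between its two polygon neighbours; L1 is
#' found by intersecting the chord of the deepest concave pair (largest total
#' chord-to-outline area) with the main vein (base to tip); L2 is the
#' base-to-tip distance.
#'
#' @param shape a `leaf_shape` (landmarks required).
#' @return list with `V`, `lobed_area`, `L1`, `L2`.
#' @export
measure_from_polygon <- function(shape) {
  stopifnot(inherits(shape, "leaf_shape"))
  if (is.null(shape$concave_pairs) || is.null(shape$tip) || is.null(shape$base))
    stop("landmarks (base, tip, concave_pairs) are required")
  xy <- shape$outline
  nv <- nrow(xy)
  V <- shoelace_area(xy)
  tri_area <- function(a, b, c)
    abs((b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])) / 2
  vertex_tri <- function(i) {
    prev <- if (i == 1L) nv else i - 1L
    nxt <- if (i == nv) 1L else i + 1L
    tri_area(xy[prev, ], xy[i, ], xy[nxt, ])
  }
  pair_area <- vapply(shape$concave_pairs,
                      function(p) sum(vapply(p, vertex_tri, numeric(1))),
                      numeric(1))
  lobed <- sum(pair_area)
  L2 <- sqrt(sum((xy[shape$tip, ] - xy[shape$base, ])^2))
  if (length(pair_area) == 0L || max(pair_area) == 0) {
    L1 <- L2      # unlobed leaf: the notch degenerates to the tip
  } else {
    deepest <- shape$concave_pairs[[which.max(pair_area)]]
    inter <- segment_intersection(xy[deepest[1L], ], xy[deepest[2L], ],
                                  xy[shape$base, ], xy[shape$tip, ])
    if (is.null(inter))
      stop(sprintf("concave-pair chord (%d, %d) does not cross the main vein",
                   deepest[1L], deepest[2L]))
    L1 <- sqrt(sum((inter - xy[shape$base, ])^2))
  }
  list(V = V, lobed_area = lobed, L1 = L1, L2 = L2)
}

# Circular local maxima of a radial profile with a prominence floor.
radial_peaks <- function(r, min_prominence) {
  n <- length(r)
  nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1L))
  cand <- which(r > r[prv] & r >= r[nxt])   # left-strict to split plateaus
  keep <- logical(length(cand))
  for (ci in seq_along(cand)) {
    i <- cand[ci]
    lo_l <- r[i]; j <- i
    repeat {
      j <- if (j == 1L) n else j - 1L
      if (j == i) { lo_l <- min(r); break }
      if (r[j] > r[i]) break
      lo_l <- min(lo_l, r[j])
    }
    lo_r <- r[i]; j <- i
    repeat {
      j <- if (j == n) 1L else j + 1L
      if (j == i) { lo_r <- min(r); break }
      if (r[j] > r[i]) break
      lo_r <- min(lo_r, r[j])
    }
    keep[ci] <- (r[i] - max(lo_l, lo_r)) >= min_prominence
  }
  cand[keep]
}

#' Count margin apexes of a leaf outline
#'
#' Uses the annotated apex set when present; otherwise counts strict local
#' maxima of the vertex distance from the outline centroid, requiring a
#' prominence of at least 1% of the base-to-tip length (or of the maximum
#' radius when base/tip landmarks are absent) to suppress discretization
#' noise.
#'
#' @param shape a `leaf_shape`, or any list with an `outline` matrix.
#' @return integer apex count.
#' @export
count_apexes <- function(shape) {
  if (!is.null(shape$apex_indices)) return(length(shape$apex_indices))
  xy <- shape$outline
  ctr <- colMeans(xy)
  r <- sqrt((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2)
  scale_len <- if (!is.null(shape$tip) && !is.null(shape$base))
    sqrt(sum((xy[shape$tip, ] - xy[shape$base, ])^2)) else max(r)
  length(radial_peaks(r, 0.01 * scale_len))
}

#' Chi-square goodness-of-fit test for a two-class segregation ratio
#'
#' One-degree-of-freedom chi-square test (no continuity correction) of
#' observed class counts against an expected ratio, as used for the 1:1
#' lobed : ovate segregation test in an RIL population.
#'
#' @param class_counts integer vector of two class counts.
#' @param expected_ratio expected ratio (default `c(1, 1)`).
#' @return list with `chi2` and `p`.
#' @export
segregation_fit <- function(class_counts, expected_ratio = c(1, 1)) {
  if (length(class_counts) != 2L || length(expected_ratio) != 2L)
    stop("exactly two classes are expected")
  total <- sum(class_counts)
  if (total <= 0) stop("total count must be positive")
  expd <- total * expected_ratio / sum(expected_ratio)
  chi2 <- sum((class_counts - expd)^2 / expd)
  list(chi2 = chi2, p = chisq_1df_p(chi2))
}

#' Phenotype a set of leaf shapes
#'
#' @param shapes list of `leaf_shape` objects (optionally named by line).
#' @return data.frame with `line_id`, `NA` (apex count), `R`, `Q`.
#' @export
leaf_phenotypes <- function(shapes) {
  ids <- names(shapes) %||% sprintf("leaf%03d", seq_along(shapes))
  rows <- lapply(seq_along(shapes), function(i) {
    m <- measure_from_polygon(shapes[[i]])
    data.frame(line_id = ids[i],
               apex_count = count_apexes(shapes[[i]]),
               R = compute_R(m$V, m$lobed_area),
               Q = compute_Q(m$L1, m$L2))
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "apex_count"] <- "NA"
  out
}
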