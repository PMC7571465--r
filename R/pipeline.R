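#' Run the whole mapping pipeline on simulated or user data
#'
#' Stages: (optional) simulation, bin genotyping, map construction, phenotype
#' assembly and ICIM QTL scanning of each requested trait; all stage outputs
#' are written as commented TSV under `out_dir` and a reconciliation report
#' (records in/out per stage) is returned.
#'
#' @param config list with entries `sim` (a [sim_config()]; or `NULL` when
#'   `snp_path` is given), `snp_path`/`pheno_path` for user data,
#'   `parent_names`, `genotyper` (a [genotyper_params()]), `scan`
#'   (a [scan_params()]), `traits` (character subset of `c("NA","R","Q")`),
#'   `out_dir`, `seed`.
#' @return list (class `ril_pipeline`) with the stage objects, QTL tables and
#'   the report; files under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% tempfile("rilmap_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gpar <- config$genotyper %||% genotyper_params()
  spar <- config$scan %||% scan_params(seed = seed)
  traits <- config$traits %||% c("NA", "R", "Q")

  if (!is.null(config$snp_path)) {
    calls <- read_snp_calls(config$snp_path,
                            config$parent_names %||% c("P1", "P2"))
    pheno <- if (!is.null(config$pheno_path)) read_pheno_tsv(config$pheno_path)
             else stop("pheno_path required when running from user SNP calls")
    sim <- NULL
  } else {
    sim_cfg <- config$sim %||% sim_config(seed = seed)
    sim <- simulate_ril_study(sim_cfg)
    calls <- sim$calls
    pheno <- sim$phenotypes
    write_geno_tsv(calls, file.path(out_dir, "snp_calls.tsv"), seed = seed)
    write_pheno_tsv(pheno, file.path(out_dir, "phenotypes.tsv"), seed = seed)
  }

  message(sprintf("[genotype] %d lines x %d SNPs in", nrow(calls$geno),
                  ncol(calls$geno)))
  bins <- genotype_bins(calls, gpar)
  report <- attr(bins, "report")
  message(sprintf("[genotype] %d lines, %d bins out (of %d raw)",
                  report$n_lines_used, report$n_bins_kept, report$n_bins_raw))
  write_bin_tsv(bins, file.path(out_dir, "bins.tsv"), seed = seed,
                params = gpar[c("window_size", "window_threshold",
                                "min_depth", "min_bin_length")])

  map <- build_map(bins)
  write_map_tsv(map, file.path(out_dir, "map.tsv"), seed = seed)
  smry <- map_summary(map)
  write_tsv_with_header(smry, file.path(out_dir, "map_summary.tsv"),
                        seed = seed)
  message(sprintf("[map] %d markers, %.2f cM total",
                  smry$n_markers[nrow(smry)], smry$total_cM[nrow(smry)]))

  # align phenotype rows with the (line-filtered) bin set; drop mixed lines
  rows <- match(bins$line_ids, pheno$line_id)
  if (anyNA(rows)) stop("phenotype table lacks some genotyped lines")
  pheno_used <- pheno[rows, , drop = FALSE]
  if ("class" %in% names(pheno_used)) {
    keep <- pheno_used$class != "mixed"
  } else keep <- rep(TRUE, nrow(pheno_used))

  scans <- list()
  qtl_all <- list()
  for (tr in intersect(traits, names(pheno_used))) {
    y <- as.numeric(pheno_used[[tr]])
    use <- keep & !is.na(y)
    sub_bins <- bins
    sub_bins$geno <- bins$geno[use, , drop = FALSE]
    sub_bins$line_ids <- bins$line_ids[use]
    sc <- icim_scan(map, sub_bins, y[use], spar, trait = tr)
    scans[[tr]] <- sc
    if (nrow(sc$qtl) > 0L) qtl_all[[tr]] <- sc$qtl
    message(sprintf("[qtl] trait %s: threshold %.2f, %d QTL", tr,
                    sc$threshold, nrow(sc$qtl)))
  }
  qtl <- if (length(qtl_all) > 0L) do.call(rbind, qtl_all)
         else call_qtl(data.frame(lg = character(0), pos_cM = numeric(0),
                                  lod = numeric(0), additive = numeric(0),
                                  pve = numeric(0)), Inf, map, bins)
  write_qtl_tsv(qtl, file.path(out_dir, "qtl.tsv"), seed = seed,
                params = spar[c("step_cM", "pin", "n_permutations", "alpha")])

  structure(list(sim = sim, calls = calls, bins = bins, map = map,
                 phenotypes = pheno, scans = scans, qtl = qtl,
                 report = report, out_dir = out_dir, seed = seed),
            class = "ril_pipeline")
}

#' @exportS3Method base::print
print.ril_pipeline <- function(x, ...) {
  cat("ril_pipeline run\n")
  cat(sprintf("  bins: %d, lines: %d\n", nrow(x$bins$bins),
              nrow(x$bins$geno)))
  cat(sprintf("  map: %.2f cM\n",
              map_summary(x$map)$total_cM[length(x$map$groups) + 1L]))
  cat(sprintf("  QTL called: %d (outputs in %s)\n", nrow(x$qtl), x$out_dir))
  invisible(x)
}
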