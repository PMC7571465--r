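# File formats: VCF (GT:DP) and TSV genotype matrices in, TSV tables out.
# All internal bp coordinates are 1-based inclusive (as in VCF); BED exports
# are 0-based half-open. On-disk genotype codes: A = parent-1 homozygote,
# H = heterozygote, B = parent-2 homozygote, "-" = missing.

#' Write a data.frame as TSV with a commented provenance header
#'
#' Every pipeline output file starts with comment lines carrying the package
#' version and, when given, the seed and key parameters; files are written in
#' binary mode so identical inputs give byte-identical files.
#'
#' @param df data.frame to write.
#' @param path file path.
#' @param seed,params recorded in the header.
#' @return the path, invisibly.
#' @export
write_tsv_with_header <- function(df, path, seed = NULL, params = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(output_header(seed, params), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0L) {
    rows <- do.call(paste, c(lapply(df, function(col) {
      if (is.numeric(col) && !is.integer(col)) format(col, trim = TRUE,
                                                      scientific = FALSE)
      else as.character(col)
    }), sep = "\t"))
    writeLines(rows, con)
  }
  invisible(path)
}

output_header <- function(seed = NULL, params = NULL) {
  ver <- as.character(utils::packageVersion("rilmap"))
  h <- sprintf("# rilmap %s", ver)
  if (!is.null(seed)) h <- c(h, sprintf("# seed: %s", seed))
  if (!is.null(params))
    h <- c(h, sprintf("# params: %s",
                      paste(names(params), unlist(params), sep = "=",
                            collapse = "; ")))
  h
}

read_tsv_skip_comments <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read SNP calls from a VCF or TSV genotype file
#'
#' VCF input needs GT and DP in FORMAT and the two parents as named samples;
#' positions are 1-based as in the standard. Multi-allelic and indel records
#' are skipped (counts attached as attribute `"skipped"`). The TSV dialect is
#' the one written by [write_geno_tsv()].
#'
#' @param path input file (`.vcf` or `.tsv`).
#' @param parent_names length-2 character vector naming the parent samples.
#' @return a `snp_callset`.
#' @export
read_snp_calls <- function(path, parent_names = c("P1", "P2")) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE))
    read_snp_vcf(path, parent_names)
  else
    read_geno_tsv(path, parent_names)
}

read_snp_vcf <- function(path, parent_names) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fmt <- v@gt[1L, "FORMAT"]
  if (!grepl("DP", fmt))
    stop("VCF lacks the DP field; use the TSV genotype matrix instead")
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  keep <- nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
    !grepl(",", fix[, "ALT"], fixed = TRUE)
  n_skipped <- sum(!keep)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)[keep, , drop = FALSE]
  samples <- colnames(gt)
  if (!all(parent_names %in% samples))
    stop(sprintf("parent sample(s) missing from VCF: %s",
                 paste(setdiff(parent_names, samples), collapse = ", ")))
  code <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_integer_, length(g))
    out[g == "0/0"] <- GENO_AA
    out[g %in% c("0/1", "1/0")] <- GENO_AB
    out[g == "1/1"] <- GENO_BB
    out
  }
  gm <- apply(gt, 2L, code)
  dp[is.na(dp)] <- 0
  lines <- setdiff(samples, parent_names)
  snps <- data.frame(chrom = as.integer(sub("^chr", "", fix[keep, "CHROM"])),
                     pos_bp = as.numeric(fix[keep, "POS"]),
                     id = fix[keep, "ID"],
                     parent1 = code(gt[, parent_names[1L]]),
                     parent2 = code(gt[, parent_names[2L]]))
  snps$pos_cM <- NA_real_
  structure(list(snps = snps,
                 geno = t(gm[, lines, drop = FALSE]),
                 depth = t(dp[, lines, drop = FALSE]),
                 line_ids = lines),
            class = "snp_callset",
            skipped = n_skipped)
}

#' Write a call set as a minimal VCF (GT:DP, parents first)
#'
#' @param callset a `snp_callset`.
#' @param path output file.
#' @param parent_names sample names for the two parents.
#' @return the path, invisibly.
#' @export
write_snp_vcf <- function(callset, path, parent_names = c("P1", "P2")) {
  gt_str <- function(g) c("0/0", "0/1", "1/1")[g]
  fmt_col <- function(g, d) {
    s <- ifelse(is.na(g), "./.", gt_str(pmax(g, 1L)))
    paste0(s, ":", d)
  }
  snps <- callset$snps
  m <- nrow(snps)
  body <- cbind(snps$chrom, format(snps$pos_bp, trim = TRUE, scientific = FALSE),
                snps$id, "A", "T", ".", "PASS", ".", "GT:DP",
                fmt_col(snps$parent1, snps$parent1_depth %||% rep(99L, m)),
                fmt_col(snps$parent2, snps$parent2_depth %||% rep(99L, m)))
  for (li in seq_len(nrow(callset$geno)))
    body <- cbind(body, fmt_col(callset$geno[li, ], callset$depth[li, ]))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", parent_names, callset$line_ids),
                     collapse = "\t")), con)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Write/read a TSV genotype matrix
#'
#' Rows are SNPs (`chrom`, `pos_bp`, `id`, parent calls), columns after them
#' are lines; genotype codes A/H/B/- on disk.
#'
#' @param callset a `snp_callset`.
#' @param path file path.
#' @param seed optional seed recorded in the header.
#' @return the path ([write_geno_tsv()]) or a `snp_callset`
#'   ([read_geno_tsv()]).
#' @export
write_geno_tsv <- function(callset, path, seed = NULL) {
  df <- data.frame(chrom = callset$snps$chrom,
                   pos_bp = callset$snps$pos_bp,
                   id = callset$snps$id,
                   parent1 = geno_to_char(callset$snps$parent1),
                   parent2 = geno_to_char(callset$snps$parent2),
                   check.names = FALSE)
  for (li in seq_along(callset$line_ids))
    df[[callset$line_ids[li]]] <- geno_to_char(callset$geno[li, ])
  write_tsv_with_header(df, path, seed = seed)
}

#' @rdname write_geno_tsv
#' @param parent_names ignored for TSV (parent calls are dedicated columns);
#'   kept for interface symmetry.
#' @export
read_geno_tsv <- function(path, parent_names = NULL) {
  df <- read_tsv_skip_comments(path)
  line_cols <- setdiff(names(df), c("chrom", "pos_bp", "id", "parent1",
                                    "parent2"))
  geno <- t(vapply(line_cols, function(cn) char_to_geno(df[[cn]]),
                   integer(nrow(df))))
  rownames(geno) <- line_cols
  snps <- data.frame(chrom = df$chrom, pos_bp = df$pos_bp, id = df$id,
                     parent1 = char_to_geno(df$parent1),
                     parent2 = char_to_geno(df$parent2))
  structure(list(snps = snps, geno = geno,
                 depth = matrix(Inf, nrow(geno), ncol(geno)),
                 line_ids = line_cols),
            class = "snp_callset")
}

#' Write a bin-marker genotype table
#'
#' @param binset a `bin_set`.
#' @param path file path.
#' @param seed,params recorded in the comment header.
#' @return the path, invisibly.
#' @export
write_bin_tsv <- function(binset, path, seed = NULL, params = NULL) {
  df <- binset$bins
  for (li in seq_along(binset$line_ids))
    df[[binset$line_ids[li]]] <- geno_to_char(binset$geno[li, ])
  write_tsv_with_header(df, path, seed = seed, params = params)
}

#' @rdname write_bin_tsv
#' @export
read_bin_tsv <- function(path) {
  df <- read_tsv_skip_comments(path)
  meta <- c("id", "chrom", "start_bp", "end_bp", "n_snps")
  line_cols <- setdiff(names(df), meta)
  geno <- t(vapply(line_cols, function(cn) char_to_geno(df[[cn]]),
                   integer(nrow(df))))
  rownames(geno) <- line_cols
  colnames(geno) <- df$id
  structure(list(bins = df[, meta], geno = geno, line_ids = line_cols),
            class = "bin_set")
}

#' Write a genetic map as TSV (cM to 4 decimal places)
#'
#' @param map a `genetic_map`.
#' @param path file path.
#' @param seed recorded in the comment header.
#' @return the path, invisibly.
#' @export
write_map_tsv <- function(map, path, seed = NULL) {
  df <- do.call(rbind, lapply(names(map$groups), function(gn) {
    g <- map$groups[[gn]]
    data.frame(marker = g$marker, lg = paste0("LG", gn),
               cM = sprintf("%.4f", g$pos_cM), chrom = g$chrom,
               start_bp = g$start_bp, end_bp = g$end_bp)
  }))
  write_tsv_with_header(df, path, seed = seed)
}

#' Write/read a phenotype table
#'
#' @param pheno a `phenotype_table` (or any data.frame with `line_id`).
#' @param path file path.
#' @param seed recorded in the comment header.
#' @return the path / the phenotype data.frame.
#' @export
write_pheno_tsv <- function(pheno, path, seed = NULL) {
  df <- as.data.frame(pheno, check.names = FALSE)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.6g", x))
  write_tsv_with_header(df, path, seed = seed)
}

#' @rdname write_pheno_tsv
#' @export
read_pheno_tsv <- function(path) {
  read_tsv_skip_comments(path)
}

#' Write QTL results (Table-2 style: LOD and PVE to 2 decimal places)
#'
#' @param qtl QTL table from [call_qtl()] / [icim_scan()].
#' @param path file path.
#' @param seed,params recorded in the comment header.
#' @return the path, invisibly.
#' @export
write_qtl_tsv <- function(qtl, path, seed = NULL, params = NULL) {
  df <- qtl
  for (cn in c("lod", "pve", "threshold"))
    if (cn %in% names(df)) df[[cn]] <- sprintf("%.2f", df[[cn]])
  for (cn in c("peak_cM", "ci_lo_cM", "ci_hi_cM", "additive"))
    if (cn %in% names(df)) df[[cn]] <- sprintf("%.4f", df[[cn]])
  write_tsv_with_header(df, path, seed = seed, params = params)
}

#' Export true haplotype breakpoints as BED-like TSV (0-based half-open)
#'
#' @param pop a `true_population`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_breakpoints_bed <- function(pop, path) {
  cfg <- pop$config
  rows <- list()
  for (li in seq_along(pop$haplotypes)) {
    for (cc in seq_len(cfg$n_chromosomes)) {
      for (hi in 1:2) {
        h <- pop$haplotypes[[li]][[cc]][[hi]]
        bnd_cM <- c(0, h$breaks, cfg$chrom_lengths_cM[cc])
        bnd_bp <- round(bnd_cM / cfg$chrom_lengths_cM[cc] *
                          cfg$chrom_lengths_bp[cc])
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = cc,
          start = bnd_bp[-length(bnd_bp)],          # 0-based half-open
          end = bnd_bp[-1L],
          name = sprintf("%s_hap%d_P%d", pop$line_ids[li], hi, h$origins))
      }
    }
  }
  df <- do.call(rbind, rows)
  write_tsv_with_header(df, path)
}

#' Write/read leaf shapes as JSON polygon + landmark records
#'
#' @param shapes list of `leaf_shape` objects.
#' @param path file path.
#' @return the path / the list of shapes.
#' @export
write_leaf_json <- function(shapes, path) {
  recs <- lapply(shapes, function(s) list(
    outline = unname(apply(s$outline, 1L, as.numeric, simplify = FALSE)),
    base = s$base, tip = s$tip, apex_indices = s$apex_indices,
    concave_pairs = s$concave_pairs,
    analytic = s$analytic))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_leaf_json
#' @export
read_leaf_json <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(recs, function(r) structure(list(
    outline = do.call(rbind, lapply(r$outline, unlist)),
    base = r$base, tip = r$tip,
    apex_indices = unlist(r$apex_indices),
    concave_pairs = lapply(r$concave_pairs, unlist),
    analytic = lapply(r$analytic, unlist)), class = "leaf_shape"))
}
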