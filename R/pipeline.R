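# Pipeline driver and plot-coordinate generation (Manhattan, Q-Q).
# The package's functions are the interface; `run_pipeline()` chains
# read -> pre-filter -> scan -> post-filter -> multiplicity -> plot data
# and writes all artifacts as TSV plus a JSON run log.

#' Linear Manhattan-plot coordinates
#'
#' Concatenates chromosomes 1-29 then X onto one linear axis: the
#' x-coordinate of a SNP on chromosome k is its position plus the sum of
#' the most terminal SNP positions of all preceding chromosomes.
#'
#' @param scan Scan table (post-filtered) with \code{chrom},
#'   \code{pos_bp} and \code{neglog10_mid_p}.
#' @return data.frame: \code{chrom}, \code{pos_bp}, \code{snp_id},
#'   \code{x}, \code{y} (-log10 mid-p) plus the input's remaining
#'   columns dropped; errors if excluded chromosome codes (0, 31, 32)
#'   are present.
#' @export
manhattan_coords <- function(scan) {
  if (any(scan$chrom %in% c(0L, 31L, 32L))) {
    stop("scan contains unmapped/Y/MT SNPs; apply post-filters first")
  }
  chroms <- sort(unique(scan$chrom))  # 1..29 then 30 (X)
  terminal <- vapply(chroms, function(k) max(scan$pos_bp[scan$chrom == k]),
                     numeric(1))
  offset <- c(0, cumsum(terminal))[seq_along(chroms)]
  names(offset) <- chroms
  data.frame(
    chrom = scan$chrom, pos_bp = scan$pos_bp, snp_id = scan$snp_id,
    model = if ("model" %in% names(scan)) scan$model else NA,
    x = scan$pos_bp + offset[as.character(scan$chrom)],
    y = scan$neglog10_mid_p,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full matched-pair association pipeline
#'
#' Reads ped/map files (or generates a synthetic dataset from a
#' \code{sim_config}), applies the pre-association SNP filters, runs the
#' six-scenario McNemar scan, applies the post-association removals,
#' computes Storey q-values per scenario set, and writes scan, q-value,
#' Manhattan and Q-Q coordinate TSVs, the filter report and a JSON run
#' log into \code{out_dir}. All randomness (pi0 bootstrap) derives from
#' \code{seed}, making reruns byte-identical.
#'
#' @param ped,map Paths to input files (ignored when \code{config}
#'   given).
#' @param config Optional \code{sim_config} for a synthetic run.
#' @param out_dir Output directory (created if absent).
#' @param maf_min,geno_max,hwe_min Pre-filter thresholds.
#' @param alpha Level for the Bonferroni threshold.
#' @param seed Seed for the q-value bootstrap.
#' @return Invisibly, a list with the filtered matrix, scan table,
#'   reports and q-value sets.
#' @export
run_pipeline <- function(ped = NULL, map = NULL, config = NULL,
                         out_dir, maf_min = 0.05, geno_max = 0.05,
                         hwe_min = 1e-4, alpha = 0.05, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage [", name, "]: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  x <- stage("input", {
    if (!is.null(config)) generate_pairs(config)
    else read_ped(ped, read_map(map))
  })
  pre <- stage("pre-filter", apply_pre_filters(x, maf_min, geno_max,
                                               hwe_min))
  scan <- stage("scan", run_genome_scan(pre$matrix))
  post <- stage("post-filter", apply_post_filters(scan))
  scan <- post$scan
  bonf <- bonferroni_threshold(alpha, length(unique(scan$snp_id)))
  set.seed(seed)
  qsets <- stage("multiplicity", {
    by_sc <- split(scan, list(scan$allele, scan$model), drop = TRUE)
    lapply(by_sc, function(s) {
      s <- s[!is.na(s$mid_p), , drop = FALSE]
      if (nrow(s) == 0L) return(NULL)
      qs <- qvalue_set(s$mid_p, method = "bootstrap")
      data.frame(snp_id = s$snp_id, allele = s$allele, model = s$model,
                 mid_p = s$mid_p, q_bootstrap = qs$q_values,
                 pi0_bootstrap = qs$pi0, stringsAsFactors = FALSE)
    })
  })
  qtab <- do.call(rbind, qsets)
  rownames(qtab) <- NULL
  man <- stage("manhattan", manhattan_coords(scan))
  qq <- stage("qq", {
    two <- scan[scan$allele == "a1" & scan$model == "two_copy", ]
    qq_coords(two$mid_p, two$b + two$c)
  })
  write_tsv(scan, file.path(out_dir, "scan.tsv"))
  write_tsv(qtab, file.path(out_dir, "qvalues.tsv"))
  write_tsv(man, file.path(out_dir, "manhattan.tsv"))
  write_tsv(qq, file.path(out_dir, "qq.tsv"))
  report <- list(
    pre_filter = unclass(pre$report)[1:6],
    post_filter = unclass(post$report)[1:6],
    n_snps_tested = length(unique(scan$snp_id)),
    bonferroni_neglog10 = bonf$neglog10,
    seed = seed,
    params = list(maf_min = maf_min, geno_max = geno_max,
                  hwe_min = hwe_min, alpha = alpha),
    r_version = as.character(getRversion())
  )
  jsonlite::write_json(report, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(matrix = pre$matrix, scan = scan,
                 pre_report = pre$report, post_report = post$report,
                 qvalues = qtab, bonferroni = bonf,
                 manhattan = man, qq = qq))
}
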