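#' Extract the shape-feature table for a whole cohort
#'
#' Reads every volume referenced by the manifest, optionally applies
#' largest-component post-processing, and computes the 14 shape features for
#' each requested region. Volumes with an empty region yield `NA` features
#' for that region (with a warning).
#'
#' @param manifest Manifest data frame (or path to the manifest CSV) with
#'   columns `subject_id`, `scan_id`, `method_id`, `path`.
#' @param postprocess Apply [postprocess_label_volume()] before extraction.
#' @param regions Regions to extract (default all three).
#' @param connectivity Connectivity for post-processing.
#' @return Data frame: one row per (subject, scan, method, region) with the
#'   14 feature columns.
#' @export
extract_features_cohort <- function(manifest, postprocess = TRUE,
                                    regions = REGIONS, connectivity = 26) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  rows <- vector("list", nrow(manifest) * length(regions))
  k <- 0L
  for (i in seq_len(nrow(manifest))) {
    lv <- read_label_volume(manifest$path[i], manifest$subject_id[i],
                            manifest$scan_id[i], manifest$method_id[i])
    if (postprocess)
      lv <- suppressWarnings(postprocess_label_volume(lv, connectivity))
    for (reg in regions) {
      m <- extract_region(lv, reg)
      feats <- if (any(m$voxels)) {
        suppressWarnings(extract_features(m))
      } else {
        warning("empty region ", reg, " for ", manifest$subject_id[i], "/",
                manifest$scan_id[i], "/", manifest$method_id[i],
                call. = FALSE)
        setNames(rep(NA_real_, length(FEATURE_NAMES)), FEATURE_NAMES)
      }
      k <- k + 1L
      rows[[k]] <- cbind(
        data.frame(subject_id = manifest$subject_id[i],
                   scan_id = manifest$scan_id[i],
                   method_id = manifest$method_id[i],
                   region = reg, stringsAsFactors = FALSE),
        as.data.frame(as.list(feats)))
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

# n x 2 (scan1, scan2) matrix of one feature for one region/method
feature_scan_matrix <- function(feature_table, region, method, feature) {
  ft <- feature_table[feature_table$region == region &
                        feature_table$method_id == method, ]
  s1 <- ft[ft$scan_id == "scan1", c("subject_id", feature)]
  s2 <- ft[ft$scan_id == "scan2", c("subject_id", feature)]
  mrg <- merge(s1, s2, by = "subject_id", suffixes = c("_1", "_2"))
  mrg <- mrg[order(mrg$subject_id), ]
  m <- as.matrix(mrg[, c(paste0(feature, "_1"), paste0(feature, "_2"))])
  rownames(m) <- mrg$subject_id
  colnames(m) <- c("scan1", "scan2")
  m
}

#' ICC table for every (region, method, feature) combination
#'
#' @param feature_table Output of [extract_features_cohort()].
#' @param features Feature names (default all 14).
#' @return Data frame keyed by (region, method, feature) with `icc`,
#'   `ci_low`, `ci_high`, `n`.
#' @export
icc_table <- function(feature_table, features = FEATURE_NAMES) {
  grid <- expand.grid(region = unique(feature_table$region),
                      method_id = unique(feature_table$method_id),
                      feature = features, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    m <- feature_scan_matrix(feature_table, grid$region[i],
                             grid$method_id[i], grid$feature[i])
    m <- m[complete.cases(m), , drop = FALSE]
    if (nrow(m) < 3)
      return(data.frame(grid[i, ], icc = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, n = nrow(m)))
    r <- suppressWarnings(icc_two_way_random_single(m))
    data.frame(grid[i, ], icc = r$icc, ci_low = r$ci_low,
               ci_high = r$ci_high, n = r$n_subjects)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Run the full reproducibility analysis
#'
#' Orchestrates the pipeline on a paired two-scan cohort: loads every
#' labelled volume, optionally applies largest-component post-processing,
#' extracts the 14 shape features per region, and computes the report
#' tables: per-feature ICC(2,1) with 95% CI, DSC summaries of every method
#' against the reference, volume comparisons (median percent difference
#' between scans, paired Wilcoxon with Benjamini-Hochberg correction),
#' Bland-Altman parameters with Spearman correlation, CI-overlap
#' significance versus the reference method, and (when quality scores are
#' available and `qc_threshold` is set) the quality-filter permutation test.
#'
#' @param manifest Manifest data frame or path to the manifest CSV.
#' @param postprocess Apply largest-component post-processing (default TRUE).
#' @param qc_threshold Quality-score exclusion threshold, or `NULL` (default)
#'   to skip quality filtering.
#' @param qc_feature Feature used for the quality-filter permutation test.
#' @param qc_runs Permutation runs (default 1000).
#' @param regions Regions analysed.
#' @param reference Reference method for DSC and CI-overlap comparisons.
#' @param bh_family `"per_region"` (default) adjusts Wilcoxon p-values
#'   within each region's table; `"pooled"` adjusts across all of them.
#' @param connectivity Post-processing connectivity (default 26).
#' @param seed Seed for the permutation tests.
#' @return An object of class `analysis_report`: list of tables
#'   `feature_table`, `icc`, `dsc_summary`, `volume_comparison`,
#'   `bland_altman`, `significance_vs_reference`, `qc_results`, and
#'   `provenance`.
#' @export
run_analysis <- function(manifest, postprocess = TRUE, qc_threshold = NULL,
                         qc_feature = "voxel_volume", qc_runs = 1000,
                         regions = REGIONS, reference = "manual",
                         bh_family = c("per_region", "pooled"),
                         connectivity = 26, seed = 1) {
  bh_family <- match.arg(bh_family)
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  manifest <- manifest[order(manifest$subject_id, manifest$scan_id,
                             manifest$method_id), ]
  methods <- sort(unique(manifest$method_id))
  if (!reference %in% methods)
    stop("reference method '", reference, "' not present in manifest")

  # complete-pair check: both scans for every method
  counts <- table(manifest$subject_id)
  expected <- 2L * length(methods)
  bad <- names(counts)[counts != expected]
  if (length(bad)) {
    warning("excluding subjects with incomplete scan/method pairs: ",
            paste(bad, collapse = ", "), call. = FALSE)
    manifest <- manifest[!manifest$subject_id %in% bad, ]
  }

  # one pass per (subject, scan): features for all methods + DSC vs reference
  feat_rows <- list(); dsc_rows <- list()
  keys <- unique(manifest[, c("subject_id", "scan_id")])
  for (i in seq_len(nrow(keys))) {
    sub <- keys$subject_id[i]; scan <- keys$scan_id[i]
    rows_i <- manifest[manifest$subject_id == sub &
                         manifest$scan_id == scan, ]
    vols <- list()
    for (j in seq_len(nrow(rows_i))) {
      lv <- read_label_volume(rows_i$path[j], sub, scan,
                              rows_i$method_id[j])
      if (postprocess)
        lv <- suppressWarnings(postprocess_label_volume(lv, connectivity))
      vols[[rows_i$method_id[j]]] <- lv
    }
    for (m in names(vols)) {
      for (reg in regions) {
        mask <- extract_region(vols[[m]], reg)
        feats <- if (any(mask$voxels)) {
          suppressWarnings(extract_features(mask))
        } else setNames(rep(NA_real_, length(FEATURE_NAMES)), FEATURE_NAMES)
        feat_rows[[length(feat_rows) + 1L]] <- cbind(
          data.frame(subject_id = sub, scan_id = scan, method_id = m,
                     region = reg, stringsAsFactors = FALSE),
          as.data.frame(as.list(feats)))
        if (m != reference && reference %in% names(vols)) {
          ref_mask <- extract_region(vols[[reference]], reg)
          d <- if (any(mask$voxels) || any(ref_mask$voxels))
            dsc(ref_mask, mask) else NA_real_
          dsc_rows[[length(dsc_rows) + 1L]] <- data.frame(
            subject_id = sub, scan_id = scan, method_id = m, region = reg,
            dsc = d, stringsAsFactors = FALSE)
        }
      }
    }
  }
  feature_table <- do.call(rbind, feat_rows)
  dsc_table <- if (length(dsc_rows)) do.call(rbind, dsc_rows) else NULL

  # optional quality filtering for the main tables
  qc_results <- NULL
  analysis_table <- feature_table
  if (!is.null(qc_threshold) && "quality_score" %in% names(manifest)) {
    qc_results <- qc_permutation_table(feature_table, manifest, methods,
                                       reference, regions, qc_threshold,
                                       qc_feature, qc_runs, seed)
  }

  icc <- icc_table(analysis_table)

  dsc_summary <- NULL
  if (!is.null(dsc_table)) {
    dsc_summary <- aggregate(dsc ~ region + method_id + scan_id, dsc_table,
                             function(v) c(median = median(v, na.rm = TRUE),
                                           iqr = IQR(v, na.rm = TRUE)))
    dsc_summary <- cbind(dsc_summary[, 1:3],
                         as.data.frame(dsc_summary$dsc))
  }

  volume_comparison <- volume_comparison_table(analysis_table, bh_family)
  ba <- bland_altman_table(analysis_table, reference)
  sig <- compare_methods_table(icc, reference)

  provenance <- list(
    seed = seed, postprocess = postprocess, qc_threshold = qc_threshold,
    reference = reference, bh_family = bh_family,
    connectivity = connectivity,
    n_subjects = length(unique(feature_table$subject_id)),
    methods = methods,
    package_version = as.character(utils::packageVersion("maskrepro")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  structure(list(feature_table = feature_table, icc = icc,
                 dsc_table = dsc_table, dsc_summary = dsc_summary,
                 volume_comparison = volume_comparison, bland_altman = ba,
                 significance_vs_reference = sig, qc_results = qc_results,
                 provenance = provenance),
            class = "analysis_report")
}

volume_comparison_table <- function(feature_table, bh_family = "per_region") {
  grid <- unique(feature_table[, c("region", "method_id")])
  res <- lapply(seq_len(nrow(grid)), function(i) {
    m <- feature_scan_matrix(feature_table, grid$region[i],
                             grid$method_id[i], "voxel_volume")
    m <- m[complete.cases(m) & m[, 1] > 0, , drop = FALSE]
    if (nrow(m) < 5)
      return(data.frame(grid[i, ], n = nrow(m),
                        percent_median_difference = NA_real_,
                        wilcoxon_p = NA_real_))
    data.frame(grid[i, ], n = nrow(m),
               percent_median_difference =
                 percent_median_difference(m[, 1], m[, 2]),
               wilcoxon_p = tryCatch(
                 suppressWarnings(wilcoxon_signed_rank(m[, 1], m[, 2])),
                 error = function(e) NA_real_))
  })
  out <- do.call(rbind, res)
  out$bh_q <- NA_real_
  if (bh_family == "pooled") {
    ok <- !is.na(out$wilcoxon_p)
    out$bh_q[ok] <- bh_adjust(out$wilcoxon_p[ok])
  } else {
    for (reg in unique(out$region)) {
      ok <- out$region == reg & !is.na(out$wilcoxon_p)
      if (any(ok)) out$bh_q[ok] <- bh_adjust(out$wilcoxon_p[ok])
    }
  }
  rownames(out) <- NULL
  out
}

bland_altman_table <- function(feature_table, reference) {
  grid <- unique(feature_table[, c("region", "method_id")])
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    reg <- grid$region[i]; m <- grid$method_id[i]
    sm <- feature_scan_matrix(feature_table, reg, m, "voxel_volume")
    sm <- sm[complete.cases(sm), , drop = FALSE]
    if (nrow(sm) >= 3) {
      b <- bland_altman(sm[, 1], sm[, 2])
      sp <- suppressWarnings(spearman(sm[, 1], sm[, 2]))
      rows[[length(rows) + 1L]] <- data.frame(
        region = reg, comparison = paste0(m, ": scan2 - scan1"),
        bias = b$bias, loa_low = b$loa_low, loa_high = b$loa_high,
        spearman_rho = sp$rho, spearman_p = sp$p, n = b$n,
        stringsAsFactors = FALSE)
    }
    # method vs reference within each scan
    if (m != reference) {
      for (scan in c("scan1", "scan2")) {
        ft <- feature_table[feature_table$region == reg &
                              feature_table$scan_id == scan, ]
        a <- ft[ft$method_id == reference, c("subject_id", "voxel_volume")]
        d <- ft[ft$method_id == m, c("subject_id", "voxel_volume")]
        mg <- merge(a, d, by = "subject_id")
        mg <- mg[complete.cases(mg), ]
        if (nrow(mg) >= 3) {
          b <- bland_altman(mg[, 2], mg[, 3])
          sp <- suppressWarnings(spearman(mg[, 2], mg[, 3]))
          rows[[length(rows) + 1L]] <- data.frame(
            region = reg,
            comparison = paste0(m, " - ", reference, " (", scan, ")"),
            bias = b$bias, loa_low = b$loa_low, loa_high = b$loa_high,
            spearman_rho = sp$rho, spearman_p = sp$p, n = b$n,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

compare_methods_table <- function(icc_tab, reference) {
  others <- setdiff(unique(icc_tab$method_id), reference)
  rows <- list()
  for (reg in unique(icc_tab$region)) {
    for (m in others) {
      for (f in unique(icc_tab$feature)) {
        a <- icc_tab[icc_tab$region == reg & icc_tab$method_id == reference &
                       icc_tab$feature == f, ]
        b <- icc_tab[icc_tab$region == reg & icc_tab$method_id == m &
                       icc_tab$feature == f, ]
        if (nrow(a) != 1 || nrow(b) != 1 || is.na(a$icc) || is.na(b$icc))
          next
        sig <- a$ci_high < b$ci_low || b$ci_high < a$ci_low
        rows[[length(rows) + 1L]] <- data.frame(
          region = reg, method_id = m, feature = f,
          icc = b$icc, reference_icc = a$icc,
          significantly_different = sig,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

qc_permutation_table <- function(feature_table, manifest, methods, reference,
                                 regions, qc_threshold, qc_feature, qc_runs,
                                 seed) {
  rows <- list()
  for (m in setdiff(methods, reference)) {
    sc <- manifest[manifest$method_id == m, ]
    s1 <- sc[sc$scan_id == "scan1", c("subject_id", "quality_score")]
    s2 <- sc[sc$scan_id == "scan2", c("subject_id", "quality_score")]
    mg <- merge(s1, s2, by = "subject_id", suffixes = c("_1", "_2"))
    filt <- apply_quality_filter(mg$subject_id, mg$quality_score_1,
                                 mg$quality_score_2, qc_threshold)
    for (reg in regions) {
      tab <- feature_scan_matrix(feature_table, reg, m, qc_feature)
      tab <- tab[complete.cases(tab), , drop = FALSE]
      kept_tab <- tab[rownames(tab) %in% filt$kept, , drop = FALSE]
      n_exc <- nrow(tab) - nrow(kept_tab)
      if (nrow(kept_tab) < 3 || nrow(tab) - n_exc < 3) next
      icc_after <- suppressWarnings(
        icc_two_way_random_single(kept_tab)$icc)
      pt <- permutation_icc_test(tab, n_exc, icc_after, runs = qc_runs,
                                 seed = seed + length(rows))
      rows[[length(rows) + 1L]] <- data.frame(
        region = reg, method_id = m, feature = qc_feature,
        n_excluded = n_exc, observed_icc_after = icc_after,
        runs = pt$runs, n_ge = pt$n_ge, significant = pt$significant,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Compare every method's feature reproducibility to a reference method
#'
#' For each (region, feature) the method's ICC confidence interval is
#' compared with the reference method's; methods whose interval overlaps the
#' reference's are "comparable". The summary counts comparable features per
#' region and method (the "14/14 features" style of summary).
#'
#' @param report An `analysis_report` from [run_analysis()].
#' @param reference Reference method (default `"manual"`).
#' @return List with `per_feature` (data frame of verdicts) and `summary`
#'   (comparable-feature counts per region and method).
#' @export
compare_methods <- function(report, reference = "manual") {
  stopifnot(inherits(report, "analysis_report"))
  icc_tab <- report$icc
  if (is.null(icc_tab) || !nrow(icc_tab)) stop("report has no ICC table")
  if (!reference %in% icc_tab$method_id)
    stop("unknown reference method: ", reference)
  per_feature <- compare_methods_table(icc_tab, reference)
  if (is.null(per_feature) || !nrow(per_feature))
    stop("no comparable method/feature combinations in report")
  summary <- aggregate(
    cbind(comparable = !per_feature$significantly_different) ~
      region + method_id, per_feature, sum)
  summary$n_features <- aggregate(
    cbind(n = rep(1, nrow(per_feature))) ~ region + method_id,
    per_feature, sum)$n
  list(per_feature = per_feature, summary = summary)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("analysis_report:", x$provenance$n_subjects, "subjects,",
      length(x$provenance$methods), "methods\n")
  cat("  tables: icc (", nrow(x$icc), " rows), volume_comparison (",
      nrow(x$volume_comparison), " rows)\n", sep = "")
  invisible(x)
}

#' Write the report tables to a directory
#'
#' Writes each table as CSV plus a JSON bundle with provenance.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("feature_table", "icc", "dsc_table", "dsc_summary",
            "volume_comparison", "bland_altman",
            "significance_vs_reference", "qc_results")
  for (t in tabs) {
    if (!is.null(report[[t]]))
      write.csv(report[[t]], file.path(dir, paste0(t, ".csv")),
                row.names = FALSE)
  }
  jsonlite::write_json(
    list(provenance = report$provenance),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}
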