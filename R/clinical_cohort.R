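# Clinical cohort schema and summary statistics. The fixtures bundled under
# inst/extdata/ hold one record per affected individual (two cohorts, one per
# snRNA gene); every printed cohort summary -- onset medians, autoantibody
# positivity, feature fractions, the IUGR rule, distinct-allele counts, and
# the transcript<->genome coordinate anchors -- is recomputed from them,
# never hard-coded.
#
# Missing-data sentinels are kept distinct: "N/A" (not applicable) and "N/R"
# (not recorded) both parse to NA for numerics, but the original kind is kept
# in a companion "<col>_missing" column, and enum fields map them to
# "not_applicable" / "not_recorded".

CLINICAL_NUMERIC_COLS <- c("age_last_assessment_years", "bw_z", "age_dx_weeks",
                           "glucose_dx_mmol_l", "hba1c_mmol_mol",
                           "insulin_dose_u_kg_day", "autoantibody_titer")
CLINICAL_REQUIRED_COLS <- c("individual_id", "family_id", "gene", "sex",
                            "genetic_ancestry", CLINICAL_NUMERIC_COLS,
                            "islet_autoantibodies", "immune_features",
                            "microcephaly", "developmental_delay",
                            "allele1_n", "allele2_n", "allele1_g", "allele2_g",
                            "zygosity", "chromosome")

parse_clinical_numeric <- function(x, col) {
  raw <- trimws(as.character(x))
  kind <- ifelse(raw %in% c("N/A", "NA_"), "not_applicable",
                 ifelse(raw %in% c("N/R", ""), "not_recorded", "value"))
  out <- rep(NA_real_, length(raw))
  isval <- kind == "value"
  suppressWarnings(out[isval] <- as.numeric(raw[isval]))
  bad <- which(isval & is.na(out))
  if (length(bad))
    stop(sprintf("load_cohort: unparseable numeric '%s' at row %d, column '%s'",
                 raw[bad[1L]], bad[1L], col), call. = FALSE)
  list(value = out, missing_kind = kind)
}

#' Load a clinical cohort table
#'
#' Reads one or more cohort CSV files (schema of the bundled fixtures) into a
#' validated `clinical_cohort` data frame. `N/A` and `N/R` sentinels are
#' recognized and preserved as distinct missing kinds; nothing is imputed.
#'
#' @param paths Character vector of CSV paths; multiple files are
#'   concatenated (e.g. one per cohort).
#' @return A `clinical_cohort` data frame, one row per individual, with
#'   parsed numeric columns, `<col>_missing` kind columns,
#'   `autoantibody_status` in `positive`/`negative`/`not_assessed`,
#'   `immune_recorded` flag, and semicolon-split `immune_features` retained
#'   verbatim.
#' @export
load_cohort <- function(paths) {
  dfs <- lapply(paths, function(p) {
    df <- utils::read.csv(p, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
    if (nrow(df) == 0L) stop("load_cohort: no records in ", p, call. = FALSE)
    miss <- setdiff(CLINICAL_REQUIRED_COLS, names(df))
    if (length(miss))
      stop("load_cohort: ", p, " is missing columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
    df
  })
  df <- do.call(rbind, dfs)
  for (col in CLINICAL_NUMERIC_COLS) {
    parsed <- parse_clinical_numeric(df[[col]], col)
    df[[col]] <- parsed$value
    df[[paste0(col, "_missing")]] <- parsed$missing_kind
  }
  if (anyDuplicated(df$individual_id))
    stop("load_cohort: duplicate individual ids: ",
         paste(unique(df$individual_id[duplicated(df$individual_id)]), collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(df$family_id)))
    stop("load_cohort: empty family_id", call. = FALSE)
  aab <- trimws(df$islet_autoantibodies)
  df$autoantibody_status <- ifelse(aab %in% c("N/A", "N/R", ""), "not_assessed",
                                   ifelse(grepl("positive", aab, ignore.case = TRUE),
                                          "positive", "negative"))
  imm <- trimws(df$immune_features)
  df$immune_recorded <- !(imm %in% c("N/A", "N/R", ""))
  map_enum <- function(x) ifelse(x == "N/R", "not_recorded",
                                 ifelse(x == "N/A", "not_applicable", x))
  df$microcephaly <- map_enum(trimws(df$microcephaly))
  df$developmental_delay <- map_enum(trimws(df$developmental_delay))
  if (!all(df$zygosity %in% c("homozygous", "compound_het")))
    stop("load_cohort: zygosity must be homozygous or compound_het", call. = FALSE)
  for (col in c("age_dx_weeks", "glucose_dx_mmol_l", "insulin_dose_u_kg_day")) {
    if (any(df[[col]] < 0, na.rm = TRUE))
      stop("load_cohort: negative values in ", col, call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("clinical_cohort", "data.frame")
  df
}

#' Median and interquartile range of possibly-missing values
#'
#' Missing values are dropped; the median is the middle order statistic (odd
#' n) or the mean of the two middle values (even n); quartiles use the
#' inclusive linear-interpolation convention by default
#' (`stats::quantile` type 7, the convention is exposed).
#'
#' @param values Numeric vector, NAs allowed.
#' @param type Quantile type passed to [stats::quantile()].
#' @return List with `median`, `q1`, `q3`, `n_used`, and `defined` (FALSE
#'   when every value is missing -- flagged, never reported as zero).
#' @export
median_iqr <- function(values, type = 7) {
  v <- values[!is.na(values)]
  if (!length(v))
    return(list(median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                n_used = 0L, defined = FALSE))
  q <- stats::quantile(v, probs = c(0.25, 0.75), type = type, names = FALSE)
  list(median = stats::median(v), q1 = q[1L], q3 = q[2L],
       n_used = length(v), defined = TRUE)
}

#' Islet-autoantibody positivity rate
#'
#' The denominator counts only assessed individuals; `not_assessed` records
#' are excluded.
#'
#' @param cohort A `clinical_cohort`.
#' @return List with `n_positive`, `n_assessed`, `percent`, and `defined`
#'   (FALSE when nobody was assessed).
#' @export
positivity_rate <- function(cohort) {
  assessed <- cohort$autoantibody_status != "not_assessed"
  n_assessed <- sum(assessed)
  n_positive <- sum(cohort$autoantibody_status == "positive")
  list(n_positive = n_positive, n_assessed = n_assessed,
       percent = if (n_assessed > 0) 100 * n_positive / n_assessed else NA_real_,
       defined = n_assessed > 0)
}

#' Count individuals satisfying a clinical predicate
#'
#' @param cohort A `clinical_cohort`.
#' @param predicate Pure function of a one-row record returning `TRUE`,
#'   `FALSE`, or `NA` (not classifiable / not recorded).
#' @param denominator_policy `"all"` counts every individual in the
#'   denominator (NA treated as unaffected); `"recorded_only"` drops NA
#'   records from both numerator and denominator.
#' @return List with `numerator` and `denominator`.
#' @export
count_feature <- function(cohort, predicate,
                          denominator_policy = c("all", "recorded_only")) {
  denominator_policy <- match.arg(denominator_policy)
  flags <- vapply(seq_len(nrow(cohort)), function(i) {
    res <- predicate(cohort[i, , drop = FALSE])
    if (is.null(res) || length(res) != 1L) NA else as.logical(res)
  }, NA)
  if (denominator_policy == "recorded_only") {
    list(numerator = sum(flags, na.rm = TRUE), denominator = sum(!is.na(flags)))
  } else {
    list(numerator = sum(flags, na.rm = TRUE), denominator = length(flags))
  }
}

#' Classify intra-uterine growth restriction from a birthweight Z score
#'
#' IUGR iff the Z score is present and strictly below -1.28 (roughly the
#' 10th centile). Missing Z scores are not classifiable (`NA`), so they drop
#' out of recorded-only denominators.
#'
#' @param bw_z Numeric birthweight Z score(s), NAs allowed.
#' @return Logical vector with NA for missing input.
#' @export
classify_iugr <- function(bw_z) {
  ifelse(is.na(bw_z), NA, bw_z < -1.28)
}

#' Record predicates for the bundled cohort fixtures
#'
#' `pred_immune_dysregulation`: any immune dysregulatory feature recorded;
#' `pred_humoral_defect`: a recorded feature matching B cell lymphopenia or
#' a-/hypogammaglobulinemia; `pred_iugr`: birthweight Z < -1.28;
#' `pred_classic_rnu4atac`: microcephaly or developmental delay (NA only when
#' neither is affirmed and at least one is unrecorded).
#'
#' @param record One-row `clinical_cohort` data frame.
#' @return `TRUE`, `FALSE`, or `NA`.
#' @name clinical-predicates
NULL

#' @rdname clinical-predicates
#' @export
pred_immune_dysregulation <- function(record) {
  if (!record$immune_recorded) return(NA)
  nzchar(trimws(record$immune_features))
}

#' @rdname clinical-predicates
#' @export
pred_humoral_defect <- function(record) {
  if (!record$immune_recorded) return(NA)
  grepl("lymphopenia|gammaglobulinemia", record$immune_features, ignore.case = TRUE)
}

#' @rdname clinical-predicates
#' @export
pred_iugr <- function(record) classify_iugr(record$bw_z)

#' @rdname clinical-predicates
#' @export
pred_classic_rnu4atac <- function(record) {
  vals <- c(record$microcephaly, record$developmental_delay)
  if (any(vals == "yes")) return(TRUE)
  if (any(vals %in% c("not_recorded", "not_applicable"))) return(NA)
  FALSE
}

normalize_allele <- function(x) toupper(gsub("\\s", "", x))

#' Count distinct alleles of a gene across a cohort
#'
#' Distinctness is keyed on the normalized transcript-level n. description,
#' so the same change reported in different individuals counts once.
#'
#' @param cohort A `clinical_cohort`.
#' @param gene Gene symbol.
#' @return Integer count.
#' @export
count_distinct_alleles <- function(cohort, gene) {
  rows <- cohort[cohort$gene == gene, , drop = FALSE]
  if (!nrow(rows)) return(0L)
  alleles <- normalize_allele(c(rows$allele1_n, rows$allele2_n))
  length(unique(alleles[nzchar(alleles)]))
}

#' Fit an snRNA transcript-to-genome coordinate anchor
#'
#' snRNA genes are single-exon, so a printed transcript position n maps to a
#' genomic position g by `g = offset + n` (plus strand) or `g = offset - n`
#' (minus strand). The anchor is inferred from >= 2 (n, g) pairs and must
#' reproduce every pair exactly.
#'
#' @param pairs Data frame or 2-column matrix of `n` and `g` positions.
#' @return List with `strand` (`"+"`/`"-"`) and integer `offset`.
#' @export
fit_gene_anchor <- function(pairs) {
  pairs <- as.data.frame(pairs)
  names(pairs)[1:2] <- c("n", "g")
  pairs <- unique(pairs[, c("n", "g")])
  if (nrow(pairs) < 2L) stop("fit_gene_anchor: need >= 2 distinct (n, g) pairs")
  plus_off <- pairs$g - pairs$n
  minus_off <- pairs$g + pairs$n
  if (length(unique(plus_off)) == 1L)
    return(list(strand = "+", offset = plus_off[1L]))
  if (length(unique(minus_off)) == 1L)
    return(list(strand = "-", offset = minus_off[1L]))
  # report a pair violating the better-supported candidate
  tab_p <- table(plus_off); tab_m <- table(minus_off)
  if (max(tab_p) >= max(tab_m)) {
    mode_off <- as.numeric(names(tab_p)[which.max(tab_p)])
    bad <- pairs[plus_off != mode_off, , drop = FALSE][1L, ]
  } else {
    mode_off <- as.numeric(names(tab_m)[which.max(tab_m)])
    bad <- pairs[minus_off != mode_off, , drop = FALSE][1L, ]
  }
  stop(sprintf("fit_gene_anchor: no consistent +/-1 anchor; violating pair (n=%s, g=%s)",
               bad$n, bad$g))
}

#' Apply a coordinate anchor to transcript positions
#'
#' @param anchor Anchor from [fit_gene_anchor()].
#' @param n Transcript position(s), 1-based on the snRNA sequence.
#' @return Genomic position(s).
#' @export
apply_gene_anchor <- function(anchor, n) {
  if (anchor$strand == "+") anchor$offset + n else anchor$offset - n
}

parse_hgvs_position <- function(x) {
  as.integer(sub("^([0-9]+).*$", "\\1", trimws(x)))
}

#' Extract (n, g) coordinate pairs for a gene from a cohort table
#'
#' @param cohort A `clinical_cohort`.
#' @param gene Gene symbol.
#' @return Data frame of unique `n` and `g` positions.
#' @export
anchor_pairs_from_cohort <- function(cohort, gene) {
  rows <- cohort[cohort$gene == gene, , drop = FALSE]
  n <- parse_hgvs_position(c(rows$allele1_n, rows$allele2_n))
  g <- parse_hgvs_position(c(rows$allele1_g, rows$allele2_g))
  unique(data.frame(n = n, g = g))
}

#' Recompute every cohort summary statistic as a JSON-able report
#'
#' Onset medians per cohort, pooled glucose and insulin medians (reporting
#' `n_used`, which surfaces any mismatch with externally printed n), GADA
#' positivity, immune-dysregulation and humoral-defect fractions, the IUGR
#' fraction over individuals with recorded birthweight Z scores, distinct
#' allele counts, family/individual totals, and the fitted coordinate
#' anchors per gene.
#'
#' @param cohort A `clinical_cohort` (typically both fixture tables).
#' @return Nested list ready for [write_json_report()].
#' @export
cohort_summary <- function(cohort) {
  genes <- sort(unique(cohort$gene))
  per_gene <- lapply(genes, function(g) {
    sub <- cohort[cohort$gene == g, , drop = FALSE]
    anchor <- tryCatch(fit_gene_anchor(anchor_pairs_from_cohort(cohort, g)),
                       error = function(e) NULL)
    list(n_individuals = nrow(sub),
         n_families = length(unique(sub$family_id)),
         onset_weeks = median_iqr(sub$age_dx_weeks),
         distinct_alleles = count_distinct_alleles(cohort, g),
         iugr = count_feature(sub, pred_iugr, "recorded_only"),
         immune_dysregulation = count_feature(sub, pred_immune_dysregulation, "all"),
         humoral_defect = count_feature(sub, pred_humoral_defect, "all"),
         anchor = anchor)
  })
  names(per_gene) <- genes
  list(
    n_individuals = nrow(cohort),
    n_families = length(unique(cohort$family_id)),
    cohorts = per_gene,
    gada_positivity = positivity_rate(cohort),
    immune_dysregulation = count_feature(cohort, pred_immune_dysregulation, "all"),
    glucose_dx_mmol_l = median_iqr(cohort$glucose_dx_mmol_l),
    insulin_dose_u_kg_day = median_iqr(cohort$insulin_dose_u_kg_day))
}

#' Path to a bundled clinical fixture
#'
#' @param which `"rnu6atac"`, `"rnu4atac"`, or `"both"` (vector of both
#'   paths, RNU6ATAC first).
#' @return File path(s) under the installed package's `extdata/`.
#' @export
clinical_fixture_path <- function(which = c("both", "rnu6atac", "rnu4atac")) {
  which <- match.arg(which)
  f <- function(name) system.file("extdata", name, package = "minorsplice",
                                  mustWork = TRUE)
  switch(which,
         rnu6atac = f("clinical_rnu6atac_cohort.csv"),
         rnu4atac = f("clinical_rnu4atac_cohort.csv"),
         both = c(f("clinical_rnu6atac_cohort.csv"),
                  f("clinical_rnu4atac_cohort.csv")))
}
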