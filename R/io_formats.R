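# Readers and writers for the plain-text formats shared across the pipeline.
# Conventions, stated once and used everywhere:
#   * VCF is 1-based; BED is 0-based half-open; snRNA transcript (n.) positions
#     are 1-based on the snRNA sequence.
#   * TSV matrices are UTF-8, tab-separated, header row, '.' for missing.
#   * Writers are deterministic, so write -> read -> write is byte-idempotent.

VCF_HEADER <- c(
  "##fileformat=VCFv4.2",
  "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Annotated gene symbol\">",
  "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Population allele frequency; absent if not in reference\">",
  "##INFO=<ID=CODING,Number=1,Type=String,Description=\"yes if the gene is protein-coding, no otherwise\">",
  "##INFO=<ID=ORIGIN,Number=1,Type=String,Description=\"Parental origin of the carried allele (maternal/paternal/unknown)\">",
  "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
)

fmt_num <- function(x) sprintf("%.10g", x)

#' Write per-sample variant calls as a minimal multi-sample VCF 4.2
#'
#' The long call table (one row per sample x variant) is collapsed to one VCF
#' record per distinct variant; samples not carrying the variant get `0/0`.
#' INFO carries `GENE`, `AF` (omitted when the allele frequency is missing,
#' i.e. absent from the population reference), `CODING`, and `ORIGIN` (the
#' carrier's parental-origin flag when a single sample carries the variant).
#'
#' @param variants Data frame with columns `sample_id`, `chromosome`,
#'   `position`, `ref`, `alt`, `genotype` (`het`/`hom_alt`), `gene`, `coding`
#'   (logical), `population_af` (NA = absent), `parental_origin`.
#' @param path Output file path.
#' @param samples Optional character vector fixing the sample-column order;
#'   defaults to sorted unique sample ids.
#' @return `path`, invisibly.
#' @export
write_vcf_minimal <- function(variants, path, samples = NULL) {
  req <- c("sample_id", "chromosome", "position", "ref", "alt", "genotype",
           "gene", "coding", "population_af", "parental_origin")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stop("write_vcf_minimal: missing columns: ", paste(miss, collapse = ", "))
  if (is.null(samples)) samples <- sort(unique(variants$sample_id))
  key <- paste(variants$chromosome, variants$position, variants$ref,
               variants$alt, variants$gene, sep = "\r")
  ord <- order(variants$chromosome, variants$position, variants$ref, variants$alt)
  ukey <- unique(key[ord])
  lines <- character(length(ukey))
  for (i in seq_along(ukey)) {
    rows <- variants[key == ukey[i], , drop = FALSE]
    v <- rows[1L, ]
    info <- c(paste0("GENE=", v$gene),
              if (!is.na(v$population_af)) paste0("AF=", fmt_num(v$population_af)),
              paste0("CODING=", if (isTRUE(v$coding)) "yes" else "no"))
    if (nrow(rows) == 1L && !is.na(rows$parental_origin[1L]) &&
        rows$parental_origin[1L] != "unknown") {
      info <- c(info, paste0("ORIGIN=", rows$parental_origin[1L]))
    }
    gts <- rep("0/0", length(samples))
    names(gts) <- samples
    gts[rows$sample_id] <- ifelse(rows$genotype == "hom_alt", "1/1", "0/1")
    lines[i] <- paste(c(v$chromosome, v$position, ".", v$ref, v$alt, ".",
                        "PASS", paste(info, collapse = ";"), "GT", gts),
                      collapse = "\t")
  }
  header <- c(VCF_HEADER,
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a minimal VCF 4.2 into a long per-sample variant table
#'
#' Inverse of [write_vcf_minimal()]: emits one row per (sample, variant) for
#' samples with a non-reference genotype. Multi-allelic ALT fields are
#' decomposed into biallelic records (AF applies per alternate allele).
#'
#' @param path VCF file path.
#' @return Data frame with the columns documented in [write_vcf_minimal()].
#' @export
read_vcf_minimal <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  if (!length(body) || !startsWith(body[1L], "#CHROM"))
    stop("read_vcf_minimal: no #CHROM header line in ", path)
  cols <- strsplit(sub("^#", "", body[1L]), "\t", fixed = TRUE)[[1L]]
  samples <- cols[-(1:9)]
  out <- list()
  for (k in seq_along(body[-1L])) {
    fields <- strsplit(body[k + 1L], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != length(cols))
      stop(sprintf("read_vcf_minimal: malformed line %d: expected %d fields, got %d",
                   k, length(cols), length(fields)))
    info <- strsplit(fields[8L], ";", fixed = TRUE)[[1L]]
    kv <- strsplit(info, "=", fixed = TRUE)
    keys <- vapply(kv, `[`, "", 1L)
    vals <- vapply(kv, function(x) if (length(x) > 1L) x[[2L]] else "", "")
    alts <- strsplit(fields[5L], ",", fixed = TRUE)[[1L]]
    for (ai in seq_along(alts)) {
      gt_raw <- fields[-(1:9)]
      gt_alleles <- strsplit(gt_raw, "[/|]")
      carried <- vapply(gt_alleles, function(a) sum(a == as.character(ai)), 0L)
      sel <- which(carried > 0L)
      if (!length(sel)) next
      af <- if ("AF" %in% keys) as.numeric(vals[keys == "AF"]) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        sample_id = samples[sel],
        chromosome = fields[1L],
        position = as.integer(fields[2L]),
        ref = fields[4L],
        alt = alts[ai],
        genotype = ifelse(carried[sel] >= 2L, "hom_alt", "het"),
        gene = if ("GENE" %in% keys) vals[keys == "GENE"] else NA_character_,
        coding = identical(unname(vals[keys == "CODING"]), "yes"),
        population_af = af,
        parental_origin = if ("ORIGIN" %in% keys) vals[keys == "ORIGIN"] else "unknown",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(sample_id = character(), chromosome = character(),
                      position = integer(), ref = character(), alt = character(),
                      genotype = character(), gene = character(), coding = logical(),
                      population_af = numeric(), parental_origin = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write an intron annotation as BED6
#'
#' Coordinates are 0-based half-open; the name field encodes
#' `gene|intron_index|class` with class one of `U2`, `U12`, `unknown`.
#'
#' @param annotation Data frame with `intron_id` (`gene|index`), `gene`,
#'   `chromosome`, `start`, `end`, `class`.
#' @param path Output file path.
#' @export
write_bed6 <- function(annotation, path) {
  idx <- sub("^.*\\|", "", annotation$intron_id)
  lines <- paste(annotation$chromosome, annotation$start, annotation$end,
                 paste(annotation$gene, idx, annotation$class, sep = "|"),
                 0L, "+", sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6 intron annotation
#'
#' @param path BED file path (name field `gene|intron_index|class`).
#' @return Data frame with `intron_id`, `gene`, `chromosome`, `start`, `end`,
#'   `class` (0-based half-open coordinates preserved).
#' @export
read_bed6 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 6L)
  if (length(bad)) stop(sprintf("read_bed6: malformed line %d (< 6 fields)", bad[1L]))
  name <- vapply(parts, `[`, "", 4L)
  nm <- strsplit(name, "|", fixed = TRUE)
  badname <- which(lengths(nm) != 3L)
  if (length(badname))
    stop(sprintf("read_bed6: line %d name field is not gene|index|class", badname[1L]))
  ann <- data.frame(
    intron_id = vapply(nm, function(x) paste(x[1L], x[2L], sep = "|"), ""),
    gene = vapply(nm, `[`, "", 1L),
    chromosome = vapply(parts, `[`, "", 1L),
    start = as.integer(vapply(parts, `[`, "", 2L)),
    end = as.integer(vapply(parts, `[`, "", 3L)),
    class = vapply(nm, `[`, "", 3L),
    stringsAsFactors = FALSE)
  if (any(ann$end <= ann$start)) stop("read_bed6: interval with end <= start")
  if (anyDuplicated(ann$intron_id)) stop("read_bed6: duplicate intron ids")
  ann
}

#' Write a numeric matrix as TSV ('.' = missing)
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_col Header of the row-name column.
#' @export
write_tsv_matrix <- function(m, path, id_col = "id") {
  body <- apply(m, 1:2, function(x) if (is.na(x)) "." else fmt_num(x))
  if (is.null(dim(body))) body <- matrix(body, nrow = nrow(m), dimnames = dimnames(m))
  lines <- c(paste(c(id_col, colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i], body[i, ]), collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a TSV numeric matrix written by [write_tsv_matrix()]
#'
#' @param path TSV path; first column is the row id, '.' parses to NA.
#' @return Numeric matrix with dimnames.
#' @export
read_tsv_matrix <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol_exp <- length(parts[[1L]])
  bad <- which(lengths(parts) != ncol_exp)
  if (length(bad)) stop(sprintf("read_tsv_matrix: malformed line %d", bad[1L]))
  header <- parts[[1L]][-1L]
  rows <- lapply(parts[-1L], function(p) {
    v <- p[-1L]
    v[v == "."] <- NA
    suppressWarnings(num <- as.numeric(v))
    if (any(is.na(num) & !is.na(v)))
      stop("read_tsv_matrix: non-numeric value in ", path)
    num
  })
  m <- do.call(rbind, rows)
  dimnames(m) <- list(vapply(parts[-1L], `[`, "", 1L), header)
  m
}

#' Read gene sets in GMT format
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`; trailing empty
#' tokens (a common dialect artifact of spreadsheet exports) are dropped.
#'
#' @param path GMT file path.
#' @return Named list of character gene vectors; descriptions kept in the
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) stop(sprintf("read_gmt: malformed line %d (< 3 fields)", bad[1L]))
  sets <- lapply(parts, function(p) {
    genes <- p[-(1:2)]
    genes[nzchar(genes)]
  })
  names(sets) <- vapply(parts, `[`, "", 1L)
  attr(sets, "descriptions") <- stats::setNames(vapply(parts, `[`, "", 2L), names(sets))
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character gene vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions; defaults to `"na"`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descriptions) && nm %in% names(descriptions)) descriptions[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample sheet mapping sample ids to groups (and optional traits)
#'
#' @param path CSV with a `sample_id` column plus `group` and/or trait columns.
#' @return Data frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop("sample sheet needs a 'sample_id' column")
  if (anyDuplicated(df$sample_id)) stop("sample sheet has duplicate sample ids")
  df
}

#' Write a JSON report
#'
#' Thin wrapper around `jsonlite::write_json` with scalar auto-unboxing and
#' full numeric precision.
#'
#' @param x Report object (list).
#' @param path Output path.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}
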