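# Recessive ultra-rare gene discovery: filter variants to the ultra-rare
# tier, call bi-allelic genotypes per gene (homozygous, or compound
# heterozygous with trans phase from parental-origin flags), intersect
# qualifying genes across probands by gene class, and screen a candidate
# panel across a cohort.

#' Filter variants to the ultra-rare tier
#'
#' Keeps variants with population allele frequency strictly below
#' `maf_threshold`, or with a missing frequency: absence from the population
#' reference is treated as rare, since a drop-missing policy would discard
#' exactly the novel alleles the screen is after.
#'
#' @param variants Long variant table (see [read_vcf_minimal()]).
#' @param maf_threshold Strict upper bound on population AF, in (0, 1).
#' @return The qualifying subset of `variants`.
#' @export
filter_ultra_rare <- function(variants, maf_threshold = 1e-5) {
  if (!is.numeric(maf_threshold) || length(maf_threshold) != 1L ||
      is.na(maf_threshold) || maf_threshold <= 0 || maf_threshold >= 1)
    stop("maf_threshold must lie in (0, 1)")
  keep <- is.na(variants$population_af) | variants$population_af < maf_threshold
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call bi-allelic genotypes per sample and gene
#'
#' A homozygous alternate variant yields a `homozygous` call (one call per
#' such variant). Two or more heterozygous variants in one gene yield a
#' compound-het call: `compound_het_trans` when both a maternal and a
#' paternal allele are present, `compound_het_phase_unknown` when phase
#' cannot be established (reported but flagged, never silently promoted),
#' and no call when all known origins agree (cis).
#'
#' @param variants Ultra-rare-filtered long variant table.
#' @return Data frame of calls: `sample_id`, `gene`, `mechanism`,
#'   `n_variants`, plus a `variants` list-column of supporting rows.
#' @export
call_biallelic <- function(variants) {
  empty <- data.frame(sample_id = character(), gene = character(),
                      mechanism = character(), n_variants = integer(),
                      stringsAsFactors = FALSE)
  empty$variants <- list()
  if (!nrow(variants)) return(empty)
  calls <- list()
  for (key in unique(paste(variants$sample_id, variants$gene, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    sub <- variants[variants$sample_id == parts[1L] & variants$gene == parts[2L], ,
                    drop = FALSE]
    homs <- sub[sub$genotype == "hom_alt", , drop = FALSE]
    for (i in seq_len(nrow(homs))) {
      calls[[length(calls) + 1L]] <- list(sample_id = parts[1L], gene = parts[2L],
                                          mechanism = "homozygous",
                                          variants = homs[i, , drop = FALSE])
    }
    hets <- sub[sub$genotype == "het", , drop = FALSE]
    if (nrow(hets) >= 2L) {
      origins <- hets$parental_origin
      mech <- if (any(origins == "maternal") && any(origins == "paternal")) {
        "compound_het_trans"
      } else if (any(origins == "unknown")) {
        "compound_het_phase_unknown"
      } else {
        NA_character_ # all known origins identical: cis, no call
      }
      if (!is.na(mech)) {
        calls[[length(calls) + 1L]] <- list(sample_id = parts[1L], gene = parts[2L],
                                            mechanism = mech, variants = hets)
      }
    }
  }
  if (!length(calls)) return(empty)
  out <- data.frame(sample_id = vapply(calls, `[[`, "", "sample_id"),
                    gene = vapply(calls, `[[`, "", "gene"),
                    mechanism = vapply(calls, `[[`, "", "mechanism"),
                    n_variants = vapply(calls, function(x) nrow(x$variants), 0L),
                    stringsAsFactors = FALSE)
  out$variants <- lapply(calls, `[[`, "variants")
  ord <- order(out$sample_id, out$gene)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# a gene's class comes from its supporting variants' CODING flag
biallelic_genes_of_class <- function(calls, gene_class) {
  if (!nrow(calls)) return(character())
  coding <- vapply(calls$variants, function(v) any(v$coding), NA)
  keep <- switch(gene_class,
                 coding = coding,
                 noncoding = !coding,
                 any = rep(TRUE, nrow(calls)))
  unique(calls$gene[keep])
}

#' Intersect qualifying genes across probands
#'
#' A gene survives when every proband carries a qualifying bi-allelic call in
#' it, restricted to the requested gene class. This is the discovery step:
#' an empty coding intersection followed by a singleton non-coding one is
#' the expected signature of a causal non-coding gene.
#'
#' @param probands List of per-proband call tables from [call_biallelic()].
#' @param gene_class `"coding"`, `"noncoding"`, or `"any"`.
#' @return Character vector of shared genes (sorted).
#' @export
intersect_candidate_genes <- function(probands, gene_class = c("any", "coding", "noncoding")) {
  gene_class <- match.arg(gene_class)
  if (!length(probands)) stop("intersect_candidate_genes: empty proband list")
  sets <- lapply(probands, biallelic_genes_of_class, gene_class = gene_class)
  sort(Reduce(intersect, sets))
}

#' Read a candidate gene panel
#'
#' One gene per line, optional tab-separated class (`coding`/`noncoding`,
#' default `coding`); `#` lines are comments.
#'
#' @param path Panel file path.
#' @return Data frame with `gene` and logical `coding`.
#' @export
read_panel <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  genes <- vapply(parts, `[`, "", 1L)
  cls <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else "coding", "")
  if (!length(genes) || anyDuplicated(genes))
    stop("read_panel: panel must be a non-empty list of unique genes")
  data.frame(gene = genes, coding = cls == "coding", stringsAsFactors = FALSE)
}

#' Screen a candidate gene panel for bi-allelic carriers across a cohort
#'
#' Applies the ultra-rare filter, calls bi-allelic genotypes, and reports
#' every individual with a qualifying call in a panel gene, ordered by gene
#' then sample. Panel genes with no variant in the cohort produce a warning
#' (possible symbol mismatch), never an error.
#'
#' @param variants Cohort-wide long variant table.
#' @param panel Data frame from [read_panel()] or a character vector of genes.
#' @param maf_threshold Passed to [filter_ultra_rare()].
#' @return Call table restricted to panel genes, ordered (gene, sample).
#' @export
screen_panel <- function(variants, panel, maf_threshold = 1e-5) {
  genes <- if (is.data.frame(panel)) panel$gene else as.character(panel)
  if (!length(genes)) stop("screen_panel: empty panel")
  unseen <- setdiff(genes, unique(variants$gene))
  if (length(unseen))
    warning("screen_panel: panel genes with no variant in the cohort: ",
            paste(utils::head(unseen, 5L), collapse = ", "),
            if (length(unseen) > 5L) sprintf(" (+%d more)", length(unseen) - 5L) else "")
  rare <- filter_ultra_rare(variants, maf_threshold)
  rare <- rare[rare$gene %in% genes, , drop = FALSE]
  calls <- call_biallelic(rare)
  ord <- order(calls$gene, calls$sample_id)
  calls <- calls[ord, , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Serialize a bi-allelic call table as a JSON-able report
#'
#' @param calls Call table from [call_biallelic()] / [screen_panel()].
#' @return List of per-call records (supporting variants inlined).
#' @export
calls_report <- function(calls) {
  lapply(seq_len(nrow(calls)), function(i) {
    v <- calls$variants[[i]]
    list(sample_id = calls$sample_id[i], gene = calls$gene[i],
         mechanism = calls$mechanism[i],
         variants = lapply(seq_len(nrow(v)), function(j) {
           as.list(v[j, c("chromosome", "position", "ref", "alt", "genotype",
                          "population_af", "parental_origin")])
         }))
  })
}
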