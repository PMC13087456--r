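# PSI computation, differential retention testing, gene-level calls, and the
# two-cohort / U12-annotation cross-tabulation.

mk_counts <- function(retained, spliced, groups) {
  intron_counts(retained, spliced, groups)
}

test_that("compute_psi applies the formula and the coverage rule", {
  retained <- matrix(c(0L, 30L, 3L), 3, 1,
                     dimnames = list(c("g|1", "g|2", "g|3"), "s1"))
  spliced <- matrix(c(50L, 30L, 2L), 3, 1, dimnames = dimnames(retained))
  psi <- compute_psi(mk_counts(retained, spliced, c(s1 = "control")),
                     min_coverage = 10)
  expect_identical(psi$psi["g|1", "s1"], 0)
  expect_identical(psi$psi["g|2", "s1"], 0.5)
  expect_true(is.na(psi$psi["g|3", "s1"])) # coverage 5 < 10
  expect_identical(psi$coverage["g|3", "s1"], 5L)
  # orientation flag
  flipped <- compute_psi(mk_counts(retained, spliced, c(s1 = "control")),
                         min_coverage = 10, measure = "spliced")
  expect_identical(flipped$psi["g|1", "s1"], 1)
})

test_that("PSI is bounded and monotone in retained reads", {
  set.seed(7)
  for (rep in 1:20) {
    spliced <- sample(0:100, 1)
    retained <- sort(sample(0:200, 10))
    psi <- retained / (retained + spliced)
    r <- matrix(as.integer(retained), 10, 1,
                dimnames = list(sprintf("g|%d", 1:10), "s1"))
    s <- matrix(as.integer(spliced), 10, 1, dimnames = dimnames(r))
    out <- compute_psi(mk_counts(r, s, c(s1 = "x")), min_coverage = 0)
    vals <- out$psi[, 1]
    vals <- vals[!is.na(vals)]
    expect_true(all(vals >= 0 & vals <= 1))
    expect_true(all(diff(vals) >= 0))
  }
})

sim_default <- simulate_intron_counts(ir_sim_config(seed = 13))
psi_default <- compute_psi(sim_default$counts)

test_that("identical case and control columns give p = 1 everywhere", {
  r <- sim_default$counts$retained[1:50, 1:3]
  base <- cbind(r, r)
  spl <- cbind(sim_default$counts$spliced[1:50, 1:3],
               sim_default$counts$spliced[1:50, 1:3])
  colnames(base) <- colnames(spl) <- sprintf("s%d", 1:6)
  groups <- stats::setNames(rep(c("case", "control"), each = 3), colnames(base))
  res <- test_differential_ir(compute_psi(mk_counts(base, spl, groups)),
                              "case", "control")
  expect_true(all(res$p_value[res$tested] == 1))
  expect_false(any(res$significant))
  expect_identical(res$delta_psi[res$tested], rep(0, sum(res$tested)))
})

test_that("adjusted p values equal an independent BH step-up", {
  res <- test_differential_ir(psi_default, "case_RNU6ATAC", "control")
  tested <- res[res$tested, ]
  expect_equal(tested$adjusted_p, bh_stepup_oracle(tested$p_value),
               tolerance = 1e-12)
  expect_true(all(tested$adjusted_p >= tested$p_value))
  set.seed(11)
  for (rep in 1:200) {
    p <- stats::runif(sample(1:40, 1))
    expect_equal(stats::p.adjust(p, "BH"), bh_stepup_oracle(p), tolerance = 1e-12)
  }
})

test_that("groups and errors are handled", {
  expect_error(test_differential_ir(psi_default, "nonexistent", "control"),
               "no samples in case group")
  expect_error(test_differential_ir(psi_default, "case_RNU6ATAC", "nope"),
               "control group")
})

test_that("results are invariant to sample order within groups", {
  perm <- c(3, 1, 2, 8, 12, 4, 5, 9, 7, 6, 11, 10) # shuffles within groups
  counts2 <- mk_counts(sim_default$counts$retained[, perm],
                       sim_default$counts$spliced[, perm],
                       sim_default$counts$groups[perm])
  res1 <- test_differential_ir(psi_default, "case_RNU6ATAC", "control")
  res2 <- test_differential_ir(compute_psi(counts2), "case_RNU6ATAC", "control")
  expect_equal(res1, res2, tolerance = 1e-12)
})

test_that("gene-level calls follow the configured rule", {
  ann <- data.frame(intron_id = sprintf("g1|%d", 1:5), gene = "g1",
                    chromosome = "chr1", start = 0:4 * 100, end = 0:4 * 100 + 50,
                    class = "U2", stringsAsFactors = FALSE)
  res <- data.frame(intron_id = ann$intron_id, p_value = c(1e-6, rep(0.9, 4)),
                    tested = TRUE, significant = c(TRUE, rep(FALSE, 4)),
                    stringsAsFactors = FALSE)
  expect_identical(call_gene_level(res, ann, "any"), "g1") # 1 of 5 is enough
  expect_identical(call_gene_level(res, ann, "majority"), character())
  res$significant <- FALSE
  expect_identical(call_gene_level(res, ann, "any"), character())
  res$intron_id[1] <- "mystery|1"
  expect_error(call_gene_level(res, ann), "missing from the annotation")
})

test_that("simulated gene calls match the intron-level truth", {
  res <- test_differential_ir(psi_default, "case_RNU6ATAC", "control")
  genes <- call_gene_level(res, sim_default$annotation)
  gene_of <- stats::setNames(sim_default$annotation$gene,
                             sim_default$annotation$intron_id)
  expect_setequal(genes, unique(gene_of[res$intron_id[res$significant]]))
})

test_that("cohort overlap cross-tabulation covers all 2x2x2 cells", {
  ann <- sim_default$annotation
  # empty inputs: everything in the all-FALSE cell
  z <- classify_cohort_overlap(character(), character(), ann)
  expect_identical(sum(z$counts$n), length(unique(ann$gene)))
  expect_identical(sum(z$counts$n[z$counts$in_A | z$counts$in_B]), 0L)
  expect_identical(nrow(z$genes), 0L)

  # disjoint cohorts: no both-cohort gene
  gs <- unique(ann$gene)
  d <- classify_cohort_overlap(gs[1:3], gs[4:6], ann)
  expect_identical(sum(d$counts$n[d$counts$in_A & d$counts$in_B]), 0L)
  expect_identical(nrow(d$genes), 6L)

  expect_error(classify_cohort_overlap("NOT_A_GENE", character(), ann),
               "not in the annotation")

  # hidden-U12 genes detected in both cohorts count as novel candidates
  simA <- simulate_intron_counts(ir_sim_config(seed = 31, frac_hidden_u12 = 0.2))
  simB <- simulate_intron_counts(ir_sim_config(seed = 31, frac_hidden_u12 = 0.2,
                                               case_group = "case_RNU4ATAC"))
  resA <- test_differential_ir(compute_psi(simA$counts), "case_RNU6ATAC", "control")
  resB <- test_differential_ir(compute_psi(simB$counts), "case_RNU4ATAC", "control")
  gA <- call_gene_level(resA, simA$annotation)
  gB <- call_gene_level(resB, simB$annotation)
  ov <- classify_cohort_overlap(gA, gB, simA$annotation)
  novel_both <- ov$genes$gene[ov$genes$significant_in_A & ov$genes$significant_in_B &
                                ov$genes$novel_candidate]
  want <- intersect(intersect(gA, gB), simA$truth$hidden_genes)
  expect_setequal(novel_both, want)
})

test_that("count matrices round-trip through the paired-column TSV", {
  f <- tempfile(fileext = ".tsv")
  write_intron_counts(sim_default$counts, f)
  back <- read_intron_counts(f, sim_default$counts$groups)
  expect_equal(back$retained, sim_default$counts$retained + 0)
  expect_equal(back$spliced, sim_default$counts$spliced + 0)
  f2 <- tempfile(fileext = ".tsv")
  write_intron_counts(intron_counts(
    matrix(as.integer(back$retained), nrow(back$retained), dimnames = dimnames(back$retained)),
    matrix(as.integer(back$spliced), nrow(back$spliced), dimnames = dimnames(back$spliced)),
    back$groups), f2)
  expect_identical(readLines(f), readLines(f2))
})
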