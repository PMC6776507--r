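test_that("orient_risk picks the allele increasing odds", {
  expect_identical(orient_risk("G", "A", 1.2)$risk_allele, "G")
  or2 <- orient_risk("G", "A", 0.8)
  expect_identical(or2$risk_allele, "A")
  expect_identical(or2$other_allele, "G")
  expect_identical(orient_risk("G", "A", 1)$status, "undetermined")
  expect_error(orient_risk("G", "A", 0), "positive")
  # involution: flipping a1/a2 and inverting OR leaves the risk allele fixed
  set.seed(2)
  for (i in 1:50) {
    or_ <- exp(rnorm(1))
    if (or_ == 1) next
    a <- sample(c("A", "C", "G", "T"), 2)
    expect_identical(orient_risk(a[1], a[2], or_)$risk_allele,
                     orient_risk(a[2], a[1], 1 / or_)$risk_allele)
  }
})

test_that("align_to_risk flips signs for the non-risk allele", {
  expect_equal(align_to_risk(1L, "G", "G"), 1L)
  expect_equal(align_to_risk(1L, "A", "G"), -1L)
  expect_equal(align_to_risk(c(-1L, 1L), c("A", "G"), "G"), c(1L, 1L))
})

test_that("promoter_map is strand-aware, upstream-only and strictly < window", {
  tss <- data.table::data.table(
    gene = c("PLUS", "MINUS"), chrom = "1", strand = c("+", "-"),
    tss_pos = c(100000L, 200000L))
  cg <- function(pos) data.table::data.table(cpg_id = "cg", cpg_chrom = "1",
                                             cpg_pos = pos)
  # + strand: upstream = below the TSS
  expect_identical(promoter_map(cg(100000L - 4999L), tss)$gene, "PLUS")
  expect_equal(nrow(promoter_map(cg(100000L - 5000L), tss)), 0L)   # boundary
  expect_equal(nrow(promoter_map(cg(100000L + 1000L), tss)), 0L)   # downstream
  expect_identical(promoter_map(cg(100000L), tss)$gene, "PLUS")    # at TSS
  # - strand: upstream = above the TSS
  expect_identical(promoter_map(cg(200000L + 4999L), tss)$gene, "MINUS")
  expect_equal(nrow(promoter_map(cg(200000L + 5000L), tss)), 0L)
  expect_equal(nrow(promoter_map(cg(200000L - 100L), tss)), 0L)
})

test_that("consistency_check returns the four verdicts and is sign-symmetric", {
  expect_identical(consistency_check(-1L, c(1L, 1L)), "consistent")
  expect_identical(consistency_check(1L, c(-1L, -1L)), "consistent")
  expect_identical(consistency_check(-1L, c(-1L, -1L)), "inconsistent")
  expect_identical(consistency_check(1L, c(1L, -1L)), "discordant-across-tissues")
  expect_identical(consistency_check(NA_integer_, 1L), "insufficient-data")
  expect_identical(consistency_check(1L, integer(0)), "insufficient-data")
  # symmetry under simultaneous sign flip
  set.seed(3)
  for (i in 1:50) {
    m <- sample(c(-1L, 1L), 1)
    e <- sample(c(-1L, 1L), sample(1:4, 1), replace = TRUE)
    expect_identical(consistency_check(m, e), consistency_check(-m, -e))
  }
})

test_that("count_marks totals mark classes and is row-order invariant", {
  regions <- paste0("r", 1:10)
  marks <- c("H3K4me1", "H3K27ac", "H3K4me3", "H3K9ac")
  full <- data.table::CJ(snp_id = "rs1", region = regions, mark = marks)
  full[, present := 1L]
  expect_equal(count_marks("rs1", full),
               list(enhancer_count = 20L, promoter_count = 20L, no_data = FALSE))

  # fixture reproducing a 17-enhancer / 16-promoter row
  set.seed(8)
  fx <- data.table::copy(full)
  enh_idx <- which(fx$mark %in% c("H3K4me1", "H3K27ac"))
  pro_idx <- which(fx$mark %in% c("H3K4me3", "H3K9ac"))
  fx[sample(enh_idx, 3), present := 0L]
  fx[sample(pro_idx, 4), present := 0L]
  expect_equal(count_marks("rs1", fx)[1:2],
               list(enhancer_count = 17L, promoter_count = 16L))
  # row-order invariance + independent summation oracle
  for (i in 1:20) {
    rnd <- data.table::copy(full)[, present := as.integer(runif(.N) < 0.3)]
    shuf <- rnd[sample(.N)]
    got <- count_marks("rs1", shuf)
    expect_equal(got$enhancer_count,
                 sum(rnd[mark %in% c("H3K4me1", "H3K27ac"), present]))
    expect_equal(got$promoter_count,
                 sum(rnd[mark %in% c("H3K4me3", "H3K9ac"), present]))
    expect_equal(got, count_marks("rs1", rnd))
  }
  expect_true(count_marks("nope", full)$no_data)
})

test_that("volume_lookup recomputes the Bonferroni denominator per run", {
  set.seed(5)
  snps <- sprintf("rs%02d", 1:50)
  vt <- data.table::CJ(snp_id = snps, structure_ = c("thalamus", "putamen"))
  vt[, `:=`(effect_allele = "G", beta_sign = 1L, p = runif(.N, 0.1, 1))]
  vt[snp_id == "rs01" & structure_ == "thalamus", p := 9e-4]  # planted hit
  res <- volume_lookup(snps, vt, alpha = 0.05)
  expect_equal(res$threshold, 0.05 / 50)       # 50 queried -> 1e-3
  expect_identical(res$hits[status == "hit", snp_id], "rs01")
  # absent SNP gets "?" and does not inflate the denominator
  res2 <- volume_lookup(c(snps, "rs99"), vt, alpha = 0.05)
  expect_equal(res2$threshold, 0.05 / 50)
  expect_identical(res2$hits[snp_id == "rs99", status], "?")
  # direction is risk-aligned
  res3 <- volume_lookup("rs01", vt, risk_alleles = c(rs01 = "A"), alpha = 0.05)
  expect_equal(res3$hits[status == "hit", direction], -1L)
})

test_that("prioritize_block: argmax with stated tie-breaks", {
  ba <- data.table::data.table(
    snp_id = c("a", "b", "c"), score = c(10, 33, 33),
    p = c(1e-4, 1e-6, 1e-5), pos = c(1L, 2L, 3L))
  expect_identical(prioritize_block(ba)$snp_id, "b")
  ba2 <- data.table::copy(ba)[, p := c(1e-4, 1e-6, 1e-6)][, score := 33]
  expect_identical(prioritize_block(ba2)$snp_id, "b")   # p tie -> leftmost
  expect_identical(prioritize_block(ba[1])$snp_id, "a") # single variant
  expect_error(prioritize_block(ba[0]), "empty block")
  # NA p ranks last in tie-break
  ba3 <- data.table::data.table(snp_id = c("x", "y"), score = 5,
                                p = c(NA_real_, 0.5), pos = c(1L, 2L))
  expect_identical(prioritize_block(ba3)$snp_id, "y")
})

test_that("risk-alignment involution holds through annotate_variants", {
  cfg <- small_sim(seed = 33)
  p <- generate_panel(cfg)
  asm <- generate_asm_catalog(p, cfg)
  ss <- generate_sumstats(p, asm, cfg)
  bundle <- generate_annotation_tables(asm, cfg, ss)
  filt <- filter_catalog(merge_sources(asm)$catalog)$catalog
  ids <- intersect(unique(filt$snp_id), colnames(p$hap))[1:5]
  vr <- data.table::data.table(snp_id = ids,
                               a1 = p$variants[match(ids, id), alt],
                               a2 = p$variants[match(ids, id), ref],
                               or_ = c(1.3, 0.7, 2.1, 0.5, 1.01),
                               p = rep(1e-4, 5))
  ann1 <- annotate_variants(vr, filt, bundle, p)
  vr2 <- data.table::copy(vr)[, `:=`(a1 = a2, a2 = a1, or_ = 1 / or_)]
  ann2 <- annotate_variants(vr2, filt, bundle, p)
  expect_identical(ann1$risk_allele, ann2$risk_allele)
  expect_identical(ann1$meth, ann2$meth)
  expect_identical(ann1$verdicts, ann2$verdicts)
  expect_equal(ann1$score, ann2$score)
})

test_that("build_report emits one row per block with arrow encoding", {
  cfg <- small_sim(seed = 44)
  run <- run_demo(seed = 44, sim = cfg)
  rep <- run$report
  expect_equal(nrow(rep), run$flow$n_blocks)
  expect_true(all(grepl("^(up|down) ", unlist(strsplit(rep$methylation, "; ")))))
  # empty significant set -> empty report
  scr0 <- screen_tags(data.table::data.table(snp_id = "z", p = 1))
  empty <- build_report(scr0, data.table::data.table(snp_id = character()),
                        data.table::data.table(snp_id = character(),
                                               block_id = character()))
  expect_equal(nrow(empty), 0L)
})
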