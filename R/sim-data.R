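# Source labels for the simulated ASM catalogs: one four-tissue study and
# one cerebellum-only study, mirroring the typical two-study brain ASM
# literature.
SIM_SOURCES <- data.table(
  study = c(rep("studyA_sim", 4), "studyB_sim"),
  tissue = c("frontal cortex", "caudal pons", "temporal cortex", "cerebellum",
             "cerebellum")
)

# fraction of simulated pairs deliberately placed in trans (CpG on another
# chromosome) so the cis filter has work to do
SIM_TRANS_FRAC <- 0.02

#' Simulate multi-study ASM SNP-CpG catalogs with ground truth
#'
#' Builds SNP-CpG pairs on top of a simulated panel: each LD block carries
#' one or more CpG sites and its SNPs correlate with them in cis. A
#' configurable fraction of pairs gets methylation R^2 below 0.2, a small
#' fraction is placed in trans, and extra pairs are planted on chromosome X
#' (their SNPs are absent from the autosomal panel) — each planted defect
#' exercises one catalog filter. Pairs are split into two pseudo-studies
#' (one with four brain tissues, one cerebellum-only) with deliberate
#' overlap: with probability `overlap_frac` a pair is also reported by a
#' second source.
#'
#' @param panel an [ld_panel()] from [generate_panel()].
#' @param config the same [sim_config()] used for the panel.
#' @return named list of per-study ASM tables (ready for
#'   [merge_sources()]), with attribute `manifest`: one row per distinct
#'   pair recording `pass_cis`, `pass_r2`, `pass_autosome`, `pass_all`.
#' @export
generate_asm_catalog <- function(panel, config) {
  validate_sim_config(config)
  set.seed(stream_seed(config$seed, 2L))
  v <- panel$variants
  n_combo <- nrow(v)
  cpgs_per_block <- max(1L, ceiling(config$n_asm_pairs / n_combo))
  combos <- rbindlist(lapply(seq_len(cpgs_per_block), function(k) {
    first <- v[, .(cpg_chrom = chrom[1L], cpg_anchor = pos[1L]), by = block]
    dt <- merge(v[, .(snp_id = id, snp_chrom = chrom, snp_pos = pos, alt, block)],
                first, by = "block")
    dt[, cpg_id := sprintf("cg%s_%d", sub("^B", "", block), k)]
    # CpGs of one block are spaced > 2x the 5 kb promoter window so each
    # simulated gene's promoter can only ever contain its own CpG
    dt[, cpg_pos := cpg_anchor + 500L + (k - 1L) * 12000L]
    dt
  }))
  if (config$n_asm_pairs > nrow(combos))
    stop("generate_asm_catalog: n_asm_pairs exceeds available SNP-CpG combinations (",
         nrow(combos), ")", call. = FALSE)
  pairs <- combos[sample(.N, config$n_asm_pairs)]

  # plant trans pairs: a distinct CpG on another chromosome
  n_trans <- floor(SIM_TRANS_FRAC * nrow(pairs))
  if (n_trans > 0) {
    ti <- sample(nrow(pairs), n_trans)
    # placed far from any simulated block so their genes cannot collide
    pairs[ti, `:=`(cpg_chrom = as.character((as.integer(snp_chrom) %% 22L) + 1L),
                   cpg_id = paste0(cpg_id, "t"),
                   cpg_pos = cpg_pos + 7000000L)]
  }
  # methylation correlation R^2: a low tail below the 0.2 filter, the rest
  # in asm_r2_range
  low <- runif(nrow(pairs)) < config$low_r2_frac
  pairs[, r2_meth := fifelse(low, runif(.N, 0, 0.199),
                             runif(.N, config$asm_r2_range[1], config$asm_r2_range[2]))]
  pairs[, meth_effect_allele := alt]
  pairs[, meth_direction := sample(c(-1L, 1L), .N, replace = TRUE)]

  # chromosome-X pairs (SNPs outside the autosomal panel)
  n_x <- round(config$chrx_frac * config$n_asm_pairs)
  if (n_x > 0) {
    xpos <- sort(sample(1e6:5e7, n_x))
    xpairs <- data.table(
      block = "BX", snp_id = sprintf("rsX%04d", seq_len(n_x)),
      snp_chrom = "X", snp_pos = xpos, alt = sample(c("A", "C", "G", "T"), n_x, TRUE),
      cpg_anchor = xpos, cpg_id = sprintf("cgX_%04d", seq_len(n_x)),
      cpg_chrom = "X", cpg_pos = xpos + 500L,
      r2_meth = runif(n_x, max(0.2, config$asm_r2_range[1]), config$asm_r2_range[2]),
      meth_effect_allele = sample(c("A", "C", "G", "T"), n_x, TRUE),
      meth_direction = sample(c(-1L, 1L), n_x, replace = TRUE)
    )
    pairs <- rbind(pairs, xpairs, use.names = TRUE)
  }

  src_i <- sample(nrow(SIM_SOURCES), nrow(pairs), replace = TRUE)
  pairs[, study := SIM_SOURCES$study[src_i]]
  pairs[, tissue := SIM_SOURCES$tissue[src_i]]
  dup <- runif(nrow(pairs)) < config$overlap_frac
  dup_rows <- pairs[dup]
  if (nrow(dup_rows)) {
    alt_i <- vapply(src_i[dup], function(i) sample(setdiff(seq_len(nrow(SIM_SOURCES)), i), 1L),
                    integer(1))
    dup_rows[, study := SIM_SOURCES$study[alt_i]]
    dup_rows[, tissue := SIM_SOURCES$tissue[alt_i]]
  }
  long <- rbind(pairs, dup_rows)
  cols <- c("snp_id", "snp_chrom", "snp_pos", "cpg_id", "cpg_chrom", "cpg_pos",
            "r2_meth", "meth_effect_allele", "meth_direction", "tissue", "study",
            "block")
  long <- long[, cols, with = FALSE]
  setorder(long, study, tissue, snp_chrom, snp_pos, cpg_id)

  manifest <- copy(pairs)[, .(snp_id, cpg_id, snp_chrom, snp_pos, cpg_chrom, cpg_pos,
                              block, r2_meth, meth_effect_allele, meth_direction)]
  manifest[, pass_cis := snp_chrom == cpg_chrom & abs(snp_pos - cpg_pos) <= 1e6]
  manifest[, pass_r2 := r2_meth >= 0.2]
  manifest[, pass_autosome := is_autosome(snp_chrom)]
  manifest[, pass_all := pass_cis & pass_r2 & pass_autosome]

  tables <- split(long[, !"block"], long$study)
  attr(tables, "manifest") <- manifest[]
  tables
}

# non-centrality needed for a two-sided z-test at level alpha to reject
# with probability target
solve_ncp <- function(target, alpha = 0.05) {
  if (target <= alpha + 1e-12) return(0)
  zc <- qnorm(1 - alpha / 2)
  f <- function(mu) pnorm(-zc - mu) + 1 - pnorm(zc - mu) - target
  uniroot(f, c(0, 40))$root
}

# significance probability for ASM SNPs giving the requested odds ratio of
# significance vs a uniform-null background at p < alpha
asm_sig_prob <- function(enrichment_or, alpha = 0.05) {
  odds0 <- alpha / (1 - alpha)
  (enrichment_or * odds0) / (1 + enrichment_or * odds0)
}

#' Simulate daner-style GWAS summary statistics over a panel
#'
#' One record per panel variant. Null variants receive z ~ N(0,1) (p
#' uniform on (0,1)); ASM SNPs receive a non-central z whose two-sided
#' rejection probability at p < 0.05 makes the odds of nominal significance
#' between ASM and non-ASM SNPs equal `enrichment_or` in expectation
#' (enrichment is injected through the test statistic because the pipeline
#' only ever consumes summary statistics). In `n_signal` randomly chosen
#' blocks one filter-passing ASM SNP is planted as a strong signal
#' (z centred on `signal_z`). A fraction `omit_frac` of ASM SNPs is omitted
#' from the output to exercise missing-SNP bookkeeping. Odds ratios are
#' `exp(z * se)` with `se` from an effective sample size of ~51,300
#' (a 20,183-case / 35,191-control design); `A1` is the panel alt allele.
#'
#' @param panel an [ld_panel()].
#' @param asm output of [generate_asm_catalog()] (its manifest defines ASM
#'   status).
#' @param config the shared [sim_config()].
#' @return a daner `data.table` (`CHR SNP BP A1 A2 OR SE P`), with
#'   attribute `manifest`: per panel variant `snp_id`, `is_asm`, `signal`,
#'   `z`, `p`, `omitted`, `risk_allele`.
#' @export
generate_sumstats <- function(panel, asm, config) {
  validate_sim_config(config)
  set.seed(stream_seed(config$seed, 3L))
  v <- copy(panel$variants)
  man_cat <- attr(asm, "manifest")
  asm_snps <- unique(man_cat$snp_id)
  v[, is_asm := id %in% asm_snps]

  mu_e <- solve_ncp(asm_sig_prob(config$enrichment_or), alpha = 0.05)
  z <- rnorm(nrow(v))
  z[v$is_asm] <- z[v$is_asm] + sample(c(-1, 1), sum(v$is_asm), TRUE) * mu_e

  # plant strong signals: one filter-passing ASM SNP in each chosen block
  v[, signal := FALSE]
  eligible <- man_cat[pass_all == TRUE & snp_id %in% v$id]
  sig_blocks <- sample(unique(eligible$block), min(config$n_signal, length(unique(eligible$block))))
  for (b in sig_blocks) {
    pick <- sample(unique(eligible[block == b, snp_id]), 1L)
    i <- match(pick, v$id)
    z[i] <- sample(c(-1, 1), 1) * (config$signal_z + rnorm(1, 0, 0.5))
    v$signal[i] <- TRUE
  }

  p <- pmax(2 * pnorm(-abs(z)), 1e-300)
  neff <- 4 / (1 / 20183 + 1 / 35191)
  maf <- if ("maf" %in% names(v)) v$maf else rep(0.3, nrow(v))
  se <- 1 / sqrt(2 * maf * (1 - maf) * neff)
  or_vec <- exp(z * se)

  n_asm_panel <- sum(v$is_asm)
  omit_ids <- character(0)
  n_omit <- floor(config$omit_frac * n_asm_panel)
  if (n_omit > 0) {
    # never omit planted signals: omission models random platform gaps
    omit_pool <- v[is_asm & !signal, id]
    omit_ids <- sample(omit_pool, min(n_omit, length(omit_pool)))
  }

  manifest <- data.table(
    snp_id = v$id, is_asm = v$is_asm, signal = v$signal, z = z, p = p,
    omitted = v$id %in% omit_ids,
    risk_allele = fifelse(or_vec > 1, v$alt, v$ref)
  )
  ss <- data.table(CHR = v$chrom, SNP = v$id, BP = v$pos, A1 = v$alt, A2 = v$ref,
                   OR = or_vec, SE = se, P = p)
  ss <- ss[!SNP %in% omit_ids]
  attr(ss, "manifest") <- manifest
  ss[]
}

#' Lightweight enrichment-study simulator
#'
#' Draws only the per-SNP p-values and ASM labels of
#' [generate_sumstats()]'s enrichment model — no panel, no alleles — for
#' type-I-error and power simulations over many replicates.
#'
#' @param n_snps total SNPs; @param n_asm how many are ASM.
#' @param enrichment_or odds ratio of nominal significance (>= 1).
#' @return `data.table` with columns `p`, `is_asm`.
#' @export
simulate_enrichment_study <- function(n_snps, n_asm, enrichment_or = 1) {
  mu_e <- solve_ncp(asm_sig_prob(enrichment_or), alpha = 0.05)
  is_asm <- c(rep(TRUE, n_asm), rep(FALSE, n_snps - n_asm))
  z <- rnorm(n_snps)
  z[is_asm] <- z[is_asm] + sample(c(-1, 1), n_asm, TRUE) * mu_e
  data.table(p = pmax(2 * pnorm(-abs(z)), 1e-300), is_asm = is_asm)
}

#' Simulate tagged LD blocks with planted partner counts
#'
#' Builds a panel of perfect-LD blocks (every variant of a block is an
#' identical haplotype column, so all within-block r^2 are exactly 1) plus
#' a catalog in which each block's SNPs share one CpG. Block `b` holds one
#' tag plus `partner_counts[b]` partners: running [ld_expand()] on the
#' tags must return exactly `sum(partner_counts) + length(partner_counts)`
#' distinct variants. Used for LD-expansion bookkeeping checks.
#'
#' @param partner_counts integer vector: tagged partners per block.
#' @param n_haplotypes panel haplotypes.
#' @param seed RNG seed.
#' @return list with `panel`, `catalog`, `tags`.
#' @export
simulate_tagged_blocks <- function(partner_counts, n_haplotypes = 100L, seed = 1L) {
  set.seed(seed)
  sizes <- as.integer(partner_counts) + 1L
  cols <- list(); meta <- list()
  k <- 0L
  for (b in seq_along(sizes)) {
    repeat {
      anchor <- rbinom(n_haplotypes, 1L, 0.4)
      if (sum(anchor) > 0 && sum(anchor) < n_haplotypes) break
    }
    for (j in seq_len(sizes[b])) {
      k <- k + 1L
      cols[[k]] <- anchor
      meta[[k]] <- data.table(
        id = sprintf("s%02d_%02d", b, j), chrom = as.character(b),
        pos = j * 1000L, ref = "A", alt = "G", block = b)
    }
  }
  vt <- rbindlist(meta)
  panel <- ld_panel(do.call(cbind, cols), vt[, !"block"])
  catalog <- vt[, .(snp_id = id, cpg_id = paste0("cg", block),
                    snp_chrom = chrom, snp_pos = pos,
                    cpg_chrom = chrom, cpg_pos = 500L,
                    r2_meth = 0.5, meth_effect_allele = "G",
                    meth_direction = 1L)]
  tags <- vt[, .SD[1], by = block]$id
  list(panel = panel, catalog = catalog, tags = tags)
}

SIM_BRAIN_REGIONS <- c(
  "hippocampus middle", "substantia nigra", "anterior caudate",
  "cingulate gyrus", "inferior temporal lobe", "angular gyrus",
  "dorsolateral prefrontal cortex", "germinal matrix",
  "fetal brain male", "fetal brain female")

SIM_HISTONE_MARKS <- c("H3K4me1", "H3K27ac", "H3K4me3", "H3K9ac")

SIM_EQTL_TISSUES <- c("cerebellum", "cortex", "caudate basal ganglia",
                      "hippocampus")

SIM_VOLUME_STRUCTURES <- c("nucleus accumbens", "amygdala", "caudate nucleus",
                           "hippocampus", "pallidum", "putamen", "thalamus")

#' Simulate TSS, histone-mark, eQTL and brain-volume annotation tables
#'
#' Emits the four lookup tables of the functional-integration stage:
#'
#' * a strand-aware TSS table with one gene per CpG; a `promoter_frac`
#'   subset of CpGs is placed strictly < 5000 bp upstream of its TSS, the
#'   rest 6-50 kb upstream;
#' * a brain eQTL table for catalog SNPs: for promoter-CpG genes, the
#'   risk-allele-aligned slope sign is opposite to the risk-aligned
#'   methylation direction with probability `consistency_rate` (the eQTL's
#'   recorded effect allele is randomized between risk and non-risk allele
#'   to exercise orientation);
#' * per-SNP histone-mark flags across 10 brain regions and 4 mark
#'   classes (Bernoulli `mark_density`);
#' * a 7-structure subcortical volume-GWAS table with uniform-null
#'   p-values, planted hits for up to three signal SNPs, and a
#'   `volume_absent_frac` of SNPs missing entirely.
#'
#' @param asm output of [generate_asm_catalog()].
#' @param config shared [sim_config()].
#' @param sumstats output of [generate_sumstats()] (its manifest supplies
#'   the risk alleles); when `NULL`, the methylation effect allele is
#'   treated as the risk allele.
#' @return an `annotation_bundle` list (`tss`, `histone`, `eqtl`,
#'   `volume`) with attribute `manifest` (promoter truth per CpG and
#'   consistency truth per SNP-gene).
#' @export
generate_annotation_tables <- function(asm, config, sumstats = NULL) {
  validate_sim_config(config)
  set.seed(stream_seed(config$seed, 4L))
  man_cat <- attr(asm, "manifest")
  ss_man <- if (!is.null(sumstats)) attr(sumstats, "manifest") else NULL

  cpgs <- unique(man_cat[, .(cpg_id, cpg_chrom, cpg_pos)])
  n_cpg <- nrow(cpgs)
  is_prom <- runif(n_cpg) < config$promoter_frac
  strand <- sample(c("+", "-"), n_cpg, replace = TRUE)
  dist_up <- ifelse(is_prom, sample(200:4800, n_cpg, TRUE), sample(6000:50000, n_cpg, TRUE))
  tss <- data.table(
    gene = paste0("G_", cpgs$cpg_id), chrom = cpgs$cpg_chrom,
    strand = strand,
    tss_pos = as.integer(ifelse(strand == "+", cpgs$cpg_pos + dist_up,
                                cpgs$cpg_pos - dist_up))
  )
  prom_truth <- data.table(cpg_id = cpgs$cpg_id, gene = tss$gene,
                           is_promoter = is_prom, distance = dist_up)

  # risk-aligned methylation sign per catalog pair
  pairs <- copy(man_cat)
  if (!is.null(ss_man)) {
    pairs <- merge(pairs, ss_man[, .(snp_id, risk_allele)], by = "snp_id", all.x = TRUE)
    pairs[is.na(risk_allele), risk_allele := meth_effect_allele]
  } else pairs[, risk_allele := meth_effect_allele]
  pairs[, meth_risk := fifelse(risk_allele == meth_effect_allele,
                               as.integer(meth_direction), -as.integer(meth_direction))]
  pairs <- merge(pairs, prom_truth, by = "cpg_id")

  # eQTLs for promoter genes of filter-passing pairs
  ep <- pairs[pass_all == TRUE & is_promoter == TRUE]
  eqtl_rows <- list(); cons_truth <- list()
  if (nrow(ep)) {
    for (i in seq_len(nrow(ep))) {
      consistent <- runif(1) < config$consistency_rate
      target <- if (consistent) -ep$meth_risk[i] else ep$meth_risk[i]
      tiss <- sample(SIM_EQTL_TISSUES, sample(1:3, 1))
      use_risk <- runif(length(tiss)) < 0.5
      other <- setdiff(c("A", "C", "G", "T"), ep$risk_allele[i])[1]
      eqtl_rows[[length(eqtl_rows) + 1L]] <- data.table(
        snp_id = ep$snp_id[i], gene = ep$gene[i], tissue = tiss,
        effect_allele = ifelse(use_risk, ep$risk_allele[i], other),
        slope_sign = ifelse(use_risk, target, -target))
      cons_truth[[length(cons_truth) + 1L]] <- data.table(
        snp_id = ep$snp_id[i], gene = ep$gene[i], cpg_id = ep$cpg_id[i],
        consistent = consistent)
    }
  }
  eqtl <- if (length(eqtl_rows)) unique(rbindlist(eqtl_rows)) else
    data.table(snp_id = character(), gene = character(), tissue = character(),
               effect_allele = character(), slope_sign = integer())

  # histone marks: full 40-flag grid per catalog SNP
  snps <- unique(man_cat$snp_id)
  grid <- CJ(snp_id = snps, region = SIM_BRAIN_REGIONS, mark = SIM_HISTONE_MARKS)
  grid[, present := as.integer(runif(.N) < config$mark_density)]

  # volume GWAS: mostly null, a few planted hits on signal SNPs
  vol_snps <- snps
  if (config$volume_absent_frac > 0)
    vol_snps <- setdiff(vol_snps, sample(snps, floor(config$volume_absent_frac * length(snps))))
  vol <- CJ(snp_id = vol_snps, structure_ = SIM_VOLUME_STRUCTURES)
  vol[, effect_allele := sample(c("A", "C", "G", "T"), .N, TRUE)]
  vol[, beta_sign := sample(c(-1L, 1L), .N, TRUE)]
  vol[, p := runif(.N)]
  planted <- character(0)
  if (!is.null(ss_man)) {
    sig_present <- intersect(ss_man[signal == TRUE, snp_id], vol_snps)
    planted <- head(sig_present, 3)
    vol[snp_id %in% planted & structure_ %in% c("nucleus accumbens", "caudate nucleus"),
        p := runif(.N, 1e-6, 1e-4)]
  }

  bundle <- structure(list(tss = tss[], histone = grid[], eqtl = eqtl[],
                           volume = vol[]),
                      class = "annotation_bundle")
  attr(bundle, "manifest") <- list(
    promoter = prom_truth[],
    consistency = if (length(cons_truth)) rbindlist(cons_truth) else
      data.table(snp_id = character(), gene = character(), cpg_id = character(),
                 consistent = logical()),
    volume_planted = planted
  )
  bundle
}

#' @export
print.annotation_bundle <- function(x, ...) {
  cat(sprintf("<annotation_bundle> %d genes, %d histone flags, %d eQTL rows, %d volume rows\n",
              nrow(x$tss), nrow(x$histone), nrow(x$eqtl), nrow(x$volume)))
  invisible(x)
}
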