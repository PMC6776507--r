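#' Orient a summary-statistic record to its risk allele
#'
#' The risk allele is the effect allele `a1` when `OR > 1` and `a2`
#' otherwise; every downstream methylation/eQTL/volume sign is then
#' re-expressed relative to it. `OR == 1` exactly is flagged undetermined
#' and excluded from direction logic.
#'
#' @param a1,a2 effect and other allele.
#' @param or_ odds ratio for `a1`.
#' @return list with `risk_allele`, `other_allele`, `status`
#'   (`"ok"`/`"undetermined"`).
#' @export
orient_risk <- function(a1, a2, or_) {
  if (is.na(or_) || or_ <= 0) stop("orient_risk: OR must be positive", call. = FALSE)
  if (or_ == 1)
    return(list(risk_allele = NA_character_, other_allele = NA_character_,
                status = "undetermined"))
  if (or_ > 1) list(risk_allele = a1, other_allele = a2, status = "ok")
  else list(risk_allele = a2, other_allele = a1, status = "ok")
}

#' Re-express an allelic effect sign relative to the risk allele
#'
#' @param sign effect sign (+1/-1) attached to `effect_allele`.
#' @param effect_allele allele the sign refers to.
#' @param risk_allele the risk allele from [orient_risk()].
#' @return the sign for the risk allele (flipped when the annotation's
#'   effect allele is the non-risk allele).
#' @export
align_to_risk <- function(sign, effect_allele, risk_allele) {
  ifelse(effect_allele == risk_allele, sign, -sign)
}

#' Map CpG sites to genes whose promoter they may lie in
#'
#' A CpG maps to a gene when it lies strictly within `window` bp upstream
#' of the TSS on the gene's strand (positions below the TSS for `+` genes,
#' above for `-`; distance 0, i.e. at the TSS, is included; downstream
#' positions never map).
#'
#' @param cpgs `data.table` with `cpg_id`, `cpg_chrom`, `cpg_pos`.
#' @param tss_table `data.table` with `gene`, `chrom`, `strand`, `tss_pos`.
#' @param window upstream window in bp (strict `<`); default 5000.
#' @return `data.table` with `cpg_id`, `gene`, `distance`.
#' @export
promoter_map <- function(cpgs, tss_table, window = 5000) {
  cg <- unique(as.data.table(cpgs)[, .(cpg_id, cpg_chrom = norm_chrom(cpg_chrom), cpg_pos)])
  ts <- as.data.table(tss_table)
  ts[, chrom := norm_chrom(chrom)]
  hits <- merge(cg, ts, by.x = "cpg_chrom", by.y = "chrom", allow.cartesian = TRUE)
  hits[, distance := fifelse(strand == "+", tss_pos - cpg_pos, cpg_pos - tss_pos)]
  hits <- hits[distance >= 0 & distance < window]
  hits[, .(cpg_id, gene, distance)][order(cpg_id, gene)]
}

#' Methylation / expression direction-consistency verdict
#'
#' Promoter methylation is expected to anti-correlate with expression: a
#' gene is `consistent` when every risk-aligned tissue-level eQTL sign is
#' opposite to the risk-aligned methylation sign of its promoter CpG,
#' `inconsistent` when every sign is equal, `discordant-across-tissues`
#' when tissues disagree, and `insufficient-data` when either side is
#' missing (never a silent pass).
#'
#' @param meth_sign risk-aligned methylation sign (+1/-1) of the promoter
#'   CpG.
#' @param eqtl_signs risk-aligned eQTL signs across tissues for the gene.
#' @return a single verdict string.
#' @export
consistency_check <- function(meth_sign, eqtl_signs) {
  eqtl_signs <- eqtl_signs[!is.na(eqtl_signs)]
  if (is.na(meth_sign) || length(eqtl_signs) == 0L) return("insufficient-data")
  if (length(unique(eqtl_signs)) > 1L) return("discordant-across-tissues")
  if (meth_sign * eqtl_signs[1] == -1) "consistent" else "inconsistent"
}

#' Count enhancer and promoter histone marks for a SNP
#'
#' Enhancer marks are H3K4me1 and H3K27ac, promoter marks H3K4me3 and
#' H3K9ac; each is counted over (region, mark) pairs across the brain
#' regions of the table (max 20 per class with 10 regions).
#'
#' @param snp a SNP id.
#' @param histone_table long `data.table` with `snp_id`, `region`, `mark`,
#'   `present` (0/1).
#' @return list `enhancer_count`, `promoter_count`, `no_data` (SNP absent
#'   from the table).
#' @export
count_marks <- function(snp, histone_table) {
  ht <- as.data.table(histone_table)[snp_id == snp]
  if (!nrow(ht)) return(list(enhancer_count = 0L, promoter_count = 0L, no_data = TRUE))
  list(
    enhancer_count = ht[mark %in% c("H3K4me1", "H3K27ac"), sum(present > 0)],
    promoter_count = ht[mark %in% c("H3K4me3", "H3K9ac"), sum(present > 0)],
    no_data = FALSE
  )
}

#' Subcortical-volume association lookup with per-run Bonferroni
#'
#' The Bonferroni denominator is the number of queried SNPs actually
#' present in the volume table (recomputed per run, never hard-coded);
#' absent SNPs get status `"?"`. Directions are re-expressed relative to
#' each SNP's risk allele.
#'
#' @param snps SNP ids to query.
#' @param volume_table `data.table` with `snp_id`, `structure_`,
#'   `effect_allele`, `beta_sign`, `p`.
#' @param risk_alleles named character vector (by SNP id).
#' @param alpha family-wise level; threshold is `alpha / n_present`.
#' @return list with `threshold`, `n_queried` (present SNPs) and `hits`
#'   (`snp_id`, `status` of `hit`/`none`/`?`, `structure_`, `direction`,
#'   `p`).
#' @export
volume_lookup <- function(snps, volume_table, risk_alleles = NULL, alpha = 0.05) {
  vt <- as.data.table(volume_table)
  present <- intersect(snps, unique(vt$snp_id))
  thr <- if (length(present)) alpha / length(present) else NA_real_
  rows <- lapply(snps, function(s) {
    if (!s %in% present)
      return(data.table(snp_id = s, status = "?", structure_ = NA_character_,
                        direction = NA_integer_, p = NA_real_))
    sub <- vt[snp_id == s & p <= thr]
    if (!nrow(sub))
      return(data.table(snp_id = s, status = "none", structure_ = NA_character_,
                        direction = NA_integer_, p = NA_real_))
    ra <- if (!is.null(risk_alleles)) risk_alleles[s] else NA_character_
    dir <- if (is.na(ra)) sub$beta_sign else
      as.integer(align_to_risk(sub$beta_sign, sub$effect_allele, ra))
    data.table(snp_id = s, status = "hit", structure_ = sub$structure_,
               direction = dir, p = sub$p)
  })
  list(threshold = thr, n_queried = length(present), hits = rbindlist(rows)[])
}

#' Annotate associated variants with all functional evidence
#'
#' Per variant: risk allele, risk-aligned methylation direction per CpG,
#' promoter genes of those CpGs, risk-aligned eQTL signs and consistency
#' verdicts per promoter gene, histone-mark counts, volume hits, and the
#' additive annotation score used for per-block prioritization
#' (`enhancer_count + promoter_count + #eQTL genes + #volume hits`; the
#' weights are exposed).
#'
#' @param variants `data.table` with `snp_id` and, when available from the
#'   join, `a1`, `a2`, `or_`, `p`.
#' @param catalog filtered ASM catalog.
#' @param bundle an `annotation_bundle`.
#' @param panel an [ld_panel()] (for positions).
#' @param promoter_window upstream window for [promoter_map()].
#' @param volume_alpha level for [volume_lookup()].
#' @param weights named numeric vector over `enhancer`, `promoter`,
#'   `eqtl`, `volume`.
#' @return `data.table`, one row per variant, with list-columns
#'   `meth` (per-CpG signs), `genes`, `eqtl_signs`, `verdicts`,
#'   `volume_hits` and scalar columns `risk_allele`, `enhancer_count`,
#'   `promoter_count`, `n_eqtl_genes`, `n_volume_hits`, `score`.
#' @export
annotate_variants <- function(variants, catalog, bundle, panel,
                              promoter_window = 5000, volume_alpha = 0.05,
                              weights = c(enhancer = 1, promoter = 1, eqtl = 1, volume = 1)) {
  vr <- as.data.table(variants)
  cat_dt <- as.data.table(catalog)
  pos_of <- setNames(panel$variants$pos, panel$variants$id)

  prom <- promoter_map(unique(cat_dt[, .(cpg_id, cpg_chrom, cpg_pos)]), bundle$tss,
                       window = promoter_window)

  # risk alleles (undetermined/absent -> NA)
  risk <- vapply(seq_len(nrow(vr)), function(i) {
    if (!all(c("a1", "a2", "or_") %in% names(vr)) || is.na(vr$or_[i])) return(NA_character_)
    orient_risk(vr$a1[i], vr$a2[i], vr$or_[i])$risk_allele
  }, character(1))
  names(risk) <- vr$snp_id

  vlk <- volume_lookup(vr$snp_id, bundle$volume, risk_alleles = risk, alpha = volume_alpha)

  rows <- lapply(seq_len(nrow(vr)), function(i) {
    s <- vr$snp_id[i]
    ra <- risk[[s]]
    pairs <- cat_dt[snp_id == s]
    meth <- if (nrow(pairs) && !is.na(ra))
      setNames(as.integer(align_to_risk(pairs$meth_direction, pairs$meth_effect_allele, ra)),
               pairs$cpg_id) else setNames(integer(0), character(0))
    pg <- prom[cpg_id %in% pairs$cpg_id]
    eq <- bundle$eqtl[snp_id == s]
    eq_genes <- unique(eq$gene)
    eq_signs <- lapply(setNames(eq_genes, eq_genes), function(g) {
      sub <- eq[gene == g]
      if (is.na(ra)) rep(NA_integer_, nrow(sub))
      else as.integer(align_to_risk(sub$slope_sign, sub$effect_allele, ra))
    })
    pg_genes <- unique(pg$gene)
    verdicts <- vapply(setNames(pg_genes, pg_genes), function(g) {
      cgs <- pg[gene == g, cpg_id]
      ms <- meth[intersect(cgs, names(meth))]
      ms <- unique(ms[!is.na(ms)])
      msig <- if (length(ms) == 1L) ms else NA_integer_
      consistency_check(msig, eq_signs[[g]] %||% integer(0))
    }, character(1), USE.NAMES = TRUE)
    mk <- count_marks(s, bundle$histone)
    vh <- vlk$hits[snp_id == s & status == "hit"]
    score <- weights[["enhancer"]] * mk$enhancer_count +
      weights[["promoter"]] * mk$promoter_count +
      weights[["eqtl"]] * length(eq_genes) +
      weights[["volume"]] * nrow(vh)
    data.table(
      snp_id = s, risk_allele = ra %||% NA_character_,
      p = if ("p" %in% names(vr)) vr$p[i] else NA_real_,
      pos = unname(pos_of[s]),
      enhancer_count = mk$enhancer_count, promoter_count = mk$promoter_count,
      no_mark_data = mk$no_data,
      n_eqtl_genes = length(eq_genes), n_volume_hits = nrow(vh),
      volume_status = if (nrow(vh)) "hit" else vlk$hits[snp_id == s, status][1],
      score = score,
      meth = list(meth), promoter_genes = list(unique(pg$gene)),
      eqtl_signs = list(eq_signs), verdicts = list(verdicts),
      volume_hits = list(vh))
  })
  res <- rbindlist(rows)
  setattr(res, "volume_threshold", vlk$threshold)
  setattr(res, "volume_n_queried", vlk$n_queried)
  res[]
}

#' Pick the putative causal SNP of an LD block
#'
#' The variant with the highest annotation score; ties broken by smaller
#' GWAS p-value, then leftmost position. Errors on an empty block.
#'
#' @param block_annotations rows of [annotate_variants()] for one block.
#' @return the selected row (single-row `data.table`).
#' @export
prioritize_block <- function(block_annotations) {
  ba <- as.data.table(block_annotations)
  if (!nrow(ba)) stop("prioritize_block: empty block", call. = FALSE)
  o <- order(-ba$score, fifelse(is.na(ba$p), Inf, ba$p), ba$pos)
  ba[o[1L]]
}

sign_arrow <- function(s) fifelse(is.na(s), "?", fifelse(s > 0, "up", "down"))

#' Build the per-block putative-causal-SNP report
#'
#' One row per LD block: the prioritized SNP with its risk allele, GWAS p,
#' per-CpG methylation arrows (`up`/`down` relative to the risk allele),
#' histone-mark counts, per-gene expression arrows (promoter genes
#' bracketed with `*`), volume arrows, the consistency verdicts, and an
#' `underline` flag for SNPs passing both the Bonferroni and
#' effective-tests thresholds.
#'
#' @param screen a `screen_result` from [screen_tags()].
#' @param annotations output of [annotate_variants()] for the expanded
#'   variant set.
#' @param blocks block assignment from [assign_blocks()].
#' @return `data.table`, one row per block, ordered by block id.
#' @export
build_report <- function(screen, annotations, blocks) {
  ann <- merge(as.data.table(annotations), as.data.table(blocks), by = "snp_id")
  sc <- as.data.table(screen)
  out <- lapply(sort(unique(ann$block_id)), function(b) {
    cand <- prioritize_block(ann[block_id == b])
    meth <- cand$meth[[1]]
    eq <- cand$eqtl_signs[[1]]
    pg <- cand$promoter_genes[[1]]
    expr_str <- if (length(eq)) paste(vapply(names(eq), function(g) {
      sgn <- unique(eq[[g]][!is.na(eq[[g]])])
      arrow <- if (length(sgn) == 1L) sign_arrow(sgn) else "mixed"
      lab <- if (g %in% pg) paste0("*", g, "*") else g
      paste0(arrow, " ", lab)
    }, character(1)), collapse = "; ") else "-"
    vh <- cand$volume_hits[[1]]
    vol_str <- if (cand$volume_status == "?") "?"
      else if (nrow(vh)) paste(paste0(sign_arrow(vh$direction), " ", vh$structure_),
                               collapse = "; ") else "-"
    verd <- cand$verdicts[[1]]
    in_screen <- sc[snp_id == cand$snp_id]
    data.table(
      block_id = b, snp_id = cand$snp_id, risk_allele = cand$risk_allele,
      p = cand$p,
      methylation = if (length(meth)) paste(paste0(sign_arrow(meth), " ", names(meth)),
                                            collapse = "; ") else "-",
      enhancer = cand$enhancer_count, promoter = cand$promoter_count,
      expression = expr_str, volumes = vol_str,
      consistency = if (length(verd)) paste(paste0(names(verd), ": ", verd),
                                            collapse = "; ") else "-",
      score = cand$score,
      underline = nrow(in_screen) > 0 && in_screen$pass_bonferroni[1] &&
        in_screen$pass_meff[1]
    )
  })
  rbindlist(out)[]
}
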