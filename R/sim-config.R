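#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. The defaults
#' describe a desk-scale world shaped like the real inputs: a CEU-sized
#' phased reference panel, a multi-study multi-tissue ASM catalog with a
#' tail of sub-0.2 methylation correlations and a small chromosome-X
#' fraction, GWAS summary statistics in which ASM SNPs are enriched for
#' sub-threshold association, and annotation tables with a tunable
#' methylation/expression direction-consistency rate.
#'
#' @param n_haplotypes number of phased haplotypes in the panel (2N). The
#'   default 200 matches the size of a CEU-like reference panel.
#' @param n_blocks number of LD blocks simulated.
#' @param snps_per_block variants per LD block.
#' @param within_block_r2 target pairwise LD r^2 inside a block, in `[0,1]`.
#' @param maf_range length-2 vector of minor-allele-frequency bounds in
#'   `(0, 0.5]`; one MAF per block is drawn uniformly from this range.
#' @param n_asm_pairs number of autosomal SNP-CpG ASM pairs to emit.
#' @param asm_r2_range length-2 vector: range of the SNP-methylation
#'   correlation R^2 assigned to passing pairs.
#' @param low_r2_frac fraction of pairs deliberately given R^2 < 0.2 so the
#'   catalog filter has work to do.
#' @param chrx_frac fraction of extra pairs placed on chromosome X (removed
#'   by the autosome filter).
#' @param overlap_frac probability that a pair is reported by a second
#'   study/tissue source (duplicated provenance).
#' @param enrichment_or odds ratio (>= 1) of nominal GWAS significance
#'   (p < 0.05) for ASM SNPs relative to non-ASM SNPs.
#' @param omit_frac fraction of ASM SNPs absent from the summary statistics
#'   (exercises missing-SNP bookkeeping). Default 0.032, i.e. ~96.8%
#'   retrieval.
#' @param n_signal number of LD blocks that receive a strongly associated
#'   ASM SNP (the planted "causal" signals).
#' @param signal_z mean of the association z-score for planted signal SNPs.
#' @param consistency_rate probability in `[0,1]` that a promoter-CpG eQTL
#'   direction is inverse to the methylation direction (relative to the
#'   risk allele).
#' @param promoter_frac fraction of CpGs placed < 5000 bp upstream of a
#'   simulated TSS.
#' @param mark_density per-(region, mark) Bernoulli rate of a histone-mark
#'   flag. The default 0.047 makes ~85% of SNPs carry at least one of the
#'   40 possible marks.
#' @param volume_absent_frac fraction of SNPs missing from the volume-GWAS
#'   table (reported as "?" downstream).
#' @param seed master RNG seed; every generator derives its own stream
#'   from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_blocks = 5, snps_per_block = 4, seed = 1)
sim_config <- function(n_haplotypes = 200L,
                       n_blocks = 40L,
                       snps_per_block = 6L,
                       within_block_r2 = 0.9,
                       maf_range = c(0.05, 0.5),
                       n_asm_pairs = 400L,
                       asm_r2_range = c(0.2, 0.95),
                       low_r2_frac = 0.15,
                       chrx_frac = 0.05,
                       overlap_frac = 0.3,
                       enrichment_or = 2,
                       omit_frac = 0.032,
                       n_signal = 8L,
                       signal_z = 6,
                       consistency_rate = 1,
                       promoter_frac = 0.8,
                       mark_density = 0.047,
                       volume_absent_frac = 0.1,
                       seed = 1L) {
  cfg <- list(
    n_haplotypes = as.integer(n_haplotypes),
    n_blocks = as.integer(n_blocks),
    snps_per_block = as.integer(snps_per_block),
    within_block_r2 = within_block_r2,
    maf_range = as.numeric(maf_range),
    n_asm_pairs = as.integer(n_asm_pairs),
    asm_r2_range = as.numeric(asm_r2_range),
    low_r2_frac = low_r2_frac,
    chrx_frac = chrx_frac,
    overlap_frac = overlap_frac,
    enrichment_or = enrichment_or,
    omit_frac = omit_frac,
    n_signal = as.integer(n_signal),
    signal_z = signal_z,
    consistency_rate = consistency_rate,
    promoter_frac = promoter_frac,
    mark_density = mark_density,
    volume_absent_frac = volume_absent_frac,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stop_if <- function(cond, msg) if (cond) stop("sim_config: ", msg, call. = FALSE)
  counts <- c("n_haplotypes", "n_blocks", "snps_per_block", "n_asm_pairs")
  for (f in counts) stop_if(is.na(cfg[[f]]) || cfg[[f]] < 1L, paste0(f, " must be a positive count"))
  stop_if(cfg$within_block_r2 < 0 || cfg$within_block_r2 > 1, "within_block_r2 must lie in [0,1]")
  stop_if(length(cfg$maf_range) != 2 || any(cfg$maf_range <= 0) || any(cfg$maf_range > 0.5) ||
            diff(cfg$maf_range) < 0, "maf_range must be an ordered pair in (0, 0.5]")
  stop_if(length(cfg$asm_r2_range) != 2 || any(cfg$asm_r2_range < 0) ||
            any(cfg$asm_r2_range > 1) || diff(cfg$asm_r2_range) < 0,
          "asm_r2_range must be an ordered pair in [0,1]")
  probs <- c("low_r2_frac", "chrx_frac", "overlap_frac", "omit_frac",
             "consistency_rate", "promoter_frac", "mark_density",
             "volume_absent_frac")
  for (f in probs) stop_if(cfg[[f]] < 0 || cfg[[f]] > 1, paste0(f, " must lie in [0,1]"))
  stop_if(cfg$enrichment_or < 1, "enrichment_or must be >= 1")
  stop_if(cfg$n_signal < 0 || cfg$n_signal > cfg$n_blocks,
          "n_signal must lie in [0, n_blocks]")
  stop_if(is.na(cfg$seed), "seed must be an integer")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (f in names(x)) cat(sprintf("  %-20s %s\n", f, paste(format(x[[f]]), collapse = ", ")))
  invisible(x)
}
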