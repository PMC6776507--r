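#' Phased haplotype reference panel
#'
#' An `ld_panel` holds a binary haplotype matrix (rows = phased haplotypes,
#' columns = variants; entries are alt-allele indicators) plus a variant
#' index. It is the single source of every LD r^2 in the pipeline, standing
#' in for a 1000 Genomes-style reference panel.
#'
#' @param hap integer matrix of 0/1 with one column per variant; column
#'   names must equal `variants$id`.
#' @param variants `data.table` with columns `id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt` and optionally `block`.
#' @return an object of class `ld_panel`.
#' @export
ld_panel <- function(hap, variants) {
  variants <- as.data.table(variants)
  hap <- as.matrix(hap)
  storage.mode(hap) <- "integer"
  if (!all(hap %in% c(0L, 1L))) stop("ld_panel: haplotype entries must be 0/1", call. = FALSE)
  if (ncol(hap) != nrow(variants)) stop("ld_panel: one haplotype column per variant required", call. = FALSE)
  if (anyDuplicated(variants$id)) stop("ld_panel: duplicate variant ids", call. = FALSE)
  variants[, chrom := norm_chrom(chrom)]
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt)
  if (anyDuplicated(key)) stop("ld_panel: duplicate variants by (chrom, pos, alleles)", call. = FALSE)
  bad <- variants[, any(diff(pos) <= 0), by = chrom][V1 == TRUE]
  if (nrow(bad)) stop("ld_panel: positions must be strictly increasing within a chromosome", call. = FALSE)
  colnames(hap) <- variants$id
  structure(list(hap = hap, variants = variants), class = "ld_panel")
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf("<ld_panel> %d haplotypes x %d variants on %d chromosome(s)\n",
              nrow(x$hap), ncol(x$hap), length(unique(x$variants$chrom))))
  invisible(x)
}

#' Number of haplotypes and variants
#' @param x an `ld_panel`.
#' @export
dim.ld_panel <- function(x) dim(x$hap)

hap_col <- function(panel, id) {
  j <- match(id, colnames(panel$hap))
  if (anyNA(j)) stop("variant(s) absent from panel: ", paste(id[is.na(j)], collapse = ", "),
                     call. = FALSE)
  panel$hap[, j, drop = TRUE]
}

#' Simulate a phased reference panel with block LD structure
#'
#' LD is induced by a haplotype-copying scheme: each block has one latent
#' anchor haplotype drawn Bernoulli(MAF) (not emitted), and every variant
#' in the block copies the anchor per-haplotype with probability
#' `within_block_r2^(1/4)` (and is otherwise redrawn independently at the
#' same MAF). Two emitted variants then have correlation
#' `within_block_r2^(1/2)`, i.e. every within-block pair has expected r^2
#' equal to `within_block_r2`; cross-block r^2 is ~0. All variants of a
#' block share one MAF (unequal frequencies would cap the attainable r^2
#' below the target).
#'
#' Blocks are distributed over autosomes 1..22 with strictly increasing
#' positions per chromosome; alleles are random distinct A/C/G/T pairs
#' (including strand-ambiguous pairs, on purpose, to exercise
#' harmonization).
#'
#' @param config a [sim_config()].
#' @return an [ld_panel()] whose `variants` carry `block` and `maf` columns.
#' @export
#' @examples
#' p <- generate_panel(sim_config(n_blocks = 3, snps_per_block = 4, seed = 1))
#' dim(p)
generate_panel <- function(config) {
  validate_sim_config(config)
  set.seed(stream_seed(config$seed, 1L))
  n_hap <- config$n_haplotypes
  c_copy <- config$within_block_r2^0.25
  bases <- c("A", "C", "G", "T")

  draw_polymorphic <- function(p) {
    for (i in 1:100) {
      x <- rbinom(n_hap, 1L, p)
      if (sum(x) > 0L && sum(x) < n_hap) return(x)
    }
    stop("generate_panel: cannot realize a polymorphic variant at MAF ", signif(p, 3),
         " with ", n_hap, " haplotypes (requested r2/MAF combination unattainable)",
         call. = FALSE)
  }

  hap_cols <- vector("list", config$n_blocks * config$snps_per_block)
  vt <- vector("list", config$n_blocks)
  chrom_block_counter <- integer(22)
  k <- 0L
  for (b in seq_len(config$n_blocks)) {
    chrom_i <- ((b - 1L) %% 22L) + 1L
    chrom_block_counter[chrom_i] <- chrom_block_counter[chrom_i] + 1L
    base_pos <- (chrom_block_counter[chrom_i] - 1L) * 1000000L + 10000L
    maf <- runif(1, config$maf_range[1], config$maf_range[2])
    anchor <- draw_polymorphic(maf)
    ids <- character(config$snps_per_block)
    poss <- integer(config$snps_per_block)
    refs <- character(config$snps_per_block)
    alts <- character(config$snps_per_block)
    for (j in seq_len(config$snps_per_block)) {
      k <- k + 1L
      for (try in 1:100) {
        keep_mask <- runif(n_hap) < c_copy
        x <- ifelse(keep_mask, anchor, rbinom(n_hap, 1L, maf))
        if (sum(x) > 0L && sum(x) < n_hap) break
        if (try == 100)
          stop("generate_panel: cannot realize requested within-block r2 at MAF ",
               signif(maf, 3), call. = FALSE)
      }
      hap_cols[[k]] <- as.integer(x)
      ids[j] <- sprintf("rs%06d", 100000L + k)
      poss[j] <- base_pos + (j - 1L) * 2500L
      al <- sample(bases, 2)
      refs[j] <- al[1]; alts[j] <- al[2]
    }
    vt[[b]] <- data.table(
      id = ids, chrom = as.character(chrom_i), pos = poss,
      ref = refs, alt = alts, block = sprintf("B%03d", b), maf = maf
    )
  }
  variants <- rbindlist(vt)
  hap <- do.call(cbind, hap_cols[seq_len(k)])
  # order variants by chromosome then position for the invariant
  o <- order(as.integer(variants$chrom), variants$pos)
  ld_panel(hap[, o, drop = FALSE], variants[o])
}

#' Write a panel as a phased VCF
#'
#' Haplotypes `2i-1` and `2i` become the phased genotype of sample `i`
#' (`GT` like `0|1`); requires an even haplotype count. Coordinates are
#' 1-based as in VCF.
#'
#' @param panel an `ld_panel`.
#' @param path output file (plain-text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  n_hap <- nrow(panel$hap)
  if (n_hap %% 2L != 0L) stop("write_panel_vcf: need an even number of haplotypes", call. = FALSE)
  n_ind <- n_hap %/% 2L
  v <- panel$variants
  gt_a <- panel$hap[seq(1L, n_hap, 2L), , drop = FALSE]
  gt_b <- panel$hap[seq(2L, n_hap, 2L), , drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=asmscan synthetic panel",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Phased genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            sprintf("SAMPLE%04d", seq_len(n_ind))), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(v)), function(j) {
    gts <- paste0(gt_a[, j], "|", gt_b[, j])
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j], ".", "PASS", ".", "GT", gts),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a phased VCF into an `ld_panel`
#'
#' Parsing is delegated to `VariantAnnotation::readVcf`; only the `GT`
#' field is used. Genotypes must be phased (`|` separator) and biallelic —
#' r^2 from haplotype frequencies is undefined without phase (use
#' [r2_unphased_em()] on dosages instead).
#'
#' @param path a plain-text VCF.
#' @return an [ld_panel()].
#' @export
read_panel_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_panel_vcf requires the VariantAnnotation package", call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT # variants x samples, e.g. "0|1"
  if (is.null(gt)) stop("read_panel_vcf: GT field required", call. = FALSE)
  if (any(grepl("/", gt, fixed = TRUE)))
    stop("read_panel_vcf: unphased genotypes found; phased GT (a|b) required", call. = FALSE)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt_list <- VariantAnnotation::alt(vcf)
  if (any(lengths(alt_list) != 1L))
    stop("read_panel_vcf: only biallelic records supported", call. = FALSE)
  M <- nrow(gt); n_ind <- ncol(gt)
  a <- substr(gt, 1L, 1L); b <- substr(gt, 3L, 3L)
  if (any(!(c(a, b) %in% c("0", "1"))))
    stop("read_panel_vcf: only 0/1 haploid alleles supported", call. = FALSE)
  hap <- matrix(0L, nrow = 2L * n_ind, ncol = M)
  hap[seq(1L, 2L * n_ind, 2L), ] <- t(matrix(as.integer(a), nrow = M))
  hap[seq(2L, 2L * n_ind, 2L), ] <- t(matrix(as.integer(b), nrow = M))
  ld_panel(hap, data.table(
    id = names(rr),
    chrom = norm_chrom(as.character(GenomicRanges::seqnames(rr))),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(unlist(alt_list))
  ))
}

#' Write / read a panel as a plain hap-matrix TSV
#'
#' Rows are variants (`id`, `chrom`, `pos`, `ref`, `alt`, optional `block`)
#' followed by one 0/1 column per haplotype (`h0001`, ...).
#'
#' @param panel an `ld_panel`.
#' @param path TSV file.
#' @return `path` (writer) or an [ld_panel()] (reader).
#' @export
write_panel_hap <- function(panel, path) {
  v <- copy(panel$variants)
  hm <- as.data.table(t(panel$hap))
  setnames(hm, sprintf("h%04d", seq_len(nrow(panel$hap))))
  fwrite(cbind(v, hm), path, sep = "\t")
  invisible(path)
}

#' @rdname write_panel_hap
#' @export
read_panel_hap <- function(path) {
  tab <- fread(path, sep = "\t")
  meta_cols <- intersect(c("id", "chrom", "pos", "ref", "alt", "block", "maf"), names(tab))
  hap_cols <- setdiff(names(tab), meta_cols)
  hap <- t(as.matrix(tab[, hap_cols, with = FALSE]))
  ld_panel(hap, tab[, meta_cols, with = FALSE])
}
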