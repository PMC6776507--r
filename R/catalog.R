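ASM_REQUIRED_COLS <- c("snp_id", "snp_chrom", "snp_pos", "cpg_id", "cpg_chrom",
                       "cpg_pos", "r2_meth", "tissue", "study")

#' Read one ASM SNP-CpG pair table
#'
#' Expects a headered TSV with at least the columns `snp_id`, `snp_chrom`,
#' `snp_pos`, `cpg_id`, `cpg_chrom`, `cpg_pos`, `r2_meth`, `tissue`,
#' `study`; `meth_effect_allele` and `meth_direction` (+1 hypermethylating
#' / -1 hypomethylating effect allele) are carried along when present.
#' Chromosome labels are accepted with or without a `chr` prefix and
#' normalized on read.
#'
#' @param path TSV file.
#' @return a `data.table`, schema-validated.
#' @export
read_asm_table <- function(path) {
  tab <- fread(path, sep = "\t")
  validate_asm_table(tab, label = path)
  tab[, snp_chrom := norm_chrom(snp_chrom)]
  tab[, cpg_chrom := norm_chrom(cpg_chrom)]
  tab[]
}

validate_asm_table <- function(tab, label = "asm table") {
  miss <- setdiff(ASM_REQUIRED_COLS, names(tab))
  if (length(miss))
    stop(label, ": missing column(s) ", paste(miss, collapse = ", "), call. = FALSE)
  bad_r2 <- tab[!is.na(r2_meth) & (r2_meth < 0 | r2_meth > 1)]
  if (nrow(bad_r2)) stop(label, ": r2_meth outside [0,1]", call. = FALSE)
  bad_chr <- setdiff(norm_chrom(c(tab$snp_chrom, tab$cpg_chrom)),
                     c(as.character(1:22), "X", "Y"))
  if (length(bad_chr))
    stop(label, ": unknown chromosome label(s) ", paste(bad_chr, collapse = ", "),
         call. = FALSE)
  invisible(tab)
}

#' Merge ASM catalogs from several studies and tissues
#'
#' Takes the union over distinct (SNP, CpG) pairs, preserving provenance as
#' a `;`-separated list of `study:tissue` entries per pair — tissues are
#' pooled before tagging, so duplicate pairs across sources collapse to one
#' catalog entry. For a pair reported by several sources, the coordinates,
#' methylation R^2 and direction of the source with the largest R^2 (the
#' strongest evidence) are retained. Already-merged catalogs can be passed
#' back in: merging is idempotent.
#'
#' @param tables a list of ASM pair `data.table`s (see [read_asm_table()]).
#' @return a list with `catalog` (one row per distinct pair, with
#'   `provenance` and `n_prov` columns) and `summary` (a `catalog_summary`:
#'   per-source pair counts, union count, distinct SNP and CpG counts).
#' @export
merge_sources <- function(tables) {
  if (inherits(tables, "data.frame")) tables <- list(tables)
  long <- rbindlist(lapply(seq_along(tables), function(i) {
    tab <- copy(as.data.table(tables[[i]]))
    tab[, snp_chrom := norm_chrom(snp_chrom)]
    tab[, cpg_chrom := norm_chrom(cpg_chrom)]
    if (!"meth_effect_allele" %in% names(tab)) tab[, meth_effect_allele := NA_character_]
    if (!"meth_direction" %in% names(tab)) tab[, meth_direction := NA_integer_]
    if ("provenance" %in% names(tab)) {
      # re-merge of an already-merged catalog: explode provenance
      tab <- tab[, {
        prov <- strsplit(provenance, ";", fixed = TRUE)[[1]]
        st <- strsplit(prov, ":", fixed = TRUE)
        c(.SD[rep(1L, length(prov)),
              !c("provenance", intersect("n_prov", names(tab))), with = FALSE],
          list(study = vapply(st, `[`, character(1), 1),
               tissue = vapply(st, `[`, character(1), 2)))
      }, by = .(snp_id, cpg_id)]
    }
    validate_asm_table(tab, label = paste0("table ", i))
    tab
  }), use.names = TRUE, fill = TRUE)

  # one snp_id must map to one coordinate across all sources
  coords <- unique(long[, .(snp_id, snp_chrom, snp_pos)])
  offenders <- coords[, .N, by = snp_id][N > 1L, snp_id]
  if (length(offenders))
    stop("merge_sources: conflicting coordinates for SNP(s): ",
         paste(offenders, collapse = ", "), call. = FALSE)

  long <- unique(long)  # (snp, cpg, tissue, study) unique after merge
  by_source <- long[, .N, by = .(study, tissue)]
  setorder(long, snp_id, cpg_id, -r2_meth, study, tissue)
  catalog <- long[, {
    prov <- sort(unique(paste0(study, ":", tissue)))
    c(.SD[1L, .(snp_chrom, snp_pos, cpg_chrom, cpg_pos, r2_meth,
                meth_effect_allele, meth_direction)],
      list(provenance = paste(prov, collapse = ";"), n_prov = length(prov)))
  }, by = .(snp_id, cpg_id)]

  summary <- structure(list(
    n_pairs_by_source = by_source,
    n_pairs_union = nrow(catalog),
    n_snps = length(unique(catalog$snp_id)),
    n_cpgs = length(unique(catalog$cpg_id))
  ), class = "catalog_summary")
  list(catalog = catalog[], summary = summary)
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat(sprintf("<catalog_summary> %d pairs (union), %d SNPs, %d CpG sites\n",
              x$n_pairs_union, x$n_snps, x$n_cpgs))
  print(x$n_pairs_by_source)
  invisible(x)
}

#' Filter the merged ASM catalog
#'
#' Applies, in order: the cis filter (SNP and CpG on the same chromosome
#' within `cis_window` bp), the methylation-correlation filter
#' (`r2_meth >= min_r2`, inclusive) and the autosome filter. Pairs with a
#' missing `r2_meth` are rejected with reason `missing_r2`, never silently
#' kept. Final membership does not depend on filter order; the audit counts
#' do.
#'
#' @param catalog merged catalog (from [merge_sources()]).
#' @param min_r2 inclusive methylation R^2 threshold; default 0.2.
#' @param autosomes_only drop non-autosomal SNPs; default `TRUE`.
#' @param require_cis enforce the cis filter; default `TRUE`.
#' @param cis_window cis distance cap in bp; default 1e6 (the +/-1 Mb
#'   convention used for TSS-centred eQTL windows).
#' @return list with `catalog` (surviving pairs), `audit` (counts removed
#'   per filter in application order) and `removed` (per-pair first failing
#'   reason).
#' @export
filter_catalog <- function(catalog, min_r2 = 0.2, autosomes_only = TRUE,
                           require_cis = TRUE, cis_window = 1e6) {
  cat_dt <- copy(as.data.table(catalog))
  reason <- rep(NA_character_, nrow(cat_dt))
  audit <- list()
  if (require_cis) {
    fail_cis <- !(cat_dt$snp_chrom == cat_dt$cpg_chrom &
                    abs(cat_dt$snp_pos - cat_dt$cpg_pos) <= cis_window)
    reason[is.na(reason) & fail_cis] <- "not_cis"
    audit$not_cis <- sum(reason == "not_cis", na.rm = TRUE)
  }
  fail_r2 <- is.na(cat_dt$r2_meth) | cat_dt$r2_meth < min_r2
  miss_r2 <- is.na(cat_dt$r2_meth)
  reason[is.na(reason) & miss_r2] <- "missing_r2"
  reason[is.na(reason) & fail_r2] <- "low_r2"
  audit$missing_r2 <- sum(reason == "missing_r2", na.rm = TRUE)
  audit$low_r2 <- sum(reason == "low_r2", na.rm = TRUE)
  if (autosomes_only) {
    fail_auto <- !is_autosome(cat_dt$snp_chrom)
    reason[is.na(reason) & fail_auto] <- "non_autosomal"
    audit$non_autosomal <- sum(reason == "non_autosomal", na.rm = TRUE)
  }
  keep <- is.na(reason)
  removed <- data.table(snp_id = cat_dt$snp_id[!keep], cpg_id = cat_dt$cpg_id[!keep],
                        reason = reason[!keep])
  audit <- c(list(n_input = nrow(cat_dt)), audit, list(n_kept = sum(keep)),
             list(params = list(min_r2 = min_r2, autosomes_only = autosomes_only,
                                require_cis = require_cis, cis_window = cis_window)))
  list(catalog = cat_dt[keep][], audit = audit, removed = removed[])
}

#' Check CpG probe footprints for underlying variants
#'
#' Array probes overlapping polymorphic positions can fake allele-specific
#' methylation; this reports, per CpG, any known variant inside a
#' fixed-width footprint centered on the CpG position.
#'
#' @param catalog ASM catalog with `cpg_id`, `cpg_chrom`, `cpg_pos`.
#' @param variant_positions `data.table` with `id`, `chrom`, `pos`.
#' @param footprint probe width in bp (window is `footprint/2` each side);
#'   default 50 (27k-array probe length).
#' @return `data.table` per CpG: `cpg_id`, `n_variants`, `variant_ids`
#'   (comma-separated), `pass` (no variant in footprint).
#' @export
probe_overlap_check <- function(catalog, variant_positions, footprint = 50) {
  cpgs <- unique(as.data.table(catalog)[, .(cpg_id, cpg_chrom, cpg_pos)])
  vp <- as.data.table(variant_positions)
  vp[, chrom := norm_chrom(chrom)]
  half <- footprint / 2
  res <- cpgs[, {
    hits <- vp[chrom == cpg_chrom & abs(pos - cpg_pos) <= half, id]
    list(n_variants = length(hits),
         variant_ids = paste(hits, collapse = ","),
         pass = length(hits) == 0L)
  }, by = .(cpg_id, cpg_chrom, cpg_pos)]
  res[]
}
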