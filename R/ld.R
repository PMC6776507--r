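#' Pairwise LD from phased haplotypes
#'
#' Computes r^2 and |D'| for two biallelic variants from exact haplotype
#' frequencies of a phased panel: with alt-allele frequencies `p_a`, `p_b`
#' and alt-alt haplotype frequency `p_ab`, `D = p_ab - p_a p_b`,
#' `r^2 = D^2 / (p_a (1-p_a) p_b (1-p_b))` and `D' = D / Dmax`.
#'
#' @param panel an [ld_panel()].
#' @param a,b variant ids present in the panel.
#' @return an `ld_result` list: `snp_a`, `snp_b`, `r2`, `d_prime`,
#'   `n_haplotypes`.
#' @export
#' @examples
#' p <- generate_panel(sim_config(n_blocks = 1, snps_per_block = 2, seed = 1))
#' r2_phased(p, p$variants$id[1], p$variants$id[2])
r2_phased <- function(panel, a, b) {
  x <- hap_col(panel, a)
  y <- hap_col(panel, b)
  pa <- mean(x); pb <- mean(y)
  if (pa %in% c(0, 1) || pb %in% c(0, 1))
    stop("r2_phased: monomorphic variant (", if (pa %in% c(0, 1)) a else b,
         "); r2 is undefined", call. = FALSE)
  pab <- mean(x == 1L & y == 1L)
  D <- pab - pa * pb
  r2 <- D^2 / (pa * (1 - pa) * pb * (1 - pb))
  dmax <- if (D >= 0) min(pa * (1 - pb), (1 - pa) * pb) else min(pa * pb, (1 - pa) * (1 - pb))
  dprime <- if (dmax == 0) 0 else abs(D) / dmax
  structure(list(snp_a = a, snp_b = b, r2 = r2, d_prime = min(dprime, 1),
                 n_haplotypes = length(x)),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf("<ld_result> %s ~ %s: r2 = %.4f, |D'| = %.4f (%d haplotypes)\n",
              x$snp_a, x$snp_b, x$r2, x$d_prime, x$n_haplotypes))
  invisible(x)
}

# pairwise r^2 matrix for a set of panel variants (squared Pearson
# correlation of alt-allele indicators; identical to the frequency formula)
r2_matrix <- function(panel, ids) {
  sub <- panel$hap[, match(ids, colnames(panel$hap)), drop = FALSE]
  mono <- which(apply(sub, 2, function(v) all(v == v[1])))
  if (length(mono))
    stop("monomorphic variant(s): ", paste(ids[mono], collapse = ", "), call. = FALSE)
  r <- cor(sub)
  r * r
}

#' Pairwise LD from unphased dosages (Hill EM)
#'
#' Maximum-likelihood haplotype frequencies for two loci from diploid
#' 0/1/2 dosages, resolving the double-heterozygote phase ambiguity by
#' expectation-maximization under Hardy-Weinberg (Hill's two-locus scheme).
#'
#' @param genotypes integer matrix, individuals x variants, entries 0/1/2,
#'   with column names.
#' @param a,b column names of the two variants.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter iteration cap; non-convergence raises a condition of
#'   class `asmscan_em_error` carrying the last estimate.
#' @return an `ld_result` as in [r2_phased()], with attribute `ambiguous`
#'   set when the likelihood cannot distinguish coupling from repulsion
#'   (e.g. every individual a double heterozygote).
#' @export
r2_unphased_em <- function(genotypes, a, b, tol = 1e-10, max_iter = 1000L) {
  x <- genotypes[, a]; y <- genotypes[, b]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (!all(x %in% 0:2) || !all(y %in% 0:2))
    stop("r2_unphased_em: dosages must be 0/1/2", call. = FALSE)
  n <- length(x)
  cnt <- table(factor(x, 0:2), factor(y, 0:2))
  nm <- function(i, j) cnt[i + 1L, j + 1L]
  ndh <- nm(1, 1)
  pa <- mean(x) / 2; pb <- mean(y) / 2
  if (pa %in% c(0, 1) || pb %in% c(0, 1))
    stop("r2_unphased_em: monomorphic variant; r2 is undefined", call. = FALSE)
  # haplotype classes: 11 (alt/alt), 10, 01, 00
  p11 <- pa * pb; p10 <- pa * (1 - pb); p01 <- (1 - pa) * pb; p00 <- (1 - pa) * (1 - pb)
  loglik <- function(p11, p10, p01, p00) {
    P <- matrix(0, 3, 3)
    P[3, 3] <- p11^2;           P[3, 2] <- 2 * p11 * p10;  P[3, 1] <- p10^2
    P[1, 3] <- p01^2;           P[1, 2] <- 2 * p01 * p00;  P[1, 1] <- p00^2
    P[2, 3] <- 2 * p11 * p01;   P[2, 1] <- 2 * p10 * p00
    P[2, 2] <- 2 * p11 * p00 + 2 * p10 * p01
    sum(ifelse(cnt > 0, cnt * log(pmax(P, 1e-300)), 0))
  }
  ll_old <- loglik(p11, p10, p01, p00)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    denom <- p11 * p00 + p10 * p01
    w <- if (denom == 0) 0.5 else (p11 * p00) / denom
    c11 <- 2 * nm(2, 2) + nm(2, 1) + nm(1, 2) + ndh * w
    c00 <- 2 * nm(0, 0) + nm(0, 1) + nm(1, 0) + ndh * w
    c10 <- 2 * nm(2, 0) + nm(2, 1) + nm(1, 0) + ndh * (1 - w)
    c01 <- 2 * nm(0, 2) + nm(1, 2) + nm(0, 1) + ndh * (1 - w)
    tot <- c11 + c00 + c10 + c01
    p11 <- c11 / tot; p00 <- c00 / tot; p10 <- c10 / tot; p01 <- c01 / tot
    ll <- loglik(p11, p10, p01, p00)
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  D <- p11 - pa * pb
  r2 <- D^2 / (pa * (1 - pa) * pb * (1 - pb))
  dmax <- if (D >= 0) min(pa * (1 - pb), (1 - pa) * pb) else min(pa * pb, (1 - pa) * (1 - pb))
  res <- structure(list(snp_a = a, snp_b = b, r2 = r2,
                        d_prime = if (dmax == 0) 0 else min(abs(D) / dmax, 1),
                        n_haplotypes = 2L * n),
                   class = "ld_result")
  attr(res, "ambiguous") <- (ndh == n)
  attr(res, "iterations") <- it
  if (!converged)
    stop(errorCondition(
      sprintf("r2_unphased_em: no convergence after %d iterations", max_iter),
      class = "asmscan_em_error", estimate = res))
  res
}

#' Greedy per-CpG tagSNP selection
#'
#' For each CpG, repeatedly picks the candidate SNP that covers the most
#' still-untagged candidates at `r^2 >= r2_min` (a SNP always covers
#' itself), until all candidates are covered — the pairwise greedy set
#' cover used by Haploview-style taggers. Coverage ties are broken by
#' smaller GWAS p-value (when `pvals` is given), then by leftmost position,
#' so output is deterministic.
#'
#' @param candidates `data.table`/data.frame with columns `cpg_id`,
#'   `snp_id`: the catalog SNPs correlated with each CpG.
#' @param panel an [ld_panel()].
#' @param r2_min tag threshold (inclusive); default 0.85.
#' @param pvals optional named numeric vector of GWAS p-values used for
#'   tie-breaking.
#' @return `data.table` with one row per (CpG, candidate): `cpg_id`,
#'   `tag_snp`, `snp_id`, `r2_to_tag`. Candidates absent from the panel are
#'   dropped with a warning and listed in the `excluded` attribute.
#' @export
select_tags <- function(candidates, panel, r2_min = 0.85, pvals = NULL) {
  cand <- unique(as.data.table(candidates)[, .(cpg_id, snp_id)])
  absent <- setdiff(cand$snp_id, colnames(panel$hap))
  if (length(absent)) {
    warning("select_tags: ", length(absent), " candidate(s) absent from panel, excluded")
    cand <- cand[!snp_id %in% absent]
  }
  pos_of <- setNames(panel$variants$pos, panel$variants$id)
  out <- vector("list", length(unique(cand$cpg_id)))
  i <- 0L
  for (cg in unique(cand$cpg_id)) {
    ids <- cand[cpg_id == cg, snp_id]
    r2m <- r2_matrix(panel, ids)
    uncovered <- rep(TRUE, length(ids))
    rows <- list()
    while (any(uncovered)) {
      # coverage counted among uncovered candidates only
      cover <- colSums(r2m[uncovered, , drop = FALSE] >= r2_min)
      cover[!uncovered] <- -1L
      best <- which(cover == max(cover))
      if (length(best) > 1L && !is.null(pvals)) {
        pv <- pvals[ids[best]]
        pv[is.na(pv)] <- Inf
        best <- best[pv == min(pv)]
      }
      if (length(best) > 1L) best <- best[which.min(pos_of[ids[best]])]
      tagged <- which(uncovered & r2m[best, ] >= r2_min)
      rows[[length(rows) + 1L]] <- data.table(
        cpg_id = cg, tag_snp = ids[best], snp_id = ids[tagged],
        r2_to_tag = r2m[best, tagged])
      uncovered[tagged] <- FALSE
    }
    i <- i + 1L
    out[[i]] <- rbindlist(rows)
  }
  res <- rbindlist(out)
  attr(res, "excluded") <- absent
  res[]
}

#' Expand significant tags to high-LD same-CpG catalog partners
#'
#' For each tag, returns every catalog SNP with `r^2 >= r2_min` to it in
#' the panel that (when `same_cpg`) correlates with at least one of the
#' same CpG sites. Tags are always members of their own expansion.
#'
#' @param tags character vector of significant tagSNP ids.
#' @param catalog filtered ASM catalog (columns `snp_id`, `cpg_id`).
#' @param panel an [ld_panel()].
#' @param r2_min LD threshold (inclusive); default 0.85.
#' @param same_cpg require a shared CpG between partner and tag.
#' @return `data.table` with columns `tag_snp`, `snp_id`, `r2`; distinct
#'   `snp_id` count is the expanded set size.
#' @export
ld_expand <- function(tags, catalog, panel, r2_min = 0.85, same_cpg = TRUE) {
  cat_dt <- unique(as.data.table(catalog)[, .(snp_id, cpg_id)])
  cpgs_of <- split(cat_dt$cpg_id, cat_dt$snp_id)
  in_panel <- intersect(unique(cat_dt$snp_id), colnames(panel$hap))
  out <- vector("list", length(tags))
  for (i in seq_along(tags)) {
    t <- tags[i]
    partners <- setdiff(in_panel, t)
    if (length(partners)) {
      ht <- hap_col(panel, t)
      sub <- panel$hap[, match(partners, colnames(panel$hap)), drop = FALSE]
      r2v <- as.vector(cor(ht, sub))^2
      keep <- !is.na(r2v) & r2v >= r2_min
      if (same_cpg && any(keep)) {
        tag_cpgs <- cpgs_of[[t]] %||% character()
        share <- vapply(partners, function(s) length(intersect(cpgs_of[[s]], tag_cpgs)) > 0,
                        logical(1))
        keep <- keep & share
      }
      partners <- partners[keep]; r2v <- r2v[keep]
    } else r2v <- numeric()
    out[[i]] <- data.table(tag_snp = t,
                           snp_id = c(t, partners),
                           r2 = c(1, r2v))
  }
  rbindlist(out)[]
}

#' Assign variants to LD blocks
#'
#' Blocks are the connected components of the graph whose edges join
#' same-chromosome variant pairs with `r^2 >= r2_min`. Labels (`B01`, ...)
#' are ordered by the leftmost (chromosome, position) of each component,
#' so output is deterministic.
#'
#' @param variants character vector of variant ids present in the panel.
#' @param panel an [ld_panel()].
#' @param r2_min edge threshold (inclusive); default 0.85.
#' @return `data.table` with columns `snp_id`, `block_id`.
#' @export
assign_blocks <- function(variants, panel, r2_min = 0.85) {
  variants <- unique(variants)
  vi <- panel$variants[match(variants, id)]
  if (anyNA(vi$id)) stop("assign_blocks: variant(s) absent from panel", call. = FALSE)
  r2m <- r2_matrix(panel, variants)
  same_chr <- outer(vi$chrom, vi$chrom, "==")
  adj <- (r2m >= r2_min) & same_chr
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership
  # order components by leftmost (chrom, pos)
  key <- data.table(comp = comp, chrom = suppressWarnings(as.integer(vi$chrom)),
                    pos = vi$pos)
  key[is.na(chrom), chrom := 98L]
  lead <- key[, .(chrom = min(chrom), pos = min(pos[chrom == min(chrom)])), by = comp]
  setorder(lead, chrom, pos)
  relabel <- setNames(seq_len(nrow(lead)), lead$comp)
  data.table(snp_id = variants,
             block_id = sprintf("B%02d", relabel[as.character(comp)]))[]
}

#' Effective number of independent tests (Li-Ji eigenvalue estimator)
#'
#' Estimates the number of effectively independent tests among correlated
#' variants from the eigenvalues of their allelic correlation matrix:
#' `Meff = sum_i [ I(lambda_i >= 1) + (lambda_i - floor(lambda_i)) ]`.
#' This is the standard stand-in for tools (such as GEC) that relax the
#' Bonferroni denominator for LD-dependent SNP sets.
#'
#' @param panel an [ld_panel()].
#' @param variants character vector of variant ids.
#' @return `Meff`, a scalar in `[1, M]`.
#' @export
effective_tests <- function(panel, variants) {
  variants <- unique(variants)
  M <- length(variants)
  if (M < 1L) stop("effective_tests: need at least one variant", call. = FALSE)
  if (M == 1L) return(1)
  sub <- panel$hap[, match(variants, colnames(panel$hap)), drop = FALSE]
  if (anyNA(sub)) stop("effective_tests: variant(s) absent from panel", call. = FALSE)
  r <- cor(sub)
  if (anyNA(r)) stop("effective_tests: monomorphic variant in set", call. = FALSE)
  lam <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (any(lam < -1e-6))
    stop("effective_tests: correlation matrix not positive semi-definite", call. = FALSE)
  lam <- pmax(lam, 0)
  # snap near-integer eigenvalues before flooring (e.g. a block of perfect
  # duplicates yields lambda = M only up to rounding error)
  near <- abs(lam - round(lam)) < 1e-9
  lam[near] <- round(lam[near])
  meff <- sum((lam >= 1) + (lam - floor(lam)))
  min(max(meff, 1), M)
}
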