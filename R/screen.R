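#' Read daner-style GWAS summary statistics
#'
#' The daner layout is a headered TSV with columns `CHR`, `SNP`, `BP`,
#' `A1`, `A2`, `OR`, `SE`, `P` (`A1` is the effect allele of `OR`); extra
#' columns are preserved. Basic sanity constraints are enforced: `P` in
#' (0, 1], `OR > 0`, alleles in A/C/G/T.
#'
#' @param path TSV file.
#' @return a `data.table` keyed by `SNP`.
#' @export
read_daner <- function(path) {
  tab <- fread(path, sep = "\t")
  need <- c("CHR", "SNP", "BP", "A1", "A2", "OR", "SE", "P")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("read_daner: missing column(s) ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(tab$P <= 0 | tab$P > 1, na.rm = TRUE))
    stop("read_daner: P must lie in (0, 1]", call. = FALSE)
  if (any(tab$OR <= 0, na.rm = TRUE)) stop("read_daner: OR must be positive", call. = FALSE)
  if (!all(c(tab$A1, tab$A2) %in% c("A", "C", "G", "T")))
    stop("read_daner: alleles must be A/C/G/T", call. = FALSE)
  tab[, CHR := norm_chrom(CHR)]
  tab[]
}

#' Join tagSNPs to summary statistics with allele harmonization
#'
#' Matches tags to summary statistics by SNP id and reconciles alleles by
#' (in order) identity, effect-allele swap (OR inverted), strand flip, and
#' strand flip + swap. Strand-ambiguous pairs (A/T, C/G) that do not match
#' by identity or swap are dropped — without allele frequencies a strand
#' flip cannot be distinguished from a swap. Association p-values are never
#' modified, only allele orientation and OR.
#'
#' @param tags `data.table` with columns `snp_id`, `a1` (effect allele),
#'   `a2`; typically the panel alleles of the selected tagSNPs.
#' @param sumstats a daner table from [read_daner()] (duplicate `SNP` ids
#'   are an error).
#' @return list with `joined` (one row per retrieved tag: `snp_id`,
#'   `chrom`, `pos`, `a1`, `a2`, `or_` oriented to the tag's `a1`, `se`,
#'   `p`, plus a `flip` code) and `report` (counts per outcome:
#'   `retrieved`, `absent`, `ambiguous_dropped`, `mismatch_dropped`, and
#'   `retrieved_frac`).
#' @export
harmonize_and_join <- function(tags, sumstats) {
  tags <- as.data.table(tags)
  ss <- as.data.table(sumstats)
  if (anyDuplicated(ss$SNP))
    stop("harmonize_and_join: duplicate SNP id(s) in summary statistics", call. = FALSE)
  idx <- match(tags$snp_id, ss$SNP)
  n <- nrow(tags)
  status <- rep("retrieved", n)
  status[is.na(idx)] <- "absent"
  out <- vector("list", n)
  for (i in seq_len(n)) {
    if (is.na(idx[i])) next
    row <- ss[idx[i]]
    ta1 <- tags$a1[i]; ta2 <- tags$a2[i]
    sa1 <- row$A1; sa2 <- row$A2
    orx <- row$OR
    code <- NA_character_
    if (sa1 == ta1 && sa2 == ta2) {
      code <- "identity"
    } else if (sa1 == ta2 && sa2 == ta1) {
      code <- "swap"; orx <- 1 / orx
    } else if (is_strand_ambiguous(ta1, ta2) || is_strand_ambiguous(sa1, sa2)) {
      status[i] <- "ambiguous_dropped"; next
    } else {
      fa1 <- flip_strand(sa1); fa2 <- flip_strand(sa2)
      if (fa1 == ta1 && fa2 == ta2) {
        code <- "strand_flip"
      } else if (fa1 == ta2 && fa2 == ta1) {
        code <- "strand_flip_swap"; orx <- 1 / orx
      } else {
        status[i] <- "mismatch_dropped"; next
      }
    }
    out[[i]] <- data.table(snp_id = tags$snp_id[i], chrom = norm_chrom(row$CHR),
                           pos = row$BP, a1 = ta1, a2 = ta2, or_ = orx,
                           se = row$SE, p = row$P, flip = code)
  }
  joined <- rbindlist(out[!vapply(out, is.null, logical(1))])
  report <- list(
    n_tags = n,
    retrieved = sum(status == "retrieved"),
    absent = sum(status == "absent"),
    ambiguous_dropped = sum(status == "ambiguous_dropped"),
    mismatch_dropped = sum(status == "mismatch_dropped"),
    retrieved_frac = sum(status == "retrieved") / n,
    status = data.table(snp_id = tags$snp_id, status = status)
  )
  list(joined = joined[], report = report)
}

#' Fisher enrichment of ASM SNPs among sub-threshold GWAS hits
#'
#' For each p-value cutoff in `thresholds`, builds the 2x2 table of
#' (ASM vs non-ASM) x (p below cutoff vs not) over all tested SNPs and
#' computes a Fisher exact test (one-sided "greater" by default — the
#' hypothesis is that risk variants are enriched in ASM SNPs) plus the
#' sample odds ratio `ad/bc` (NA when a margin is empty; the exact p-value
#' is still returned).
#'
#' @param sumstats table with columns `p` (or daner `P`) and logical
#'   `is_asm`.
#' @param thresholds p-value cutoffs; default the ladder 5e-2 ... 5e-8.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return `data.table` with one row per threshold: counts `a` (ASM &
#'   significant), `b`, `c`, `d`, `odds_ratio`, `p_value`.
#' @export
enrichment_scan <- function(sumstats,
                            thresholds = 5 * 10^-(2:8),
                            alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  ss <- as.data.table(sumstats)
  pcol <- if ("p" %in% names(ss)) ss$p else ss$P
  if (is.null(pcol) || !("is_asm" %in% names(ss)))
    stop("enrichment_scan: need columns p (or P) and is_asm", call. = FALSE)
  asm <- as.logical(ss$is_asm)
  rbindlist(lapply(thresholds, function(tau) {
    sig <- pcol < tau
    a <- sum(asm & sig); b <- sum(asm & !sig)
    c_ <- sum(!asm & sig); d <- sum(!asm & !sig)
    orx <- if (a + b == 0 || c_ + d == 0 || a + c_ == 0 || b + d == 0) NA_real_
           else (a * d) / (b * c_)
    pv <- fisher.test(matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE),
                      alternative = alternative)$p.value
    data.table(threshold = tau, a = a, b = b, c = c_, d = d,
               odds_ratio = orx, p_value = pv)
  }))[]
}

#' Storey q-values with smoother pi0 estimate
#'
#' Computes q-values `q_i = min_{j >= i} pi0 * m * p_(j) / j` with the
#' proportion of true nulls `pi0` estimated by Storey's smoother over the
#' lambda grid 0.05, 0.10, ..., 0.95 (a cubic smoothing spline through
#' `pi0(lambda) = mean(p > lambda) / (1 - lambda)` evaluated at the largest
#' lambda). For fewer than 100 tests, or when smoothing fails, `pi0` falls
#' back to 1, which reduces q-values to Benjamini-Hochberg adjusted
#' p-values. Also reports `fdr_p_star`, the largest observed p with
#' `q <= alpha` (0 when none) — the "p-value threshold corresponding to an
#' alpha-level FDR".
#'
#' @param pvals p-values in (0, 1].
#' @param alpha FDR level for `fdr_p_star`; default 0.05.
#' @param lambda grid for the pi0 smoother.
#' @param pi0 optionally force pi0 (e.g. 1 for plain BH).
#' @return list with `qvalues` (same order as input), `pi0`, `fdr_p_star`.
#' @export
storey_qvalues <- function(pvals, alpha = 0.05, lambda = seq(0.05, 0.95, by = 0.05),
                           pi0 = NULL) {
  m <- length(pvals)
  if (m < 1L) stop("storey_qvalues: need at least one p-value", call. = FALSE)
  if (any(is.na(pvals)) || any(pvals <= 0 | pvals > 1))
    stop("storey_qvalues: p-values must lie in (0, 1]", call. = FALSE)
  if (is.null(pi0)) {
    pi0 <- if (m < 100L) 1 else tryCatch({
      pi0_l <- vapply(lambda, function(l) mean(pvals > l) / (1 - l), numeric(1))
      fit <- smooth.spline(lambda, pi0_l, df = 3)
      est <- predict(fit, x = max(lambda))$y
      if (!is.finite(est) || est <= 0) 1 else min(est, 1)
    }, error = function(e) 1)
  }
  o <- order(pvals)
  ro <- order(o)
  ps <- pvals[o]
  q <- pi0 * m * ps / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  qvalues <- q[ro]
  passing <- pvals[qvalues <= alpha]
  fdr_p_star <- if (length(passing)) max(passing) else 0
  list(qvalues = qvalues, pi0 = pi0, fdr_p_star = fdr_p_star)
}

#' Bonferroni-corrected p-value threshold
#'
#' @param alpha family-wise error level.
#' @param m number of tests (>= 1).
#' @return `alpha / m` exactly; the rendering to 3 significant figures is
#'   attached as attribute `printed`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 3771)
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (length(m) != 1L || is.na(m) || m < 1) stop("bonferroni_threshold: m must be >= 1", call. = FALSE)
  thr <- alpha / m
  attr(thr, "printed") <- formatC(thr, format = "e", digits = 2)
  thr
}

#' Screen tagSNPs under FDR, Bonferroni and effective-tests thresholds
#'
#' Flags each joined tagSNP under the three multiple-testing regimes:
#' Storey 5% FDR (`q <= alpha`), Bonferroni (`p <= alpha/m`, inclusive)
#' and the effective-number-of-tests relaxation (`p <= alpha/Meff`). When
#' the thresholds are ordered `alpha/m <= alpha/Meff <= fdr_p_star`, the
#' pass sets nest: Bonferroni implies Meff implies FDR.
#'
#' @param joined output of [harmonize_and_join()]`$joined` (needs `snp_id`,
#'   `p`).
#' @param alpha significance level; default 0.05.
#' @param meff effective number of tests (e.g. [effective_tests()]);
#'   default `m` (plain Bonferroni).
#' @param m number of tests in the family; defaults to `nrow(joined)`.
#'   Override when the rows are a subset of a larger screen (e.g. applying
#'   a 0.05/3771 threshold to a handful of reported p-values).
#' @param pi0 optionally force pi0 of the q-value step.
#' @return a `screen_result`: `data.table` with `snp_id`, `p`, `q`,
#'   `pass_fdr`, `pass_bonferroni`, `pass_meff`, and attributes
#'   `thresholds` (`fdr_p_star`, `alpha_over_m`, `alpha_over_meff`),
#'   `pi0`, `meff`.
#' @export
screen_tags <- function(joined, alpha = 0.05, meff = NULL, m = NULL, pi0 = NULL) {
  jd <- as.data.table(joined)
  if (!all(c("snp_id", "p") %in% names(jd)))
    stop("screen_tags: need columns snp_id and p", call. = FALSE)
  m <- m %||% nrow(jd)
  meff <- meff %||% m
  st <- storey_qvalues(jd$p, alpha = alpha, pi0 = pi0)
  alpha_over_m <- alpha / m
  alpha_over_meff <- alpha / meff
  res <- copy(jd)
  res[, q := st$qvalues]
  res[, pass_fdr := q <= alpha]
  res[, pass_bonferroni := p <= alpha_over_m]
  res[, pass_meff := p <= alpha_over_meff]
  setattr(res, "thresholds",
          list(fdr_p_star = st$fdr_p_star, alpha_over_m = alpha_over_m,
               alpha_over_meff = alpha_over_meff, alpha = alpha))
  setattr(res, "pi0", st$pi0)
  setattr(res, "meff", meff)
  setattr(res, "class", c("screen_result", class(res)))
  res[]
}

#' @export
print.screen_result <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf(
    "<screen_result> %d tagSNPs | FDR p* = %.3g, alpha/m = %.3g, alpha/Meff = %.3g\n",
    nrow(x), th$fdr_p_star, th$alpha_over_m, th$alpha_over_meff))
  cat(sprintf("  pass: FDR %d, Meff %d, Bonferroni %d\n",
              sum(x$pass_fdr), sum(x$pass_meff), sum(x$pass_bonferroni)))
  NextMethod()
}
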