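library(data.table)

# build an ld_panel directly from a 0/1 matrix (columns = variants)
make_panel <- function(mat, chrom = NULL, pos = NULL, ref = NULL, alt = NULL) {
  M <- ncol(mat)
  ld_panel(mat, data.table::data.table(
    id = sprintf("v%03d", seq_len(M)),
    chrom = chrom %||% rep("1", M),
    pos = pos %||% seq_len(M) * 1000L,
    ref = ref %||% rep("A", M),
    alt = alt %||% rep("G", M)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random polymorphic panel, independent columns
random_panel <- function(n_hap = 200L, M = 10L, seed = 1L, maf = NULL) {
  set.seed(seed)
  cols <- lapply(seq_len(M), function(j) {
    p <- if (is.null(maf)) runif(1, 0.1, 0.5) else maf
    repeat {
      x <- rbinom(n_hap, 1L, p)
      if (sum(x) > 0 && sum(x) < n_hap) return(x)
    }
  })
  make_panel(do.call(cbind, cols))
}

# ---- independent oracles -------------------------------------------------

# r^2 and |D'| by brute-force 2x2 haplotype counting
r2_count_oracle <- function(x, y) {
  n <- length(x)
  n_ab <- sum(x == 1 & y == 1); n_aB <- sum(x == 1 & y == 0)
  n_Ab <- sum(x == 0 & y == 1); n_AB <- sum(x == 0 & y == 0)
  pa <- (n_ab + n_aB) / n; pb <- (n_ab + n_Ab) / n
  D <- n_ab / n - pa * pb
  D^2 / (pa * (1 - pa) * pb * (1 - pb))
}

# one-sided (greater) Fisher p by direct hypergeometric tail summation
hyper_tail_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  lo <- max(0, k - m2); hi <- min(k, m1)
  terms <- vapply(a:hi, function(x) {
    exp(lchoose(m1, x) + lchoose(m2, k - x) - lchoose(m1 + m2, k))
  }, numeric(1))
  sum(terms)
}

# union-find connected components over an adjacency matrix
union_find_oracle <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && adj[i, j]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# canonical form of a partition (relabelled by first appearance)
canon_partition <- function(labels) {
  match(labels, unique(labels))
}

# exhaustive minimum set cover size for tag selection (small candidate sets)
min_cover_oracle <- function(r2m, r2_min) {
  n <- nrow(r2m)
  for (k in 1:n) {
    combos <- utils::combn(n, k, simplify = FALSE)
    for (cmb in combos) {
      covered <- rep(FALSE, n)
      for (j in cmb) covered <- covered | (r2m[j, ] >= r2_min)
      if (all(covered)) return(k)
    }
  }
  n
}

# Li-Ji Meff via an independent eigenvalue route (SVD of the standardized
# haplotype matrix)
meff_svd_oracle <- function(hap) {
  z <- scale(hap)
  lam <- svd(z)$d^2 / (nrow(hap) - 1)
  lam <- c(lam, rep(0, ncol(hap) - length(lam)))
  sum((lam >= 1) + (lam - floor(lam)))
}

# small, fast sim config for pipeline-level tests
small_sim <- function(seed = 7L, ...) {
  sim_config(n_haplotypes = 60L, n_blocks = 8L, snps_per_block = 3L,
             n_asm_pairs = 40L, n_signal = 2L, seed = seed, ...)
}

# fixture for LD expansion bookkeeping: perfect-LD blocks with planted
# partner counts (thin wrapper over the packaged generator)
make_expansion_fixture <- function(partner_counts, seed = 1L, n_hap = 100L) {
  simulate_tagged_blocks(partner_counts, n_haplotypes = n_hap, seed = seed)
}
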