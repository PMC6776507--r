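#' Write every synthetic input (plus ground-truth manifests) to a directory
#'
#' Runs all four generators under one [sim_config()] and writes: the panel
#' as phased VCF and hap-matrix TSV, one ASM table per pseudo-study, the
#' daner summary statistics, the TSS/histone/eQTL/volume annotation
#' tables, and the ground-truth manifests (all headered TSV, coordinates
#' 1-based). The same seed and config always produce byte-identical files.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return named list of file paths, invisibly; the generated objects are
#'   attached as attribute `objects`.
#' @export
write_sim_inputs <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  panel <- generate_panel(config)
  asm <- generate_asm_catalog(panel, config)
  ss <- generate_sumstats(panel, asm, config)
  bundle <- generate_annotation_tables(asm, config, sumstats = ss)

  fp <- function(name) file.path(dir, name)
  paths <- list(panel_vcf = fp("panel.vcf"), panel_hap = fp("panel_hap.tsv"),
                sumstats = fp("sumstats.tsv"),
                tss = fp("tss.tsv"), histone = fp("histone.tsv"),
                eqtl = fp("eqtl.tsv"), volume = fp("volume.tsv"),
                manifest_catalog = fp("manifest_catalog.tsv"),
                manifest_sumstats = fp("manifest_sumstats.tsv"),
                manifest_promoter = fp("manifest_promoter.tsv"),
                manifest_consistency = fp("manifest_consistency.tsv"))
  write_panel_vcf(panel, paths$panel_vcf)
  write_panel_hap(panel, paths$panel_hap)
  for (st in names(asm)) {
    paths[[paste0("asm_", st)]] <- fp(paste0("asm_", st, ".tsv"))
    fwrite(asm[[st]], paths[[paste0("asm_", st)]], sep = "\t")
  }
  fwrite(ss, paths$sumstats, sep = "\t")
  fwrite(bundle$tss, paths$tss, sep = "\t")
  fwrite(bundle$histone, paths$histone, sep = "\t")
  fwrite(bundle$eqtl, paths$eqtl, sep = "\t")
  fwrite(bundle$volume, paths$volume, sep = "\t")
  fwrite(attr(asm, "manifest"), paths$manifest_catalog, sep = "\t")
  fwrite(attr(ss, "manifest"), paths$manifest_sumstats, sep = "\t")
  man_b <- attr(bundle, "manifest")
  fwrite(man_b$promoter, paths$manifest_promoter, sep = "\t")
  fwrite(man_b$consistency, paths$manifest_consistency, sep = "\t")
  attr(paths, "objects") <- list(panel = panel, asm = asm, sumstats = ss,
                                 bundle = bundle)
  invisible(paths)
}

RUN_CONFIG_DEFAULTS <- list(
  panel = NA_character_, asm_tables = NA_character_, sumstats = NA_character_,
  tss = NA_character_, histone = NA_character_, eqtl = NA_character_,
  volume = NA_character_,
  min_r2_meth = 0.2, tag_r2 = 0.85, expand_r2 = 0.85, block_r2 = 0.85,
  alpha = 0.05, promoter_window = 5000, cis_window = 1e6,
  enrichment_thresholds = "5e-2,5e-3,5e-4,5e-5,5e-6,5e-7,5e-8",
  autosomes_only = TRUE, same_cpg = TRUE, one_sided = TRUE,
  probe_footprint = 50,
  seed = 1L, out_dir = NA_character_
)

#' Validate a flat key-value run configuration
#'
#' The config file holds one `key = value` pair per line (`#` comments
#' allowed). Unknown keys are hard errors — no silent typo tolerance.
#' Defaults equal the standard analysis thresholds: methylation R^2 0.2,
#' tag/expansion/block LD r^2 0.85, alpha 0.05, promoter window 5000 bp,
#' cis window 1 Mb. File-path values must exist at validation time.
#'
#' @param path config file, or a named list of overrides (for programmatic
#'   use).
#' @return a validated `run_config` list with defaults applied.
#' @export
validate_config <- function(path) {
  if (is.character(path)) {
    if (!file.exists(path)) stop("validate_config: no such file: ", path, call. = FALSE)
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", lines))
    bad <- lines[vapply(kv, length, integer(1)) != 3L]
    if (length(bad)) stop("validate_config: unparseable line(s): ",
                          paste(bad, collapse = " | "), call. = FALSE)
    overrides <- setNames(lapply(kv, function(m) trimws(m[3])),
                          vapply(kv, `[`, character(1), 2))
  } else overrides <- as.list(path)
  unknown <- setdiff(names(overrides), names(RUN_CONFIG_DEFAULTS))
  if (length(unknown))
    stop("validate_config: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- modifyList(RUN_CONFIG_DEFAULTS, overrides)
  num_keys <- c("min_r2_meth", "tag_r2", "expand_r2", "block_r2", "alpha",
                "promoter_window", "cis_window", "probe_footprint")
  for (k in num_keys) cfg[[k]] <- as.numeric(cfg[[k]])
  cfg$seed <- as.integer(cfg$seed)
  for (k in c("autosomes_only", "same_cpg", "one_sided"))
    cfg[[k]] <- as.logical(toupper(as.character(cfg[[k]])))
  for (k in c("min_r2_meth", "tag_r2", "expand_r2", "block_r2", "alpha")) {
    if (is.na(cfg[[k]]) || cfg[[k]] < 0 || cfg[[k]] > 1)
      stop("validate_config: ", k, " must lie in [0,1]", call. = FALSE)
  }
  cfg$enrichment_thresholds <-
    as.numeric(strsplit(as.character(cfg$enrichment_thresholds), ",")[[1]])
  if (any(is.na(cfg$enrichment_thresholds)))
    stop("validate_config: bad enrichment_thresholds", call. = FALSE)
  for (k in c("panel", "asm_tables", "sumstats")) {
    if (is.na(cfg[[k]]))
      stop("validate_config: required field missing: ", k, call. = FALSE)
  }
  cfg$asm_tables <- strsplit(cfg$asm_tables, ",")[[1]]
  for (k in c("panel", "sumstats", "tss", "histone", "eqtl", "volume")) {
    if (!is.na(cfg[[k]]) && !file.exists(cfg[[k]]))
      stop("validate_config: file for '", k, "' does not exist: ", cfg[[k]],
           call. = FALSE)
  }
  for (f in cfg$asm_tables) if (!file.exists(f))
    stop("validate_config: asm table does not exist: ", f, call. = FALSE)
  structure(cfg, class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full ASM-GWAS integration pipeline
#'
#' Executes, in order: catalog merge and filtering; panel loading; per-CpG
#' tagSNP selection; allele-harmonized join to the summary statistics;
#' Fisher enrichment scan over the threshold ladder; the three-regime
#' significance screen (Storey FDR, Bonferroni, Li-Ji effective tests);
#' LD expansion of the FDR-significant tags; LD-block assignment; and
#' (when annotation tables are configured) functional annotation with
#' per-block causal-SNP prioritization. Every stage writes its TSV output
#' plus a sidecar of the parameters used; a machine-readable flow-count
#' summary (pairs, SNPs, tags, retrieved, significant, expanded, blocks)
#' and a run log complete the output directory. Any stage failure aborts
#' with the stage name; earlier outputs are preserved.
#'
#' @param config a `run_config` from [validate_config()] (or a path to a
#'   config file).
#' @param out_dir output directory; overrides the config's `out_dir`.
#' @return an `asmscan_run` list with all stage objects, the flow summary
#'   and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir) || is.na(out_dir)) stop("run_pipeline: out_dir required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(name) file.path(out_dir, name)
  log_lines <- c(sprintf("asmscan %s | %s", as.character(utils::packageVersion("asmscan")),
                         format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 sprintf("R %s; data.table %s", getRversion(),
                         as.character(utils::packageVersion("data.table"))))
  logp <- function(fmt, ...) log_lines <<- c(log_lines, sprintf(fmt, ...))

  merged <- stage("merge_catalog", {
    tabs <- lapply(config$asm_tables, read_asm_table)
    merge_sources(tabs)
  })
  logp("merge: %d pairs, %d SNPs, %d CpGs", merged$summary$n_pairs_union,
       merged$summary$n_snps, merged$summary$n_cpgs)

  filt <- stage("filter_catalog",
    filter_catalog(merged$catalog, min_r2 = config$min_r2_meth,
                   autosomes_only = config$autosomes_only,
                   require_cis = TRUE, cis_window = config$cis_window))
  fwrite(filt$catalog, fp("filtered_catalog.tsv"), sep = "\t")
  jsonlite::write_json(filt$audit, fp("filter_audit.json"), auto_unbox = TRUE)
  logp("filter: kept %d of %d pairs (min_r2=%.2f)", filt$audit$n_kept,
       filt$audit$n_input, config$min_r2_meth)

  panel <- stage("load_panel", {
    if (grepl("\\.vcf$", config$panel)) read_panel_vcf(config$panel)
    else read_panel_hap(config$panel)
  })

  sumstats <- stage("read_sumstats", read_daner(config$sumstats))

  tags <- stage("select_tags", {
    cand <- unique(filt$catalog[, .(cpg_id, snp_id)])
    pv <- setNames(sumstats$P, sumstats$SNP)
    suppressWarnings(select_tags(cand, panel, r2_min = config$tag_r2, pvals = pv))
  })
  fwrite(tags, fp("tag_assignments.tsv"), sep = "\t")
  tag_ids <- unique(tags$tag_snp)
  logp("tags: %d tagSNPs over %d candidates (r2 >= %.2f)", length(tag_ids),
       length(unique(tags$snp_id)), config$tag_r2)

  join <- stage("harmonize_join", {
    tag_dt <- panel$variants[match(tag_ids, id), .(snp_id = id, a1 = alt, a2 = ref)]
    harmonize_and_join(tag_dt, sumstats)
  })
  fwrite(join$joined, fp("joined_tags.tsv"), sep = "\t")
  fwrite(join$report$status, fp("join_status.tsv"), sep = "\t")
  logp("join: retrieved %d/%d tags (%.1f%%)", join$report$retrieved,
       join$report$n_tags, 100 * join$report$retrieved_frac)

  enr <- stage("enrichment_scan", {
    asm_snps <- unique(merged$catalog$snp_id)
    ss2 <- copy(sumstats)[, is_asm := SNP %in% asm_snps]
    enrichment_scan(ss2, thresholds = config$enrichment_thresholds,
                    alternative = if (config$one_sided) "greater" else "two.sided")
  })
  fwrite(enr, fp("enrichment.tsv"), sep = "\t")

  meff <- stage("effective_tests", effective_tests(panel, join$joined$snp_id))
  scr <- stage("screen", screen_tags(join$joined, alpha = config$alpha, meff = meff))
  fwrite(as.data.table(scr), fp("screen_results.tsv"), sep = "\t")
  th <- attr(scr, "thresholds")
  jsonlite::write_json(c(th, list(meff = meff, pi0 = attr(scr, "pi0"))),
                       fp("screen_thresholds.json"), auto_unbox = TRUE, digits = NA)
  logp("screen: m=%d, Meff=%.1f | FDR p*=%.3g, alpha/m=%.3g, alpha/Meff=%.3g",
       nrow(scr), meff, th$fdr_p_star, th$alpha_over_m, th$alpha_over_meff)

  sig_tags <- scr[pass_fdr == TRUE, snp_id]
  expanded <- stage("ld_expand",
    ld_expand(sig_tags, filt$catalog, panel, r2_min = config$expand_r2,
              same_cpg = config$same_cpg))
  fwrite(expanded, fp("expanded_set.tsv"), sep = "\t")
  exp_ids <- unique(expanded$snp_id)

  blocks <- if (length(exp_ids))
    stage("assign_blocks", assign_blocks(exp_ids, panel, r2_min = config$block_r2))
  else data.table(snp_id = character(), block_id = character())
  fwrite(blocks, fp("ld_blocks.tsv"), sep = "\t")
  logp("expand: %d significant tags -> %d variants in %d LD blocks",
       length(sig_tags), length(exp_ids), length(unique(blocks$block_id)))

  report <- NULL
  have_ann <- !any(is.na(c(config$tss, config$histone, config$eqtl, config$volume)))
  if (have_ann && length(exp_ids)) {
    bundle <- stage("load_annotations", structure(list(
      tss = fread(config$tss, sep = "\t"),
      histone = fread(config$histone, sep = "\t"),
      eqtl = fread(config$eqtl, sep = "\t"),
      volume = fread(config$volume, sep = "\t")), class = "annotation_bundle"))
    ann <- stage("annotate", {
      exp_dt <- panel$variants[match(exp_ids, id), .(snp_id = id, a1 = alt, a2 = ref)]
      exp_join <- harmonize_and_join(exp_dt, sumstats)$joined
      vr <- merge(data.table(snp_id = exp_ids), exp_join, by = "snp_id", all.x = TRUE)
      annotate_variants(vr, filt$catalog, bundle, panel,
                        promoter_window = config$promoter_window,
                        volume_alpha = config$alpha)
    })
    report <- stage("report", build_report(scr, ann, blocks))
    fwrite(report, fp("causal_candidates.tsv"), sep = "\t")
  }

  flow <- list(
    n_pairs_union = merged$summary$n_pairs_union,
    n_snps_union = merged$summary$n_snps,
    n_cpgs_union = merged$summary$n_cpgs,
    n_pairs_filtered = filt$audit$n_kept,
    n_tags = length(tag_ids),
    n_retrieved = join$report$retrieved,
    retrieved_frac = join$report$retrieved_frac,
    n_fdr_significant = length(sig_tags),
    n_bonferroni_meff = sum(scr$pass_bonferroni & scr$pass_meff),
    n_expanded = length(exp_ids),
    n_blocks = length(unique(blocks$block_id))
  )
  jsonlite::write_json(flow, fp("flow_summary.json"), auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, fp("run_log.txt"))

  structure(list(config = config, merged = merged, filtered = filt, tags = tags,
                 join = join, enrichment = enr, screen = scr, meff = meff,
                 expanded = expanded, blocks = blocks, report = report,
                 flow = flow, out_dir = out_dir),
            class = "asmscan_run")
}

#' @export
print.asmscan_run <- function(x, ...) {
  cat("<asmscan_run> flow counts:\n")
  for (f in names(x$flow)) cat(sprintf("  %-20s %s\n", f, format(x$flow[[f]])))
  cat("outputs in ", x$out_dir, "\n")
  invisible(x)
}

#' Demo: simulate every input and run the pipeline end to end
#'
#' @param seed master seed for the synthetic world.
#' @param out_dir where to put inputs and outputs (default: a fresh temp
#'   directory).
#' @param sim a [sim_config()] (seed is overridden by `seed`).
#' @return the `asmscan_run`, with the simulation file paths in attribute
#'   `sim_paths`.
#' @export
run_demo <- function(seed = 42L, out_dir = tempfile("asmscan_demo_"),
                     sim = sim_config()) {
  sim$seed <- as.integer(seed)
  validate_sim_config(sim)
  in_dir <- file.path(out_dir, "inputs")
  paths <- write_sim_inputs(sim, in_dir)
  cfg <- validate_config(list(
    panel = paths$panel_hap,
    asm_tables = paste(unlist(paths[grep("^asm_", names(paths))]), collapse = ","),
    sumstats = paths$sumstats, tss = paths$tss, histone = paths$histone,
    eqtl = paths$eqtl, volume = paths$volume, seed = sim$seed,
    out_dir = file.path(out_dir, "results")))
  run <- run_pipeline(cfg)
  attr(run, "sim_paths") <- paths
  run
}
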