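#' Consistency analysis of a multi-library expression matrix
#'
#' The package's central entry point. Calls expression per library, splits
#' genes into consistently expressed (CE, detected in every library),
#' inconsistently expressed (IE, detected in some but not all) and
#' unexpressed groups, evaluates the housekeeping reference panel, and
#' computes the descriptive statistics that characterise the groups:
#' per-gene CV tables and binned distributions, per-group CV summaries,
#' percentile-sampled log10 expression profiles, group mean FPKMs with fold
#' ratios, pairwise library correlations, and expressed-gene set overlaps.
#'
#' @param x validated expression matrix (genes x libraries), e.g. from
#'   [read_expression_table()] or [simulate_matrix()].
#' @param hkg optional housekeeping panel (character vector of symbols).
#' @param threshold FPKM expression-call threshold (strict; default 0).
#' @param quantile_levels levels for the percentile profiles.
#' @param cv_ref reference CV cutoff reported for the housekeeping panel
#'   (default 0.55).
#' @param cv_bin_edges bin edges for the housekeeping CV distribution;
#'   computed from the data when `NULL` (0.05-wide bins).
#' @param correlation_transform transform for library-pair scatter
#'   correlations, see [pairwise_correlation()].
#' @return object of class `sct_consistency` with components `partition`,
#'   `hkg_report`, `hkg_cv` (table, distribution, `frac_below_ref` computed
#'   over the expressed panel and over the full panel), `group_cv`,
#'   `profiles`, `group_means`, `correlations`, `overlaps`, `threshold`,
#'   `libraries`.
#' @export
sct_consistency <- function(x, hkg = NULL, threshold = 0,
                            quantile_levels = seq(0.05, 0.95, by = 0.10),
                            cv_ref = 0.55, cv_bin_edges = NULL,
                            correlation_transform = "log10p1") {
  validate_expression_matrix(x)
  calls <- call_expressed(x, threshold)
  partition <- partition_genes(calls)
  hkg_report <- if (!is.null(hkg)) evaluate_hkgs(x, calls, hkg) else NULL

  hkg_cv <- NULL
  if (!is.null(hkg)) {
    present <- intersect(unique(hkg), rownames(x))
    tab <- cv_table(x, present)              # mean-0 panel genes excluded
    edges <- cv_bin_edges
    if (is.null(edges))
      edges <- seq(0, ceiling(max(tab$cv) / 0.05) * 0.05 + 1e-9, by = 0.05)
    hkg_cv <- list(
      table = tab,
      distribution = cv_distribution(tab$cv, edges),
      cv_ref = cv_ref,
      frac_below_ref = c(expressed = mean(tab$cv < cv_ref),
                         all = sum(tab$cv < cv_ref) / length(unique(hkg))))
  }

  gmeans <- group_means(x, partition, hkg)
  per_gene_mean <- rowMeans(x)
  grp <- list(HKG = if (is.null(hkg)) character() else
                intersect(hkg, partition_members(partition, "expressed")),
              CE = partition_members(partition, "CE"),
              IE = partition_members(partition, "IE"))
  grp <- grp[lengths(grp) > 0]
  profiles <- do.call(rbind, lapply(names(grp), function(g)
    percentile_profile(per_gene_mean[grp[[g]]], quantile_levels, group = g)))

  expressed_sets <- lapply(colnames(x), function(l)
    rownames(x)[calls[, l]])
  names(expressed_sets) <- colnames(x)

  structure(list(
    partition = partition,
    hkg_report = hkg_report,
    hkg_cv = hkg_cv,
    group_cv = group_cv_summary(x, partition, hkg),
    profiles = profiles,
    group_means = gmeans,
    correlations = correlation_table(x, correlation_transform),
    overlaps = overlap_analysis(expressed_sets),
    threshold = threshold,
    libraries = colnames(x),
    n_genes = nrow(x)),
    class = "sct_consistency")
}

#' @export
print.sct_consistency <- function(x, ...) {
  cat(sprintf("sct_consistency: %d genes x %d libraries (threshold %g)\n",
              x$n_genes, length(x$libraries), x$threshold))
  print(x$partition)
  if (!is.null(x$hkg_report))
    cat(sprintf("  HKG panel: %d/%d consistently expressed, %d silenced\n",
                length(x$hkg_report$ce), x$hkg_report$panel_size,
                length(x$hkg_report$silenced)))
  print(x$group_means)
  invisible(x)
}

#' @export
summary.sct_consistency <- function(object, ...) {
  print(object)
  if (!is.null(object$hkg_cv))
    cat(sprintf("  HKG CV < %.2f: %.1f%% of expressed panel (%.1f%% of full panel)\n",
                object$hkg_cv$cv_ref,
                100 * object$hkg_cv$frac_below_ref[["expressed"]],
                100 * object$hkg_cv$frac_below_ref[["all"]]))
  cat("\nper-group CV summary:\n")
  print(object$group_cv$per_gene, row.names = FALSE, digits = 4)
  cat("\npairwise library correlations:\n")
  print(object$correlations, row.names = FALSE, digits = 4)
  cat("\nexpressed-gene overlaps (dual percentages):\n")
  print(object$overlaps$pairwise, row.names = FALSE, digits = 4)
  invisible(object)
}

#' Plot percentile-sampled log10 expression profiles
#'
#' One line per group over the sampled quantile levels, the plot-ready view
#' of the group expression-level contrast.
#'
#' @param x an `sct_consistency` object.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.sct_consistency <- function(x, ...) {
  pr <- x$profiles
  groups <- unique(pr$group)
  lv <- sort(unique(pr$level))
  mat <- sapply(groups, function(g)
    pr$log10_fpkm[pr$group == g][order(pr$level[pr$group == g])])
  graphics::matplot(lv, mat, type = "b", pch = 19, lty = 1,
                    xlab = "quantile level", ylab = "log10 mean FPKM", ...)
  graphics::legend("topleft", legend = groups, col = seq_along(groups),
                   pch = 19, bty = "n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# end-to-end pipeline
# ---------------------------------------------------------------------------

default_config <- function() {
  list(expression_table = NULL, hkg_list = NULL, obo = NULL, gene2go = NULL,
       gmt = NULL, simulate = FALSE, threshold = 0,
       quantiles = seq(0.05, 0.95, by = 0.10), tail = "ge",
       percent_min = 80, p_max = 1e-3, propagate = TRUE, taxon = NULL,
       seed = 1L, outdir = "sctcons-out")
}

#' Run the full consistency pipeline and write a report bundle
#'
#' Reads (or simulates) the inputs, runs [sct_consistency()] and, when an
#' ontology/annotation or pathway collection is available, the
#' over-representation analyses for the CE and IE queries; writes every
#' result as TSV (with JSON provenance sidecars carrying the config hash)
#' plus a consolidated JSON run summary. Numeric TSV output is full
#' precision; re-running with an identical config (and seed, when
#' simulating) reproduces byte-identical tables.
#'
#' @param config named list overriding [default_config()] fields, or the path
#'   to a YAML file of the same flat key-value layout. Recognised fields:
#'   `expression_table`, `hkg_list`, `obo`, `gene2go`, `gmt` (paths),
#'   `simulate` (logical: generate the matrix and companion ontology from the
#'   seed instead of reading files), `threshold`, `quantiles`, `tail`,
#'   `percent_min`, `p_max`, `propagate`, `taxon`, `seed`, `outdir`.
#' @return (invisibly) the report bundle: list with `analysis`
#'   (`sct_consistency`), `enrichment` (named list or NULL), `pathway_enrichment`,
#'   `hkg`, `config`, `config_hash`, `files`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  for (p in c("expression_table", "hkg_list", "obo", "gene2go", "gmt"))
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
      stop("config path does not exist: ", p, " = ", cfg[[p]], call. = FALSE)
  cfg_hash <- substr(digest_config(cfg), 1, 12)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  emit <- function(df, name) {
    path <- file.path(cfg$outdir, paste0(name, ".tsv"))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    write_sidecar(path, list(config_hash = cfg_hash, seed = cfg$seed))
    files <<- c(files, path)
    path
  }

  stage <- "input"
  bundle <- tryCatch({
    hkg <- NULL; sim <- NULL
    if (isTRUE(cfg$simulate)) {
      sim <- simulate_matrix(synthetic_spec(seed = cfg$seed))
      mat <- sim$matrix
      hkg <- sim$truth$gene[startsWith(sim$truth$stratum, "hkg")]
    } else {
      if (is.null(cfg$expression_table))
        stop("no expression_table configured (and simulate is FALSE)")
      mat <- read_expression_table(cfg$expression_table)
      if (!is.null(cfg$hkg_list)) hkg <- read_gene_list(cfg$hkg_list)
    }

    stage <- "consistency"
    an <- sct_consistency(mat, hkg = hkg, threshold = cfg$threshold,
                          quantile_levels = cfg$quantiles)
    part_df <- data.frame(gene = names(an$partition$label),
                          label = as.character(an$partition$label),
                          stringsAsFactors = FALSE)
    emit(part_df, "partition")
    if (!is.null(an$hkg_report)) emit(an$hkg_report$per_library, "hkg_report")
    if (!is.null(an$hkg_cv)) {
      emit(an$hkg_cv$table, "hkg_cv")
      emit(an$hkg_cv$distribution, "hkg_cv_distribution")
    }
    emit(an$group_cv$per_gene, "group_cv_per_gene")
    emit(an$group_cv$per_library, "group_cv_per_library")
    emit(an$profiles, "percentile_profiles")
    gm <- as.data.frame(an$group_means)
    emit(gm, "group_means")
    fr <- attr(an$group_means, "fold_ratios")
    emit(data.frame(ratio = names(fr), value = unname(fr)), "fold_ratios")
    emit(an$correlations, "correlations")
    emit(an$overlaps$pairwise, "overlap_pairwise")
    emit(an$overlaps$venn, "overlap_venn")

    stage <- "enrichment"
    enr <- NULL; penr <- NULL
    dag <- NULL; ann <- NULL; pw <- NULL
    if (isTRUE(cfg$simulate)) {
      onto <- simulate_ontology(sim$spec, sim$truth)
      dag <- onto$dag; ann <- onto$annotations; pw <- onto$pathways
    } else {
      if (!is.null(cfg$obo)) dag <- read_obo(cfg$obo)
      if (!is.null(cfg$gene2go) && !is.null(dag))
        ann <- read_gene2go(cfg$gene2go, taxon = cfg$taxon, dag = dag)
      if (!is.null(cfg$gmt)) pw <- read_gmt(cfg$gmt)
    }
    ce_genes <- partition_members(an$partition, "CE")
    ie_genes <- partition_members(an$partition, "IE")
    if (!is.null(dag) && !is.null(ann)) {
      if (isTRUE(cfg$propagate)) ann <- propagate_annotations(dag, ann)
      enr <- list()
      for (nsp in names(ann)) {
        if (length(ann[[nsp]]) == 0) next
        for (q in c("CE", "IE")) {
          qg <- if (q == "CE") ce_genes else ie_genes
          res <- enrich_terms(qg, ann, nsp, dag = dag, tail = cfg$tail)
          key <- paste0(q, "_", abbreviate_ns(nsp))
          enr[[key]] <- res
          epath <- file.path(cfg$outdir, paste0("enrichment_", key, ".tsv"))
          write_enrichment(res, epath, extra = list(config_hash = cfg_hash))
          files <- c(files, epath)
        }
      }
    }
    if (!is.null(pw)) {
      penr <- enrich_pathways(ce_genes, pw, percent_min = cfg$percent_min,
                              p_max = cfg$p_max, tail = cfg$tail)
      p <- file.path(cfg$outdir, "pathway_enrichment_CE.tsv")
      write_enrichment(penr, p, extra = list(config_hash = cfg_hash))
      files <- c(files, p)
    }

    stage <- "summary"
    summary_path <- file.path(cfg$outdir, "run_summary.json")
    jsonlite::write_json(list(
      config = cfg[!vapply(cfg, is.null, TRUE)],
      config_hash = cfg_hash,
      defaults_used = list(threshold = cfg$threshold, tail = cfg$tail,
                           propagate = cfg$propagate,
                           quantile_rule = "nearest-rank, half-up rounding"),
      partition = as.list(table(an$partition$label)),
      group_means = stats::setNames(as.list(gm$mean_fpkm), gm$group),
      files = basename(files)),
      summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, summary_path)

    list(analysis = an, enrichment = enr, pathway_enrichment = penr,
         hkg = hkg, config = cfg, config_hash = cfg_hash, files = files)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(bundle)
}

abbreviate_ns <- function(nsp) {
  c(biological_process = "BP", cellular_component = "CC",
    molecular_function = "MF")[[nsp]]
}

# order-stable hash of the effective configuration
digest_config <- function(cfg) {
  cfg <- cfg[order(names(cfg))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

#' Render a human-readable report from a pipeline bundle
#'
#' Single markdown summary with group sizes, group mean FPKMs (rounded to one
#' decimal), the housekeeping panel table, variability and similarity
#' summaries, and the top over-represented terms. Missing bundle components
#' are listed as unavailable rather than failing.
#'
#' @param bundle return value of [run_pipeline()].
#' @param top how many enrichment rows to show per query/namespace.
#' @return character vector of markdown lines.
#' @export
render_report <- function(bundle, top = 5L) {
  an <- bundle$analysis
  out <- c("# Expression consistency report", "",
           sprintf("Config hash: `%s`", bundle$config_hash), "")
  sec <- function(title, body) c(sprintf("## %s", title), "", body, "")

  tab <- table(an$partition$label)
  out <- c(out, sec("Gene partition", sprintf(
    "- CE: %d  |  IE: %d  |  unexpressed: %d  (total %d over %d libraries)",
    tab[["CE"]], tab[["IE"]], tab[["unexpressed"]], length(an$partition$label),
    length(an$libraries))))

  out <- c(out, sec("Housekeeping reference", if (is.null(an$hkg_report))
    "unavailable (no panel supplied)" else c(
      sprintf("- panel %d genes: %d consistently expressed, %d inconsistent, %d silenced",
              an$hkg_report$panel_size, length(an$hkg_report$ce),
              length(an$hkg_report$ie), length(an$hkg_report$silenced)),
      sprintf("- %s: %d expressed%s", an$hkg_report$per_library$library,
              an$hkg_report$per_library$n_expressed,
              ifelse(nzchar(an$hkg_report$per_library$unexpressed),
                     paste0(" (unexpressed: ",
                            an$hkg_report$per_library$unexpressed, ")"), "")),
      if (!is.null(an$hkg_cv)) sprintf(
        "- CV < %.2f: %.1f%% of the expressed panel",
        an$hkg_cv$cv_ref, 100 * an$hkg_cv$frac_below_ref[["expressed"]]))))

  gm <- as.data.frame(an$group_means)
  fr <- attr(an$group_means, "fold_ratios")
  out <- c(out, sec("Expression levels", c(
    sprintf("- %s: mean %.1f FPKM (n = %d)", gm$group, gm$mean_fpkm, gm$n),
    sprintf("- fold ratios: %s",
            paste(sprintf("%s = %.1f", names(fr), fr), collapse = ", ")))))

  out <- c(out, sec("Variability (CV)", sprintf(
    "- %s: mean CV %.3f, median %.3f (n = %d)",
    an$group_cv$per_gene$group, an$group_cv$per_gene$mean_cv,
    an$group_cv$per_gene$median_cv, an$group_cv$per_gene$n)))

  ov <- an$overlaps$pairwise
  out <- c(out, sec("Library similarity", c(
    sprintf("- correlation %s vs %s: r = %.3f", an$correlations$lib_a,
            an$correlations$lib_b, an$correlations$r),
    sprintf("- overlap %s vs %s: %d common (%.1f%% / %.1f%%)",
            ov$set_a, ov$set_b, ov$common, ov$pct_a, ov$pct_b))))

  enr_body <- if (is.null(bundle$enrichment) || length(bundle$enrichment) == 0)
    "unavailable (no ontology supplied)"
  else unlist(lapply(names(bundle$enrichment), function(key) {
    df <- utils::head(bundle$enrichment[[key]], top)
    c(sprintf("### %s", key),
      sprintf("- %s %s (k=%d/m=%d, p=%.3g)", df$id,
              ifelse(is.na(df$name), "", df$name), df$k, df$m, df$p_value))
  }))
  pw_body <- if (is.null(bundle$pathway_enrichment))
    "pathways unavailable (no collection supplied)"
  else {
    df <- bundle$pathway_enrichment
    sig <- df[df$significant, , drop = FALSE]
    sprintf("- significant pathways (coverage > %g%%, p < %g): %s",
            attr(df, "percent_min"), attr(df, "p_max"),
            if (nrow(sig)) paste(sig$id, collapse = ", ") else "none")
  }
  out <- c(out, sec("Over-representation", c(enr_body, "", pw_body)))
  out
}
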