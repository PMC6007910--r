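#' Coefficient of variation of one gene's expression across libraries
#'
#' CV = sample standard deviation (n-1 denominator) divided by the mean; a
#' scale-free measure of expression fluctuation across libraries. Undefined
#' (returned as `NA`) when the mean is 0.
#'
#' @param values numeric vector of FPKM values (>= 2 values).
#' @param zeros `"include"` (default) uses all libraries; `"exclude"` drops
#'   zero-FPKM libraries first, measuring dispersion among detected
#'   measurements only (genes detected in < 2 libraries return `NA`).
#' @return named numeric vector `c(mean, sd, cv)`.
#' @export
gene_cv <- function(values, zeros = c("include", "exclude")) {
  zeros <- match.arg(zeros)
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  if (zeros == "exclude") values <- values[values > 0]
  if (length(values) < 2 || mean(values) == 0)
    return(c(mean = if (length(values)) mean(values) else 0,
             sd = NA_real_, cv = NA_real_))
  m <- mean(values)
  s <- stats::sd(values)
  c(mean = m, sd = s, cv = s / m)
}

#' Per-gene CV table
#'
#' @param x validated expression matrix.
#' @param genes optional subset of gene symbols (default: all rows).
#' @inheritParams gene_cv
#' @return data frame with columns gene, mean, sd, cv; genes whose CV is
#'   undefined (mean 0, or < 2 detected libraries under `zeros = "exclude"`)
#'   are excluded, with the count recorded in attribute `n_excluded`.
#' @export
cv_table <- function(x, genes = NULL, zeros = c("include", "exclude")) {
  zeros <- match.arg(zeros)
  validate_expression_matrix(x)
  if (is.null(genes)) genes <- rownames(x)
  miss <- setdiff(genes, rownames(x))
  if (length(miss) > 0)
    stop("genes not in matrix: ", paste(miss, collapse = ", "), call. = FALSE)
  rec <- t(vapply(genes, function(g) gene_cv(x[g, ], zeros = zeros),
                  c(mean = 0, sd = 0, cv = 0)))
  out <- data.frame(gene = genes, rec, row.names = NULL,
                    stringsAsFactors = FALSE)
  excluded <- is.na(out$cv)
  structure(out[!excluded, , drop = FALSE], n_excluded = sum(excluded))
}

#' Bin CVs into a percentage distribution
#'
#' @param cv numeric vector of CV values (non-empty).
#' @param bin_edges strictly increasing edges; bins are `(e[i], e[i+1]]` with
#'   the first bin closed on the left. Values outside the edges are an error.
#' @return data frame with columns bin (label), count, percent; percents sum
#'   to 100.
#' @export
cv_distribution <- function(cv, bin_edges) {
  cv <- cv[!is.na(cv)]
  if (length(cv) == 0) stop("no CV records", call. = FALSE)
  if (length(bin_edges) < 2 || any(diff(bin_edges) <= 0))
    stop("bin edges must be strictly increasing", call. = FALSE)
  if (any(cv < bin_edges[1] | cv > bin_edges[length(bin_edges)]))
    stop("CV value(s) outside bin edges", call. = FALSE)
  cut_ <- cut(cv, breaks = bin_edges, include.lowest = TRUE)
  counts <- as.integer(table(cut_))
  data.frame(bin = levels(cut_), count = counts,
             percent = 100 * counts / length(cv),
             stringsAsFactors = FALSE)
}

#' Per-group CV summaries
#'
#' Summarises per-gene (across-library) CVs within the housekeeping, CE and
#' IE groups, and additionally reports a per-library across-gene CV for each
#' group. By default dropout zeros are excluded from the per-gene CV, so the
#' group contrast measures fluctuation among detected measurements; with
#' `zeros = "include"` the structural zeros of IE genes dominate their
#' dispersion.
#'
#' @param x validated expression matrix.
#' @param partition a `gene_partition` computed on `x`.
#' @param hkg character vector of housekeeping symbols (optional). The HKG
#'   group contains the expressed panel genes; CE and IE are the full groups
#'   (housekeeping members included, as they are genes like any other).
#' @inheritParams gene_cv
#' @return object of class `group_cv_summary`: list with `per_gene` (data
#'   frame: group, n, mean_cv, median_cv, q1, q3) and `per_library` (data
#'   frame: group, library, cv of expression across the group's genes).
#'   Empty groups are omitted with a warning.
#' @export
group_cv_summary <- function(x, partition, hkg = NULL,
                             zeros = c("exclude", "include")) {
  zeros <- match.arg(zeros)
  validate_expression_matrix(x)
  groups <- list(
    HKG = if (is.null(hkg)) character() else
      intersect(hkg, partition_members(partition, "expressed")),
    CE = partition_members(partition, "CE"),
    IE = partition_members(partition, "IE"))
  empty <- names(groups)[lengths(groups) == 0]
  if (length(empty) > 0) {
    if (!(is.null(hkg) && identical(empty, "HKG")))
      warning("empty group(s) omitted: ", paste(empty, collapse = ", "))
    groups <- groups[lengths(groups) > 0]
  }
  if (length(groups) == 0) stop("all groups empty", call. = FALSE)
  per_gene <- do.call(rbind, lapply(names(groups), function(g) {
    cvs <- cv_table(x, groups[[g]], zeros = zeros)$cv
    q <- stats::quantile(cvs, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = g, n = length(cvs), mean_cv = mean(cvs),
               median_cv = q[2], q1 = q[1], q3 = q[3],
               stringsAsFactors = FALSE)
  }))
  per_library <- do.call(rbind, lapply(names(groups), function(g) {
    sub <- x[groups[[g]], , drop = FALSE]
    data.frame(group = g, library = colnames(sub),
               cv = apply(sub, 2, function(v)
                 if (mean(v) > 0) stats::sd(v) / mean(v) else NA_real_),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(per_gene = per_gene, per_library = per_library,
                 zeros = zeros),
            class = "group_cv_summary")
}

#' @export
print.group_cv_summary <- function(x, ...) {
  cat("group_cv_summary (per-gene CV across libraries, zeros ",
      x$zeros, "d):\n", sep = "")
  print(x$per_gene, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Percentile-sampled log10 expression profile
#'
#' Per-gene mean FPKMs are sorted ascendingly; at each quantile level the
#' observed value of nearest rank `max(1, round(level * n))` (half-up
#' rounding) is sampled and converted to log10. Sampling actual observed
#' values (no interpolation) keeps the profile on real measurements.
#'
#' @param means positive per-gene mean FPKMs.
#' @param levels quantile levels in (0, 1); default 5%, 15%, ..., 95%.
#' @param group optional group label stored in the result.
#' @return data frame with columns group, level, rank, fpkm, log10_fpkm;
#'   log10 values are non-decreasing in level.
#' @export
percentile_profile <- function(means, levels = seq(0.05, 0.95, by = 0.10),
                               group = NA_character_) {
  if (length(means) == 0) stop("no per-gene means supplied", call. = FALSE)
  if (any(means <= 0)) stop("per-gene means must be positive", call. = FALSE)
  if (any(levels <= 0 | levels >= 1))
    stop("levels must lie in (0, 1)", call. = FALSE)
  s <- sort(means)
  n <- length(s)
  rank <- pmax(1L, as.integer(floor(levels * n + 0.5)))
  data.frame(group = group, level = levels, rank = rank,
             fpkm = s[rank], log10_fpkm = log10(s[rank]),
             stringsAsFactors = FALSE)
}

#' Group mean expression levels and fold ratios
#'
#' Per-gene mean = arithmetic mean over ALL libraries (zeros included, so an
#' inconsistently expressed gene's dropouts count against it). The group mean
#' is the arithmetic mean of per-gene means over: the expressed housekeeping
#' panel, the CE group, the IE group, and all expressed genes overall.
#'
#' @param x validated expression matrix.
#' @param partition a `gene_partition` computed on `x`.
#' @param hkg optional housekeeping panel symbols.
#' @return object of class `group_means`: data frame with columns group, n,
#'   mean_fpkm, plus attribute `fold_ratios` (named numeric: CE_vs_IE,
#'   HKG_vs_CE, HKG_vs_IE where denominators are positive).
#' @export
group_means <- function(x, partition, hkg = NULL) {
  validate_expression_matrix(x)
  gm <- rowMeans(x)
  groups <- list(
    HKG = if (is.null(hkg)) character() else
      intersect(hkg, partition_members(partition, "expressed")),
    CE = partition_members(partition, "CE"),
    IE = partition_members(partition, "IE"),
    expressed = partition_members(partition, "expressed"))
  out <- data.frame(
    group = names(groups),
    n = lengths(groups),
    mean_fpkm = vapply(groups, function(g)
      if (length(g) > 0) mean(gm[g]) else NA_real_, 0),
    stringsAsFactors = FALSE, row.names = NULL)
  mf <- stats::setNames(out$mean_fpkm, out$group)
  ratio <- function(a, b)
    if (!is.na(mf[[a]]) && !is.na(mf[[b]]) && mf[[b]] > 0)
      mf[[a]] / mf[[b]] else NA_real_
  fr <- c(CE_vs_IE = ratio("CE", "IE"),
          HKG_vs_CE = ratio("HKG", "CE"),
          HKG_vs_IE = ratio("HKG", "IE"))
  structure(out, fold_ratios = fr, class = c("group_means", "data.frame"))
}

#' @export
print.group_means <- function(x, ...) {
  cat("group mean FPKM (per-gene means over all libraries):\n")
  print.data.frame(x, row.names = FALSE, digits = 5)
  fr <- attr(x, "fold_ratios")
  cat("fold ratios:",
      paste(sprintf("%s = %.1f", names(fr), fr), collapse = ", "), "\n")
  invisible(x)
}

#' Pairwise expression correlation between two libraries
#'
#' Pearson correlation over genes expressed (> 0) in at least one of the two
#' libraries. FPKM spans several orders of magnitude, so the default
#' correlates log10(FPKM + 1) values; `transform = "raw"` gives the
#' untransformed coefficient.
#'
#' @param x validated expression matrix.
#' @param lib_a,lib_b library names (columns of `x`).
#' @param transform `"log10p1"` (default) or `"raw"`.
#' @return single numeric correlation coefficient.
#' @export
pairwise_correlation <- function(x, lib_a, lib_b,
                                 transform = c("log10p1", "raw")) {
  transform <- match.arg(transform)
  validate_expression_matrix(x)
  if (!all(c(lib_a, lib_b) %in% colnames(x)))
    stop("library not in matrix", call. = FALSE)
  a <- x[, lib_a]; b <- x[, lib_b]
  keep <- a > 0 | b > 0
  if (sum(keep) < 3)
    stop("fewer than 3 genes expressed in the pair", call. = FALSE)
  a <- a[keep]; b <- b[keep]
  if (transform == "log10p1") { a <- log10(a + 1); b <- log10(b + 1) }
  stats::cor(a, b)
}

#' All pairwise library correlations
#'
#' @inheritParams pairwise_correlation
#' @return data frame with columns lib_a, lib_b, r for every unordered pair.
#' @export
correlation_table <- function(x, transform = c("log10p1", "raw")) {
  transform <- match.arg(transform)
  libs <- colnames(x)
  pairs <- utils::combn(libs, 2)
  data.frame(lib_a = pairs[1, ], lib_b = pairs[2, ],
             r = apply(pairs, 2, function(p)
               pairwise_correlation(x, p[1], p[2], transform)),
             stringsAsFactors = FALSE)
}

#' Multi-set overlap analysis (pairwise percentages and Venn regions)
#'
#' For each unordered pair of gene sets, the number of common symbols and the
#' two directional percentages (common over each set's size), matching the
#' dual-percentage convention used when comparing expressed-gene lists
#' between libraries. Also returns the full Venn decomposition over all sets:
#' one count per non-empty membership pattern.
#'
#' @param sets named list (>= 2) of character vectors.
#' @return object of class `overlap_result`: list with `pairwise` (data
#'   frame: set_a, set_b, size_a, size_b, common, pct_a, pct_b; percentages
#'   are `NA` for empty sets, flagged with a warning) and `venn` (data frame:
#'   pattern such as `"110"` over the set order, regions, count).
#' @export
overlap_analysis <- function(sets) {
  if (!is.list(sets) || length(sets) < 2)
    stop("need at least 2 sets", call. = FALSE)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named", call. = FALSE)
  sets <- lapply(sets, unique)
  if (any(lengths(sets) == 0))
    warning("empty set(s): percentages undefined for ",
            paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  pairs <- utils::combn(names(sets), 2)
  pairwise <- do.call(rbind, apply(pairs, 2, function(p) {
    a <- sets[[p[1]]]; b <- sets[[p[2]]]
    common <- length(intersect(a, b))
    data.frame(set_a = p[1], set_b = p[2],
               size_a = length(a), size_b = length(b), common = common,
               pct_a = if (length(a)) 100 * common / length(a) else NA_real_,
               pct_b = if (length(b)) 100 * common / length(b) else NA_real_,
               stringsAsFactors = FALSE)
  }, simplify = FALSE))
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  pattern <- apply(member, 1, function(r) paste(as.integer(r), collapse = ""))
  tab <- table(pattern)
  venn <- data.frame(pattern = names(tab),
                     regions = vapply(names(tab), function(p) {
                       on <- strsplit(p, "")[[1]] == "1"
                       paste(names(sets)[on], collapse = "&")
                     }, ""),
                     count = as.integer(tab),
                     stringsAsFactors = FALSE, row.names = NULL)
  structure(list(pairwise = pairwise, venn = venn, set_names = names(sets)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("overlap_result over", length(x$set_names), "sets:\n")
  print(x$pairwise, row.names = FALSE, digits = 4)
  invisible(x)
}
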