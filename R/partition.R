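#' Call genes expressed per library
#'
#' A gene is called expressed in a library when its FPKM strictly exceeds
#' `threshold`. The default threshold of 0 treats any detected signal as
#' expression; raising it makes calls more conservative and can only move
#' genes out of the consistently expressed group, never into it.
#'
#' @param x validated expression matrix (genes x libraries).
#' @param threshold non-negative FPKM floor; expressed means FPKM > threshold.
#' @return logical matrix of the same shape and dimnames as `x`.
#' @export
call_expressed <- function(x, threshold = 0) {
  validate_expression_matrix(x)
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0)
    stop("threshold must be a single non-negative number", call. = FALSE)
  x > threshold
}

#' Partition genes into consistently / inconsistently expressed groups
#'
#' Genes detected in every library are consistently expressed (CE); genes
#' detected in at least one but not all libraries are inconsistently
#' expressed (IE); the rest are unexpressed. The three labels are disjoint
#' and cover all genes. Unexpressed genes are retained with their label but
#' excluded from downstream group statistics.
#'
#' @param calls logical gene-by-library matrix from [call_expressed()].
#' @return object of class `gene_partition`: list with `label` (named factor
#'   with levels CE/IE/unexpressed), `calls`, and `libraries`.
#' @export
partition_genes <- function(calls) {
  if (!is.matrix(calls) || !is.logical(calls))
    stop("calls must be a logical matrix", call. = FALSE)
  if (ncol(calls) < 2)
    stop("consistency is undefined for fewer than 2 libraries", call. = FALSE)
  n_on <- rowSums(calls)
  lab <- ifelse(n_on == ncol(calls), "CE", ifelse(n_on > 0, "IE", "unexpressed"))
  label <- factor(lab, levels = c("CE", "IE", "unexpressed"))
  names(label) <- rownames(calls)
  structure(list(label = label, calls = calls, libraries = colnames(calls)),
            class = "gene_partition")
}

#' @export
print.gene_partition <- function(x, ...) {
  n <- table(x$label)
  cat(sprintf(
    "gene_partition over %d libraries (%s)\n  CE %d | IE %d | unexpressed %d (total %d)\n",
    length(x$libraries), paste(x$libraries, collapse = ", "),
    n[["CE"]], n[["IE"]], n[["unexpressed"]], length(x$label)))
  invisible(x)
}

#' Genes carrying a given partition label
#'
#' @param partition a `gene_partition`.
#' @param label one of `"CE"`, `"IE"`, `"unexpressed"`, or `"expressed"`
#'   (CE and IE combined).
#' @return character vector of gene symbols.
#' @export
partition_members <- function(partition, label = c("CE", "IE", "unexpressed",
                                                   "expressed")) {
  label <- match.arg(label)
  if (label == "expressed")
    return(names(partition$label)[partition$label != "unexpressed"])
  names(partition$label)[partition$label == label]
}

#' Evaluate a housekeeping-gene reference panel
#'
#' Housekeeping genes (HKGs) are assumed constitutively expressed, so the
#' panel serves as a sensitivity/reproducibility control: per library, how
#' many panel genes are detected, and which are not. Panel genes absent from
#' the matrix entirely (never assembled) are treated as unexpressed in every
#' library, mirroring the treatment of a transcriptionally silenced control
#' gene. The expressed panel genes are sub-partitioned into CE and IE.
#'
#' @param x validated expression matrix.
#' @param calls logical call matrix from [call_expressed()] on `x`.
#' @param hkg character vector of panel gene symbols (non-empty).
#' @return object of class `hkg_report`: list with `panel_size`, `in_matrix`,
#'   `missing` (symbols absent from the matrix), `per_library` (data frame:
#'   library, n_expressed, unexpressed symbols as comma string),
#'   `unexpressed_by_library` (named list), `silenced` (panel genes expressed
#'   nowhere, including missing ones), `ce`, `ie` (symbol vectors).
#' @export
evaluate_hkgs <- function(x, calls, hkg) {
  validate_expression_matrix(x)
  hkg <- unique(as.character(hkg))
  if (length(hkg) == 0) stop("HKG list is empty", call. = FALSE)
  present <- intersect(hkg, rownames(x))
  missing <- setdiff(hkg, rownames(x))
  sub <- calls[present, , drop = FALSE]
  unexp <- lapply(colnames(sub), function(l)
    sort(c(present[!sub[, l]], missing)))
  names(unexp) <- colnames(sub)
  per_library <- data.frame(
    library = colnames(sub),
    n_expressed = vapply(unexp, function(u) length(hkg) - length(u), 0L),
    unexpressed = vapply(unexp, paste, "", collapse = ","),
    stringsAsFactors = FALSE, row.names = NULL)
  part <- partition_genes(calls)
  lab <- part$label[present]
  structure(list(panel_size = length(hkg),
                 in_matrix = length(present),
                 missing = missing,
                 per_library = per_library,
                 unexpressed_by_library = unexp,
                 silenced = sort(c(present[rowSums(sub) == 0], missing)),
                 ce = sort(present[lab == "CE"]),
                 ie = sort(present[lab == "IE"])),
            class = "hkg_report")
}

#' @export
print.hkg_report <- function(x, ...) {
  cat(sprintf("hkg_report: panel of %d genes (%d in matrix, %d missing)\n",
              x$panel_size, x$in_matrix, length(x$missing)))
  cat(sprintf("  consistently expressed: %d | inconsistently: %d | silenced: %d\n",
              length(x$ce), length(x$ie), length(x$silenced)))
  for (i in seq_len(nrow(x$per_library)))
    cat(sprintf("  %-8s expressed %d/%d%s\n",
                x$per_library$library[i], x$per_library$n_expressed[i],
                x$panel_size,
                if (nzchar(x$per_library$unexpressed[i]))
                  paste0("  (unexpressed: ", x$per_library$unexpressed[i], ")")
                else ""))
  invisible(x)
}
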