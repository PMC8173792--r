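#' Construct an ASV table
#'
#' The central container for 16S amplicon sequence variant (ASV) data:
#' integer counts (samples x ASVs), a SILVA-style semicolon-delimited
#' lineage string per ASV, and per-sample metadata (treatment and an
#' extraction-control flag).
#'
#' @param counts Non-negative integer matrix, samples in rows, ASVs in
#'   columns, both dimnames set.
#' @param taxonomy Named character vector of lineage strings, one per ASV.
#' @param sample_meta Data frame with columns `sample_id`, `treatment`,
#'   `is_control`, one row per sample.
#' @return Object of class `asv_table`.
#' @export
asv_table <- function(counts, taxonomy, sample_meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` needs sample rownames and ASV colnames", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("`counts` must be non-negative integers", call. = FALSE)
  }
  miss <- setdiff(c("sample_id", "treatment", "is_control"),
                  names(sample_meta))
  if (length(miss)) {
    stop("sample_meta missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sample_meta <- sample_meta[match(rownames(counts), sample_meta$sample_id), ]
  if (anyNA(sample_meta$sample_id)) {
    stop("sample_meta does not cover all samples in `counts`", call. = FALSE)
  }
  if (is.null(names(taxonomy))) names(taxonomy) <- colnames(counts)
  taxonomy <- taxonomy[colnames(counts)]
  if (anyNA(taxonomy)) {
    stop("taxonomy missing for some ASVs", call. = FALSE)
  }
  empty <- rowSums(counts) == 0 & !sample_meta$is_control
  if (any(empty)) {
    stop("non-control sample(s) with zero reads: ",
         paste(rownames(counts)[empty], collapse = ", "), call. = FALSE)
  }
  structure(list(counts = counts, taxonomy = taxonomy,
                 sample_meta = sample_meta),
            class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat("ASV table:", nrow(x$counts), "samples x", ncol(x$counts), "ASVs;",
      sum(x$counts), "reads;",
      sum(x$sample_meta$is_control), "control sample(s)\n")
  invisible(x)
}

#' Read an ASV table and its sample metadata from TSV
#'
#' Default orientation mirrors the usual supplement layout: ASVs as rows
#' (first column = ASV id), samples as columns, plus optional `taxonomy`
#' and `sequence` columns. Set `transposed = TRUE` for samples-as-rows
#' input.
#'
#' @param counts_path TSV of counts (see Details).
#' @param meta_path TSV with `sample_id`, `treatment`, `is_control`.
#' @param transposed Counts file has samples as rows.
#' @return An [asv_table()].
#' @export
read_asv_table <- function(counts_path, meta_path, transposed = FALSE) {
  raw <- read_delim_auto(counts_path)
  meta <- read_delim_auto(meta_path,
                          required = c("sample_id", "treatment",
                                       "is_control"))
  meta$is_control <- as.logical(meta$is_control)
  ids <- raw[[1]]
  aux <- intersect(c("taxonomy", "sequence"), names(raw))
  numcols <- setdiff(names(raw)[-1], aux)
  m <- as.matrix(raw[, numcols, drop = FALSE])
  rownames(m) <- ids
  if (!transposed) m <- t(m)
  taxonomy <- if ("taxonomy" %in% aux && !transposed) {
    stats::setNames(raw$taxonomy, ids)
  } else if ("taxonomy" %in% aux) {
    stats::setNames(raw$taxonomy, ids)[colnames(m)]
  } else {
    stats::setNames(rep("unclassified", ncol(m)), colnames(m))
  }
  asv_table(m, taxonomy, meta)
}

#' Write an ASV table to TSV (ASVs as rows)
#'
#' @param table An [asv_table()].
#' @param counts_path,meta_path Output paths; `meta_path = NULL` skips the
#'   metadata file.
#' @return `counts_path`, invisibly.
#' @export
write_asv_table <- function(table, counts_path, meta_path = NULL) {
  df <- data.frame(asv_id = colnames(table$counts),
                   t(table$counts),
                   taxonomy = unname(table$taxonomy),
                   check.names = FALSE)
  write_tsv(df, counts_path)
  if (!is.null(meta_path)) write_tsv(table$sample_meta, meta_path)
  invisible(counts_path)
}

#' Remove extraction-control contaminants
#'
#' An ASV is flagged as a contaminant when its reads in the extraction
#' control make up at least `threshold` of its reads across all libraries
#' (control included, the default; set `include_control_in_total = FALSE`
#' for a biological-samples-only denominator). The control sample is
#' dropped from the output table, as are ASVs left with zero reads.
#'
#' @param table An [asv_table()] with exactly one control sample flagged.
#' @param threshold Contamination fraction cut-off (default 0.10).
#' @param include_control_in_total Include the control's reads in the
#'   per-ASV denominator.
#' @return List with `table` (filtered, control removed) and `removed`
#'   (data frame of removed ASVs with `control_fraction` and
#'   `control_only`).
#' @export
filter_contaminants <- function(table, threshold = 0.10,
                                include_control_in_total = TRUE) {
  ctl <- which(table$sample_meta$is_control)
  if (length(ctl) != 1) {
    stop("exactly one control sample must be flagged (found ",
         length(ctl), ")", call. = FALSE)
  }
  ctl_counts <- table$counts[ctl, ]
  denom <- colSums(table$counts)
  if (!include_control_in_total) denom <- denom - ctl_counts
  frac <- ifelse(denom == 0, Inf, ctl_counts / denom)
  # an ASV absent from the control can never reach a positive threshold
  contaminated <- ctl_counts > 0 & frac >= threshold
  removed <- data.frame(
    asv_id = colnames(table$counts)[contaminated],
    control_reads = unname(ctl_counts[contaminated]),
    total_reads = unname(colSums(table$counts)[contaminated]),
    control_fraction = unname(frac[contaminated]),
    control_only = unname(ctl_counts[contaminated] ==
                            colSums(table$counts)[contaminated])
  )
  keep_counts <- table$counts[-ctl, !contaminated, drop = FALSE]
  keep_counts <- keep_counts[, colSums(keep_counts) > 0, drop = FALSE]
  out <- asv_table(keep_counts, table$taxonomy[colnames(keep_counts)],
                   table$sample_meta[-ctl, , drop = FALSE])
  list(table = out, removed = removed)
}

#' Per-sample relative abundances
#'
#' @param table An [asv_table()] or a counts matrix (samples x ASVs).
#' @return Matrix of proportions; each row sums to 1.
#' @export
relative_abundance <- function(table) {
  m <- if (inherits(table, "asv_table")) table$counts else as.matrix(table)
  depths <- rowSums(m)
  if (any(depths == 0)) {
    stop("sample(s) with zero reads: ",
         paste(rownames(m)[depths == 0], collapse = ", "), call. = FALSE)
  }
  sweep(m, 1, depths, "/")
}

#' Extract a taxonomic rank from SILVA-style lineage strings
#'
#' Lineages are semicolon-delimited with optional `x__` rank prefixes.
#' Unresolvable ranks become `"unclassified"`.
#'
#' @param taxonomy Character vector of lineage strings.
#' @param rank One of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @return Character vector of rank names.
#' @export
taxonomy_rank <- function(taxonomy, rank = "family") {
  levels <- c(domain = 1, phylum = 2, class = 3, order = 4, family = 5,
              genus = 6)
  i <- levels[[match.arg(rank, names(levels))]]
  vapply(strsplit(taxonomy, ";"), function(parts) {
    if (length(parts) < i) return("unclassified")
    p <- trimws(sub("^[a-z]__", "", trimws(parts[i])))
    if (p == "" || grepl("^(unknown|unassigned|uncultured)$", tolower(p))) {
      "unclassified"
    } else p
  }, character(1))
}

#' Family-level community composition
#'
#' Aggregates relative abundances to family rank, keeps the `top_k`
#' families by overall mean abundance, and pools the remainder into an
#' `"others"` bucket.
#'
#' @param table An [asv_table()].
#' @param top_k Number of families listed individually.
#' @return Matrix of proportions, samples x (families + others); rows sum
#'   to 1.
#' @export
family_composition <- function(table, top_k = 8) {
  rel <- relative_abundance(table)
  fam <- taxonomy_rank(table$taxonomy, "family")
  agg <- t(rowsum(t(rel), group = fam))
  keep <- names(sort(colMeans(agg), decreasing = TRUE))
  keep <- utils::head(keep, top_k)
  rest <- setdiff(colnames(agg), keep)
  out <- agg[, keep, drop = FALSE]
  out <- cbind(out, others = if (length(rest)) {
    rowSums(agg[, rest, drop = FALSE])
  } else 0)
  out
}

#' Core, symbiome and apobiome membership sets
#'
#' Ubiquity-based ASV sets on a filtered (control-free) table: the core
#' microbiome holds ASVs present in every sample; the symbiome those
#' present in every symbiotic sample (light and dark); the apobiome those
#' present in every aposymbiotic sample. The sets overlap by construction
#' (core is a subset of both).
#'
#' @param table A filtered [asv_table()] without control samples.
#' @param sym_treatments,apo_treatments Treatment labels defining the
#'   symbiotic and aposymbiotic groups.
#' @return List of character vectors `core`, `symbiome`, `apobiome`.
#' @export
core_sets <- function(table, sym_treatments = c("SymL", "SymD"),
                      apo_treatments = "ApoL") {
  if (any(table$sample_meta$is_control)) {
    stop("core sets are defined on the filtered, control-free table",
         call. = FALSE)
  }
  present <- table$counts > 0
  in_all <- function(rows) {
    colnames(present)[colSums(present[rows, , drop = FALSE]) == length(rows)]
  }
  sym_rows <- which(table$sample_meta$treatment %in% sym_treatments)
  apo_rows <- which(table$sample_meta$treatment %in% apo_treatments)
  list(core = in_all(seq_len(nrow(present))),
       symbiome = in_all(sym_rows),
       apobiome = in_all(apo_rows))
}
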