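# Summaries of N-cycling functional gene data from captured metagenomes and
# qPCR: relative abundances, the (nirK+nirS)/nosZ indicator of N2O production
# potential, and copy-number arithmetic.

.GENE_FAMILIES <- c("nifH", "amoA_bacterial", "amoA_archaeal", "narG", "napA",
                    "nirK", "nirS", "norB", "nosZ", "nrfA", "hdhA", "other")

# coerce a count table (data.frame or matrix, samples x genes) to a numeric
# matrix, keeping non-gene metadata columns out
.count_matrix <- function(table) {
  if (is.data.frame(table)) {
    num <- vapply(table, is.numeric, logical(1))
    m <- as.matrix(table[, num, drop = FALSE])
  } else {
    m <- as.matrix(table)
  }
  if (any(m < 0, na.rm = TRUE)) stop("counts must be non-negative")
  m
}

#' Relative abundance of a gene set
#'
#' Percentage of all captured functional-gene sequences falling in a set of
#' gene families, per sample. Aggregate families by listing their members,
#' e.g. `c("nirK", "nirS")` for nir or
#' `c("amoA_bacterial", "amoA_archaeal")` for amoA. The denominator is the
#' per-sample total over all (numeric) gene columns including `other`.
#'
#' @param table Count table, samples x gene families (data frame or matrix;
#'   non-numeric metadata columns are ignored).
#' @param gene_set Character vector of column names to aggregate.
#' @return Numeric vector, % per sample.
#' @export
relative_abundance <- function(table, gene_set) {
  if (!length(gene_set)) stop("`gene_set` must name at least one gene family")
  m <- .count_matrix(table)
  miss <- setdiff(gene_set, colnames(m))
  if (length(miss)) stop("gene families not in table: ", paste(miss, collapse = ", "))
  tot <- rowSums(m)
  if (any(tot <= 0)) stop("zero row sum: sample(s) with no captured sequences")
  100 * rowSums(m[, gene_set, drop = FALSE]) / tot
}

#' Full relative-abundance table
#'
#' @param table Count table, samples x gene families.
#' @return Matrix of per-sample percentages, rows summing to 100.
#' @export
relative_abundance_table <- function(table) {
  m <- .count_matrix(table)
  tot <- rowSums(m)
  if (any(tot <= 0)) stop("zero row sum: sample(s) with no captured sequences")
  sweep(m, 1, tot, "/") * 100
}

#' (nirK + nirS)/nosZ gene ratio
#'
#' Ratio of nitrite-reductase to N2O-reductase gene counts per sample, a
#' commonly used indicator of a soil's N2O production potential: nirK/nirS
#' encode the step producing the N2O precursor, nosZ the only sink (N2O ->
#' N2). Identical on counts and on relative abundances.
#'
#' @param table Count table with `nirK`, `nirS` and `nosZ` columns.
#' @return Numeric vector per sample; `NA` (with a warning) where nosZ = 0.
#' @export
nir_nosz_ratio <- function(table) {
  m <- .count_matrix(table)
  need <- c("nirK", "nirS", "nosZ")
  miss <- setdiff(need, colnames(m))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  out <- (m[, "nirK"] + m[, "nirS"]) / m[, "nosZ"]
  if (any(m[, "nosZ"] == 0)) {
    warning("nosZ = 0 in ", sum(m[, "nosZ"] == 0), " sample(s); ratio undefined")
    out[m[, "nosZ"] == 0] <- NA_real_
  }
  out
}

#' qPCR copies per gram of dry soil
#'
#' Scales copies detected per reaction to the whole DNA elution and the dry
#' soil mass extracted:
#' copies_per_reaction x (elution_volume/template_volume) / soil_dw.
#'
#' @param copies_per_reaction Gene copies detected in one reaction.
#' @param template_volume Template volume per reaction, uL.
#' @param elution_volume DNA elution volume, uL.
#' @param soil_dw_extracted Dry soil mass extracted, g.
#' @return Copies per g dry soil (vectorised).
#' @examples
#' qpcr_copies_per_g(1000, 2, 100, 0.5)  # 1e5
#' @export
qpcr_copies_per_g <- function(copies_per_reaction, template_volume,
                              elution_volume, soil_dw_extracted) {
  if (any(template_volume <= 0) || any(elution_volume <= 0) ||
      any(soil_dw_extracted <= 0)) {
    stop("volumes and soil mass must be positive")
  }
  copies_per_reaction * (elution_volume / template_volume) / soil_dw_extracted
}

#' Per-surface summary of gene abundances
#'
#' Mean and standard error of a per-sample statistic (relative abundance or
#' gene ratio) within surface classes, matching how individual values and
#' means are reported for n = 3 replicates.
#'
#' @param values Per-sample numeric vector.
#' @param surface_class Per-sample grouping labels.
#' @return Data frame with `surface_class`, `mean`, `se`, `n`.
#' @export
summarize_by_surface <- function(values, surface_class) {
  sp <- split(values, surface_class)
  out <- data.frame(
    surface_class = names(sp),
    mean = vapply(sp, mean, numeric(1), na.rm = TRUE),
    se = vapply(sp, function(v) {
      v <- v[!is.na(v)]
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
    }, numeric(1)),
    n = vapply(sp, function(v) sum(!is.na(v)), integer(1))
  )
  rownames(out) <- NULL
  out
}
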