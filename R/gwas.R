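#' Default GWAS column mapping
#'
#' Maps the canonical tripnet field names to the column names found in the
#' input TSV. The defaults follow UK-Biobank-style summary-statistic exports
#' (`variant`, `rsid`, `chr`, `pos`, `minor_AF`, `beta`, `se`, `pval`).
#' Fields mapped to `NA` are treated as absent; `variant` (or `rsid`),
#' `minor_AF` and `pval` are mandatory.
#'
#' @param variant,rsid,chr,pos,minor_AF,beta,se,pval Column names in the file.
#' @return Named character vector usable as `column_map` in
#'   [read_gwas_table()].
#' @export
#' @examples
#' gwas_column_map(pval = "p_value")
gwas_column_map <- function(variant = "variant", rsid = "rsid", chr = "chr",
                            pos = "pos", minor_AF = "minor_AF", beta = "beta",
                            se = "se", pval = "pval") {
  c(variant_id = variant, rsid = rsid, chrom = chr, pos = pos,
    maf = minor_AF, beta = beta, se = se, pval = pval)
}

#' Read one trait's GWAS summary statistics
#'
#' Reads a tab-separated summary-statistic file into a tidy tibble with the
#' canonical columns `variant_id`, `rsid`, `chrom`, `pos`, `maf`, `beta`,
#' `se`, `pval`. Rows whose mandatory fields (`variant_id`/`rsid`, `maf`,
#' `pval`) fail to parse are dropped; the drop count is reported and stored
#' in the `n_dropped` attribute. Variant identity is normalized to the rsid
#' when present, otherwise the chrom:pos:ref:alt style id is kept.
#' Duplicated ids keep the row with the smallest p-value.
#'
#' @param path Path to a TSV file.
#' @param column_map Named character vector from [gwas_column_map()].
#' @return A tibble of GWAS records (attribute `n_dropped` counts rows
#'   removed for unparseable mandatory fields, `n_dedup` duplicate-id rows
#'   collapsed).
#' @export
read_gwas_table <- function(path, column_map = gwas_column_map()) {
  if (!file.exists(path)) stop_config("GWAS file not found: %s", path)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0L) {
    warn(sprintf("GWAS file %s is empty", path))
    return(empty_gwas_tbl())
  }
  have_variant <- !is.na(column_map[["variant_id"]]) &&
    column_map[["variant_id"]] %in% names(raw)
  have_rsid <- !is.na(column_map[["rsid"]]) &&
    column_map[["rsid"]] %in% names(raw)
  if (!have_variant && !have_rsid) {
    stop_config("neither variant column `%s` nor rsid column `%s` present",
                column_map[["variant_id"]], column_map[["rsid"]])
  }
  for (fld in c("maf", "pval")) {
    if (!(column_map[[fld]] %in% names(raw))) {
      stop_config("mandatory column `%s` (field %s) missing from %s",
                  column_map[[fld]], fld, path)
    }
  }

  pick <- function(fld, parse = identity) {
    col <- column_map[[fld]]
    if (is.na(col) || !(col %in% names(raw))) return(rep(NA, nrow(raw)))
    parse(raw[[col]])
  }
  tbl <- tibble(
    variant_id = if (have_variant) as.character(raw[[column_map[["variant_id"]]]]) else NA_character_,
    rsid  = if (have_rsid) as.character(raw[[column_map[["rsid"]]]]) else NA_character_,
    chrom = as.character(pick("chrom")),
    pos   = suppressWarnings(as.integer(pick("pos"))),
    maf   = suppressWarnings(as.numeric(pick("maf"))),
    beta  = suppressWarnings(as.numeric(pick("beta"))),
    se    = suppressWarnings(as.numeric(pick("se"))),
    pval  = suppressWarnings(as.numeric(pick("pval")))
  )
  # normalize identity: rsid wins when present and non-empty
  tbl$variant_id <- dplyr::if_else(
    !is.na(tbl$rsid) & tbl$rsid != "" & tbl$rsid != ".",
    tbl$rsid, tbl$variant_id
  )
  ok <- !is.na(tbl$variant_id) & !is.na(tbl$maf) & !is.na(tbl$pval) &
    tbl$pval > 0 & tbl$pval <= 1
  n_dropped <- sum(!ok)
  if (n_dropped > 0L) {
    inform(sprintf("read_gwas_table: dropped %d row(s) with unparseable or out-of-range mandatory fields", n_dropped))
  }
  tbl <- tbl[ok, , drop = FALSE]
  n0 <- nrow(tbl)
  tbl <- tbl |>
    arrange(.data$pval) |>
    distinct(.data$variant_id, .keep_all = TRUE) |>
    arrange(.data$variant_id)
  n_dedup <- n0 - nrow(tbl)
  if (n_dedup > 0L) {
    inform(sprintf("read_gwas_table: collapsed %d duplicated variant id(s), keeping smallest p-value", n_dedup))
  }
  attr(tbl, "n_dropped") <- n_dropped
  attr(tbl, "n_dedup") <- n_dedup
  tbl
}

empty_gwas_tbl <- function() {
  tibble(variant_id = character(), rsid = character(), chrom = character(),
         pos = integer(), maf = double(), beta = double(), se = double(),
         pval = double())
}

#' Remove low-confidence variants by minor-allele frequency
#'
#' Drops variants whose minor-allele frequency falls below the threshold.
#' Variants exactly at the threshold are kept (the removal rule is
#' `maf < maf_threshold`). Row order is preserved.
#'
#' @param gwas Tibble of GWAS records with a `maf` column.
#' @param maf_threshold Minimum MAF retained (default 0.001).
#' @return The filtered tibble.
#' @export
filter_low_confidence <- function(gwas, maf_threshold = 0.001) {
  if (!is.numeric(maf_threshold) || length(maf_threshold) != 1L ||
      is.na(maf_threshold) || maf_threshold < 0) {
    stop_config("`maf_threshold` must be a single non-negative number")
  }
  assert_columns(gwas, "maf", "GWAS table")
  if (anyNA(gwas$maf)) stop_validation("`maf` contains missing values")
  gwas[gwas$maf >= maf_threshold, , drop = FALSE]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, aligned to the input order.
#' Thin wrapper over `stats::p.adjust(method = "BH")` with the input-domain
#' checks this pipeline requires (p-values in (0, 1]).
#'
#' @param pvals Numeric vector of raw p-values in (0, 1].
#' @return Numeric vector of adjusted p-values, same length and order.
#' @export
#' @examples
#' adjust_pvalues_bh(c(0.005, 0.009, 0.05, 0.5))
adjust_pvalues_bh <- function(pvals) {
  if (!is.numeric(pvals)) stop_validation("p-values must be numeric")
  if (length(pvals) == 0L) return(numeric(0))
  bad <- which(is.na(pvals) | pvals <= 0 | pvals > 1)
  if (length(bad) > 0L) {
    stop_validation("p-value outside (0, 1] at index %d", bad[1L])
  }
  p.adjust(pvals, method = "BH")
}

#' Add BH-adjusted p-values to a GWAS table
#'
#' @param gwas Tibble of GWAS records with a `pval` column.
#' @return The tibble with an `adj_pval` column appended.
#' @export
add_adjusted_pvalues <- function(gwas) {
  assert_columns(gwas, "pval", "GWAS table")
  gwas$adj_pval <- adjust_pvalues_bh(gwas$pval)
  gwas
}

#' Select significant variants
#'
#' Returns the ids of variants whose BH-adjusted p-value is strictly below
#' `alpha`.
#'
#' @param gwas Tibble of GWAS records with `variant_id` and `adj_pval`
#'   columns (run [add_adjusted_pvalues()] first).
#' @param alpha Significance level on the adjusted scale (default 0.05).
#' @return Sorted character vector of significant variant ids.
#' @export
select_significant <- function(gwas, alpha = 0.05) {
  assert_fraction(alpha, "alpha")
  if (!("adj_pval" %in% names(gwas))) {
    stop_state("`adj_pval` absent: run add_adjusted_pvalues() first")
  }
  sort_ids(gwas$variant_id[gwas$adj_pval < alpha])
}

#' Combine significant-variant calls across a trait's files
#'
#' A trait may be represented by several summary-statistic files (for
#' example different phenotype codes). Each file is MAF-filtered and
#' FDR-adjusted independently (the per-file default) and its significant
#' set extracted; the per-file sets are then combined under the chosen
#' policy. With `pooled_fdr = TRUE` the files are concatenated and adjusted
#' once before selection instead.
#'
#' @param tables List of GWAS tibbles (one per file) or a single tibble.
#' @param alpha Significance level (default 0.05).
#' @param maf_threshold MAF filter threshold (default 0.001).
#' @param policy One of `"union"` (significant in at least one file, the
#'   default), `"intersection"` (in all files), `"single"` (first file
#'   only).
#' @param pooled_fdr Adjust once over the pooled variant list instead of
#'   per file (default `FALSE`).
#' @return Sorted character vector of significant variant ids; attribute
#'   `policy` records the policy applied.
#' @export
combine_trait_files <- function(tables, alpha = 0.05, maf_threshold = 0.001,
                                policy = c("union", "intersection", "single"),
                                pooled_fdr = FALSE) {
  policy <- tryCatch(match.arg(policy),
                     error = function(e) stop_config("unknown combine policy"))
  if (is.data.frame(tables)) tables <- list(tables)
  if (length(tables) == 0L) stop_config("at least one GWAS table required")
  if (policy == "single") tables <- tables[1L]

  prep <- function(tbl) filter_low_confidence(tbl, maf_threshold)
  if (isTRUE(pooled_fdr)) {
    pooled <- bind_rows(lapply(tables, prep))
    ids <- select_significant(add_adjusted_pvalues(pooled), alpha)
  } else {
    sets <- lapply(tables, function(tbl) {
      select_significant(add_adjusted_pvalues(prep(tbl)), alpha)
    })
    ids <- switch(policy,
      union = sort_ids(unlist(sets)),
      intersection = sort_ids(Reduce(intersect, sets)),
      single = sets[[1L]]
    )
  }
  inform(sprintf("combine_trait_files: policy=%s files=%d -> %d significant id(s)",
                 policy, length(tables), length(ids)))
  structure(ids, policy = policy)
}

#' Intersect significant variants of two traits
#'
#' @param ids_a,ids_b Character vectors of variant ids (same id scheme).
#' @return Sorted character vector of ids significant in both traits.
#' @export
intersect_traits <- function(ids_a, ids_b) {
  sort_ids(intersect(as.character(ids_a), as.character(ids_b)))
}
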