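#' Read a taxa-by-sample count table from TSV
#'
#' Expects rows = taxa, columns = samples, with a header row of sample ids
#' and the taxon label in the first column.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble with a `taxon` character column followed by one integer
#'   column per sample.
#' @export
read_count_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "taxon"
  x$taxon <- as.character(x$taxon)
  if (anyDuplicated(x$taxon)) abort("duplicate taxon labels in count table")
  x
}

#' Read a mothur shared/taxonomy file pair and aggregate OTUs to genus
#'
#' Uses phyloseq's mothur importer; OTU counts are summed within the genus
#' (last rank of the constaxonomy file).
#'
#' @param shared_path Path to a mothur `.shared` file (label/Group/numOtus).
#' @param taxonomy_path Path to the matching `.cons.taxonomy` file.
#' @return A tibble in the shape of [read_count_table()]: `taxon` column
#'   (genus) plus one column per sample.
#' @export
read_mothur_counts <- function(shared_path, taxonomy_path) {
  if (!requireNamespace("phyloseq", quietly = TRUE)) {
    abort("phyloseq is required to read mothur files")
  }
  ps <- phyloseq::import_mothur(mothur_shared_file = shared_path,
                                mothur_constaxonomy_file = taxonomy_path)
  otu <- as(phyloseq::otu_table(ps), "matrix") # taxa x samples
  tax <- as(phyloseq::tax_table(ps), "matrix")
  genus <- tax[, ncol(tax)]
  agg <- rowsum(otu, group = genus[rownames(otu)])
  tibble::as_tibble(agg, rownames = "taxon")
}

#' Read per-sample metadata
#'
#' @param path TSV with one row per sample and columns `sample_id`,
#'   `weight_g`, `age_d`, `sex`, `compartment`, `bsf_pct`, `replicate`.
#' @return A tibble with those columns; `sex`, `compartment`, `bsf_pct` and
#'   `replicate` are kept as character/numeric as read.
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample_id", "weight_g", "age_d", "sex", "compartment",
                "bsf_pct", "replicate")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    abort(paste0("metadata is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(meta$sample_id)) abort("duplicate sample ids in metadata")
  meta
}

#' Build an abundance table of relative abundances
#'
#' Relative abundance of a genus in a sample is its count divided by the
#' sample's total count.
#'
#' @param counts A tibble as returned by [read_count_table()] (taxa rows,
#'   `taxon` column first), or a taxa-by-sample integer matrix with row and
#'   column names.
#' @param metadata Optional per-sample metadata tibble
#'   (see [read_sample_metadata()]); matched to samples by `sample_id`.
#' @return An `abundance_table`: list with `samples`, `taxa`,
#'   `counts`/`rel_abund` (samples x taxa matrices), `sample_totals`
#'   and `metadata`.
#' @export
compute_relative_abundances <- function(counts, metadata = NULL) {
  if (is.data.frame(counts)) {
    taxa <- as.character(counts[[1]])
    m <- as.matrix(counts[, -1, drop = FALSE])
    rownames(m) <- taxa
  } else {
    m <- as.matrix(counts)
    taxa <- rownames(m)
  }
  if (is.null(taxa) || anyDuplicated(taxa)) abort("taxa labels must be present and unique")
  samples <- colnames(m)
  if (is.null(samples) || anyDuplicated(samples)) abort("sample ids must be present and unique")
  if (any(m < 0)) abort("counts must be non-negative")
  cnt <- t(m) # samples x taxa
  totals <- rowSums(cnt)
  if (any(totals == 0)) {
    abort(paste0("sample(s) with zero total count: ",
                 paste(samples[totals == 0], collapse = ", ")))
  }
  ra <- cnt / totals
  if (!is.null(metadata)) {
    metadata <- as_tibble(metadata)
    if (!all(samples %in% metadata$sample_id)) {
      abort("metadata does not cover all samples")
    }
    metadata <- metadata[match(samples, metadata$sample_id), ]
  }
  structure(
    list(samples = samples, taxa = taxa, counts = cnt, rel_abund = ra,
         sample_totals = totals, metadata = metadata),
    class = "abundance_table"
  )
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("<abundance_table> ", length(x$samples), " samples x ", length(x$taxa),
      " taxa\n", sep = "")
  if (!is.null(x$metadata)) cat("  with metadata: ",
                                paste(names(x$metadata), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @describeIn compute_relative_abundances Long tibble (sample, taxon, count,
#'   rel_abund) view of an abundance table.
#' @param x An `abundance_table`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.abundance_table <- function(x, ...) {
  tibble(
    sample = rep(x$samples, times = length(x$taxa)),
    taxon = rep(x$taxa, each = length(x$samples)),
    count = as.vector(x$counts),
    rel_abund = as.vector(x$rel_abund)
  )
}

#' Drop taxa that never rise above a relative-abundance threshold
#'
#' A taxon is kept iff, within at least one group of samples (by default the
#' replicate), some sample's relative abundance strictly exceeds the
#' threshold.  Remaining relative abundances are deliberately not
#' renormalized, so downstream log values are unchanged by filtering.
#'
#' @param table An `abundance_table`.
#' @param threshold Fraction; default `1e-4` (i.e. 0.01%). Strictly-greater
#'   comparison, ties are dropped.
#' @param group_key Metadata column defining the groups (default
#'   `"replicate"`); if metadata is absent all samples form one group.
#' @return The filtered `abundance_table`, with a `filter_report` attribute:
#'   a tibble of per-taxon max relative abundance per group and the kept flag.
#' @export
filter_low_abundance <- function(table, threshold = 1e-4, group_key = "replicate") {
  stopifnot(inherits(table, "abundance_table"))
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  if (!is.null(table$metadata) && group_key %in% names(table$metadata)) {
    groups <- as.character(table$metadata[[group_key]])
  } else {
    if (!is.null(table$metadata) && !is.null(group_key)) {
      abort(paste0("group_key '", group_key, "' not found in metadata"))
    }
    groups <- rep("all", length(table$samples))
  }
  glev <- sort(unique(groups))
  # per-group max relative abundance for every taxon
  gmax <- vapply(glev, function(g) {
    apply(table$rel_abund[groups == g, , drop = FALSE], 2, max)
  }, numeric(length(table$taxa)))
  gmax <- matrix(gmax, nrow = length(table$taxa),
                 dimnames = list(table$taxa, glev))
  keep <- apply(gmax > threshold, 1, any)
  if (!any(keep)) abort("all taxa removed by the abundance filter")
  report <- as_tibble(gmax, rownames = "taxon")
  names(report)[-1] <- paste0("max_ra_", glev)
  report$kept <- unname(keep)
  out <- table
  out$taxa <- table$taxa[keep]
  out$counts <- table$counts[, keep, drop = FALSE]
  out$rel_abund <- table$rel_abund[, keep, drop = FALSE]
  attr(out, "filter_report") <- report
  out
}

#' @rdname filter_low_abundance
#' @export
filter_report <- function(table) attr(table, "filter_report")

#' Log-transform nonzero relative abundances
#'
#' Zeros cannot be log-transformed; they are marked `NA` and downstream
#' discretization routes them into a dedicated zero category.
#'
#' @param table An `abundance_table`.
#' @param base Logarithm base (> 1), default 10.
#' @return A samples-by-taxa numeric matrix of `log_base`(relative
#'   abundance), `NA` where the abundance is zero.
#' @export
log_transform_nonzero <- function(table, base = 10) {
  stopifnot(inherits(table, "abundance_table"))
  if (base <= 1) abort("log base must be > 1")
  ra <- table$rel_abund
  if (any(ra < 0)) abort("negative relative abundance")
  out <- ifelse(ra > 0, log(ra, base = base), NA_real_)
  dimnames(out) <- list(table$samples, table$taxa)
  out
}
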