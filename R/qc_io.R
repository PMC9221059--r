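# Expression-matrix container, readers/writers for the pipeline's
# plain-text formats, and the quality-control filters applied to the
# proteomic abundance matrix before any analysis.

#' Construct an expression matrix object
#'
#' The root object of the pipeline: a proteins x samples real matrix of
#' log-ratio abundances with `NA` marking missing measurements, plus an
#' optional tumor/healthy group label per sample.
#'
#' @param values numeric matrix, rownames = protein (gene) symbols,
#'   colnames = sample identifiers. Both must be unique.
#' @param group optional character/factor vector of `"tumor"`/`"healthy"`,
#'   either named by sample or in column order.
#' @return an object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, group = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have protein rownames and sample colnames")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicate protein identifiers: ", paste(unique(dup), collapse = ", "))
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup))
    stop("duplicate sample identifiers: ", paste(unique(dup), collapse = ", "))
  if (!is.null(group)) {
    group <- as.character(group)
    if (is.null(names(group))) {
      if (length(group) != ncol(values))
        stop("'group' must have one entry per sample")
      names(group) <- colnames(values)
    }
    if (!all(colnames(values) %in% names(group)))
      stop("'group' is missing labels for some samples")
    group <- group[colnames(values)]
    bad <- setdiff(unique(group), c("tumor", "healthy"))
    if (length(bad))
      stop("unknown group labels: ", paste(bad, collapse = ", "))
  }
  structure(list(values = values, group = group), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d proteins x %d samples, %d missing (%.1f%%)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values)),
              100 * mean(is.na(x$values))))
  if (!is.null(x$group)) {
    tb <- table(x$group)
    cat("  groups:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Sample identifiers belonging to one group
#' @param m an `expr_matrix` with group labels.
#' @param group `"tumor"` or `"healthy"`.
#' @return character vector of sample ids.
#' @export
samples_in_group <- function(m, group) {
  if (is.null(m$group)) stop("expression matrix has no group labels")
  names(m$group)[m$group == group]
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of protein
#' symbols; empty cells and `NA` tokens are treated as missing. Protein
#' symbols are upper-cased so joins with annotation tables are
#' case-insensitive.
#'
#' @param path TSV file.
#' @param metadata optional sample metadata (from [read_sample_metadata()])
#'   used to attach tumor/healthy labels.
#' @return an `expr_matrix`.
#' @export
read_expression_matrix <- function(path, metadata = NULL) {
  raw <- read.delim(path, header = TRUE, colClasses = "character",
                    check.names = FALSE, na.strings = c("", "NA"))
  if (ncol(raw) < 2) stop("expected a protein column plus sample columns")
  proteins <- toupper(raw[[1]])
  dup <- unique(proteins[duplicated(proteins)])
  if (length(dup))
    stop("duplicate protein identifiers in ", path, ": ",
         paste(dup, collapse = ", "))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at row %d ('%s'), column '%s'",
                 bad[1, 1], proteins[bad[1, 1]], colnames(vals)[bad[1, 2]]))
  rownames(num) <- proteins
  colnames(num) <- colnames(vals)
  group <- NULL
  if (!is.null(metadata)) {
    group <- setNames(metadata$group, metadata$sample_id)
    group <- group[colnames(num)]
    names(group) <- colnames(num)
  }
  expression_matrix(num, group)
}

#' Write an expression matrix to TSV
#'
#' Finite values are printed with 17 significant digits so that
#' `read_expression_matrix(write_expression_matrix(m))` round-trips
#' bit-exactly; missing entries are written as `NA`.
#'
#' @param m an `expr_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  vals <- m$values
  txt <- array("NA", dim = dim(vals))
  ok <- !is.na(vals)
  txt[ok] <- sprintf("%.17g", vals[ok])
  out <- cbind(pGene = rownames(vals), as.data.frame(txt))
  colnames(out) <- c("pGene", colnames(vals))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' TSV with columns `sample_id`, `group` (`tumor`/`healthy`) and `flagged`
#' (logical; e.g. samples showing protein decay that must be excluded).
#'
#' @param path TSV file.
#' @return data.frame with those three columns.
#' @export
read_sample_metadata <- function(path) {
  md <- read.delim(path, header = TRUE, check.names = FALSE,
                   colClasses = "character")
  need <- c("sample_id", "group", "flagged")
  miss <- setdiff(need, colnames(md))
  if (length(miss))
    stop("metadata is missing columns: ", paste(miss, collapse = ", "))
  md$flagged <- as.logical(md$flagged)
  md[need]
}

#' Drop proteins with too many missing values
#'
#' Removes every protein whose number of missing entries exceeds
#' `max_missing` samples (the abundance-matrix curation rule; the default
#' of 60 matches a ~111-sample study). Alternatively a fraction of the
#' sample count can be given for matrices of other widths.
#'
#' @param m an `expr_matrix`.
#' @param max_missing maximum allowed missing sample count per protein.
#' @param max_missing_frac if non-`NULL`, overrides `max_missing` with
#'   `floor(frac * n_samples)`.
#' @return filtered `expr_matrix`, protein order preserved.
#' @export
filter_pgenes_by_missingness <- function(m, max_missing = 60,
                                         max_missing_frac = NULL) {
  if (!is.null(max_missing_frac)) {
    stop_if_not_fraction(max_missing_frac, "max_missing_frac")
    max_missing <- floor(max_missing_frac * ncol(m$values))
  }
  stop_if_not_count(max_missing, "max_missing", min = 0)
  n_miss <- rowSums(is.na(m$values))
  keep <- n_miss <= max_missing
  if (!any(keep)) warning("all proteins removed by missingness filter")
  expression_matrix(m$values[keep, , drop = FALSE], m$group)
}

#' Remove quality-flagged samples
#'
#' @param m an `expr_matrix`.
#' @param flagged character vector of sample ids to drop (e.g. samples
#'   with significant protein decay identified from study metadata).
#' @return `expr_matrix` with those samples removed.
#' @export
drop_flagged_samples <- function(m, flagged) {
  flagged <- unique(as.character(flagged))
  unknown <- setdiff(flagged, colnames(m$values))
  if (length(unknown))
    stop("unknown sample identifiers: ", paste(unknown, collapse = ", "))
  keep <- setdiff(colnames(m$values), flagged)
  expression_matrix(m$values[, keep, drop = FALSE],
                    if (is.null(m$group)) NULL else m$group[keep])
}

#' Keep only proteins fully measured in one sample group
#'
#' Used to guarantee that contrasts against the (small) healthy group are
#' computed from complete data: proteins with any missing value in the
#' given group are removed.
#'
#' @param m an `expr_matrix` with group labels.
#' @param group `"tumor"` or `"healthy"`.
#' @return filtered `expr_matrix`.
#' @export
require_complete_in_group <- function(m, group = "healthy") {
  ids <- samples_in_group(m, group)
  if (length(ids) == 0) stop("no samples in group '", group, "'")
  keep <- rowSums(is.na(m$values[, ids, drop = FALSE])) == 0
  expression_matrix(m$values[keep, , drop = FALSE], m$group)
}

#' Impute remaining missing values by per-protein medians
#'
#' After filtering, remaining gaps are filled with the median of each
#' protein's observed values. Rank-based mutual information downstream is
#' insensitive to this monotone-neutral choice; observed values are never
#' altered.
#'
#' @param m an `expr_matrix` in which every protein has at least one
#'   observed value.
#' @return complete `expr_matrix`.
#' @export
impute_missing <- function(m) {
  vals <- m$values
  all_na <- rowSums(!is.na(vals)) == 0
  if (any(all_na))
    stop("proteins with no observed values (filter first): ",
         paste(rownames(vals)[all_na], collapse = ", "))
  for (i in which(rowSums(is.na(vals)) > 0)) {
    med <- median(vals[i, ], na.rm = TRUE)
    vals[i, is.na(vals[i, ])] <- med
  }
  expression_matrix(vals, m$group)
}

#' Read a gene-to-chromosome map
#'
#' Two-column TSV (gene symbol, chromosome label such as `1`-`22`, `X`,
#' `Y`, `MT`), as exported from BioMart. Gene symbols are upper-cased; if
#' a gene appears with conflicting chromosomes the first entry is kept and
#' a warning issued.
#'
#' @param path TSV file (header optional; detected by a non-numeric,
#'   non-chromosome second field named `chromosome`).
#' @return named character vector: `chromosome[gene]`.
#' @export
read_chromosome_map <- function(path) {
  tab <- read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(tab) < 2) stop("chromosome map needs two columns")
  if (tolower(tab[1, 2]) %in% c("chromosome", "chrom", "chr"))
    tab <- tab[-1, , drop = FALSE]
  genes <- toupper(tab[[1]])
  chroms <- sub("^chr", "", tab[[2]])
  dup <- duplicated(genes)
  if (any(dup)) {
    conflict <- unique(genes[dup][chroms[dup] !=
                                    chroms[match(genes[dup], genes)]])
    if (length(conflict))
      warning("conflicting chromosome for: ",
              paste(conflict, collapse = ", "), "; keeping first entry")
  }
  setNames(chroms[!dup], genes[!dup])
}

#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#' Members are upper-cased and de-duplicated.
#'
#' @param path GMT file.
#' @return named list of character vectors of member genes.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("malformed GMT line %d: fewer than 3 fields", i))
    nm[i] <- f[1]
    sets[[i]] <- unique(toupper(f[-(1:2)]))
  }
  setNames(sets, nm)
}

#' Write a gene-set collection to GMT
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional character vector of descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("NA", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
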