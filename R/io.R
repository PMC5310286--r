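# File formats: TSV z-score matrices, TSV paired expression tables
# (<pair>_case / <pair>_control header convention), GMT gene-set
# collections, and the TSV + JSON-sidecar result pair.

#' Read a z-score matrix from TSV
#'
#' First column: gene identifier; remaining columns: one numeric z-score
#' column per dataset.  Duplicate gene identifiers, missing values and
#' non-numeric entries are rejected with diagnostics.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return Numeric m x K matrix with gene rownames and dataset colnames.
#' @export
read_zscore_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  if (ncol(df) < 2) stop("expected a gene-ID column plus at least one dataset column")
  ids <- trimws(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop(sprintf("duplicate gene IDs: %s", paste(utils::head(dup, 5), collapse = ", ")))
  z <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(z) <- "double")
  bad <- which(!is.finite(z), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric or missing z-score at row %d (gene %s), column '%s'",
                 bad[1, 1], ids[bad[1, 1]], colnames(z)[bad[1, 2]]))
  rownames(z) <- ids
  z
}

#' Write a z-score matrix to TSV
#'
#' @param z Numeric matrix with gene rownames.
#' @param path Output path.
#' @param id_col Name of the gene-ID column.
#' @return `path`, invisibly.
#' @export
write_zscore_tsv <- function(z, path, id_col = "gene") {
  df <- data.frame(rownames(z), z, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a paired expression dataset from TSV
#'
#' First column: gene identifier.  Remaining column names must follow the
#' `<pair>_case` / `<pair>_control` convention, with exactly one case and
#' one control column per pair.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param scale Expression scale, see [paired_dataset()].
#' @return A [paired_dataset()].
#' @export
read_paired_expression_tsv <- function(path, scale = c("ratio", "log")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, quote = "", comment.char = "")
  ids <- trimws(as.character(df[[1]]))
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  cn <- colnames(vals)
  is_case <- grepl("_case$", cn)
  is_ctrl <- grepl("_control$", cn)
  if (!all(is_case | is_ctrl))
    stop("every expression column must end in _case or _control")
  pairs_case <- sub("_case$", "", cn[is_case])
  pairs_ctrl <- sub("_control$", "", cn[is_ctrl])
  if (anyDuplicated(pairs_case) || anyDuplicated(pairs_ctrl) ||
      !setequal(pairs_case, pairs_ctrl))
    stop("each pair needs exactly one _case and one _control column")
  pair_ids <- pairs_case
  paired_dataset(
    values = vals, gene_ids = ids, pair_ids = pair_ids,
    case_cols = match(paste0(pair_ids, "_case"), cn),
    control_cols = match(paste0(pair_ids, "_control"), cn),
    scale = scale
  )
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of gene identifiers.
#' @param source Free-text provenance string.
#' @param case_sensitive Match gene identifiers case-sensitively when
#'   scoring (stored as metadata).
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, source = NA_character_,
                                case_sensitive = TRUE) {
  stopifnot(is.list(sets), length(sets) >= 1)
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("set names must be present and unique")
  sets <- lapply(sets, function(g) unique(trimws(as.character(g))))
  if (any(vapply(sets, length, integer(1)) < 1))
    stop("every set must contain at least one gene")
  structure(list(sets = sets, source = source,
                 case_sensitive = case_sensitive),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- vapply(x$sets, length, integer(1))
  cat(sprintf("Gene-set collection: %d sets (sizes %d..%d)%s\n",
              length(x$sets), min(sizes), max(sizes),
              if (is.na(x$source)) "" else sprintf(" [%s]", x$source)))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then member genes.  Duplicate genes within a line are
#' deduplicated with a warning; duplicate set names or lines with fewer
#' than three fields are errors.  CRLF and LF line endings parse
#' identically.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    fields <- fields[nzchar(fields) | seq_along(fields) <= 2]
    if (length(fields) < 3)
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    nm <- fields[1]
    if (nm %in% names(sets))
      stop(sprintf("duplicate set name '%s' at line %d", nm, i))
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("duplicate genes within set '%s' were deduplicated", nm))
      genes <- unique(genes)
    }
    sets[[nm]] <- genes
    desc[nm] <- fields[2]
  }
  coll <- gene_set_collection(sets, source = path)
  coll$descriptions <- desc
  coll
}

#' Write enrichment results as TSV plus JSON sidecar
#'
#' The TSV holds the per-set table ordered by decreasing DES; the sidecar
#' records theta, lambda, the scoring method and any seeds, so every result
#' file carries its provenance.
#'
#' @param result A `discordance_result` from [score_collection()].
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @param extra Named list merged into the sidecar (e.g. seeds, input
#'   paths).
#' @return Character vector of the two paths, invisibly.
#' @export
write_results <- function(result, prefix, extra = list()) {
  stopifnot(inherits(result, "discordance_result"))
  tsv <- paste0(prefix, ".tsv")
  json <- paste0(prefix, ".json")
  utils::write.table(result$table, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sidecar <- c(list(
    theta = result$theta, lambda = result$lambda,
    n_sets_scored = nrow(result$table),
    skipped_sets = result$skipped_sets,
    fdr = result$fdr,
    version = as.character(utils::packageVersion("discoset"))
  ), extra)
  jsonlite::write_json(sidecar, json, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(tsv, json))
}
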