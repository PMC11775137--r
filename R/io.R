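#' @name paleorange-io
#' @title Readers and writers for occurrence, lake and trait tables
#'
#' @description
#' The pipeline consumes three plain-text tables:
#' \describe{
#'   \item{occurrence table}{long-format rows of
#'     (`lake_id`, `slice_index`, `taxon_id`, `family`, `reads`): the read
#'     count of one taxon in one lake and one 1000-year time-slice.}
#'   \item{lake registry}{(`lake_id`, `lon`, `lat`) in decimal degrees; the
#'     single source of geometry.}
#'   \item{trait table}{(`key`, `group`) mapping a taxon id or a family name
#'     to a growth-form group, one of `"cushion"`, `"tree"`, `"other"`.}
#' }
#' Files are CSV or TSV (delimiter inferred from the extension: `.tsv`/`.txt`
#' use tabs), UTF-8, with a header row.
NULL

TRAIT_GROUPS <- c("cushion", "tree", "other")

delim_for <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

read_delim_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = delim_for(path),
                    stringsAsFactors = FALSE, quote = "\"",
                    fileEncoding = "UTF-8", check.names = FALSE)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("schema error in '", path, "': missing column(s) ",
         paste0("'", missing, "'", collapse = ", "), call. = FALSE)
  }
}

#' Read and validate a long-format occurrence table
#'
#' Loads a CSV/TSV of per-lake, per-slice, per-taxon read counts, applies the
#' table invariants (integer non-negative reads, zero-read rows dropped,
#' duplicate (lake, slice, taxon) rows summed with a warning, all lakes known
#' to the registry if one is supplied) and attaches a load report.
#'
#' @param path Path to the CSV/TSV file.
#' @param columns Named character vector mapping the canonical column names
#'   (`lake_id`, `slice_index`, `taxon_id`, `family`, `reads`) to the names
#'   used in the file.
#' @param registry Optional lake registry (see [read_lake_registry()]); if
#'   supplied, every `lake_id` must be present in it.
#' @return A `data.frame` with canonical columns and an attribute
#'   `"load_report"` (rows read, zero-read rows dropped, duplicates merged).
#' @export
read_occurrence_table <- function(path,
                                  columns = c(lake_id = "lake_id",
                                              slice_index = "slice_index",
                                              taxon_id = "taxon_id",
                                              family = "family",
                                              reads = "reads"),
                                  registry = NULL) {
  canonical <- c("lake_id", "slice_index", "taxon_id", "family", "reads")
  stopifnot(all(canonical %in% names(columns)))
  raw <- read_delim_file(path)
  require_columns(raw, unname(columns[canonical]), path)
  df <- data.frame(
    lake_id = as.character(raw[[columns[["lake_id"]]]]),
    slice_index = raw[[columns[["slice_index"]]]],
    taxon_id = as.character(raw[[columns[["taxon_id"]]]]),
    family = as.character(raw[[columns[["family"]]]]),
    reads = raw[[columns[["reads"]]]],
    stringsAsFactors = FALSE
  )
  n_read <- nrow(df)

  reads_num <- suppressWarnings(as.numeric(df$reads))
  bad <- which(!is.finite(reads_num) | reads_num != round(reads_num))
  if (length(bad)) {
    stop("parse error in '", path, "': non-integer reads value '",
         df$reads[bad[1]], "' at data row ", bad[1], call. = FALSE)
  }
  if (any(reads_num < 0)) {
    stop("parse error in '", path, "': negative reads at data row ",
         which(reads_num < 0)[1], call. = FALSE)
  }
  sl <- suppressWarnings(as.numeric(df$slice_index))
  if (any(!is.finite(sl) | sl != round(sl) | sl < 1)) {
    stop("parse error in '", path, "': slice_index must be a positive integer",
         call. = FALSE)
  }
  df$slice_index <- as.integer(sl)
  df$reads <- as.integer(reads_num)

  validated <- validate_occurrence_table(df, registry = registry)
  rep0 <- attr(validated, "load_report")
  rep0$rows_read <- n_read
  attr(validated, "load_report") <- rep0
  validated
}

#' Validate (and canonicalise) an occurrence table already in memory
#'
#' Drops zero-read rows, sums duplicate (lake, slice, taxon) rows with a
#' warning, and checks lakes against a registry. Idempotent: re-validating a
#' validated table returns it unchanged.
#'
#' @param df Data frame with columns `lake_id`, `slice_index`, `taxon_id`,
#'   `family`, `reads`.
#' @inheritParams read_occurrence_table
#' @return The validated data frame with a `"load_report"` attribute.
#' @export
validate_occurrence_table <- function(df, registry = NULL) {
  stopifnot(is.data.frame(df))
  require_columns(df, c("lake_id", "slice_index", "taxon_id", "family", "reads"),
                  "occurrence table")
  if (any(df$reads < 0)) stop("occurrence table: reads must be >= 0", call. = FALSE)
  n_zero <- sum(df$reads == 0)
  df <- df[df$reads > 0, , drop = FALSE]

  key <- paste(df$lake_id, df$slice_index, df$taxon_id, sep = "\r")
  n_dup <- nrow(df) - length(unique(key))
  if (n_dup > 0) {
    warning("occurrence table: ", n_dup,
            " duplicate (lake, slice, taxon) row(s) merged by summing reads",
            call. = FALSE)
    agg <- rowsum(df$reads, group = key, reorder = FALSE)
    first <- !duplicated(key)
    df <- df[first, , drop = FALSE]
    df$reads <- as.integer(agg[match(key[first], rownames(agg)), 1])
  }
  if (!is.null(registry)) {
    unknown <- setdiff(unique(df$lake_id), registry$lake_id)
    if (length(unknown)) {
      stop("occurrence table: lake(s) not in registry: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  rownames(df) <- NULL
  attr(df, "load_report") <- list(rows_read = nrow(df) + n_zero,
                                  zero_read_dropped = n_zero,
                                  duplicates_merged = n_dup)
  df
}

#' Write an occurrence table as CSV/TSV
#'
#' @param df Occurrence table data frame.
#' @param path Output path; delimiter inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_occurrence_table <- function(df, path) {
  utils::write.table(df[, c("lake_id", "slice_index", "taxon_id", "family", "reads")],
                     path, sep = delim_for(path), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a lake registry
#'
#' @param path CSV/TSV with columns `lake_id`, `lon`, `lat`.
#' @return A `data.frame` (lake_id, lon, lat), lake ids unique, coordinates
#'   finite, longitude in \[-180, 180\] and latitude in \[-90, 90\].
#' @export
read_lake_registry <- function(path) {
  raw <- read_delim_file(path)
  require_columns(raw, c("lake_id", "lon", "lat"), path)
  reg <- data.frame(lake_id = as.character(raw$lake_id),
                    lon = as.numeric(raw$lon),
                    lat = as.numeric(raw$lat),
                    stringsAsFactors = FALSE)
  validate_lake_registry(reg)
}

#' @rdname read_lake_registry
#' @param reg In-memory registry data frame to validate.
#' @export
validate_lake_registry <- function(reg) {
  require_columns(reg, c("lake_id", "lon", "lat"), "lake registry")
  dup <- unique(reg$lake_id[duplicated(reg$lake_id)])
  if (length(dup)) {
    stop("lake registry: duplicated lake_id: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(reg$lon)) || any(!is.finite(reg$lat))) {
    stop("lake registry: coordinates must be finite", call. = FALSE)
  }
  if (any(reg$lon < -180 | reg$lon > 180)) {
    stop("lake registry: longitude out of range [-180, 180]", call. = FALSE)
  }
  if (any(reg$lat < -90 | reg$lat > 90)) {
    stop("lake registry: latitude out of range [-90, 90]", call. = FALSE)
  }
  rownames(reg) <- NULL
  reg
}

#' Read and validate a growth-form trait table
#'
#' Maps taxon ids or family names to the growth-form groups used by the
#' interaction analysis. Allowed groups: `"cushion"`, `"tree"`, `"other"`.
#'
#' @param path CSV/TSV with columns `key`, `group`.
#' @return A `data.frame` (key, group) with unique keys.
#' @export
read_trait_table <- function(path) {
  raw <- read_delim_file(path)
  require_columns(raw, c("key", "group"), path)
  tr <- data.frame(key = as.character(raw$key),
                   group = as.character(raw$group),
                   stringsAsFactors = FALSE)
  validate_trait_table(tr)
}

#' @rdname read_trait_table
#' @param tr In-memory trait data frame to validate.
#' @export
validate_trait_table <- function(tr) {
  require_columns(tr, c("key", "group"), "trait table")
  bad <- setdiff(unique(tr$group), TRAIT_GROUPS)
  if (length(bad)) {
    stop("trait table: unknown group label(s) ",
         paste0("'", bad, "'", collapse = ", "),
         "; allowed: ", paste(TRAIT_GROUPS, collapse = ", "), call. = FALSE)
  }
  dup <- unique(tr$key[duplicated(tr$key)])
  if (length(dup)) {
    stop("trait table: duplicated key(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  rownames(tr) <- NULL
  tr
}

# Resolve the growth-form group of each taxon: taxon_id match wins over
# family match; anything unresolved falls back to "other".
resolve_groups <- function(taxon_id, family, traits) {
  if (is.null(traits)) {
    g <- rep("other", length(taxon_id))
    attr(g, "n_unmatched") <- length(taxon_id)
    return(g)
  }
  g <- traits$group[match(taxon_id, traits$key)]
  byfam <- traits$group[match(family, traits$key)]
  g[is.na(g)] <- byfam[is.na(g)]
  n_un <- sum(is.na(g))
  g[is.na(g)] <- "other"
  attr(g, "n_unmatched") <- n_un
  g
}
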