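#' Write / read a mixture design as CSV
#'
#' Columns: `run_id`, `role`, `replicate_of`, then one proportion column per
#' taxon. Proportions are written with 17 significant digits so the
#' write/read round trip is bit-exact.
#'
#' @param design a `mixture_design`.
#' @param path output CSV path.
#' @return `read_design` returns the validated `mixture_design`.
#' @export
write_design <- function(design, path) {
  out <- as.data.frame(design)
  for (tx in design_taxa(design))
    out[[tx]] <- sprintf("%.17g", out[[tx]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("run_id", "role", "replicate_of")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("design file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$replicate_of <- as.integer(df$replicate_of)
  class(df) <- c("mixture_design", "data.frame")
  validate_design(df)
  df
}

#' Write / read a count table as TSV
#'
#' Samples as rows (first column `sample_id`), taxa as columns, integer
#' counts. The round trip is exact and preserves column order. Samples with
#' zero total counts pass reading but are flagged with a warning.
#'
#' @param counts integer matrix (samples x taxa) with rownames.
#' @param path output TSV path.
#' @return `read_counts` returns the integer count matrix.
#' @export
write_counts <- function(counts, path) {
  counts <- as.matrix(counts)
  df <- data.frame(sample_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("count file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  if (names(df)[1] != "sample_id")
    stop("count table must have 'sample_id' as its first column (found '",
         names(df)[1], "')", call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || any(is.na(m)) || any(m < 0) || any(m != round(m)))
    stop("counts must be nonnegative integers", call. = FALSE)
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(df$sample_id)
  if (any(rowSums(m) == 0))
    warning("sample(s) with zero total counts: ",
            paste(rownames(m)[rowSums(m) == 0], collapse = ", "), call. = FALSE)
  m
}

#' Read a flat key-value run configuration
#'
#' One `key = value` per line; `#` starts a comment. Unknown keys are errors
#' (fail fast on typos). Values are parsed as numbers when possible.
#'
#' @param path config file path.
#' @return Named list merged over the defaults of [default_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- default_config()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop("malformed config line: '", ln, "'", call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(cfg))
      stop("unknown config key: '", key, "'", call. = FALSE)
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num else val
  }
  cfg
}

#' Default run configuration
#'
#' @return Named list of all recognized configuration keys and defaults.
#' @export
default_config <- function() {
  list(
    taxa = system.file("extdata", "vaginal_taxa.csv", package = "mockbias"),
    scenario = "default",
    seed = 1,
    depth = 16000,
    noise_cv = 0.03,
    n_lack_of_fit = 2,
    n_replicates = 15,
    alpha = 0.05,
    n_boot = 2000,
    boot_level = 0.95,
    ntree = 500,
    mtry = 2,
    factor_orientation = "obs_over_actual",
    n_clinical = 50,
    out_dir = "mockbias_out"
  )
}
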