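#' Read a taxon metadata table
#'
#' The table has one row per taxon with its 16S rRNA gene copy number, genome
#' size in megabases and Gram status. Copy number inflates amplicon read
#' counts proportionally (it is divided out when cells are mixed); genome
#' size determines how many 16S templates a given mass of genomic DNA
#' carries (counts from DNA mixtures are multiplied by genome size and
#' divided by copy number).
#'
#' A fixture for the seven-taxon vaginal panel ships with the package:
#' `system.file("extdata", "vaginal_taxa.csv", package = "mockbias")`.
#'
#' @param path CSV with columns `name`, `copy_number`, `genome_size`, `gram`.
#' @return Data frame of validated taxon metadata.
#' @export
read_taxa <- function(path) {
  if (!file.exists(path)) stop("taxa file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_taxa(df)
}

#' Validate taxon metadata
#' @param df data frame with columns `name`, `copy_number`, `genome_size`, `gram`.
#' @return The validated data frame; errors on schema violations.
#' @export
validate_taxa <- function(df) {
  need <- c("name", "copy_number", "genome_size", "gram")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("taxa table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0) stop("taxa table is empty", call. = FALSE)
  if (anyDuplicated(df$name)) stop("duplicate taxon names", call. = FALSE)
  if (any(is.na(df$copy_number)) || any(df$copy_number < 1) ||
      any(df$copy_number != round(df$copy_number)))
    stop("copy_number must be an integer >= 1", call. = FALSE)
  if (any(is.na(df$genome_size)) || any(df$genome_size <= 0))
    stop("genome_size must be positive (megabases)", call. = FALSE)
  df$copy_number <- as.integer(df$copy_number)
  df
}

## metadata vectors aligned to a taxon name ordering
.taxa_lookup <- function(taxa, names_needed) {
  idx <- match(names_needed, taxa$name)
  if (anyNA(idx))
    stop("no metadata for taxon/taxa: ",
         paste(names_needed[is.na(idx)], collapse = ", "), call. = FALSE)
  taxa[idx, , drop = FALSE]
}
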