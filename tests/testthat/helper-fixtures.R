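# shared fixtures: all built in code, nothing read from disk except the
# shipped taxon panel

vag_taxa <- function() {
  read_taxa(system.file("extdata", "vaginal_taxa.csv", package = "mockbias"))
}

# metadata with no copy-number / genome-size distortion
uniform_taxa <- function(p, names = paste0("t", seq_len(p))) {
  data.frame(name = names, copy_number = 1L, genome_size = 1,
             gram = "+", stringsAsFactors = FALSE)
}

# wrap a plain proportion matrix as a mixture_design of support runs
design_from_matrix <- function(m, taxa = colnames(m)) {
  if (is.null(taxa)) taxa <- paste0("t", seq_len(ncol(m)))
  d <- data.frame(run_id = seq_len(nrow(m)), role = "support",
                  replicate_of = NA_integer_, stringsAsFactors = FALSE)
  pm <- as.data.frame(m)
  names(pm) <- taxa
  rownames(pm) <- NULL
  d <- cbind(d, pm)
  class(d) <- c("mixture_design", "data.frame")
  validate_design(d)
}

# p=3 candidate set enlarged with the three axial points (2/3, 1/6, 1/6):
# gives a 10-point pool for brute-force D-optimality checks
enlarged_candidates_p3 <- function() {
  ax <- matrix(1 / 6, 3, 3)
  diag(ax) <- 2 / 3
  rbind(candidate_set(3), ax)
}

logdet_information <- function(points) {
  X <- scheffe_matrix(points, check = FALSE)
  d <- determinant(crossprod(X), logarithm = TRUE)
  if (d$sign <= 0) -Inf else as.numeric(d$modulus)
}
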