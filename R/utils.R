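## RNG hygiene: functions taking an explicit seed must not clobber the
## caller's random stream
.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

## normalize rows of a nonnegative matrix to sum 1; errors on all-zero rows
.row_normalize <- function(m, what = "sample") {
  s <- rowSums(m)
  bad <- which(s <= 0)
  if (length(bad))
    stop(sprintf("%s(s) %s have zero total; proportions undefined",
                 what, paste(rownames(m)[bad], collapse = ", ")), call. = FALSE)
  sweep(m, 1, s, "/")
}
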