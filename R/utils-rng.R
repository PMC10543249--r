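# Scoped seeding: set.seed for the duration of the calling function only,
# restoring the ambient RNG stream on exit.
saveRNG <- function() get0(".Random.seed", globalenv(), inherits = FALSE)
restoreRNG <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
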