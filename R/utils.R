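# Run code under a temporary RNG seed, restoring the caller's stream.
# seed = NULL draws from the current stream without reseeding.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_invalid <- function(...) {
  stop(structure(class = c("chimic_invalid_input", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
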