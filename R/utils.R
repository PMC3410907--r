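`%||%` <- function(a, b) if (is.null(a)) b else a

## Column index lookup by variant id, with a clear error on misses.
.idIndex <- function(x, ids) {
  all <- variantIds(x)
  idx <- match(ids, all)
  if (anyNA(idx))
    stop("unknown variant id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  idx
}

## Seeded evaluation that never leaks RNG state into the caller.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}
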