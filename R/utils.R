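# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Solve M s = v for a symmetric PSD M, tolerating rank deficiency
# (collinear predictors) via an SVD pseudo-inverse fallback.
psd_solve <- function(M, v) {
  out <- tryCatch(drop(chol2inv(chol(M)) %*% v), error = function(e) NULL)
  if (!is.null(out)) return(out)
  sv <- svd(M)
  pos <- sv$d > max(sv$d[1L], 0) * 1e-12
  drop(sv$v[, pos, drop = FALSE] %*%
         ((crossprod(sv$u[, pos, drop = FALSE], v)) / sv$d[pos]))
}
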