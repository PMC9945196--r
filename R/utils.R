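#' @import methods
#' @importFrom stats lm coef fitted resid quantile rnorm runif sd t.test pt
#'   var cor prcomp
NULL

# Run an expression with a temporary RNG seed, restoring global RNG state.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Shift a 3D array by integer offsets, padding with `fill`.
.shift3d <- function(a, dx, dy, dz, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  lo <- pmax(1, 1 + c(dx, dy, dz))
  hi <- pmin(d, d + c(dx, dy, dz))
  if (any(hi < lo)) return(out)
  sx <- lo[1]:hi[1]; sy <- lo[2]:hi[2]; sz <- lo[3]:hi[3]
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
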