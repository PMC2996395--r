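#' @importFrom stats cor cutree dist hclust loess median optim phyper pt
#'   qnorm quantile rnorm runif sd setNames t.test var cmdscale predict
#'   complete.cases p.adjust
#' @importFrom utils head
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_mrs <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_mrs(msg)
}

# Run expr with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards (so library code never disturbs user RNG).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# interquartile range with linear-interpolation (type 7) quantiles
iqr7 <- function(x) {
  q <- quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE, type = 7)
  q[2] - q[1]
}

row_iqr <- function(mat) apply(mat, 1L, iqr7)
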