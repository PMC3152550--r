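# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
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

# Derive a reproducible sub-seed (< 2^31) from a top-level seed and an index.
# Keeps every intermediate below 2^53 so the arithmetic is exact in doubles.
derive_seed <- function(seed, index) {
  s <- as.double(seed) %% 100003
  as.integer((s * 10007 + as.double(index) * 101 + 1) %% 2147483629)
}

assert_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_min && x <= min) {
    abort(sprintf("`%s` must be > %s.", name, format(min)))
  }
  if (!strict_min && x < min) {
    abort(sprintf("`%s` must be >= %s.", name, format(min)))
  }
  invisible(x)
}

# Population (divide by n) or sample (divide by n - 1) standard deviation.
sd_by_type <- function(x, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  n <- length(x)
  if (n == 0L) return(NA_real_)
  if (sd_type == "sample") return(stats::sd(x))
  sqrt(sum((x - mean(x))^2) / n)
}

is_matrix_image <- function(x) is.matrix(x) && is.numeric(x)

assert_image <- function(x, name = "image") {
  if (!is_matrix_image(x)) {
    abort(sprintf("`%s` must be a numeric matrix (2-D grayscale image).", name))
  }
  invisible(x)
}

# Strip EBImage's Image class back to a plain matrix.
ebi_mat <- function(x) {
  m <- EBImage::imageData(x)
  dim(m) <- dim(m)[1:2]
  as.matrix(m)
}
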