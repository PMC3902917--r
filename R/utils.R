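# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validate a scalar numeric argument; name is used in the error message.
check_num <- function(x, name, lower = -Inf, upper = Inf,
                      strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop(sprintf("'%s' = %g is outside its valid range %s%g, %g%s", name, x,
                 if (strict_lower) "(" else "[", lower, upper,
                 if (strict_upper) ")" else "]"), call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < lower)
    stop(sprintf("'%s' must be an integer >= %d", name, lower), call. = FALSE)
  invisible(as.integer(x))
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    check_num(seed, "seed")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

# Fold a free path into [lo, hi] by specular reflection. Applying the folding
# map to the unreflected cumulative path is exact for a reflecting interval
# (repeated fold-back, vectorised via the mod-2-width identity).
reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  if (!is.finite(w) || w <= 0) stop("reflection interval must have positive width")
  y <- (x - lo) %% (2 * w)
  y <- ifelse(y > w, 2 * w - y, y)
  lo + y
}

# 3x3 mean filter with edge replication (used by the spot localizer).
mean_filter3 <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- img[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  acc <- matrix(0, nr, nc)
  for (dr in 0:2) for (dc in 0:2)
    acc <- acc + pad[dr + seq_len(nr), dc + seq_len(nc)]
  acc / 9
}

# Validate nucleoid intervals given in relative [0,1] long-axis coordinates:
# each 0 <= start < end <= 1, pairwise disjoint.
check_nucleoid_intervals <- function(iv) {
  if (is.null(iv) || length(iv) == 0L) return(matrix(numeric(0), ncol = 2))
  if (is.list(iv)) iv <- do.call(rbind, lapply(iv, as.numeric))
  iv <- matrix(as.numeric(iv), ncol = 2)
  if (any(!is.finite(iv)) || any(iv < 0) || any(iv > 1) || any(iv[, 1] >= iv[, 2]))
    stop("nucleoid intervals must satisfy 0 <= start < end <= 1", call. = FALSE)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  if (nrow(iv) > 1L && any(iv[-1L, 1] < iv[-nrow(iv), 2]))
    stop("nucleoid intervals must be disjoint", call. = FALSE)
  iv
}
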