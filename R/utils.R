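#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

.trim_lower <- function(x) tolower(trimws(x))

# Row-wise Welch (unequal variance) two-sample t. x, y: matrices with the
# same rows, samples in columns. Returns t = mean(x) - mean(y) scaled,
# Welch-Satterthwaite df, and the two-sided p.
.row_welch_t <- function(x, y, var_floor = NULL) {
  n1 <- ncol(x)
  n2 <- ncol(y)
  if (n1 < 2L || n2 < 2L) {
    stop("Welch t-test needs at least 2 samples per group (got ",
         n1, " and ", n2, ")")
  }
  m1 <- rowMeans(x)
  m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1L)
  v2 <- rowSums((y - m2)^2) / (n2 - 1L)
  if (!is.null(var_floor)) {
    zero <- v1 + v2 == 0
    if (any(zero)) {
      v1[zero & v1 == 0] <- var_floor
      v2[zero & v2 == 0] <- var_floor
    }
  }
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  # both variances zero and no floor: define t = 0 (no evidence either way)
  deg <- !is.finite(t)
  t[deg] <- 0
  df[deg] <- n1 + n2 - 2L
  p <- 2 * stats::pt(abs(t), df = df, lower.tail = FALSE)
  list(t = t, df = df, p = p)
}

.assert_scalar_count <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < 0)
    stop("'", name, "' must be a single non-negative integer")
  as.integer(x)
}
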