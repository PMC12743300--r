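## Shared internal helpers: argument checking, seed substreams, summaries.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pt <- function(fmt, ..., class = "phycotherm_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_pt("`%s` must be a single finite number", name,
            class = "invalid_parameter")
  if (x < lower || (strict_lower && x <= lower) || x > upper)
    stop_pt("`%s` = %g is outside its valid range", name, x,
            class = "invalid_parameter")
  invisible(x)
}

#' Derive a reproducible substream seed from a master seed
#'
#' All stochastic operations take an explicit integer seed. When one master
#' seed drives several independent random streams (e.g. the pipeline's
#' simulate stages), each stream gets a deterministic substream seed so that
#' adding a stream never perturbs the others.
#'
#' @param seed master integer seed.
#' @param stream stream label (character) or index (integer).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @examples
#' derive_stream_seed(1, "thermal")
#' @export
derive_stream_seed <- function(seed, stream) {
  check_number(seed, "seed")
  if (is.character(stream)) {
    stream <- sum(as.integer(charToRaw(stream)) *
                    (seq_along(charToRaw(stream)) %% 31L + 1L))
  }
  as.integer((abs(seed) * 48271 + stream * 16807 + 12345) %% (2^31 - 1))
}

## mean and standard error over replicates
mean_se <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  c(mean = mean(x),
    se = if (n > 1L) stats::sd(x) / sqrt(n) else NA_real_,
    n = n)
}

## pooled-variance two-sided Student's t (the paper's "Student's t-test")
pooled_t_test <- function(x, y) {
  na <- length(x); nb <- length(y)
  if (na < 2L || nb < 2L)
    stop_pt("pooled t-test needs >= 2 values per group",
            class = "insufficient_data")
  df <- na + nb - 2L
  sp2 <- ((na - 1) * stats::var(x) + (nb - 1) * stats::var(y)) / df
  diff <- mean(x) - mean(y)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tstat <- if (diff == 0) 0 else if (se == 0) sign(diff) * Inf else diff / se
  p <- if (is.infinite(tstat)) 0 else 2 * stats::pt(-abs(tstat), df)
  list(t = tstat, df = df, p = p,
       mean_x = mean(x), se_x = stats::sd(x) / sqrt(na),
       mean_y = mean(y), se_y = stats::sd(y) / sqrt(nb))
}
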