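# Minimal exact non-negative integer arithmetic (base 1e4, little-endian
# digit vectors). Theoretical library diversities (e.g. 150*69*17^15) exceed
# the 2^53 exact-double range, and only products/sums of modest operands are
# needed, so schoolbook routines suffice.

big_from_num <- function(x) {
  stopifnot(length(x) == 1, x >= 0, x == floor(x), x < 2^53)
  d <- integer(0)
  repeat {
    d <- c(d, x %% 1e4)
    x <- x %/% 1e4
    if (x == 0) break
  }
  structure(as.numeric(d), class = "bigint")
}

big_trim <- function(d) {
  while (length(d) > 1 && d[length(d)] == 0) d <- d[-length(d)]
  structure(d, class = "bigint")
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(unclass(a), rep(0, n - length(a)))
  b <- c(unclass(b), rep(0, n - length(b)))
  s <- a + b
  carry <- 0
  for (i in seq_len(n)) {
    s[i] <- s[i] + carry
    carry <- s[i] %/% 1e4
    s[i] <- s[i] %% 1e4
  }
  if (carry > 0) s <- c(s, carry)
  big_trim(s)
}

big_mul <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  res <- numeric(length(a) + length(b))
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    res[i:(i + length(b) - 1)] <- res[i:(i + length(b) - 1)] + a[i] * b
    # normalize eagerly to stay far below 2^53
    carry <- 0
    for (k in seq_along(res)) {
      res[k] <- res[k] + carry
      carry <- res[k] %/% 1e4
      res[k] <- res[k] %% 1e4
    }
    stopifnot(carry == 0)
  }
  big_trim(res)
}

big_pow <- function(base, exp) {
  stopifnot(exp >= 0, exp == floor(exp))
  out <- big_from_num(1)
  b <- big_from_num(base)
  for (i in seq_len(exp)) out <- big_mul(out, b)
  out
}

#' @export
format.bigint <- function(x, ...) {
  d <- rev(unclass(x))
  paste0(d[1], paste(sprintf("%04d", d[-1]), collapse = ""))
}

#' @export
print.bigint <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

big_as_num <- function(x) sum(unclass(x) * 1e4^(seq_along(x) - 1))

#' @export
as.double.bigint <- function(x, ...) big_as_num(x)

# -1 / 0 / +1 comparison
big_cmp <- function(a, b) {
  a <- unclass(big_trim(unclass(a))); b <- unclass(big_trim(unclass(b)))
  if (length(a) != length(b)) return(sign(length(a) - length(b)))
  for (i in rev(seq_along(a))) {
    if (a[i] != b[i]) return(sign(a[i] - b[i]))
  }
  0
}
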