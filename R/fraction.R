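#' Exact fractions
#'
#' A vctrs record class for exact rational numbers. Segregation
#' probabilities in this package are carried as `frac` vectors so that
#' invariants (distributions summing to one, oracle equivalence) can be
#' asserted as exact equalities, and so that expected counts feeding the
#' chi-square statistic are never pre-rounded. Numerators and denominators
#' are stored as doubles; all values arising here are ratios of small
#' integers, far below the 2^53 exact-integer limit.
#'
#' @param num integer-valued numerators.
#' @param den integer-valued denominators (non-zero); recycled against
#'   `num`. Sign is normalised onto the numerator.
#' @return A `frac` vector.
#' @examples
#' frac(1, 6) + frac(5, 6) * frac(4, 6)
#' as.numeric(frac(13, 24))
#' sum(frac(c(1, 4, 1), 6)) == frac(1)
#' @export
frac <- function(num, den = 1) {
  num <- vctrs::vec_cast(num, double(), x_arg = "num")
  den <- vctrs::vec_cast(den, double(), x_arg = "den")
  if (any(num != trunc(num)) || any(den != trunc(den))) {
    rlang::abort("`num` and `den` must be integer-valued.")
  }
  if (any(den == 0)) {
    rlang::abort("Zero denominator in `frac()`.")
  }
  args <- vctrs::vec_recycle_common(num = num, den = den)
  new_frac(args$num, args$den)
}

# constructor: reduces to lowest terms, denominator kept positive
new_frac <- function(num, den) {
  s <- sign(den)
  num <- num * s
  den <- den * s
  g <- gcd_vec(abs(num), den)
  g[g == 0] <- 1
  vctrs::new_rcrd(list(num = num / g, den = den / g), class = "tetraseg_frac")
}

gcd_vec <- function(a, b) {
  while (any(b != 0)) {
    r <- ifelse(b == 0, 0, a %% b)
    a <- ifelse(b == 0, a, b)
    b <- r
  }
  a
}

#' Coerce a numeric vector to exact fractions
#'
#' Recovers the simplest rational `p/q` with `q <= max_den` within
#' `.Machine$double.eps^0.5` of each value, by continued-fraction
#' expansion. Decimal inputs such as `0.1` convert exactly; an input with
#' no such representation is an error rather than a silent approximation.
#'
#' @param x a numeric vector, or already a `frac` vector (returned as is).
#' @param max_den largest denominator searched.
#' @param strict if `TRUE` (default), error when no rational within
#'   `max_den` reproduces `x`; if `FALSE`, return the best convergent —
#'   used where callers feed arbitrary doubles (e.g. root-finding
#'   iterates) and a nearest small rational is acceptable.
#' @return A `frac` vector equal to `x`.
#' @examples
#' as_frac(0.1)    # 1/10
#' as_frac(1 / 6)  # 1/6
#' @export
as_frac <- function(x, max_den = 1e6, strict = TRUE) {
  if (is_frac(x)) {
    return(x)
  }
  x <- vctrs::vec_cast(x, double(), x_arg = "x")
  out <- purrr::map(x, rationalise1, max_den = max_den, strict = strict)
  new_frac(purrr::map_dbl(out, 1), purrr::map_dbl(out, 2))
}

rationalise1 <- function(x, max_den, strict = TRUE) {
  if (!is.finite(x)) rlang::abort("Cannot convert non-finite value to `frac`.")
  # continued-fraction convergents p/q, stopping at max_den
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0
  r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0
    q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < .Machine$double.eps^0.5) break
    if (abs(r - a) < .Machine$double.eps) break
    r <- 1 / (r - a)
  }
  if (strict && abs(p1 / q1 - x) >= .Machine$double.eps^0.5) {
    rlang::abort(sprintf("No exact rational with denominator <= %g for %g.", max_den, x))
  }
  c(p1, q1)
}

#' Test for the fraction class
#' @param x an object.
#' @return `TRUE` if `x` is a `frac` vector.
#' @export
is_frac <- function(x) inherits(x, "tetraseg_frac")

frac_num <- function(x) vctrs::field(x, "num")
frac_den <- function(x) vctrs::field(x, "den")

#' @export
format.tetraseg_frac <- function(x, ...) {
  n <- frac_num(x)
  d <- frac_den(x)
  ifelse(d == 1, format(n, trim = TRUE, scientific = FALSE),
         paste0(format(n, trim = TRUE, scientific = FALSE), "/",
                format(d, trim = TRUE, scientific = FALSE)))
}

#' @export
vec_ptype_abbr.tetraseg_frac <- function(x, ...) "frac"

#' @export
as.double.tetraseg_frac <- function(x, ...) frac_num(x) / frac_den(x)

#' @export
vec_ptype2.tetraseg_frac.tetraseg_frac <- function(x, y, ...) new_frac(double(), double())

#' @export
vec_ptype2.tetraseg_frac.double <- function(x, y, ...) double()

#' @export
vec_ptype2.double.tetraseg_frac <- function(x, y, ...) double()

#' @export
vec_cast.tetraseg_frac.tetraseg_frac <- function(x, to, ...) x

#' @export
vec_cast.double.tetraseg_frac <- function(x, to, ...) as.double(x)

#' @export
vec_cast.tetraseg_frac.double <- function(x, to, ...) as_frac(x)

#' @export
vec_proxy_compare.tetraseg_frac <- function(x, ...) frac_num(x) / frac_den(x)

#' @export
#' @method vec_arith tetraseg_frac
vec_arith.tetraseg_frac <- function(op, x, y, ...) {
  UseMethod("vec_arith.tetraseg_frac", y)
}

#' @export
#' @method vec_arith.tetraseg_frac default
vec_arith.tetraseg_frac.default <- function(op, x, y, ...) {
  vctrs::stop_incompatible_op(op, x, y)
}

#' @export
#' @method vec_arith.tetraseg_frac tetraseg_frac
vec_arith.tetraseg_frac.tetraseg_frac <- function(op, x, y, ...) {
  args <- vctrs::vec_recycle_common(x = x, y = y)
  xn <- frac_num(args$x); xd <- frac_den(args$x)
  yn <- frac_num(args$y); yd <- frac_den(args$y)
  switch(op,
    "+" = new_frac(xn * yd + yn * xd, xd * yd),
    "-" = new_frac(xn * yd - yn * xd, xd * yd),
    "*" = new_frac(xn * yn, xd * yd),
    "/" = {
      if (any(yn == 0)) rlang::abort("Division by zero `frac`.")
      new_frac(xn * yd, xd * yn)
    },
    vctrs::stop_incompatible_op(op, x, y)
  )
}

#' @export
#' @method vec_arith.tetraseg_frac numeric
vec_arith.tetraseg_frac.numeric <- function(op, x, y, ...) {
  vec_arith.tetraseg_frac.tetraseg_frac(op, x, as_frac(y), ...)
}

#' @export
#' @method vec_arith.numeric tetraseg_frac
vec_arith.numeric.tetraseg_frac <- function(op, x, y, ...) {
  vec_arith.tetraseg_frac.tetraseg_frac(op, as_frac(x), y, ...)
}

#' @export
#' @method vec_arith.tetraseg_frac MISSING
vec_arith.tetraseg_frac.MISSING <- function(op, x, y, ...) {
  switch(op,
    "-" = new_frac(-frac_num(x), frac_den(x)),
    "+" = x,
    vctrs::stop_incompatible_op(op, x, y)
  )
}

#' @export
vec_math.tetraseg_frac <- function(.fn, .x, ...) {
  switch(.fn,
    sum = {
      out <- frac(0)
      for (i in seq_along(.x)) out <- out + .x[[i]]
      out
    },
    abs = new_frac(abs(frac_num(.x)), frac_den(.x)),
    cumsum = {
      acc <- frac(0)
      res <- vctrs::vec_init(.x, length(.x))
      for (i in seq_along(.x)) {
        acc <- acc + .x[[i]]
        res[[i]] <- acc
      }
      res
    },
    vctrs::vec_math_base(.fn, .x, ...)
  )
}
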