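# Exact rational arithmetic on integer-valued doubles.
#
# Probabilities in built-in models are rationals with modest denominators
# (products of population size, edge weights and mutation-rate denominators).
# Symmetry (Definition-style probability equality) and lumpability are exact
# equality tests, so they are carried out on reduced num/den pairs rather than
# floating point. Values are stored as doubles but kept integral; any
# intermediate exceeding 2^53 aborts rather than silently losing exactness.

.RAT_MAX <- 2^53

rat_check <- function(x) {
  if (any(abs(x) >= .RAT_MAX)) {
    stop("exact rational arithmetic overflow (value >= 2^53); ",
         "reduce the model size or use float mode", call. = FALSE)
  }
  x
}

rat_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b != 0)) {
    t <- b
    b <- ifelse(b != 0, a %% b, 0)
    a <- t
  }
  a
}

# Reduce num/den pairs to canonical form: gcd 1, den > 0, 0 stored as 0/1.
rat_reduce <- function(num, den) {
  if (any(den == 0)) stop("rational with zero denominator", call. = FALSE)
  s <- ifelse(den < 0, -1, 1)
  num <- num * s; den <- den * s
  g <- rat_gcd(num, den)
  g[g == 0] <- 1
  list(num = num / g, den = den / g)
}

rat_add <- function(n1, d1, n2, d2) {
  g <- rat_gcd(d1, d2)
  d1g <- d1 / g
  num <- rat_check(n1 * (d2 / g) + n2 * d1g)
  den <- rat_check(d1g * d2)
  rat_reduce(num, den)
}

rat_mul <- function(n1, d1, n2, d2) {
  g1 <- rat_gcd(n1, d2); g1[g1 == 0] <- 1
  g2 <- rat_gcd(n2, d1); g2[g2 == 0] <- 1
  rat_reduce(rat_check((n1 / g1) * (n2 / g2)),
             rat_check((d1 / g2) * (d2 / g1)))
}

rat_div <- function(n1, d1, n2, d2) {
  if (any(n2 == 0)) stop("rational division by zero", call. = FALSE)
  rat_mul(n1, d1, d2, n2)
}

# Sum a vector of rationals (num, den parallel vectors).
rat_sum <- function(num, den) {
  acc_n <- 0; acc_d <- 1
  for (i in seq_along(num)) {
    r <- rat_add(acc_n, acc_d, num[i], den[i])
    acc_n <- r$num; acc_d <- r$den
  }
  list(num = acc_n, den = acc_d)
}

# Exact integer power of a rational.
rat_pow <- function(num, den, k) {
  rn <- 1; rd <- 1
  for (i in seq_len(k)) {
    r <- rat_mul(rn, rd, num, den)
    rn <- r$num; rd <- r$den
  }
  list(num = rn, den = rd)
}

rat_eq <- function(n1, d1, n2, d2) {
  # exact cross-multiplied comparison; safe for reduced or unreduced input
  rat_check(n1 * d2) == rat_check(n2 * d1)
}

#' Convert a numeric value to an exact rational
#'
#' Uses continued-fraction expansion to find the simplest fraction reproducing
#' the double exactly (e.g. `0.1` becomes 1/10). Used by the model
#' constructors to carry user-supplied parameters such as mutation rates and
#' fitness in exact arithmetic.
#'
#' @param x numeric scalar.
#' @param max_den largest denominator to consider before giving up.
#' @return list with components `num` and `den` (integers stored as doubles).
#' @keywords internal
as_rational <- function(x, max_den = 1e9) {
  stopifnot(is.numeric(x), length(x) == 1, is.finite(x))
  if (x == round(x)) return(list(num = x, den = 1))
  # continued fractions
  sign <- if (x < 0) -1 else 1
  z <- abs(x)
  h1 <- 1; h0 <- 0; k1 <- 0; k0 <- 1
  b <- z
  repeat {
    a <- floor(b)
    h <- a * h1 + h0; k <- a * k1 + k0
    if (k > max_den) return(NULL)
    if (h / k == z) return(rat_reduce(sign * h, k))
    h0 <- h1; h1 <- h; k0 <- k1; k1 <- k
    b <- 1 / (b - a)
  }
}

# Parse "3/16", "1/3" or a bare number into a rational.
parse_rational <- function(s) {
  if (is.numeric(s)) {
    r <- as_rational(s)
    if (is.null(r)) stop("value ", s, " is not representable as an exact rational")
    return(r)
  }
  s <- trimws(as.character(s))
  if (grepl("/", s, fixed = TRUE)) {
    parts <- strsplit(s, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("malformed rational string: ", s)
    rat_reduce(as.numeric(parts[1]), as.numeric(parts[2]))
  } else {
    parse_rational(as.numeric(s))
  }
}

rat_format <- function(num, den) {
  ifelse(den == 1, format(num, scientific = FALSE),
         paste0(format(num, scientific = FALSE), "/",
                format(den, scientific = FALSE)))
}
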