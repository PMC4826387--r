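#' Exact rational numbers
#'
#' A minimal exact-arithmetic scalar/vector type used by the closed-form
#' traveling-wave constructor. All closed forms of the wave construction are
#' field arithmetic on the model parameters, so carrying them as reduced
#' integer fractions gives exact breakpoints and periods (e.g. a period of
#' exactly 14/15 rather than 0.9333...).
#'
#' Numerators and denominators are stored as doubles holding integer values;
#' this is exact as long as intermediates stay below 2^53, far beyond what
#' the closed forms here produce.
#'
#' @param num integer-valued numerator(s).
#' @param den integer-valued denominator(s), non-zero.
#' @return An object of class `rational`.
#' @examples
#' rational(3, 10) + rational(1, 2) * rational(2, 5)
#' min(rational(3, 10), rational(2, 15))
#' @export
rational <- function(num, den = 1) {
  if (any(den == 0)) stop("rational: zero denominator")
  if (any(num != round(num)) || any(den != round(den)))
    stop("rational: numerator and denominator must be integer-valued")
  n <- length(num)
  if (length(den) != n) {
    m <- max(n, length(den))
    num <- rep_len(num, m); den <- rep_len(den, m)
  }
  sgn <- ifelse(den < 0, -1, 1)
  num <- num * sgn; den <- den * sgn
  g <- mapply(.gcd2, abs(num), den)
  g[g == 0] <- 1
  structure(list(num = num / g, den = den / g), class = "rational")
}

.gcd2 <- function(a, b) {
  while (b > 0) { r <- a %% b; a <- b; b <- r }
  a
}

#' Test for the rational class
#' @param x object.
#' @return `TRUE` if `x` is a `rational`.
#' @export
is_rational <- function(x) inherits(x, "rational")

.as_rat <- function(x) {
  if (is_rational(x)) return(x)
  if (is.numeric(x) && all(x == round(x))) return(rational(x, 1))
  stop("exact mode: cannot coerce non-integer numeric ", deparse(x),
       " to rational; wrap parameters with rational()")
}

#' @export
as.double.rational <- function(x, ...) x$num / x$den

#' @export
length.rational <- function(x) length(x$num)

#' @export
`[.rational` <- function(x, i) rational(x$num[i], x$den[i])

#' @export
format.rational <- function(x, ...) {
  ifelse(x$den == 1, sprintf("%g", x$num),
         sprintf("%g/%g", x$num, x$den))
}

#' @export
print.rational <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
Ops.rational <- function(e1, e2) {
  if (nargs() == 1L) {
    e1 <- .as_rat(e1)
    return(switch(.Generic,
                  "-" = rational(-e1$num, e1$den),
                  "+" = e1,
                  stop("unary ", .Generic, " not defined for rational")))
  }
  a <- .as_rat(e1); b <- .as_rat(e2)
  switch(.Generic,
         "+" = rational(a$num * b$den + b$num * a$den, a$den * b$den),
         "-" = rational(a$num * b$den - b$num * a$den, a$den * b$den),
         "*" = rational(a$num * b$num, a$den * b$den),
         "/" = {
           if (any(b$num == 0)) stop("rational: division by zero")
           rational(a$num * b$den, a$den * b$num)
         },
         "==" = a$num * b$den == b$num * a$den,
         "!=" = a$num * b$den != b$num * a$den,
         "<"  = a$num * b$den <  b$num * a$den,
         "<=" = a$num * b$den <= b$num * a$den,
         ">"  = a$num * b$den >  b$num * a$den,
         ">=" = a$num * b$den >= b$num * a$den,
         stop(.Generic, " not defined for rational"))
}

#' @export
Summary.rational <- function(..., na.rm = FALSE) {
  args <- lapply(list(...), .as_rat)
  num <- unlist(lapply(args, function(a) a$num))
  den <- unlist(lapply(args, function(a) a$den))
  val <- num / den
  switch(.Generic,
         "min" = rational(num[which.min(val)], den[which.min(val)]),
         "max" = rational(num[which.max(val)], den[which.max(val)]),
         "range" = rational(c(num[which.min(val)], num[which.max(val)]),
                            c(den[which.min(val)], den[which.max(val)])),
         "sum" = Reduce(`+`, lapply(seq_along(num), function(i)
           rational(num[i], den[i])), rational(0)),
         stop(.Generic, " not defined for rational"))
}
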