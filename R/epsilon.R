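# Exact scalar arithmetic over rationals extended with a symbolic
# infinitesimal eps. Values are polynomials sum_k (num_k/den_k) * eps^k with
# integer-valued double numerators/denominators, gcd-reduced after every
# operation. Ordering is lexicographic by ascending power of eps, i.e. the
# eps -> 0+ limit order.

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) { r <- a %% b; a <- b; b <- r }
  a
}

# reduce a single rational; den forced positive; 0 stored as 0/1
.rat_reduce <- function(num, den) {
  if (den == 0) stop("zero denominator in rational")
  if (num == 0) return(c(0, 1))
  if (den < 0) { num <- -num; den <- -den }
  g <- .gcd2(num, den)
  c(num / g, den / g)
}

.rat_add <- function(a, b) .rat_reduce(a[1] * b[2] + b[1] * a[2], a[2] * b[2])
.rat_mul <- function(a, b) .rat_reduce(a[1] * b[1], a[2] * b[2])
.rat_div <- function(a, b) {
  if (b[1] == 0) stop("division by zero rational")
  .rat_reduce(a[1] * b[2], a[2] * b[1])
}

# exact rational from an integer-or-decimal numeric via its printed decimal
# representation (removes float tie ambiguity for inputs like 0.025)
.rat_from_numeric <- function(x) {
  if (!is.finite(x)) stop("non-finite value cannot be made rational")
  if (x == round(x)) return(c(x, 1))
  s <- format(x, digits = 15, scientific = FALSE, trim = TRUE)
  neg <- startsWith(s, "-")
  if (neg) s <- substring(s, 2)
  parts <- strsplit(s, ".", fixed = TRUE)[[1]]
  frac <- if (length(parts) > 1) parts[2] else ""
  den <- 10^nchar(frac)
  num <- as.numeric(parts[1]) * den + if (nchar(frac)) as.numeric(frac) else 0
  .rat_reduce(if (neg) -num else num, den)
}

.new_ev <- function(pow, num, den) {
  structure(list(pow = pow, num = num, den = den), class = "eps_value")
}

# normalize term lists: reduce, merge duplicate powers, drop zeros, sort
.ev_norm <- function(pow, num, den) {
  stopifnot(length(pow) == length(num), length(num) == length(den))
  if (length(pow)) {
    o <- order(pow)
    pow <- pow[o]; num <- num[o]; den <- den[o]
    out_p <- integer(0); out_n <- numeric(0); out_d <- numeric(0)
    i <- 1L
    while (i <= length(pow)) {
      acc <- .rat_reduce(num[i], den[i])
      j <- i + 1L
      while (j <= length(pow) && pow[j] == pow[i]) {
        acc <- .rat_add(acc, c(num[j], den[j]))
        j <- j + 1L
      }
      if (acc[1] != 0) {
        out_p <- c(out_p, as.integer(pow[i]))
        out_n <- c(out_n, acc[1]); out_d <- c(out_d, acc[2])
      }
      i <- j
    }
    return(.new_ev(out_p, out_n, out_d))
  }
  .new_ev(integer(0), numeric(0), numeric(0))
}

#' Construct an exact epsilon-polynomial value
#'
#' An `eps_value` represents an exact scalar of the form
#' \eqn{\sum_k (n_k/d_k)\,\varepsilon^k} with non-negative integer powers of a
#' symbolic infinitesimal \eqn{\varepsilon}. Comparisons order values in the
#' limit \eqn{\varepsilon \to 0^+}: the coefficient at the lowest differing
#' power decides, so e.g. `eps() > 0` but `eps() < 1e-300`... is false --
#' numeric operands are converted to exact rationals first, and any positive
#' rational exceeds every pure-epsilon value.
#'
#' @param pow integer vector of epsilon powers (>= 0).
#' @param num,den parallel numerator/denominator vectors (integer-valued).
#' @return An object of class `eps_value`.
#' @examples
#' ev("1/2") + ev("1/2")          # 1
#' eps() + ev("1-eps")            # 1
#' ev("1/4") + ev("1/4") * ev("1-eps")
#' @seealso [ev()], [eps()], [ev_limit()], [ev_compare()]
#' @export
eps_value <- function(pow = integer(), num = numeric(), den = rep(1, length(num))) {
  if (any(pow < 0)) stop("epsilon powers must be >= 0")
  .ev_norm(pow, num, den)
}

#' The symbolic infinitesimal epsilon
#' @param power integer power (default 1).
#' @return `eps_value` equal to epsilon^power.
#' @export
eps <- function(power = 1L) eps_value(as.integer(power), 1, 1)

#' Coerce to an exact epsilon-polynomial value
#'
#' Numerics are converted through their decimal representation (so `0.025`
#' becomes exactly 1/40); strings are parsed with [parse_weight()];
#' `eps_value`s pass through.
#'
#' @param x numeric scalar, weight string, or `eps_value`.
#' @return An `eps_value`.
#' @export
ev <- function(x) {
  if (inherits(x, "eps_value")) return(x)
  if (is.character(x)) return(parse_weight(x))
  if (is.numeric(x) && length(x) == 1) {
    r <- .rat_from_numeric(x)
    return(eps_value(0L, r[1], r[2]))
  }
  stop("cannot coerce to eps_value: ", paste(class(x), collapse = "/"))
}

#' @export
is_eps_value <- function(x) inherits(x, "eps_value")

.ev_zero <- function() .new_ev(integer(0), numeric(0), numeric(0))

.ev_is_zero <- function(v) length(v$pow) == 0L

.ev_add <- function(a, b) .ev_norm(c(a$pow, b$pow), c(a$num, b$num), c(a$den, b$den))

.ev_neg <- function(a) .new_ev(a$pow, -a$num, a$den)

.ev_sub <- function(a, b) .ev_add(a, .ev_neg(b))

.ev_mul <- function(a, b, K = Inf) {
  if (.ev_is_zero(a) || .ev_is_zero(b)) return(.ev_zero())
  pow <- integer(0); num <- numeric(0); den <- numeric(0)
  for (i in seq_along(a$pow)) {
    for (j in seq_along(b$pow)) {
      p <- a$pow[i] + b$pow[j]
      if (p > K) next
      r <- .rat_mul(c(a$num[i], a$den[i]), c(b$num[j], b$den[j]))
      pow <- c(pow, p); num <- c(num, r[1]); den <- c(den, r[2])
    }
  }
  .ev_norm(pow, num, den)
}

# dense coefficient table (list of c(num, den)) for powers 0..maxp
.ev_dense <- function(v, maxp) {
  out <- rep(list(c(0, 1)), maxp + 1L)
  for (i in seq_along(v$pow)) {
    if (v$pow[i] <= maxp) out[[v$pow[i] + 1L]] <- c(v$num[i], v$den[i])
  }
  out
}

#' Divide two epsilon values, expanding as a series around eps = 0
#'
#' The common lowest power of eps is factored from numerator and denominator;
#' the ratio is then expanded as a power series in eps and truncated at power
#' `K`. Errors if the denominator is exactly zero, or if the ratio would
#' diverge as eps -> 0+ (numerator of strictly lower order than denominator).
#'
#' @param num,den `eps_value` (or coercible) operands.
#' @param K truncation order of the resulting series.
#' @return An `eps_value`.
#' @export
ev_div_limit <- function(num, den, K = 8L) {
  a <- ev(num); b <- ev(den)
  if (.ev_is_zero(b)) stop("division by exact zero (degenerate transition update)")
  if (.ev_is_zero(a)) return(.ev_zero())
  q <- min(b$pow)
  if (min(a$pow) < q) stop("ratio diverges as eps -> 0+ (numerator of lower epsilon order)")
  a <- .new_ev(a$pow - q, a$num, a$den)
  b <- .new_ev(b$pow - q, b$num, b$den)
  ad <- .ev_dense(a, K); bd <- .ev_dense(b, K)
  d0 <- bd[[1]]
  # series inversion: q_k = (a_k - sum_{i=1..k} b_i q_{k-i}) / b_0
  qs <- vector("list", K + 1L)
  for (k in 0:K) {
    acc <- ad[[k + 1L]]
    if (k > 0) {
      for (i in 1:k) {
        acc <- .rat_add(acc, .rat_mul(c(-1, 1), .rat_mul(bd[[i + 1L]], qs[[k - i + 1L]])))
      }
    }
    qs[[k + 1L]] <- .rat_div(acc, d0)
  }
  .ev_norm(0:K, vapply(qs, `[`, 0, 1L), vapply(qs, `[`, 0, 2L))
}

#' Compare two epsilon values in the eps -> 0+ order
#'
#' @param a,b values coercible by [ev()].
#' @return -1, 0 or 1 as the sign of `a - b`: the lowest-power nonzero
#'   coefficient of the difference decides.
#' @export
ev_compare <- function(a, b) {
  d <- .ev_sub(ev(a), ev(b))
  if (.ev_is_zero(d)) return(0L)
  as.integer(sign(d$num[which.min(d$pow)]))
}

#' Limit of an epsilon value as eps -> 0+
#' @param v an `eps_value` (or coercible).
#' @return The coefficient at power 0, as a double.
#' @export
ev_limit <- function(v) {
  v <- ev(v)
  i <- match(0L, v$pow)
  if (is.na(i)) 0 else v$num[i] / v$den[i]
}

# limit as exact rational c(num, den)
.ev_limit_rat <- function(v) {
  i <- match(0L, v$pow)
  if (is.na(i)) c(0, 1) else c(v$num[i], v$den[i])
}

#' Evaluate an epsilon value at a concrete numeric epsilon
#' @param v an `eps_value` (or coercible).
#' @param eps_num numeric value substituted for eps (e.g. `1e-8`).
#' @return A double.
#' @export
ev_eval <- function(v, eps_num) {
  v <- ev(v)
  if (.ev_is_zero(v)) return(0)
  sum(v$num / v$den * eps_num^v$pow)
}

#' @export
Ops.eps_value <- function(e1, e2) {
  if (missing(e2)) {
    if (.Generic == "-") return(.ev_neg(ev(e1)))
    if (.Generic == "+") return(ev(e1))
    stop("unary ", .Generic, " not defined for eps_value")
  }
  a <- ev(e1); b <- ev(e2)
  switch(.Generic,
    "+" = .ev_add(a, b),
    "-" = .ev_sub(a, b),
    "*" = .ev_mul(a, b),
    "/" = {
      if (!.ev_is_zero(b) && any(b$pow > 0)) {
        stop("use ev_div_limit() to divide by a value carrying eps terms")
      }
      if (.ev_is_zero(b)) stop("division by zero")
      r <- .rat_div(c(1, 1), c(b$num[1], b$den[1]))
      .ev_mul(a, eps_value(0L, r[1], r[2]))
    },
    "^" = {
      k <- ev_limit(b)
      if (!.ev_is_zero(.ev_sub(b, ev(k))) || k != round(k) || k < 0) {
        stop("^ only defined for non-negative integer exponents")
      }
      out <- ev(1)
      if (k > 0) for (i in seq_len(k)) out <- .ev_mul(out, a)
      out
    },
    "==" = ev_compare(a, b) == 0L,
    "!=" = ev_compare(a, b) != 0L,
    "<"  = ev_compare(a, b) < 0L,
    "<=" = ev_compare(a, b) <= 0L,
    ">"  = ev_compare(a, b) > 0L,
    ">=" = ev_compare(a, b) >= 0L,
    stop(.Generic, " not defined for eps_value")
  )
}

.rat_string <- function(num, den) {
  if (den == 1) format(num, scientific = FALSE) else paste0(format(num, scientific = FALSE), "/", format(den, scientific = FALSE))
}

#' Render an epsilon value as a parseable weight string
#'
#' The output round-trips exactly through [parse_weight()].
#' @param v an `eps_value` (or coercible).
#' @return A string like `"1/2 - 1/4*eps + eps^2"`.
#' @export
ev_to_string <- function(v) {
  v <- ev(v)
  if (.ev_is_zero(v)) return("0")
  terms <- character(length(v$pow))
  for (i in seq_along(v$pow)) {
    coef <- .rat_string(abs(v$num[i]), v$den[i])
    base <- if (v$pow[i] == 0L) coef
      else {
        e <- if (v$pow[i] == 1L) "eps" else paste0("eps^", v$pow[i])
        if (coef == "1") e else paste0(coef, "*", e)
      }
    terms[i] <- base
  }
  out <- terms[1]
  if (v$num[1] < 0) out <- paste0("-", out)
  if (length(terms) > 1) {
    for (i in 2:length(terms)) {
      out <- paste0(out, if (v$num[i] < 0) " - " else " + ", terms[i])
    }
  }
  out
}

#' @export
format.eps_value <- function(x, ...) ev_to_string(x)

#' @export
print.eps_value <- function(x, ...) {
  cat("<eps_value> ", ev_to_string(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.numeric.eps_value <- function(x, ...) ev_limit(x)

# ---- weight-string grammar -------------------------------------------------
# expr   := term (('+'|'-') term)*
# term   := factor (('*'|'/') factor)*
# factor := '-' factor | primary ('^' INT)?
# primary:= NUMBER | 'eps' | '(' expr ')'

.tokenize_weight <- function(s) {
  s <- gsub("[[:space:]]+", "", s)
  if (!nzchar(s)) stop("empty weight string")
  toks <- character(0)
  i <- 1L; n <- nchar(s)
  while (i <= n) {
    rest <- substring(s, i)
    m <- regmatches(rest, regexpr("^([0-9]+(\\.[0-9]+)?|eps|[-+*/()^])", rest))
    if (!length(m) || !nzchar(m)) {
      stop("cannot parse weight string near: '", rest, "'")
    }
    toks <- c(toks, m)
    i <- i + nchar(m)
  }
  toks
}

parse_weight_tokens <- function(st) {
  peek <- function() if (st$i <= length(st$toks)) st$toks[st$i] else ""
  take <- function() { t <- peek(); st$i <- st$i + 1L; t }
  primary <- function() {
    t <- take()
    if (t == "(") {
      v <- expr()
      if (take() != ")") stop("unbalanced parentheses in weight string")
      return(v)
    }
    if (t == "eps") return(eps())
    if (grepl("^[0-9]", t)) {
      if (grepl(".", t, fixed = TRUE)) {
        r <- .rat_from_numeric(as.numeric(t))
      } else {
        r <- c(as.numeric(t), 1)
      }
      return(eps_value(0L, r[1], r[2]))
    }
    stop("unexpected token '", t, "' in weight string")
  }
  factor_ <- function() {
    if (peek() == "-") { take(); return(.ev_neg(factor_())) }
    v <- primary()
    if (peek() == "^") {
      take()
      t <- take()
      if (!grepl("^[0-9]+$", t)) stop("exponent must be a non-negative integer")
      v <- v ^ as.numeric(t)
    }
    v
  }
  term <- function() {
    v <- factor_()
    while (peek() %in% c("*", "/")) {
      op <- take()
      rhs <- factor_()
      v <- if (op == "*") v * rhs else v / rhs
    }
    v
  }
  expr <- function() {
    v <- term()
    while (peek() %in% c("+", "-")) {
      op <- take()
      rhs <- term()
      v <- if (op == "+") v + rhs else v - rhs
    }
    v
  }
  out <- expr()
  if (st$i <= length(st$toks)) stop("trailing input in weight string: '", peek(), "'")
  out
}

#' Parse a weight string into an exact epsilon value
#'
#' Grammar: rational literals (`"1/2"`, `"0.025"`, `"3"`), the symbol `eps`,
#' arithmetic with `+ - * / ^` and parentheses, e.g. `"1-eps"`,
#' `"(1-2*eps)"`, `"3/4"`. Division requires a plain rational divisor.
#'
#' @param s a single weight string.
#' @return An `eps_value`.
#' @examples
#' parse_weight("1-2*eps")
#' parse_weight("0.025") == parse_weight("1/40")
#' @export
parse_weight <- function(s) {
  stopifnot(is.character(s), length(s) == 1)
  st <- new.env(parent = emptyenv())
  st$toks <- .tokenize_weight(s)
  st$i <- 1L
  parse_weight_tokens(st)
}
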