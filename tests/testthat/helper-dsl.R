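# Random expression generator emitting both the DSL string and an
# equivalent base-R expression: the independent evaluation route for the
# parser-oracle property tests.
random_expr <- function(depth) {
  vars <- c("a", "b", "c")
  if (depth == 0 || runif(1) < 0.25) {
    if (runif(1) < 0.5) {
      v <- sample(vars, 1)
      return(list(dsl = v, r = v))
    }
    k <- sprintf("%.4f", runif(1, 0.1, 3))
    return(list(dsl = k, r = k))
  }
  pick <- sample(c("add", "sub", "mul", "fun1", "min", "max", "pow"), 1)
  l <- random_expr(depth - 1)
  r <- random_expr(depth - 1)
  switch(pick,
    add = list(dsl = sprintf("(%s + %s)", l$dsl, r$dsl),
               r = sprintf("(%s + %s)", l$r, r$r)),
    sub = list(dsl = sprintf("(%s - %s)", l$dsl, r$dsl),
               r = sprintf("(%s - %s)", l$r, r$r)),
    mul = list(dsl = sprintf("(%s * %s)", l$dsl, r$dsl),
               r = sprintf("(%s * %s)", l$r, r$r)),
    fun1 = {
      fn <- sample(c("sin", "cos", "tanh", "exp"), 1)
      arg <- if (fn == "exp") {
        list(dsl = sprintf("-abs(%s)", l$dsl),
             r = sprintf("-abs(%s)", l$r))
      } else {
        l
      }
      list(dsl = sprintf("%s(%s)", fn, arg$dsl),
           r = sprintf("%s(%s)", fn, arg$r))
    },
    min = list(dsl = sprintf("min(%s, %s)", l$dsl, r$dsl),
               r = sprintf("pmin(%s, %s)", l$r, r$r)),
    max = list(dsl = sprintf("max(%s, %s)", l$dsl, r$dsl),
               r = sprintf("pmax(%s, %s)", l$r, r$r)),
    pow = list(dsl = sprintf("pow(%s, 2)", l$dsl),
               r = sprintf("(%s)^2", l$r))
  )
}
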