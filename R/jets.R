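# Second-order forward-mode differentiation on truncated Taylor "jets".
#
# A jet is c(value, first derivative, second derivative) of a quantity with
# respect to the response level RR~P.  The steady-state elimination only
# uses +, -, * and /, so propagating jets through it yields f(0), f'(0) and
# f''(0) exactly (to machine precision), which is what the curvature-at-zero
# classifier needs.  No step-size choices, no differencing noise.

jet_const <- function(v) c(v, 0, 0)
jet_var <- function(v) c(v, 1, 0)

jet_add <- function(a, b) a + b
jet_sub <- function(a, b) a - b

jet_mul <- function(a, b) {
  c(a[1] * b[1],
    a[1] * b[2] + a[2] * b[1],
    a[1] * b[3] + 2 * a[2] * b[2] + a[3] * b[1])
}

jet_div <- function(a, b) {
  if (b[1] == 0) stop("jet division by zero value")
  v <- a[1] / b[1]
  d1 <- (a[2] - v * b[2]) / b[1]
  d2 <- (a[3] - 2 * d1 * b[2] - v * b[3]) / b[1]
  c(v, d1, d2)
}
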