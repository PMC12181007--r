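# Central finite-difference gradient of scalar_fn at each entry of the
# matrices in `params` (a named list). scalar_fn(params) must return a number.
numeric_grad <- function(scalar_fn, params, h = 1e-5) {
  out <- params
  for (nm in names(params)) {
    g <- params[[nm]] * 0
    for (i in seq_along(g)) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - h
      g[i] <- (scalar_fn(pp) - scalar_fn(pm)) / (2 * h)
    }
    out[[nm]] <- g
  }
  out
}

# Run a forward function returning a scalar node, backprop, return grads.
analytic_grad <- function(forward_fn, params) {
  tape <- ddifuse:::ad_tape()
  nodes <- ddifuse:::ad_params_to_nodes(tape, params)
  loss <- forward_fn(nodes)
  ddifuse:::ad_backward(loss)
  ddifuse:::ad_collect_grads(nodes)
}

expect_grad_match <- function(forward_fn, params, tol = 1e-5) {
  ag <- analytic_grad(forward_fn, params)
  ng <- numeric_grad(function(ps) {
    tape <- ddifuse:::ad_tape()
    nodes <- ddifuse:::ad_params_to_nodes(tape, ps)
    ddifuse:::ad_val(forward_fn(nodes))
  }, params)
  for (nm in names(params)) {
    expect_lt(max(abs(ag[[nm]] - ng[[nm]])), tol)
  }
}
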