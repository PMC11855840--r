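# Finite-difference gradient checking for the autodiff engine.
# f takes a named list of matrices (already wrapped as tracked values when
# a tape is supplied) and returns a scalar node / 1x1 matrix.

ad_run <- function(f, params) {
  tape <- gsfl:::new_tape()
  tracked <- lapply(params, function(p) gsfl:::ad_param(tape, p))
  out <- f(tracked)
  grads <- gsfl:::ad_backward(out)
  list(value = as.numeric(gsfl:::ad_value(out)),
       grads = lapply(tracked, function(tp) {
         g <- grads[[tp$id]]
         if (is.null(g)) matrix(0, nrow(tp$v), ncol(tp$v)) else g
       }))
}

num_grad <- function(f, params, eps = 1e-5) {
  lapply(names(params), function(nm) {
    p <- params[[nm]]
    g <- p * 0
    for (i in seq_along(p)) {
      up <- params; up[[nm]][i] <- p[i] + eps
      dn <- params; dn[[nm]][i] <- p[i] - eps
      g[i] <- (as.numeric(gsfl:::ad_value(f(up))) -
               as.numeric(gsfl:::ad_value(f(dn)))) / (2 * eps)
    }
    g
  }) |> stats::setNames(names(params))
}

expect_gradcheck <- function(f, params, tol = 1e-6) {
  got <- ad_run(f, params)
  want <- num_grad(f, params)
  for (nm in names(params)) {
    expect_lt(max(abs(got$grads[[nm]] - want[[nm]])), tol,
              label = sprintf("max grad error for '%s'", nm))
  }
  invisible(got)
}
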