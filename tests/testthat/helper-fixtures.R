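# Shared fixtures, built in code.  The small grid keeps unit tests fast;
# production-scale objects are built only where a test needs them.

erf <- pracma::erf
erfc <- pracma::erfc

# direct Lagrange basis evaluation: the independent interpolation oracle
lagrangeWeights <- function(x0, nodes) {
  vapply(seq_along(nodes), function(v) {
    prod((x0 - nodes[-v]) / (nodes[v] - nodes[-v]))
  }, numeric(1))
}

# small working grid/propagator shared within test files
smallGrid <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- buildGrid(50.01, nearBase = 15, farBase = 25,
                                    refine = FALSE)
    g
  }
})

smallProp <- local({
  P <- NULL
  function() {
    if (is.null(P)) P <<- assemblePropagator(smallGrid(), 10, 8)
    P
  }
})
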