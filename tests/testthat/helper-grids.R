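# Shared fixtures: parameter grids spanning the figure-caption regimes, and
# the closed-form vs collocation comparison used throughout.

rep_params <- function(variant = "ucm")
  flow_params(alpha = 0.5, reynolds = 10, chi = 0.3, lambda1 = 0.5,
              variant = variant)

# 3x3x3x3 grid covering the figure-caption parameter values
figure_grid <- function() {
  g <- expand.grid(alpha = c(0.1, 0.5, 1), reynolds = c(10, 100, 1e4),
                   chi = c(0.001, 0.3, 0.6), lambda1 = c(0, 0.5, 5))
  lapply(seq_len(nrow(g)), function(i)
    flow_params(g$alpha[i], g$reynolds[i], chi = g$chi[i],
                lambda1 = g$lambda1[i]))
}

# max-norm discrepancy between closed form and collocation oracle, relative
# to the largest field magnitude
oracle_discrepancy <- function(p, ...) {
  fo <- first_order(p)
  sol <- solve_first_order_bvp(p, ...)
  cf <- first_order_fields(fo, sol$y, derivatives = FALSE)
  scl <- max(Mod(sol$U1), Mod(sol$V1), Mod(sol$P1))
  max(Mod(cf$U1 - sol$U1), Mod(cf$V1 - sol$V1), Mod(cf$P1 - sol$P1)) / scl
}
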