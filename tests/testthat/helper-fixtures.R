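# Shared fixtures, memoised so expensive FEM chains run once per session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# standard head phantom at a mid test resolution
test_phantom <- function(edge = 8) {
  memo(paste0("phantom_", edge),
       suppressWarnings(build_layered_sphere(layer_spec(edge_length = edge))))
}

# calibrated thickness-to-field surrogate (about 12 FEM chains)
test_surrogate <- function() {
  memo("surrogate",
       suppressWarnings(calibrate_field_surrogate(
         layers = layer_spec(edge_length = 10))))
}

# five-layer slab with grid-aligned tissue interfaces:
# scalp 7 / skull 6 / CSF 2 / GM 3 / WM 10 mm from the top face down
test_slab <- function() {
  memo("slab5",
       build_slab(40, 40, 28, nx = 8, ny = 8, nz = 28,
                  z_labels = c(white_matter = 10, gray_matter = 13,
                               CSF = 15, skull = 21, scalp = Inf)))
}

# synthetic mediation dataset with known paths:
# m = a*t + 0.1*age/10 + N(0, sd); y = b*m + direct*t + N(0, sd)
make_mediation_data <- function(n = 500, a = 1, b = 0.5, direct = 0.5,
                                noise_sd = 1, seed = 1) {
  set.seed(seed)
  g <- rep(c("control", "psychosis"), length.out = n)
  t01 <- as.integer(g == "psychosis")
  age <- stats::rnorm(n, 40, 10)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  m <- a * t01 + 0.01 * age + stats::rnorm(n, 0, noise_sd)
  y <- b * m + direct * t01 + stats::rnorm(n, 0, noise_sd)
  data.frame(group = factor(g), age = age, sex = sex,
             mediator = m, outcome = y)
}

# exact two-sample Wilcoxon (Mann-Whitney U) by exhaustive enumeration
wilcoxon_enumeration <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  W_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  Ws <- apply(combs, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p <- mean(abs(Ws - n1 * n2 / 2) >= abs(W_obs - n1 * n2 / 2))
  list(W = W_obs, p = p)
}
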