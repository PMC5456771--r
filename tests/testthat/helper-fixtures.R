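# Shared fixtures: reported coefficient sets and curve builders.

# Yeoh and Mooney-Rivlin coefficient sets of the three tracheal tissues
tissue_yeoh <- list(
  cartilage = hyper_params("yeoh", c(3.583, -2.534, 12.020)),
  smooth_muscle = hyper_params("yeoh", c(0.063, 0.394, -0.171)),
  connective = hyper_params("yeoh", c(0.257, 0.483, -0.148))
)
tissue_mr <- list(
  cartilage = hyper_params("mooney_rivlin", c(2.766, 0.770)),
  smooth_muscle = hyper_params("mooney_rivlin", c(1.164, -1.223)),
  connective = hyper_params("mooney_rivlin", c(1.836, -1.775))
)

# noiseless curve from a parameter set on the tissue's standard grid
curve_from_params <- function(params, tissue, lambda_max = NULL, step = 0.01) {
  if (is.null(lambda_max)) lambda_max <- default_lambda_max(tissue)
  grid <- seq(1, lambda_max, by = step)
  stress_stretch_curve(grid, cauchy_stress(params, grid), tissue = tissue)
}

# random but tame parameter draws per model, for property tests
random_params <- function(model) {
  draw_stress <- function(n) stats::runif(n, -1.5, 3)
  draw_exp <- function(n) stats::runif(n, 0.2, 4)
  coeffs <- switch(model,
    neo_hookean = abs(draw_stress(1)) + 0.05,
    mooney_rivlin = draw_stress(2),
    yeoh = draw_stress(3),
    fung = c(abs(draw_stress(1)) + 0.05, draw_exp(1)),
    humphrey = c(abs(draw_stress(1)) + 0.05, draw_exp(1)),
    ogden = as.vector(rbind(draw_stress(3), draw_exp(3))),
    veronda_westmann = c(abs(draw_stress(1)) + 0.05, draw_exp(1)),
    stop("unknown model"))
  hyper_params(model, coeffs)
}
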