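# Small simulation helpers shared across test files.

# a compact probit bank with alternating weak/strong loadings
toy_bank <- function(I = 10, link = "probit", seed = 100) {
  set.seed(seed)
  if (link == "probit") {
    item_bank(loading = rep(c(0.4, 0.8), length.out = I),
              difficulty = runif(I, -1, 1), link = link)
  } else {
    item_bank(loading = rep(c(0.6, 1.4), length.out = I),
              difficulty = runif(I, -1, 1), link = link)
  }
}

# simulate a dataset from a single-cause MIMIC population
toy_data <- function(n = 400, I = 10, gamma = 0.5, link = "probit",
                     seed = 101, bank = NULL) {
  set.seed(seed)
  if (is.null(bank)) bank <- toy_bank(I, link, seed = seed + 1)
  latent <- latent_structure(gamma)
  simulate_mimic_dataset(bank, latent, n)
}

# a bank with one DIF item (single covariate)
dif_bank <- function(I = 8, item = 3, kind = "uniform", coefficient = 1,
                     link = "probit", seed = 102) {
  set.seed(seed)
  loading <- if (link == "probit") rep(c(0.5, 0.7), length.out = I)
             else rep(c(0.8, 1.3), length.out = I)
  dif_int <- matrix(0, I, 1); dif_load <- matrix(0, I, 1)
  if (kind == "uniform") dif_int[item, 1] <- coefficient
  else dif_load[item, 1] <- coefficient
  item_bank(loading = loading, difficulty = runif(I, -1, 1),
            dif_intercept = dif_int, dif_loading = dif_load, link = link)
}

fast_ctrl <- function(q = 21) mimic_control(quadrature = q)
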