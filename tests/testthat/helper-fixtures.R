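# Shared fixtures: tiny networks and generated datasets (all built in
# code; no stored data).

# fast fit options for unit tests
light_opts <- function(...) {
  o <- sapm_fit_opts(n_restarts = 2L, max_iter = 100L, ...)
  o
}

# two regions a -> b with a latent into a
toy2_net <- function(cycle = FALSE) {
  con <- data.frame(source = "a", target = "b")
  if (cycle) con <- rbind(con, data.frame(source = "b", target = "a"))
  network_model(
    regions = data.frame(name = c("region a", "region b"),
                         abbrev = c("a", "b"), n_subregions = 5L),
    connections = con,
    latents = list(list(name = "int1", targets = "a")))
}

# chain a -> b -> c with a latent into a
toy3_net <- function() {
  network_model(
    regions = data.frame(name = paste("region", c("a", "b", "c")),
                         abbrev = c("a", "b", "c"), n_subregions = 5L),
    connections = data.frame(source = c("a", "b"), target = c("b", "c")),
    latents = list(list(name = "int1", targets = "a")))
}

# 4 regions, 8 inter-region edges, 1 latent (scaled type-I-error world)
mini8_net <- function() {
  network_model(
    regions = data.frame(name = paste("region", letters[1:4]),
                         abbrev = letters[1:4], n_subregions = 5L),
    connections = data.frame(
      source = c("a", "a", "b", "b", "c", "c", "d", "d"),
      target = c("b", "c", "c", "d", "d", "a", "a", "b")),
    latents = list(list(name = "int1", targets = "a")))
}

# latent series exactly inside the default cosine basis (makes noiseless
# recovery exact regardless of basis truncation)
basis_latent <- function(V = 40, k = 3) {
  v <- (seq_len(V) - 0.5) / V
  l <- cos(pi * k * v)
  (l - mean(l)) / stats::sd(l)
}

# synthetic observation for a toy net at given weights/latent/noise
toy_observed <- function(net, db, latent, noise_sd = 0, seed = 1) {
  O <- forward_model(net, db, matrix(latent, 1,
                                     dimnames = list("int1", NULL)))
  if (noise_sd > 0) {
    set.seed(seed)
    O <- O + matrix(rnorm(length(O), 0, noise_sd), nrow(O))
  }
  O - rowMeans(O)
}

# ground truth with all-zero weights for a network
zero_gt <- function(net) ground_truth(net, group = NULL, condition = NULL)
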