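test_that("forward model solves the summed-input system exactly", {
  net3 <- toy3_net()
  L <- matrix(basis_latent(), 1, dimnames = list("int1", NULL))
  # chain: latent -> a (w=1), a -> b (w=0.5): O_b = 0.5 L
  O <- forward_model(net3, c("a->b" = 0.5, "b->c" = 0, "int1->a" = 1), L)
  expect_equal(O["a", ], L[1, ], ignore_attr = TRUE)
  expect_equal(O["b", ], 0.5 * L[1, ], ignore_attr = TRUE)
  expect_equal(O["c", ], rep(0, ncol(L)), ignore_attr = TRUE)

  # all inter-region weights zero: latent targets get M L, others zero
  O0 <- forward_model(net3, c("a->b" = 0, "b->c" = 0), L)
  expect_equal(O0["a", ], L[1, ], ignore_attr = TRUE)
  expect_true(all(O0[c("b", "c"), ] == 0))

  # 2-cycle geometric-series closed form
  net2 <- toy2_net(cycle = TRUE)
  Oc <- forward_model(net2, c("a->b" = 0.4, "b->a" = 0.5, "int1->a" = 1), L)
  expect_equal(Oc["a", ], L[1, ] / (1 - 0.2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(Oc["b", ], 0.4 * L[1, ] / (1 - 0.2), tolerance = 1e-12,
               ignore_attr = TRUE)

  # instability error names the radius
  expect_error(forward_model(net2, c("a->b" = 1.2, "b->a" = 1.1), L),
               "spectral radius")
})

test_that("scale identifiability: latent rescaling is absorbed", {
  net3 <- toy3_net()
  L <- matrix(basis_latent(), 1, dimnames = list("int1", NULL))
  O1 <- forward_model(net3, c("a->b" = 0.5, "b->c" = -0.3, "int1->a" = 2), L)
  O2 <- forward_model(net3, c("a->b" = 0.5, "b->c" = -0.3, "int1->a" = 1),
                      2 * L)
  expect_equal(O1, O2, tolerance = 1e-12)
})

test_that("positive weights are excitatory (covariance increases)", {
  net2 <- toy2_net()
  L <- matrix(basis_latent(), 1, dimnames = list("int1", NULL))
  covs <- vapply(c(0.2, 0.4, 0.6), function(w) {
    O <- forward_model(net2, c("a->b" = w, "int1->a" = 1), L)
    cov(O["a", ], O["b", ])
  }, numeric(1))
  expect_true(all(diff(covs) > 0))
})

test_that("noiseless self-consistency: fitter recovers generating weights", {
  net3 <- toy3_net()
  truth <- c("a->b" = 0.62, "b->c" = -0.41, "int1->a" = 1)
  Y <- toy_observed(net3, truth, basis_latent())
  f <- fit_sapm(Y, net3, light_opts())
  expect_lt(max(abs(f$db[c("a->b", "b->c")] - truth[c("a->b", "b->c")])),
            1e-6)
  expect_gt(f$r2_total, 1 - 1e-9)
  expect_true(f$converged)
  # latent link weight recovered up to the documented sign convention
  expect_equal(unname(abs(f$db["int1->a"])), 1, tolerance = 1e-6)
  expect_gte(f$db["int1->a"], 0)
})

test_that("fitter matches a dense grid-search SSE oracle on 2-region toys", {
  net2 <- toy2_net()
  set.seed(13)
  truth <- c("a->b" = 0.37, "int1->a" = 1)
  Y <- toy_observed(net2, truth, basis_latent(), noise_sd = 0.15, seed = 5)
  f <- fit_sapm(Y, net2, light_opts())
  # conditional model: region b regressed on observed a; SSE(w) is
  # separable, so scan w on a dense grid (independent oracle)
  grid <- seq(-1, 1, by = 1e-3)
  sse <- vapply(grid, function(w) sum((Y["b", ] - w * Y["a", ])^2),
                numeric(1))
  w_star <- grid[which.min(sse)]
  expect_lt(abs(f$db["a->b"] - w_star), 1e-3 + 1e-8)
})

test_that("SSE is monotone over ALS iterations", {
  net3 <- toy3_net()
  truth <- c("a->b" = 0.5, "b->c" = 0.4, "int1->a" = 1)
  Y <- toy_observed(net3, truth, basis_latent(k = 2), noise_sd = 0.3,
                    seed = 9)
  sses <- vapply(1:6, function(k)
    fit_sapm(Y, net3, sapm_fit_opts(max_iter = k, n_restarts = 1,
                                    seed = 4))$sse,
    numeric(1))
  expect_true(all(diff(sses) < 1e-10))
})

test_that("fitter guards inputs and rank deficiency", {
  net3 <- toy3_net()
  Y <- toy_observed(net3, c("a->b" = 0.5, "b->c" = 0.4), basis_latent())
  expect_error(fit_sapm(Y[, 1:5], net3), "8 volumes")
  Yb <- Y; Yb[1, 1] <- NA
  expect_error(fit_sapm(Yb, net3), "non-finite")
  # duplicated source series => rank-deficient regression
  net_dup <- network_model(
    data.frame(name = paste("r", 1:3), abbrev = c("a", "b", "c")),
    data.frame(source = c("a", "b"), target = c("c", "c")),
    list(list(name = "int1", targets = "a")))
  Yd <- rbind(a = basis_latent(), b = basis_latent(),
              c = 0.4 * basis_latent())
  expect_warning(fit_sapm(Yd, net_dup, sapm_fit_opts(n_restarts = 1)),
                 "rank-deficient")
})

test_that("sub-region selection finds the signal-bearing combination", {
  net3 <- toy3_net()
  truth <- c("a->b" = 0.7, "b->c" = -0.5, "int1->a" = 1)
  Y <- toy_observed(net3, truth, basis_latent(), noise_sd = 0.02, seed = 6)
  set.seed(31)
  cands <- array(rnorm(3 * 5 * 40, 0, 1), c(3, 5, 40),
                 dimnames = list(c("a", "b", "c"), NULL, NULL))
  for (r in 1:3) cands[r, 2, ] <- Y[r, ]          # signal in sub-region 2
  sel <- select_subregions(cands, net3, light_opts())
  expect_identical(unname(sel$subregion_choice), rep(2L, 3))

  # independent oracle: full enumeration of all 125 combinations
  combos <- as.matrix(expand.grid(1:5, 1:5, 1:5))
  r2s <- apply(combos, 1, function(idx) {
    obs <- rbind(a = cands[1, idx[1], ], b = cands[2, idx[2], ],
                 c = cands[3, idx[3], ])
    fit_sapm(obs, net3, light_opts())$r2_total
  })
  expect_identical(unname(sel$subregion_choice),
                   as.integer(combos[which.max(r2s), ]))

  # identical candidates tie-break to the lowest index
  same <- cands
  for (r in 1:3) for (s in 1:5) same[r, s, ] <- Y[r, ]
  sel2 <- select_subregions(same, net3, light_opts())
  expect_identical(unname(sel2$subregion_choice), rep(1L, 3))
})

test_that("greedy selection beats the naive baseline on larger networks", {
  net <- mini8_net()
  # 5 regions needed for greedy path: extend mini net with one region
  net5 <- network_model(
    data.frame(name = paste("region", letters[1:5]), abbrev = letters[1:5]),
    data.frame(source = c("a", "b", "c", "d"), target = c("b", "c", "d", "e")),
    list(list(name = "int1", targets = "a")))
  truth <- c("a->b" = 0.6, "b->c" = 0.5, "c->d" = -0.4, "d->e" = 0.5,
             "int1->a" = 1)
  Y <- toy_observed(net5, truth, basis_latent(), noise_sd = 0.05, seed = 2)
  set.seed(17)
  cands <- array(rnorm(5 * 5 * 40), c(5, 5, 40),
                 dimnames = list(letters[1:5], NULL, NULL))
  for (r in 1:5) cands[r, 3, ] <- Y[r, ]
  sel <- select_subregions(cands, net5, light_opts(), combo_restarts = 2)
  base <- fit_sapm(rbind(a = cands[1, 1, ], b = cands[2, 1, ],
                         c = cands[3, 1, ], d = cands[4, 1, ],
                         e = cands[5, 1, ]), net5, light_opts())
  expect_gte(sel$r2_total, base$r2_total)
  expect_identical(unname(sel$subregion_choice), rep(3L, 5))
})

test_that("null reference: input guards and determinism", {
  net3 <- toy3_net()
  Y <- toy_observed(net3, c("a->b" = 0.5, "b->c" = 0.4, "int1->a" = 1),
                    basis_latent(), noise_sd = 0.1, seed = 3)
  expect_error(fit_null_reference(Y, net3, n_null = 1), "n_null")
  nr1 <- fit_null_reference(Y, net3, n_null = 4, seed = 2,
                            opts = light_opts())
  nr2 <- fit_null_reference(Y, net3, n_null = 4, seed = 2,
                            opts = light_opts())
  expect_identical(nr1$samples, nr2$samples)
  expect_identical(dim(nr1$samples), c(4L, 3L))
})

test_that("derived D shares normalize outgoing weights per source", {
  net <- default_network()
  db <- setNames(numeric(35), connection_labels(net, TRUE))
  db["LC->Hypothalamus"] <- 0.3
  db["LC->Thalamus"] <- 0.1
  sh <- derived_D(db, net)
  expect_equal(unname(sh["LC->Hypothalamus"]), 0.75)
  expect_equal(unname(sh["LC->Thalamus"]), 0.25)
  expect_equal(unname(sh["int1->C6RD"]), 1)      # single-target source
  # per-source shares always sum to 1
  src <- sub("->.*$", "", names(sh))
  sums <- tapply(sh, src, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("signal decomposition is exactly additive", {
  net <- default_network()
  d <- generate_participant(net, ground_truth(net, "FM", "Pain"),
                            build_paradigm("Pain"), noise_sd = 0.1, seed = 7)
  f <- fit_sapm(d$region_series, net, light_opts())
  dec <- signal_decomposition(f, net, "LC")
  # LC receives PAG, PBN, Hypothalamus, NTS and the int2 latent input
  expect_setequal(rownames(dec$contributions),
                  c("PAG", "PBN", "Hypothalamus", "NTS", "int2"))
  expect_equal(colSums(dec$contributions), dec$total_input,
               tolerance = 1e-12)
  expect_length(dec$output, 40L)
  # region with only a latent link: single contribution equals the model
  net1 <- network_model(data.frame(name = "solo", abbrev = "a"), NULL,
                        list(list(name = "int1", targets = "a")))
  Y1 <- matrix(basis_latent(), 1, dimnames = list("a", NULL))
  f1 <- fit_sapm(Y1, net1, light_opts())
  dec1 <- signal_decomposition(f1, net1, "a")
  expect_identical(nrow(dec1$contributions), 1L)
  expect_equal(dec1$contributions[1, ], dec1$total_input, tolerance = 1e-12)
})
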