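# Building a full-size network is expensive; build small-but-structured
# instances for most checks and share one default-size instance.
small_params <- function(...) {
  network_params(e_cluster_size = 40, i_cluster_size = 12,
                 background_e = 80, ...)
}

test_that("population sizes and fixed in-degrees are exact", {
  p <- small_params()
  expect_identical(p$n_e, 14 * 40 + 80)
  expect_identical(p$n_i, 14 * 12)
  # default-size arithmetic from the architecture definition
  pd <- network_params()
  expect_identical(pd$n_e, 4000)
  expect_identical(pd$n_i, 994)
  net <- build_network(p, seed = 1)
  W <- net$weights
  k_ee <- round(p$p_ee * p$n_e); k_ei <- round(p$p_ei * p$n_i)
  e_rows <- 1:p$n_e
  expect_true(all(Matrix::rowSums(W[e_rows, 1:p$n_e] != 0) == k_ee))
  expect_true(all(Matrix::rowSums(W[e_rows, p$n_e + 1:p$n_i] != 0) == k_ei))
  # identical in-degrees across instances, different partners
  net2 <- build_network(p, seed = 2)
  expect_true(all(Matrix::rowSums(net2$weights[e_rows, 1:p$n_e] != 0) ==
                    k_ee))
  expect_false(identical(net$weights@i, net2$weights@i))
  # same seed gives the identical matrix
  net1b <- build_network(p, seed = 1)
  expect_identical(net$weights, net1b$weights)
  expect_identical(net$role_of_cluster, net1b$role_of_cluster)
  # no self-connections
  expect_true(all(Matrix::diag(W) == 0))
  # infeasible in-degree is a configuration error
  expect_error(build_network(small_params(p_ee = 1.0), seed = 1),
               "in-degree")
})

test_that("degenerate potentiation factors collapse to the reference", {
  eps <- 1e-9
  p <- small_params(jE_pp = 1 + 2 * eps, jE_p = 1 + eps, jE_m = 1 - eps,
                    jI_pp = 1 + 2 * eps, jI_p = 1 + eps, jI_m = 1 - eps)
  net <- build_network(p, seed = 3, apply_role_wiring = FALSE)
  W <- net$weights
  ee <- W[1:p$n_e, 1:p$n_e]
  expect_equal(range(ee@x), rep(p$j_ee, 2), tolerance = 1e-6)
  ii <- W[p$n_e + 1:p$n_i, p$n_e + 1:p$n_i]
  expect_equal(range(ii@x), rep(p$j_ii, 2), tolerance = 1e-6)
})

test_that("taste overlap blocks match the closed-form means", {
  p <- network_params()
  net <- build_network(p, seed = 11)
  n_pairs <- p$e_cluster_size^2
  # binomial error bound for a block mean with connection prob p_ee
  se_block <- function(w) sqrt(p$p_ee * (1 - p$p_ee) / n_pairs) * w
  # overlap subset size is round(f_ov * cluster size)
  expect_equal(
    unname(lengths(net$overlap_members)),
    rep(round(0.25 * 250) + round(0.25 * 71), 4))
  # same-quality pair: P[fov^2 J++ + (1 - fov^2) J-] J_EE
  mu_sm <- p$p_ee * (p$f_ov^2 * p$jE_pp + (1 - p$f_ov^2) * p$jE_m) * p$j_ee
  expect_lt(abs(block_mean(net, "S", "M") - mu_sm),
            3 * se_block(p$jE_pp * p$j_ee))
  expect_lt(abs(block_mean(net, "Q", "O") - mu_sm),
            3 * se_block(p$jE_pp * p$j_ee))
  # cross-quality taste blocks are plain inter-cluster blocks
  mu_inter <- p$p_ee * p$jE_m * p$j_ee
  expect_lt(abs(block_mean(net, "S", "Q") - mu_inter),
            3 * se_block(p$jE_m * p$j_ee))
  # within-taste-cluster mean: fov^2 at J++, rest at J+
  mu_taste_intra <- p$p_ee *
    (p$f_ov^2 * p$jE_pp + (1 - p$f_ov^2) * p$jE_p) * p$j_ee
  expect_lt(abs(block_mean(net, "S", "S") - mu_taste_intra),
            3 * se_block(p$jE_p * p$j_ee))
  # generic intra-cluster block
  gen <- which(net$role_of_cluster == "generic")
  mu_intra <- p$p_ee * p$jE_pp * p$j_ee
  expect_lt(abs(block_mean(net, gen[1], gen[1]) - mu_intra),
            3 * se_block(p$jE_pp * p$j_ee))
  assign("shared_default_net", net, envir = topenv())
})

test_that("cue/action wiring biases follow their probabilities", {
  p <- network_params()
  net <- if (exists("shared_default_net", envir = topenv()))
    get("shared_default_net", envir = topenv())
  else build_network(p, seed = 11)
  # fraction of modified synapses in the S -> CueL block is ~60%
  rows <- cluster_members(net, "CueL", "E")
  cols <- cluster_members(net, "S", "E")
  w <- net$weights[rows, cols]@x
  base <- p$jE_m * p$j_ee
  frac_up <- mean(abs(w - base * p$j_ct_e) < 1e-9)
  n_syn <- length(w)
  expect_lt(abs(frac_up - p$p_ct_e), 3 * sqrt(0.6 * 0.4 / n_syn))
  # correct cue->action outweighs incorrect on average
  expect_gt(block_mean(net, "ActL", "CueL"),
            block_mean(net, "ActL", "CueR"))
  expect_gt(block_mean(net, "ActR", "CueR"),
            block_mean(net, "ActR", "CueL"))
  # closed-form audit of both blocks
  mu_cor <- p$p_ee * (p$p_ac_cor * p$j_ac_cor + 1 - p$p_ac_cor) *
    p$jE_m * p$j_ee
  mu_inc <- p$p_ee * (p$p_ac_inc * p$j_ac_inc + 1 - p$p_ac_inc) *
    p$jE_m * p$j_ee
  se <- sqrt(p$p_ee / 250^2) * p$j_ac_cor * p$jE_m * p$j_ee
  expect_lt(abs(block_mean(net, "ActL", "CueL") - mu_cor), 3 * se)
  expect_lt(abs(block_mean(net, "ActL", "CueR") - mu_inc), 3 * se)
  # with all application probabilities 0 the wiring stage is a no-op
  p0 <- small_params(p_ct_e = 0, p_cc_e = 0, p_cc_i = 0, p_ac_cor = 0,
                     p_ac_inc = 0, p_aa_e = 0, p_aa_i = 0, p_ca_i = 0)
  a <- build_network(p0, seed = 5, apply_role_wiring = TRUE)
  b <- build_network(p0, seed = 5, apply_role_wiring = FALSE)
  expect_identical(a$weights, b$weights)
})

test_that("stimulus targets cover half of each taste cluster", {
  p <- small_params()
  net <- build_network(p, seed = 7)
  for (r in c("S", "Q", "M", "O")) {
    tgt <- net$stimulus_targets[[r]]
    expect_equal(length(tgt), round(0.5 * p$e_cluster_size))
    expect_true(all(tgt %in% cluster_members(net, r, "E")))
  }
})
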