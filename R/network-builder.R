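#' Architecture parameters of the clustered E/I network
#'
#' Defines the clustered excitatory/inhibitory architecture: 4000 E
#' neurons (14 clusters of 250 plus a 500-neuron background population)
#' and 994 I neurons (14 partner clusters of 71), random connectivity
#' with fixed in-degrees, intra/inter-cluster potentiation/depression
#' factors, the 25% same-quality taste-cluster overlap, and the
#' taste-to-cue-to-action wiring biases with their application
#' probabilities. Weight units are pA x ms (the time-integral of one
#' postsynaptic current equals the weight).
#'
#' Baseline connection probabilities and reference weights are exposed
#' here; the shipped defaults are tuned so that the unstimulated network
#' expresses spontaneous metastable cluster switching with dwell times
#' of order 10^2-10^3 ms and spontaneous E rates of a few Hz, in line
#' with the clustered-network literature this architecture follows.
#'
#' @param n_clusters Number of E (and I) clusters.
#' @param e_cluster_size,i_cluster_size Neurons per E / I cluster.
#' @param background_e Unclustered E neurons.
#' @param p_ee,p_ei,p_ie,p_ii Connection probabilities (post-pre:
#'   `p_ei` is the probability of an I to E connection).
#' @param j_ee,j_ei,j_ie,j_ii Reference synaptic weights in pA x ms.
#' @param jE_pp,jE_p,jE_m Intra-cluster potentiation (`++`, `+`) and
#'   inter-cluster depression (`-`) factors for E-E synapses; must
#'   satisfy `jE_m < 1 < jE_p < jE_pp`.
#' @param jI_pp,jI_p,jI_m The same for synapses involving I neurons
#'   (intra-I-cluster `++`, E-I partner-pair `+`, non-partner `-`).
#' @param f_ov Overlap fraction of same-quality taste clusters.
#' @param j_ct_e,p_ct_e Taste-to-cue weight factor (correct pairings
#'   only) and its application probability.
#' @param j_cc_e,p_cc_e Cue intra-cluster E factor and probability.
#' @param j_cc_i,p_cc_i Cue-I to opposite cue-E factor and probability.
#' @param j_ac_cor,p_ac_cor,j_ac_inc,p_ac_inc Cue-E to action-E factors
#'   (correct / incorrect pairing) and probabilities.
#' @param j_aa_e,p_aa_e Action intra-cluster E factor and probability.
#' @param j_aa_i,p_aa_i Action-I to opposite action-E factor and
#'   probability.
#' @param j_ca_i,p_ca_i Action-I to cue-E factor and probability.
#' @param tau_mult_cue_e,tau_mult_cue_i Synaptic time-constant
#'   multipliers for neurons in cue E clusters / their I partners.
#' @param tau_mult_act_e,tau_mult_act_i The same for action clusters.
#' @param stim_fraction Fraction of neurons in a taste cluster that
#'   receive the stimulus input.
#' @return An object of class `network_params`.
#' @export
network_params <- function(
    n_clusters = 14, e_cluster_size = 250, i_cluster_size = 71,
    background_e = 500,
    p_ee = 0.2, p_ei = 0.5, p_ie = 0.5, p_ii = 0.5,
    j_ee = 0.60, j_ei = 1.40, j_ie = 0.52, j_ii = 1.40,
    jE_pp = 3.6, jE_p = 2.6, jE_m = 0.8267,
    jI_pp = 1.8, jI_p = 1.7, jI_m = 0.9462,
    f_ov = 0.25,
    j_ct_e = 1.85, p_ct_e = 0.60,
    j_cc_e = 1.05, p_cc_e = 0.60,
    j_cc_i = 1.40, p_cc_i = 0.50,
    j_ac_cor = 2.75, p_ac_cor = 0.50,
    j_ac_inc = 2.60, p_ac_inc = 0.50,
    j_aa_e = 1.07, p_aa_e = 0.50,
    j_aa_i = 3.00, p_aa_i = 0.50,
    j_ca_i = 1.40, p_ca_i = 0.50,
    tau_mult_cue_e = 2.3, tau_mult_cue_i = 1.3,
    tau_mult_act_e = 3.30, tau_mult_act_i = 3.25,
    stim_fraction = 0.5) {
  p <- as.list(environment())
  if (!(p$jE_m < 1 && 1 < p$jE_p && p$jE_p < p$jE_pp))
    abort_field("need jE_m < 1 < jE_p < jE_pp")
  if (!(p$jI_m < 1 && 1 < p$jI_p && p$jI_p < p$jI_pp))
    abort_field("need jI_m < 1 < jI_p < jI_pp")
  probs <- unlist(p[grep("^p_", names(p))])
  if (any(probs < 0 | probs > 1)) abort_field("probabilities must be in [0,1]")
  p$n_e <- n_clusters * e_cluster_size + background_e
  p$n_i <- n_clusters * i_cluster_size
  structure(p, class = "network_params")
}

ROLES <- c("S", "Q", "M", "O", "CueL", "CueR", "ActL", "ActR")

# Sample exactly k presynaptic partners for each postsynaptic neuron
# from pool (a vector of candidate pre indices); self excluded.
fixed_indegree_edges <- function(post_idx, pool, k) {
  if (k == 0)
    return(list(post = integer(), pre = integer()))
  if (k > length(pool) - 1)
    abort_field("in-degree %d infeasible for population of size %d",
                k, length(pool))
  pre <- integer(length(post_idx) * k)
  for (q in seq_along(post_idx)) {
    cand <- pool[pool != post_idx[q]]
    pre[((q - 1) * k + 1):(q * k)] <- cand[sample.int(length(cand), k)]
  }
  list(post = rep(post_idx, each = k), pre = pre)
}

#' Build a clustered E/I synaptic weight matrix
#'
#' Constructs a network instance: cluster membership, random role
#' assignment (8 of the 14 E clusters get the roles S, Q, M, O, CueL,
#' CueR, ActL, ActR; partner I clusters mirror them), fixed in-degree
#' random connectivity (each postsynaptic neuron draws exactly
#' `round(P * population size)` presynaptic partners per population,
#' without replacement), generic intra/inter-cluster weights, the
#' same-quality taste-cluster overlap, and the cue/action wiring biases.
#' The in-degree from each presynaptic population is identical across
#' instances built with the same parameters; only partner identities
#' differ with the seed.
#'
#' @param params A [network_params()] object.
#' @param seed Integer seed.
#' @param apply_overlap,apply_role_wiring Set `FALSE` to stop after the
#'   generic architecture (used for block-level audits).
#' @return An object of class `synaptic_matrix`: a list with `weights`
#'   (a `Matrix::dgCMatrix`, rows = postsynaptic, columns =
#'   presynaptic, nonnegative entries in pA x ms; the inhibitory sign is
#'   applied at simulation time), `is_inh`, `cluster` (0 = background),
#'   `role_of_cluster`, `overlap_members`, `stimulus_targets`,
#'   `tau_mult_e`/`tau_mult_i` (per-neuron synaptic time-constant
#'   multipliers) and `params`.
#' @export
build_network <- function(params = network_params(), seed = 1,
                          apply_overlap = TRUE, apply_role_wiring = TRUE) {
  stopifnot(inherits(params, "network_params"))
  p <- params
  with_seed(seed, {
    n_e <- p$n_e; n_i <- p$n_i; n <- n_e + n_i
    # neuron layout: E clusters, E background, I clusters
    cluster <- integer(n)
    for (c in seq_len(p$n_clusters))
      cluster[((c - 1) * p$e_cluster_size + 1):(c * p$e_cluster_size)] <- c
    i_start <- n_e
    for (c in seq_len(p$n_clusters))
      cluster[i_start + ((c - 1) * p$i_cluster_size + 1):
                (c * p$i_cluster_size)] <- c
    is_inh <- c(rep(FALSE, n_e), rep(TRUE, n_i))

    role_clusters <- sample(p$n_clusters, length(ROLES))
    role_of_cluster <- rep("generic", p$n_clusters)
    role_of_cluster[role_clusters] <- ROLES

    # fixed in-degrees
    k_from_e <- c(E = round(p$p_ee * n_e), I = round(p$p_ie * n_e))
    k_from_i <- c(E = round(p$p_ei * n_i), I = round(p$p_ii * n_i))
    e_idx <- seq_len(n_e); i_idx <- n_e + seq_len(n_i)
    ed <- list(
      fixed_indegree_edges(e_idx, e_idx, k_from_e[["E"]]),
      fixed_indegree_edges(e_idx, i_idx, k_from_i[["E"]]),
      fixed_indegree_edges(i_idx, e_idx, k_from_e[["I"]]),
      fixed_indegree_edges(i_idx, i_idx, k_from_i[["I"]]))
    post <- c(ed[[1]]$post, ed[[2]]$post, ed[[3]]$post, ed[[4]]$post)
    pre <- c(ed[[1]]$pre, ed[[2]]$pre, ed[[3]]$pre, ed[[4]]$pre)

    post_inh <- is_inh[post]; pre_inh <- is_inh[pre]
    base <- ifelse(!post_inh & !pre_inh, p$j_ee,
            ifelse(!post_inh & pre_inh, p$j_ei,
            ifelse(post_inh & !pre_inh, p$j_ie, p$j_ii)))
    pc <- cluster[post]; qc <- cluster[pre]
    same <- pc == qc & pc > 0
    factor <- numeric(length(post))
    bothE <- !post_inh & !pre_inh
    bothI <- post_inh & pre_inh
    mixed <- post_inh != pre_inh
    factor[bothE] <- ifelse(same[bothE], p$jE_pp, p$jE_m)
    factor[bothI] <- ifelse(same[bothI], p$jI_pp, p$jI_m)
    factor[mixed] <- ifelse(same[mixed], p$jI_p, p$jI_m)

    # taste overlap structure
    overlap_members <- list()
    if (apply_overlap) {
      n_sub_e <- round(p$f_ov * p$e_cluster_size)
      n_sub_i <- round(p$f_ov * p$i_cluster_size)
      in_subset <- rep(FALSE, n)
      taste_cl <- integer(0)
      for (r in c("S", "Q", "M", "O")) {
        c <- which(role_of_cluster == r)
        taste_cl <- c(taste_cl, c)
        mem_e <- which(cluster == c & !is_inh)
        mem_i <- which(cluster == c & is_inh)
        sub <- c(mem_e[sample.int(length(mem_e), n_sub_e)],
                 mem_i[sample.int(length(mem_i), n_sub_i)])
        in_subset[sub] <- TRUE
        overlap_members[[r]] <- sub
      }
      # quality code per cluster: 1 sweet, 2 bitter, 0 otherwise
      qual_code <- integer(p$n_clusters + 1L)   # index cluster + 1
      qual_code[1 + which(role_of_cluster %in% c("S", "M"))] <- 1L
      qual_code[1 + which(role_of_cluster %in% c("Q", "O"))] <- 2L
      is_taste_p <- pc %in% taste_cl
      is_taste_q <- qc %in% taste_cl
      # within a taste cluster: subset pairs keep ++, the rest drop to +
      within_taste <- same & is_taste_p
      sub_pair <- in_subset[post] & in_subset[pre]
      dn <- within_taste & !sub_pair
      factor[dn & bothE] <- p$jE_p
      factor[dn & bothI] <- p$jI_p
      # mixed within partner pair is already jI_p
      # across same-quality clusters: subset pairs get ++
      qp <- qual_code[pc + 1L]; qq <- qual_code[qc + 1L]
      same_quality <- is_taste_p & is_taste_q & pc != qc &
        qp > 0L & qp == qq
      # cross-cluster subset potentiation is within-type (E-E and I-I);
      # cross-type subset pairs keep the generic non-partner weight so
      # the partner cluster's overlap can co-activate with the stimulus
      up <- same_quality & sub_pair
      factor[up & bothE] <- p$jE_pp
      factor[up & bothI] <- p$jI_pp
    }

    # cue/action wiring biases
    if (apply_role_wiring) {
      cl_of_role <- function(r) which(role_of_cluster == r)
      rp <- role_of_cluster[pmax(pc, 1)]; rp[pc == 0] <- "bg"
      rq <- role_of_cluster[pmax(qc, 1)]; rq[qc == 0] <- "bg"
      mod <- function(sel, prob, fac) {
        idx <- which(sel)
        if (!length(idx)) return()
        hit <- idx[runif(length(idx)) < prob]
        factor[hit] <<- factor[hit] * fac
      }
      # taste -> cue, correct pairings, E->E
      mod(bothE & rp == "CueL" & rq %in% c("S", "Q"), p$p_ct_e, p$j_ct_e)
      mod(bothE & rp == "CueR" & rq %in% c("M", "O"), p$p_ct_e, p$j_ct_e)
      # cue intracluster E->E
      mod(bothE & same & rp %in% c("CueL", "CueR"), p$p_cc_e, p$j_cc_e)
      # cue-I -> opposite cue-E
      mod(!post_inh & pre_inh & rp == "CueL" & rq == "CueR",
          p$p_cc_i, p$j_cc_i)
      mod(!post_inh & pre_inh & rp == "CueR" & rq == "CueL",
          p$p_cc_i, p$j_cc_i)
      # cue-E -> action-E
      mod(bothE & rp == "ActL" & rq == "CueL", p$p_ac_cor, p$j_ac_cor)
      mod(bothE & rp == "ActR" & rq == "CueR", p$p_ac_cor, p$j_ac_cor)
      mod(bothE & rp == "ActL" & rq == "CueR", p$p_ac_inc, p$j_ac_inc)
      mod(bothE & rp == "ActR" & rq == "CueL", p$p_ac_inc, p$j_ac_inc)
      # action intracluster E->E
      mod(bothE & same & rp %in% c("ActL", "ActR"), p$p_aa_e, p$j_aa_e)
      # action-I -> opposite action-E
      mod(!post_inh & pre_inh & rp == "ActL" & rq == "ActR",
          p$p_aa_i, p$j_aa_i)
      mod(!post_inh & pre_inh & rp == "ActR" & rq == "ActL",
          p$p_aa_i, p$j_aa_i)
      # action-I -> cue-E
      mod(!post_inh & pre_inh & rp %in% c("CueL", "CueR") &
            rq %in% c("ActL", "ActR"), p$p_ca_i, p$j_ca_i)
    }

    weights <- Matrix::sparseMatrix(i = post, j = pre,
                                    x = base * factor, dims = c(n, n))

    # stimulus targets: half the neurons of each taste E cluster,
    # drawn once per network instance
    stimulus_targets <- list()
    for (r in c("S", "Q", "M", "O")) {
      c <- which(role_of_cluster == r)
      mem_e <- which(cluster == c & !is_inh)
      stimulus_targets[[r]] <-
        sort(mem_e[sample.int(length(mem_e),
                              round(p$stim_fraction * length(mem_e)))])
    }

    # per-neuron synaptic time-constant multipliers: members of cue and
    # action E-I cluster pairs integrate synaptic input with slower
    # kinetics, supporting persistent representations; excitatory and
    # inhibitory synapses are slowed by separate factors
    tau_mult_e <- rep(1, n); tau_mult_i <- rep(1, n)
    for (r in c("CueL", "CueR")) {
      c <- which(role_of_cluster == r)
      tau_mult_e[cluster == c] <- p$tau_mult_cue_e
      tau_mult_i[cluster == c] <- p$tau_mult_cue_i
    }
    for (r in c("ActL", "ActR")) {
      c <- which(role_of_cluster == r)
      tau_mult_e[cluster == c] <- p$tau_mult_act_e
      tau_mult_i[cluster == c] <- p$tau_mult_act_i
    }

    structure(list(weights = weights, is_inh = is_inh, cluster = cluster,
                   role_of_cluster = role_of_cluster,
                   overlap_members = overlap_members,
                   stimulus_targets = stimulus_targets,
                   tau_mult_e = tau_mult_e, tau_mult_i = tau_mult_i,
                   n_e = n_e, n_i = n_i, params = p, seed = seed),
              class = "synaptic_matrix")
  })
}

#' @exportS3Method base::print
print.synaptic_matrix <- function(x, ...) {
  cat(sprintf("<synaptic_matrix> %d E + %d I neurons, %d synapses\n",
              x$n_e, x$n_i, length(x$weights@x)))
  cat("  roles:", paste(x$role_of_cluster, collapse = " "), "\n")
  invisible(x)
}

#' Neuron indices of a role's E (or I) cluster
#'
#' @param net A `synaptic_matrix`.
#' @param role One of `"S","Q","M","O","CueL","CueR","ActL","ActR"` or
#'   a cluster number.
#' @param type `"E"` or `"I"`.
#' @return Integer vector of neuron indices.
#' @export
cluster_members <- function(net, role, type = "E") {
  cl <- if (is.character(role)) which(net$role_of_cluster == role)
  else as.integer(role)
  if (!length(cl)) abort_field("no cluster with role '%s'", role)
  which(net$cluster == cl & (net$is_inh == (type == "I")))
}

#' Empirical block means of the synaptic matrix
#'
#' Average weight from presynaptic cluster `pre_cl` to postsynaptic
#' cluster `post_cl` (E or I side), counting absent connections as zero
#' so the value is comparable to the closed-form
#' `P * (P_M J_M + 1 - P_M) * J_factor * J_base` block average.
#'
#' @param net A `synaptic_matrix`.
#' @param post_cl,pre_cl Cluster numbers (or role names).
#' @param post_type,pre_type `"E"` or `"I"`.
#' @return The mean weight over all ordered neuron pairs in the block.
#' @export
block_mean <- function(net, post_cl, pre_cl, post_type = "E",
                       pre_type = "E") {
  rows <- cluster_members(net, post_cl, post_type)
  cols <- cluster_members(net, pre_cl, pre_type)
  sub <- net$weights[rows, cols, drop = FALSE]
  sum(sub) / (length(rows) * length(cols))
}
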