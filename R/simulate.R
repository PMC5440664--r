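# Seed-deterministic generators for every input the pipeline consumes:
# birth-death trees conditioned on tip count, continuous traits under BM
# (with planted branch-rate shifts) and OU (with planted regime shifts,
# coupled or uncoupled across two life-history phases), Mk character
# matrices, and two-phase FPKM expression tables.

#' Simulate a birth-death tree conditioned on its number of tips
#'
#' Forward Gillespie simulation from two crown lineages under a
#' birth-death process with speciation rate
#' `lambda(s) = lambda * exp(-decline * s)` (`s` = time since the crown
#' origin, so `decline > 0` means speciation falls off through the
#' radiation) and constant extinction `mu`. Conditioning on exactly
#' `n` extant tips follows the generalized sampling approach: the history
#' is simulated past `n`, the observation time is drawn uniformly from the
#' periods during which exactly `n` lineages were alive (chosen with
#' probability proportional to their duration), and extinct lineages are
#' pruned. Under a pure-birth process the expected crown age is
#' `sum_{k=2..n} 1/(lambda k)`.
#'
#' @param n number of extant tips (>= 3).
#' @param lambda speciation rate at the crown origin (events/lineage/Myr).
#' @param mu constant extinction rate (events/lineage/Myr).
#' @param decline exponential decline rate of speciation through forward
#'   time (1/Myr, >= 0; 0 = constant rate).
#' @param seed optional RNG seed; if `NULL` the current RNG state is used.
#' @param max_tries retry budget for histories that die out or never spend
#'   time at `n` lineages.
#' @return an ultrametric `phylo` with tips `t1..tn`.
#' @export
simulate_tree <- function(n, lambda = 0.1, mu = 0, decline = 0, seed = NULL,
                          max_tries = 1000) {
  stopifnot(n >= 3, lambda > 0, mu >= 0, decline >= 0)
  if (!is.null(seed)) set.seed(seed)
  for (try in seq_len(max_tries)) {
    h <- sim_bd_history(n, lambda, mu, decline)
    if (is.null(h)) next
    tree <- history_to_tree(h$lineages, h$t_obs)
    if (!is.null(tree) && ape::Ntip(tree) == n) {
      tree$tip.label <- paste0("t", seq_len(n))
      return(validate_tree(tree, tol = 1e-4))
    }
  }
  stop("birth-death process failed to yield ", n, " tips in ", max_tries,
       " tries")
}

# One forward history. Returns lineage table and observation time, or NULL.
sim_bd_history <- function(n, lambda, mu, decline) {
  cap <- if (mu == 0) n else 4L * n
  lin <- data.frame(id = 1:2, parent = c(0L, 0L), t_birth = 0, t_death = NA_real_)
  extant <- c(1L, 2L)
  s <- 0
  windows <- matrix(numeric(0), ncol = 2) # periods with exactly n lineages
  win_open <- if (n == 2) 0 else NA_real_
  repeat {
    k <- length(extant)
    if (k == 0 || k > cap) break
    # thinning: lambda(s) is non-increasing, so k*(lambda(s)+mu) bounds ahead
    repeat {
      B <- k * (lambda * exp(-decline * s) + mu)
      if (B <= 0) { s <- Inf; break }
      s <- s + rexp(1, B)
      rate_now <- k * (lambda * exp(-decline * s) + mu)
      if (runif(1) <= rate_now / B) break
    }
    if (!is.finite(s)) break
    if (!is.na(win_open)) { windows <- rbind(windows, c(win_open, s)); win_open <- NA_real_ }
    speciation <- runif(1) <= lambda * exp(-decline * s) /
      (lambda * exp(-decline * s) + mu)
    who <- extant[sample.int(length(extant), 1)]
    if (speciation) {
      id <- nrow(lin) + 1L
      lin <- rbind(lin, data.frame(id = id, parent = who, t_birth = s,
                                   t_death = NA_real_))
      extant <- c(extant, id)
    } else {
      lin$t_death[who] <- s
      extant <- setdiff(extant, who)
    }
    if (length(extant) == n) win_open <- s
    if (mu == 0 && length(extant) > n) break
  }
  if (nrow(windows) == 0) return(NULL)
  len <- windows[, 2] - windows[, 1]
  w <- windows[sample.int(nrow(windows), 1, prob = len), ]
  list(lineages = lin, t_obs = runif(1, w[1], w[2]))
}

# Assemble a phylo from a lineage table observed at t_obs; extinct tips
# are dropped (merging the degree-2 nodes this creates).
history_to_tree <- function(lin, t_obs) {
  # birth times are non-decreasing in id, so filtering keeps a prefix and
  # row i still holds lineage id i
  lin <- lin[lin$t_birth <= t_obs, , drop = FALSE]
  end <- ifelse(!is.na(lin$t_death) & lin$t_death <= t_obs, lin$t_death, t_obs)
  kids <- split(lin$id, factor(lin$parent, levels = lin$id))
  build <- function(id, from) {
    ev <- kids[[as.character(id)]]
    ev <- ev[order(lin$t_birth[ev])]
    if (!length(ev)) return(sprintf("L%d:%.10f", id, end[id] - from))
    build_seq(id, from, ev)
  }
  build_seq <- function(id, from, ev) {
    # nest child births along lineage id, earliest birth outermost
    times <- lin$t_birth[ev]
    inner <- sprintf("L%d:%.10f", id, end[id] - times[length(times)])
    for (j in rev(seq_along(ev))) {
      sub <- build(ev[j], times[j])
      top <- if (j > 1) times[j - 1] else from
      inner <- sprintf("(%s,%s):%.10f", inner, sub, times[j] - top)
    }
    inner
  }
  if (nrow(lin) < 2) return(NULL)
  left <- build(1L, 0)
  right <- build(2L, 0)
  txt <- sprintf("(%s,%s);", left, right)
  tree <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL)
  if (is.null(tree)) return(NULL)
  alive <- lin$id[is.na(lin$t_death) | lin$t_death > t_obs]
  tree <- tryCatch(ape::keep.tip(tree, paste0("L", alive)),
                   error = function(e) NULL)
  if (!is.null(tree) && any(tree$edge.length <= 0)) return(NULL)
  tree
}

#' Simulate Brownian-motion traits, optionally with branch-rate shifts
#'
#' @param tree a `phylo` object.
#' @param sig2 base BM rate (trait variance per Myr).
#' @param root_state trait value at the root.
#' @param edge_rates optional per-edge rate multipliers (in the edge order
#'   of `tree$edge`); default 1 everywhere.
#' @return named numeric vector of tip values.
#' @export
sim_bm <- function(tree, sig2 = 1, root_state = 0, edge_rates = NULL) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  ne <- nrow(tree$edge)
  if (is.null(edge_rates)) edge_rates <- rep(1, ne)
  stopifnot(length(edge_rates) == ne, all(edge_rates > 0), sig2 > 0)
  x <- numeric(ape::Ntip(tree) + tree$Nnode)
  x[root_node(tree)] <- root_state
  inc <- rnorm(ne, 0, sqrt(sig2 * edge_rates * tree$edge.length))
  for (e in seq_len(ne)) x[tree$edge[e, 2]] <- x[tree$edge[e, 1]] + inc[e]
  setNames(x[seq_len(ape::Ntip(tree))], tree$tip.label)
}

#' Simulate Ornstein-Uhlenbeck traits under a regime painting
#'
#' Along each branch the trait relaxes toward the optimum of the branch's
#' regime with strength `alpha`. The root state is the root-regime optimum.
#'
#' @param tree a `phylo` object.
#' @param painting a [paint_from_shifts()] regime painting.
#' @param alpha selection strength (1/Myr, > 0).
#' @param sig2 diffusion variance (trait^2/Myr).
#' @param theta numeric vector of optima, one per regime.
#' @return named numeric vector of tip values.
#' @export
sim_ou <- function(tree, painting, alpha, sig2, theta) {
  stopifnot(inherits(painting, "regime_painting"), alpha > 0, sig2 > 0,
            length(theta) == painting$n_regimes)
  tree <- ape::reorder.phylo(tree, "cladewise")
  ne <- nrow(tree$edge)
  x <- numeric(ape::Ntip(tree) + tree$Nnode)
  x[root_node(tree)] <- theta[painting$root_regime]
  for (e in seq_len(ne)) {
    l <- tree$edge.length[e]
    th <- theta[painting$edge_regime[e]]
    m <- th + (x[tree$edge[e, 1]] - th) * exp(-alpha * l)
    v <- sig2 / (2 * alpha) * (1 - exp(-2 * alpha * l))
    x[tree$edge[e, 2]] <- rnorm(1, m, sqrt(v))
  }
  setNames(x[seq_len(ape::Ntip(tree))], tree$tip.label)
}

#' Choose edges on which to plant regime or rate shifts
#'
#' Samples `k` edges whose subtended clades have between `min_clade` tips
#' and `max_frac` of all tips, optionally with mutually disjoint clades, so
#' planted shifts are in principle recoverable.
#'
#' @param tree a `phylo` object.
#' @param k number of shift edges.
#' @param min_clade minimum clade size below a shift edge.
#' @param max_frac maximum clade size as a fraction of all tips.
#' @param disjoint require the shift clades to be non-overlapping.
#' @return integer vector of edge indices.
#' @export
plant_shifts <- function(tree, k, min_clade = 4, max_frac = 0.5,
                         disjoint = TRUE) {
  tips <- edge_tip_sets(tree)
  sz <- lengths(tips)
  elig <- which(sz >= min_clade & sz <= max_frac * ape::Ntip(tree))
  if (!disjoint) {
    if (length(elig) < k) stop("not enough eligible edges")
    return(sort(sample(elig, k)))
  }
  chosen <- integer(0)
  pool <- sample(elig)
  for (e in pool) {
    if (length(chosen) == k) break
    if (!any(vapply(chosen, function(c0)
      length(intersect(tips[[c0]], tips[[e]])) > 0, logical(1))))
      chosen <- c(chosen, e)
  }
  if (length(chosen) < k) stop("could not place ", k, " disjoint shifts")
  sort(chosen)
}

#' Simulate two-phase OU traits with coupled or uncoupled regime shifts
#'
#' Generates one trait per life-history phase under multi-optimum OU. In
#' `"coupled"` mode both phases share the same shift edges (the planted
#' shift nodes coincide); in `"uncoupled"` mode shift edges are placed
#' independently per phase. Each new regime's optimum steps away from its
#' parent regime's optimum by `effect` stationary standard deviations
#' (`sqrt(sig2 / (2 alpha))`), with random sign.
#'
#' @param tree a `phylo` object.
#' @param n_shifts_a,n_shifts_b number of planted shifts per phase;
#'   defaults mirror the adult/tadpole shift counts reported for the
#'   mantellid radiation (15 and 17).
#' @param coupling `"coupled"` or `"uncoupled"`.
#' @param alpha,sig2 OU parameters shared by the phases.
#' @param effect optimum step size in stationary SD units.
#' @param min_clade,disjoint passed to [plant_shifts()]. The defaults
#'   (clades of two or more tips, nesting allowed) accommodate realistic
#'   shift counts; recovery benchmarks use fewer, larger, disjoint clades.
#' @return list with per-phase elements `a` and `b`, each holding `trait`,
#'   `shift_edges`, `painting`, `theta`.
#' @export
simulate_phase_traits <- function(tree, n_shifts_a = 15, n_shifts_b = 17,
                                  coupling = c("coupled", "uncoupled"),
                                  alpha = 0.2, sig2 = 1, effect = 4,
                                  min_clade = 2, disjoint = FALSE) {
  coupling <- match.arg(coupling)
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0,
            is.numeric(sig2), sig2 > 0, is.numeric(effect))
  edges_a <- plant_shifts(tree, n_shifts_a, min_clade, disjoint = disjoint)
  edges_b <- if (coupling == "coupled" && n_shifts_b == n_shifts_a) edges_a
    else if (coupling == "coupled") sort(sample(edges_a, min(n_shifts_b, n_shifts_a)))
    else plant_shifts(tree, n_shifts_b, min_clade, disjoint = disjoint)
  one_phase <- function(edges) {
    p <- paint_from_shifts(tree, edges)
    sdst <- sqrt(sig2 / (2 * alpha))
    theta <- numeric(p$n_regimes)
    # regimes are numbered in preorder, so a nested regime's parent regime
    # already has its optimum when we get to it
    parent_regime <- regime_parents(tree, p)
    for (r in seq_len(p$n_regimes)[-1])
      theta[r] <- theta[parent_regime[r]] + sample(c(-1, 1), 1) * effect * sdst
    list(trait = sim_ou(tree, p, alpha, sig2, theta),
         shift_edges = p$shift_edges, painting = p, theta = theta)
  }
  list(a = one_phase(edges_a), b = one_phase(edges_b),
       coupling = coupling, alpha = alpha, sig2 = sig2, effect = effect)
}

# For each regime, the regime of the branch ancestral to its shift edge.
regime_parents <- function(tree, painting) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  out <- integer(painting$n_regimes)
  node_regime <- integer(ape::Ntip(tree) + tree$Nnode)
  node_regime[root_node(tree)] <- painting$root_regime
  for (e in seq_len(nrow(tree$edge)))
    node_regime[tree$edge[e, 2]] <- painting$edge_regime[e]
  for (e in painting$shift_edges)
    out[painting$edge_regime[e]] <- node_regime[tree$edge[e, 1]]
  out
}

#' Simulate independent Mk characters on a tree
#'
#' Characters evolve under a symmetric k-state Markov model with total
#' leaving rate `rate` (events/Myr); transition probabilities use the
#' Jukes-Cantor-type closed form. With `rate = 0` all tips inherit the
#' root state.
#'
#' @param tree a `phylo` object.
#' @param nchar number of characters.
#' @param k_states number of states per character (2-10).
#' @param rate total substitution rate per Myr.
#' @param ordered ordered flags for the resulting matrix (the simulation
#'   itself is unordered; flags only affect downstream distance coding).
#' @return a [char_matrix()].
#' @export
simulate_mk <- function(tree, nchar = 20, k_states = 3, rate = 0.05,
                        ordered = FALSE) {
  stopifnot(k_states >= 2, k_states <= 10, rate >= 0)
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- ape::Ntip(tree)
  m <- matrix(NA_integer_, ntip, nchar, dimnames = list(tree$tip.label, NULL))
  k <- k_states
  for (j in seq_len(nchar)) {
    x <- integer(ntip + tree$Nnode)
    x[root_node(tree)] <- sample.int(k, 1) - 1L
    for (e in seq_len(nrow(tree$edge))) {
      p_same <- 1 / k + (1 - 1 / k) * exp(-rate * k / (k - 1) * tree$edge.length[e])
      par <- x[tree$edge[e, 1]]
      x[tree$edge[e, 2]] <- if (runif(1) <= p_same) par else
        sample(setdiff(0:(k - 1L), par), 1)
    }
    m[, j] <- x[seq_len(ntip)]
  }
  char_matrix(m, ordered = ordered)
}

#' Simulate a pair of binary characters under a joint 4-state chain
#'
#' Evolves the joint states (00, 01, 10, 11) of two binary characters by
#' exact Gillespie simulation along each branch under the 8-rate dependent
#' model of [ctmc_loglik()] (rates in the order documented there). Setting
#' the rate pairs equal recovers two independent characters.
#'
#' @param tree a `phylo` object.
#' @param rates8 numeric vector of 8 transition rates.
#' @param root_probs probabilities of the 4 joint root states (default
#'   uniform).
#' @return integer matrix with columns `a` and `b` of tip states (0/1).
#' @export
simulate_dependent_pair <- function(tree, rates8, root_probs = rep(0.25, 4)) {
  Q <- dependent_Q(rates8)
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- ape::Ntip(tree)
  x <- integer(ntip + tree$Nnode)
  x[root_node(tree)] <- sample.int(4, 1, prob = root_probs)
  for (e in seq_len(nrow(tree$edge))) {
    s <- x[tree$edge[e, 1]]
    t_left <- tree$edge.length[e]
    repeat {
      out <- -Q[s, s]
      if (out <= 0) break
      w <- rexp(1, out)
      if (w > t_left) break
      t_left <- t_left - w
      s <- sample.int(4, 1, prob = pmax(Q[s, ], 0))
    }
    x[tree$edge[e, 2]] <- s
  }
  joint <- x[seq_len(ntip)]
  cbind(a = (joint - 1L) %/% 2L, b = (joint - 1L) %% 2L)
}

#' Simulate a two-phase FPKM expression table
#'
#' Baseline expression is log-normal; a controllable fraction of genes
#' receives a multiplicative adult- or tadpole-specific effect strong
#' enough (default 4x) to clear the 1.6 / 0.4 ratio thresholds, a further
#' fraction is expressed below the classification floor in both phases,
#' and morphology-association flags are drawn with class-specific
#' enrichment. Defaults for the enrichment mirror the morphology-gene
#' fractions reported for the two-phase frog transcriptome comparison
#' (24.8% adult-biased, 54.5% tadpole-biased, 16.3% evenly expressed).
#'
#' @param n_genes number of genes.
#' @param frac_adult,frac_tadpole fractions of adult- and tadpole-biased
#'   genes.
#' @param frac_low fraction of genes expressed below `1` FPKM in both
#'   phases (unclassifiable).
#' @param effect multiplicative phase effect for biased genes.
#' @param base_meanlog,base_sdlog log-normal parameters of baseline FPKM.
#' @param noise_sdlog per-phase log-normal measurement noise.
#' @param p_morph named vector of morphology-flag probabilities for
#'   classes `adult`, `tadpole`, `even`.
#' @param seed optional RNG seed.
#' @return data.frame with columns `gene`, `fpkm_adult`, `fpkm_tadpole`,
#'   `annotation`, `morph_flag`, `class_true`.
#' @export
simulate_expression <- function(n_genes = 2000, frac_adult = 0.15,
                                frac_tadpole = 0.15, frac_low = 0.05,
                                effect = 4, base_meanlog = log(10),
                                base_sdlog = 1.5, noise_sdlog = 0.15,
                                p_morph = c(adult = 0.248, tadpole = 0.545,
                                            even = 0.163),
                                seed = NULL) {
  stopifnot(frac_adult >= 0, frac_tadpole >= 0, frac_low >= 0,
            frac_adult + frac_tadpole + frac_low <= 1)
  if (!is.null(seed)) set.seed(seed)
  cls <- sample(c("adult", "tadpole", "low", "even"), n_genes, replace = TRUE,
                prob = c(frac_adult, frac_tadpole, frac_low,
                         1 - frac_adult - frac_tadpole - frac_low))
  base <- rlnorm(n_genes, base_meanlog, base_sdlog)
  base[cls == "low"] <- rlnorm(sum(cls == "low"), log(0.1), 0.5)
  fa <- base * exp(rnorm(n_genes, 0, noise_sdlog))
  ft <- base * exp(rnorm(n_genes, 0, noise_sdlog))
  fa[cls == "adult"] <- fa[cls == "adult"] * effect
  ft[cls == "tadpole"] <- ft[cls == "tadpole"] * effect
  pm <- ifelse(cls == "adult", p_morph[["adult"]],
        ifelse(cls == "tadpole", p_morph[["tadpole"]], p_morph[["even"]]))
  flag <- runif(n_genes) < pm
  data.frame(gene = sprintf("g%04d", seq_len(n_genes)),
             fpkm_adult = fa, fpkm_tadpole = ft,
             annotation = annotation_text(flag),
             morph_flag = flag, class_true = cls,
             stringsAsFactors = FALSE)
}

# GO-style annotation snippets; flagged genes carry a morphology term.
morphology_terms <- c("osteoclast differentiation",
                      "skeletal system development",
                      "cartilage condensation", "keratinization",
                      "limb morphogenesis", "cranial skeleton development",
                      "bone mineralization", "tail fin morphogenesis")
other_terms <- c("oxidative phosphorylation", "mRNA splicing",
                 "ion transport", "translation initiation",
                 "lipid metabolic process", "DNA repair",
                 "proteolysis", "signal transduction")

annotation_text <- function(flag) {
  n <- length(flag)
  a <- sample(other_terms, n, replace = TRUE)
  b <- sample(other_terms, n, replace = TRUE)
  a[flag] <- sample(morphology_terms, sum(flag), replace = TRUE)
  paste(a, b, sep = "; ")
}
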