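# Multi-locus protein evolution simulator along a time tree.
#
# Sites evolve under a 20-state continuous-time Markov chain. The default
# model is the equal-rates (Jukes-Cantor-type) amino-acid chain, whose
# transition probability has the closed form
#   P(same | d) = 1/20 + (19/20) exp(-(20/19) d)
# where d is the expected number of substitutions per site on the branch.
# This keeps an analytic oracle available for every downstream check:
#   E[p-distance] = (19/20) (1 - exp(-(20/19) d_path)).
# A general reversible model can be supplied as a 20x20 exchangeability
# matrix + equilibrium frequencies and is handled via eigendecomposition.
#
# Branch expected distance: d_e = mu * (t_e/100) * branch_rate * locus_scalar
# * site_rate, with mu in substitutions/site/100 MY. Lineage-specific rates
# (e.g. rodent-fast, marsupial-slow) enter through branch_rate multipliers
# keyed by the branch's child node name.

#' Simulation configuration
#'
#' @param tree A `time_tree` (branch lengths in MY).
#' @param mu Baseline rate, substitutions per site per 100 MY.
#' @param loci Data frame with columns `name`, `length` and optionally
#'   `scalar` (per-locus rate scalar, default 1).
#' @param branch_rate Named numeric vector of per-branch rate multipliers
#'   keyed by child-node name (tips by taxon name, internal nodes by their
#'   label; unnamed internal nodes are auto-named `nodeK` in post-order).
#'   Unlisted branches get 1.
#' @param gamma_shape Optional gamma shape for site-rate heterogeneity.
#' @param gamma_categories Discrete gamma category count (default 4).
#' @param dropout Optional data frame with columns `locus`, `taxon`:
#'   these sequences are omitted from the emitted alignments (emulating
#'   unannotated subunits).
#' @param seed Integer seed.
#' @param freqs Equilibrium frequencies (default uniform 1/20).
#' @param exchangeability Optional symmetric 20x20 exchangeability matrix
#'   for a general reversible model.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(tree, mu, loci, branch_rate = NULL,
                       gamma_shape = NULL, gamma_categories = 4,
                       dropout = NULL, seed = 1,
                       freqs = rep(1 / 20, 20), exchangeability = NULL) {
  stopifnot(inherits(tree, "time_tree"))
  if (mu <= 0) stop("config error: mu must be > 0", call. = FALSE)
  if (!all(c("name", "length") %in% names(loci)))
    stop("config error: loci needs columns name, length", call. = FALSE)
  if (is.null(loci$scalar)) loci$scalar <- 1
  if (any(loci$length < 1) || any(loci$scalar <= 0))
    stop("config error: locus lengths >= 1 and scalars > 0", call. = FALSE)
  if (!is.null(branch_rate) && any(branch_rate <= 0))
    stop("config error: branch rate multipliers must be > 0", call. = FALSE)
  if (length(freqs) != 20 || abs(sum(freqs) - 1) > 1e-9 || any(freqs < 0))
    stop("config error: freqs must be 20 non-negative values summing to 1",
         call. = FALSE)
  if (!is.null(gamma_shape) && gamma_shape <= 0)
    stop("config error: gamma shape must be > 0", call. = FALSE)
  if (!is.null(exchangeability)) {
    if (!is.matrix(exchangeability) || any(dim(exchangeability) != 20) ||
        max(abs(exchangeability - t(exchangeability))) > 1e-9)
      stop("config error: exchangeability must be a symmetric 20x20 matrix",
           call. = FALSE)
  }
  phy <- name_internal_nodes(tree$phy)
  structure(
    list(tree = structure(list(phy = phy, ages = tree$ages), class = "time_tree"),
         mu = mu, loci = loci, branch_rate = branch_rate,
         gamma_shape = gamma_shape, gamma_categories = gamma_categories,
         dropout = dropout, seed = as.integer(seed), freqs = freqs,
         exchangeability = exchangeability),
    class = "sim_config"
  )
}

# Deterministic auto-naming of unnamed internal nodes (post-order).
name_internal_nodes <- function(phy) {
  if (is.null(phy$node.label)) phy$node.label <- rep("", phy$Nnode)
  empty <- which(phy$node.label == "" | is.na(phy$node.label))
  if (length(empty) > 0) {
    ntip <- length(phy$tip.label)
    post <- unique(stats::reorder(phy, "postorder")$edge[, 1])
    rank <- match(empty + ntip, post)
    rank[is.na(rank)] <- length(post) + 1   # root of a postorder edge list
    phy$node.label[empty] <- paste0("node", rank)
  }
  phy
}

# Node name lookup (tips + internal labels) in ape numbering.
node_names <- function(phy) {
  c(phy$tip.label, phy$node.label)
}

# Mean relative rate of each equal-probability discrete gamma category
# (mean-per-category discretization; rates ~ Gamma(shape, shape)).
discrete_gamma_rates <- function(shape, ncat = 4) {
  q <- stats::qgamma(seq(0, 1, length.out = ncat + 1), shape = shape, rate = shape)
  means <- ncat * (stats::pgamma(q[-1], shape = shape + 1, rate = shape) -
                   stats::pgamma(q[-(ncat + 1)], shape = shape + 1, rate = shape))
  means / mean(means) * 1   # normalize exactly to mean 1
}

# Per-edge expected substitutions/site at unit locus scalar & site rate.
edge_expected_distance <- function(config) {
  phy <- config$tree$phy
  nm <- node_names(phy)
  rates <- rep(1, nrow(phy$edge))
  if (!is.null(config$branch_rate)) {
    child <- nm[phy$edge[, 2]]
    hit <- child %in% names(config$branch_rate)
    rates[hit] <- config$branch_rate[child[hit]]
  }
  config$mu * (phy$edge.length / 100) * rates
}

# Eigendecomposition of a reversible rate matrix Q built from
# exchangeability S and frequencies pi, scaled to 1 expected
# substitution/site per unit time.
build_general_model <- function(exchangeability, freqs) {
  Q <- exchangeability %*% diag(freqs)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))
  Q <- Q / scale
  # symmetrize for stable eigen: B = D^(1/2) Q D^(-1/2)
  sq <- sqrt(freqs)
  B <- diag(sq) %*% Q %*% diag(1 / sq)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(values = e$values,
       right = diag(1 / sq) %*% e$vectors,
       left = t(e$vectors) %*% diag(sq))
}

transition_matrix_general <- function(model, d) {
  P <- model$right %*% diag(exp(model$values * d)) %*% model$left
  P[P < 0] <- 0
  P / rowSums(P)
}

# Evolve a vector of states (integers 1..20) along one branch.
# d_site: per-site expected distance vector.
evolve_branch_equal_rates <- function(states, d_site) {
  p_same <- 1 / 20 + (19 / 20) * exp(-(20 / 19) * d_site)
  change <- stats::runif(length(states)) >= p_same
  n_change <- sum(change)
  if (n_change > 0) {
    # uniform over the 19 other states
    shift <- sample.int(19, n_change, replace = TRUE)
    states[change] <- ((states[change] - 1 + shift) %% 20) + 1
  }
  states
}

evolve_branch_general <- function(states, d_site, model) {
  out <- states
  for (d in unique(d_site)) {
    P <- transition_matrix_general(model, d)
    idx <- which(d_site == d)
    cum <- t(apply(P, 1, cumsum))
    u <- stats::runif(length(idx))
    out[idx] <- vapply(seq_along(idx), function(k) {
      which(u[k] <= cum[states[idx[k]], ])[1]
    }, integer(1))
  }
  out
}

#' Simulate multi-locus protein alignments along a time tree
#'
#' Root sequences are drawn from the equilibrium frequencies; each branch
#' then evolves every site under the configured Markov chain with branch
#' expected distance `mu * (t/100) * branch_rate * locus_scalar *
#' site_rate`. No indels are simulated: the true alignment is exact, and
#' gaps enter downstream only via dropout and gap-fill concatenation.
#'
#' @param config A [sim_config].
#' @return A `sim_result`: list with `loci` (list of [locus_alignment]),
#'   `tree` (the node-named `time_tree`), `site_rates` (per-locus rate
#'   category draws) and `manifest` (everything needed to regenerate).
#' @export
simulate_alignments <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  phy <- config$tree$phy
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  # preorder traversal (cladewise): parents always precede children
  pre <- stats::reorder(phy, "cladewise")
  ord <- match(paste(pre$edge[, 1], pre$edge[, 2]),
               paste(phy$edge[, 1], phy$edge[, 2]))
  edges <- phy$edge[ord, , drop = FALSE]
  base_d <- edge_expected_distance(config)[ord]
  gamma_rates <- if (!is.null(config$gamma_shape))
    discrete_gamma_rates(config$gamma_shape, config$gamma_categories) else 1
  model <- if (!is.null(config$exchangeability))
    build_general_model(config$exchangeability, config$freqs) else NULL

  loci_out <- vector("list", nrow(config$loci))
  site_rates_out <- vector("list", nrow(config$loci))
  for (k in seq_len(nrow(config$loci))) {
    L <- config$loci$length[k]
    scalar <- config$loci$scalar[k]
    site_rate <- if (length(gamma_rates) > 1)
      gamma_rates[sample.int(length(gamma_rates), L, replace = TRUE)]
    else rep(1, L)
    seqs <- matrix(NA_integer_, nrow = ntip + phy$Nnode, ncol = L)
    seqs[root, ] <- sample.int(20, L, replace = TRUE, prob = config$freqs)
    for (e in seq_len(nrow(edges))) {
      parent <- edges[e, 1]; child <- edges[e, 2]
      d_site <- base_d[e] * scalar * site_rate
      seqs[child, ] <- if (is.null(model))
        evolve_branch_equal_rates(seqs[parent, ], d_site)
      else evolve_branch_general(seqs[parent, ], d_site, model)
    }
    members <- apply(seqs[seq_len(ntip), , drop = FALSE], 1, function(s)
      paste(AA_LETTERS[s], collapse = ""))
    names(members) <- phy$tip.label
    # dropout: omit unannotated (locus, taxon) combinations
    if (!is.null(config$dropout)) {
      drop_tx <- config$dropout$taxon[config$dropout$locus == config$loci$name[k]]
      members <- members[!(names(members) %in% drop_tx)]
    }
    loci_out[[k]] <- locus_alignment(config$loci$name[k], members)
    site_rates_out[[k]] <- site_rate
  }
  names(loci_out) <- config$loci$name
  names(site_rates_out) <- config$loci$name
  structure(
    list(loci = loci_out, tree = config$tree, site_rates = site_rates_out,
         manifest = list(
           seed = config$seed, mu = config$mu, loci = config$loci,
           branch_rate = config$branch_rate, gamma_shape = config$gamma_shape,
           gamma_categories = config$gamma_categories,
           dropout = config$dropout, freqs = config$freqs,
           newick = ape::write.tree(phy)
         )),
    class = "sim_result"
  )
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result: %d loci, %d taxa, seed %d>\n",
              length(x$loci), length(x$tree$phy$tip.label), x$manifest$seed))
  invisible(x)
}

#' Expected p-distance between two leaves (analytic oracle)
#'
#' For the equal-rates model,
#' `p_exp = (19/20) (1 - exp(-(20/19) d_path))` with `d_path` the summed
#' branch expected distances on the path between the leaves. With gamma
#' site-rate heterogeneity, the mean over discrete categories. General
#' exchangeability models have no closed form here and raise an error
#' (compare by Monte-Carlo instead).
#'
#' @param config A [sim_config].
#' @param taxonA,taxonB Leaf names.
#' @param locus Locus name (for its rate scalar).
#' @return Expected proportion of differing sites.
#' @export
expected_p <- function(config, taxonA, taxonB, locus) {
  if (!is.null(config$exchangeability))
    stop("unsupported-oracle error: closed form requires the equal-rates model",
         call. = FALSE)
  k <- match(locus, config$loci$name)
  if (is.na(k)) stop(sprintf("unknown locus '%s'", locus), call. = FALSE)
  d_path <- path_expected_distance(config, taxonA, taxonB) * config$loci$scalar[k]
  p_of_d <- function(d) (19 / 20) * (1 - exp(-(20 / 19) * d))
  if (is.null(config$gamma_shape)) return(p_of_d(d_path))
  rates <- discrete_gamma_rates(config$gamma_shape, config$gamma_categories)
  mean(p_of_d(d_path * rates))
}

# Summed expected substitutions/site (unit scalar) on the A<->B path.
path_expected_distance <- function(config, taxonA, taxonB) {
  phy <- config$tree$phy
  ia <- match(taxonA, phy$tip.label)
  ib <- match(taxonB, phy$tip.label)
  if (is.na(ia) || is.na(ib))
    stop("lookup error: unknown taxon for expected_p", call. = FALSE)
  if (ia == ib) return(0)
  d_edge <- edge_expected_distance(config)
  path_nodes <- ape::nodepath(phy, ia, ib)
  d <- 0
  for (s in seq_len(length(path_nodes) - 1)) {
    a <- path_nodes[s]; b <- path_nodes[s + 1]
    e <- which((phy$edge[, 1] == a & phy$edge[, 2] == b) |
               (phy$edge[, 1] == b & phy$edge[, 2] == a))
    d <- d + d_edge[e]
  }
  d
}

#' Fixed 15-taxon therian study dataset
#'
#' Emulates the structure of the real analysis: a time-calibrated tree of
#' five clades — primates (4), rodents (4), Laurasiatherians (3),
#' Afrotherians (2) and marsupials (2, splitting from eutherians at 160
#' MYA and from each other at 82 MYA) — with ten loci named after the
#' CatSper subunits, rodent stem-and-crown branches evolving at 2x the
#' baseline and marsupial branches at 0.5x, and one marsupial taxon
#' (the opossum-like tip) missing the CatSperz locus, as in genomes where
#' that subunit is not annotated.
#'
#' Locus lengths are the real subunit lengths scaled to a ~2,600-column
#' supermatrix; the baseline rate mu = 0.25 substitutions/site/100 MY
#' places raw p-distances in the empirically observed range, with the
#' deepest pairs approaching the 0.6 display cap.
#'
#' @param seed Integer seed.
#' @param mu Baseline substitution rate per site per 100 MY.
#' @return List with `sim` (a `sim_result`), `config`, `clades` (named
#'   vector taxon -> clade) and `tree` (the `time_tree`).
#' @export
make_paper_like_dataset <- function(seed = 1, mu = 0.25) {
  newick <- paste0(
    "(((((((Hsapiens:29,Mmulatta:29):14,Cjacchus:43):31,Ogarnettii:74)",
    "Primates:16,(Itridecemlineatus:70,(Hglaber:60,(Mmusculus:25,",
    "Pmaniculatus:25)Murinae:35)Myomorpha:10)Rodentia:20)",
    "Euarchontoglires:6,(Ecaballus:76,(Btaurus:56,Oorcinus:56)",
    "Cetartiodactyla:20)Laurasiatheria:20)Boreoeutheria:3,",
    "(Lafricana:65,Tmanatus:65)Afrotheria:34)Eutheria:61,",
    "(Mdomestica:82,Sharrisii:82)Marsupialia:78)Theria;"
  )
  tree <- read_timetree(newick)
  clades <- c(
    Hsapiens = "primates", Mmulatta = "primates", Cjacchus = "primates",
    Ogarnettii = "primates",
    Itridecemlineatus = "rodents", Hglaber = "rodents",
    Mmusculus = "rodents", Pmaniculatus = "rodents",
    Ecaballus = "Laurasiatherians", Btaurus = "Laurasiatherians",
    Oorcinus = "Laurasiatherians",
    Lafricana = "Afrotherians", Tmanatus = "Afrotherians",
    Mdomestica = "marsupials", Sharrisii = "marsupials"
  )
  # real subunit lengths x 0.4 (CatSper1..4, beta, gamma, delta, epsilon,
  # zeta, EFCAB9)
  loci <- data.frame(
    name = c("CatSper1", "CatSper2", "CatSper3", "CatSper4", "CatSperB",
             "CatSperG", "CatSperD", "CatSperE", "CatSperZ", "EFCAB9"),
    length = c(312L, 235L, 158L, 177L, 444L, 430L, 322L, 378L, 78L, 72L),
    scalar = c(1, 1, 1, 1, 1, 1, 1, 1, 1.3, 1.1),
    stringsAsFactors = FALSE
  )
  fast <- c("Rodentia", "Itridecemlineatus", "Myomorpha", "Hglaber",
            "Murinae", "Mmusculus", "Pmaniculatus")
  slow <- c("Marsupialia", "Mdomestica", "Sharrisii")
  branch_rate <- stats::setNames(
    c(rep(2.0, length(fast)), rep(0.5, length(slow))), c(fast, slow))
  dropout <- data.frame(locus = "CatSperZ", taxon = "Mdomestica",
                        stringsAsFactors = FALSE)
  config <- sim_config(tree, mu = mu, loci = loci, branch_rate = branch_rate,
                       dropout = dropout, seed = seed)
  list(sim = simulate_alignments(config), config = config,
       clades = clades, tree = config$tree)
}
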