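#' Expected number of extant lineages of a crown birth-death process
#'
#' Starting from the two crown lineages, the expected extant diversity after
#' time `depth` is `2 * exp((lambda - mu) * depth)` (no survival
#' conditioning).
#'
#' @param lambda,mu Speciation and extinction rates.
#' @param depth Elapsed time since the crown.
#' @return Expected number of extant lineages.
#' @export
expected_N <- function(lambda, mu, depth) {
  stopifnot(depth >= 0)
  2 * exp((lambda - mu) * depth)
}

#' Solve rates from a target expected richness
#'
#' Inverts [expected_N()] for a fixed extinction fraction
#' `epsilon = mu / lambda`: `lambda = log(expected_n / 2) / (depth * (1 -
#' epsilon))` and `mu = epsilon * lambda`. This is how the simulation-study
#' parameter grids are set up: vary net diversification to hit a target
#' `E(N)` while holding relative turnover constant.
#'
#' @param expected_n Target expected number of extant lineages (> 2).
#' @param depth Tree depth T.
#' @param extinction_fraction `epsilon = mu / lambda` in `[0, 1)`.
#' @return List with `lambda` and `mu`.
#' @export
rates_from_EN <- function(expected_n, depth, extinction_fraction = 0.25) {
  stopifnot(expected_n > 2, depth > 0,
            extinction_fraction >= 0, extinction_fraction < 1)
  lambda <- log(expected_n / 2) / (depth * (1 - extinction_fraction))
  list(lambda = lambda, mu = extinction_fraction * lambda)
}

# Internal seed-stream derivation: replicate r of a run seeded with `seed`
# uses its own derived seed, so experiments are reproducible replicate by
# replicate. Kept strictly below 2^31.
.derive_seed <- function(seed, r) {
  as.integer((as.double(seed) %% 2147483629 * 48271 +
                as.double(r) * 16807) %% 2147483629) + 1L
}

# Forward Gillespie simulation of a crown birth-death process for duration
# `depth`: waiting times are exponential at total rate n(lambda+mu), the
# event is a birth with probability lambda/(lambda+mu), and the affected
# lineage is uniform among those alive. Lineages are stored as a table
# (parent, birth time, death time); td = Inf marks survival to the present.
.sim_bd_lineages <- function(lambda, mu, depth, max_lineages = 2e5) {
  cap <- 256L
  parent <- integer(cap); tb <- numeric(cap); td <- rep(Inf, cap)
  parent[1:2] <- c(0L, 1L); tb[1:2] <- 0
  L <- 2L
  alive <- c(1L, 2L)
  t <- 0
  total_rate <- lambda + mu
  if (total_rate > 0) {
    p_birth <- lambda / total_rate
    repeat {
      n <- length(alive)
      if (n == 0L) break
      t <- t + stats::rexp(1L, n * total_rate)
      if (t >= depth) break
      pick <- sample.int(n, 1L)
      k <- alive[pick]
      if (stats::runif(1L) < p_birth) {
        L <- L + 1L
        if (L > cap) {
          if (L > max_lineages) {
            stop("simulation exceeded ", max_lineages,
                 " lineages; rates too high for this depth", call. = FALSE)
          }
          cap <- cap * 2L
          parent <- c(parent, integer(cap / 2L))
          tb <- c(tb, numeric(cap / 2L))
          td <- c(td, rep(Inf, cap / 2L))
        }
        parent[L] <- k; tb[L] <- t
        alive <- c(alive, L)
      } else {
        td[k] <- t
        alive <- alive[-pick]
      }
    }
  }
  list(parent = parent[seq_len(L)], tb = tb[seq_len(L)], td = td[seq_len(L)],
       L = L, alive = alive)
}

# Convert the lineage table of a completed simulation into a binary `phylo`
# containing every lineage (extinct included). Each lineage contributes one
# tip (its terminal segment) and, for lineages 2..L, one internal node (its
# birth event); the crown event (birth of lineage 2 at time 0) is the root.
.lineages_to_phylo <- function(parent, tb, td, depth) {
  L <- length(parent)
  end_t <- pmin(td, depth)
  kids_of <- split(2:L, parent[2:L])
  nE <- 2L * L - 2L
  e1 <- integer(nE); e2 <- integer(nE); el <- numeric(nE)
  pos <- 0L
  for (k in seq_len(L)) {
    kids <- kids_of[[as.character(k)]]
    if (k >= 2L) {
      seq_nodes <- c(L + k - 1L, if (length(kids)) L + kids - 1L, k)
      seq_t <- c(tb[k], tb[kids], end_t[k])
    } else {
      seq_nodes <- c(if (length(kids)) L + kids - 1L, k)
      seq_t <- c(tb[kids], end_t[k])
    }
    nn <- length(seq_nodes)
    idx <- pos + seq_len(nn - 1L)
    e1[idx] <- seq_nodes[-nn]
    e2[idx] <- seq_nodes[-1L]
    el[idx] <- diff(seq_t)
    pos <- pos + nn - 1L
  }
  phy <- structure(list(
    edge = cbind(e1, e2),
    edge.length = el,
    tip.label = paste0("t", seq_len(L)),
    Nnode = L - 1L
  ), class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

#' Simulate a reconstructed crown birth-death tree
#'
#' Simulates a birth-death process forward in time from the two crown
#' lineages for a fixed duration `depth`, then prunes extinct lineages and
#' (when `rho < 1`) randomly unsampled tips to obtain the reconstructed
#' tree. A replicate is accepted only if both crown lineages leave at least
#' one sampled descendant — so the reconstructed crown age equals `depth`
#' deterministically, matching the crown-age conditioning of the likelihood
#' — and the pre-sampling extant tip count is at least `min_tips`. Rejected
#' replicates are redrawn.
#'
#' @param lambda,mu Speciation and extinction rates (per lineage per unit
#'   time).
#' @param depth Total tree depth T (crown age of every accepted tree).
#' @param rho Sampling fraction: each extant tip is retained independently
#'   with this probability after pruning extinct lineages. Default 1.
#' @param min_tips Minimum extant (pre-sampling) tip count for acceptance;
#'   default 5, the rejection rule used in the power studies. Set to 2 to
#'   disable beyond the survival requirement.
#' @param n_target Optional exact sampled tip count to condition on
#'   (matched by rejection).
#' @param seed Optional RNG seed.
#' @param max_rejections Error after this many consecutive rejected
#'   replicates.
#' @return A reconstructed ultrametric `phylo` with attributes `n_extant`
#'   (pre-sampling extant count) and `n_sampled` (tip count after
#'   subsampling).
#' @export
simulate_crown_bd <- function(lambda, mu, depth, rho = 1, min_tips = 5,
                              n_target = NULL, seed = NULL,
                              max_rejections = 1e6) {
  stopifnot(lambda >= 0, mu >= 0, depth > 0, rho > 0, rho <= 1,
            min_tips >= 2)
  if (!is.null(n_target) && n_target < 2) stop("n_target must be >= 2",
                                               call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  for (attempt in seq_len(max_rejections)) {
    sim <- .sim_bd_lineages(lambda, mu, depth)
    n_extant <- length(sim$alive)
    if (n_extant < max(min_tips, 2L)) next
    # crown side of each lineage (parents always precede children)
    side <- integer(sim$L)
    side[1:2] <- c(1L, 2L)
    if (sim$L > 2L) {
      for (j in 3:sim$L) side[j] <- side[sim$parent[j]]
    }
    if (length(unique(side[sim$alive])) < 2L) next
    sampled <- sim$alive
    if (rho < 1) {
      sampled <- sampled[stats::runif(n_extant) < rho]
      if (length(sampled) < 2L) next
      if (length(unique(side[sampled])) < 2L) next
    }
    if (!is.null(n_target) && length(sampled) != n_target) next
    full <- .lineages_to_phylo(sim$parent, sim$tb, sim$td, depth)
    rec <- if (length(sampled) == sim$L) full else {
      ape::keep.tip(full, paste0("t", sampled))
    }
    attr(rec, "n_extant") <- n_extant
    attr(rec, "n_sampled") <- length(sampled)
    return(rec)
  }
  stop("no acceptable tree after ", max_rejections, " rejections; ",
       "the acceptance probability is too low for lambda=", lambda,
       ", mu=", mu, ", depth=", depth,
       " — consider different rates or a lower min_tips/n_target",
       call. = FALSE)
}

#' Simulate a Yule tree conditioned on both tip count and crown age
#'
#' Generates a pure-birth tree with exactly `n` tips and crown age exactly
#' `depth`. Conditional on those, the `n - 2` non-crown node ages of a Yule
#' tree are independent draws from the truncated density with CDF
#' `F(t) = (1 - exp(-lambda t)) / (1 - exp(-lambda T))` on `(0, T)`, which is
#' inverted analytically; the topology is built by letting a uniformly
#' chosen extant lineage split at each branching event, in age order.
#'
#' @param lambda Speciation rate (> 0).
#' @param n Number of tips (>= 2).
#' @param depth Crown age T (> 0).
#' @param seed Optional RNG seed.
#' @return An ultrametric `phylo` with `n` tips and depth `depth`.
#' @export
simulate_yule_NT <- function(lambda, n, depth, seed = NULL) {
  stopifnot(lambda > 0, n >= 2, depth > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  ages <- depth
  if (n > 2L) {
    u <- stats::runif(n - 2L)
    drawn <- -log1p(-u * (1 - exp(-lambda * depth))) / lambda
    ages <- c(depth, sort(drawn, decreasing = TRUE))
  }
  # sequential construction root -> present; internal ids n+1, n+2, ... in
  # age order so the root is n+1
  nE <- 2L * n - 2L
  e1 <- integer(nE); e2 <- integer(nE); el <- numeric(nE)
  pos <- 0L
  root <- n + 1L
  next_internal <- n + 2L
  act_parent <- c(root, root)
  act_age <- c(ages[1], ages[1])
  for (a in ages[-1]) {
    i <- sample.int(length(act_parent), 1L)
    v <- next_internal; next_internal <- next_internal + 1L
    pos <- pos + 1L
    e1[pos] <- act_parent[i]; e2[pos] <- v; el[pos] <- act_age[i] - a
    act_parent[i] <- v; act_age[i] <- a
    act_parent <- c(act_parent, v); act_age <- c(act_age, a)
  }
  for (i in seq_along(act_parent)) {
    pos <- pos + 1L
    e1[pos] <- act_parent[i]; e2[pos] <- i; el[pos] <- act_age[i]
  }
  phy <- structure(list(
    edge = cbind(e1, e2),
    edge.length = el,
    tip.label = paste0("t", seq_len(n)),
    Nnode = n - 1L
  ), class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

#' Randomly subsample the tips of a tree
#'
#' Retains each tip independently with probability `rho` and prunes the
#' rest, preserving the branch-length geometry (all pairwise divergence
#' times) among the survivors — the missing-at-random incomplete-sampling
#' model.
#'
#' @param tree A `phylo`.
#' @param rho Retention probability in `(0, 1]`.
#' @param seed Optional RNG seed.
#' @return The pruned `phylo`; an error if fewer than 2 tips survive (the
#'   caller decides whether to redraw).
#' @export
subsample_tips <- function(tree, rho, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), rho > 0, rho <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (rho == 1) return(tree)
  keep <- stats::runif(ape::Ntip(tree)) < rho
  if (sum(keep) < 2L) {
    stop("fewer than 2 tips survived subsampling at rho = ", rho,
         call. = FALSE)
  }
  ape::keep.tip(tree, which(keep))
}
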