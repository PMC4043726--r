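# Independent brute-force oracles, implemented with different code paths
# than the package internals they check.

# variable / parsimony-informative site counts by direct column enumeration
oracle_variable_sites <- function(seqs, gap_as_state = FALSE) {
  variable <- 0L
  informative <- 0L
  for (j in seq_len(ncol(seqs))) {
    col <- seqs[, j]
    if (!gap_as_state && "-" %in% col) next
    col <- col[col != "N"]
    if (!gap_as_state) col <- col[col != "-"]
    states <- unique(col)
    if (length(states) >= 2L) {
      variable <- variable + 1L
      n_per <- vapply(states, function(s) sum(col == s), 1L)
      if (sum(n_per >= 2L) >= 2L) informative <- informative + 1L
    }
  }
  c(variable = variable, parsimony_informative = informative)
}

# minimum-spanning-network oracle: an edge (i, j) with d = D[i, j] <= limit
# belongs to the network iff i and j are not connected by any path in the
# complete graph restricted to pairs at distance strictly below d.
# Reachability by hand-rolled BFS (no igraph, no union-find).
oracle_msn_edges <- function(D, limit) {
  n <- nrow(D)
  reachable <- function(adj, from, to) {
    seen <- rep(FALSE, n)
    queue <- from
    seen[from] <- TRUE
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (v == to) return(TRUE)
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    FALSE
  }
  edges <- NULL
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in (i + 1L):n) {
      d <- D[i, j]
      if (d > limit) next
      adj <- D < d
      diag(adj) <- FALSE
      adj[D > limit] <- FALSE  # pairs beyond the limit are never usable
      if (!reachable(adj, i, j)) {
        edges <- rbind(edges, c(i, j, d))
      }
    }
  }
  edges
}

# exact one-way two-group permutation p by group-assignment enumeration,
# with F computed by lm/anova (fully independent of the package internals)
oracle_exhaustive_p <- function(y, g) {
  g <- as.factor(g)
  n1 <- sum(g == levels(g)[1L])
  f_of <- function(gg) {
    # perfect separation warns about unreliable F; the Inf branch below
    # handles it deliberately
    tab <- suppressWarnings(anova(lm(y ~ gg)))
    f <- tab[["F value"]][1L]
    if (is.nan(f)) f <- 0
    if (!is.finite(f) || tab[["Mean Sq"]][2L] < 1e-12) {
      f <- if (tab[["Sum Sq"]][1L] > 1e-12) Inf else 0
    }
    f
  }
  f_obs <- f_of(g)
  combos <- combn(length(y), n1)
  f_all <- apply(combos, 2L, function(idx) {
    gg <- factor(ifelse(seq_along(y) %in% idx, "A", "B"))
    f_of(gg)
  })
  # assignments tied with the observed F in exact arithmetic (e.g. group
  # sums symmetric about the grand mean) differ here only by round-off;
  # count them as reaching the observed statistic
  thr <- if (is.finite(f_obs)) f_obs - 1e-8 * (1 + abs(f_obs)) else f_obs
  mean(f_all >= thr)
}

# random small ANOVA designs satisfying the package preconditions
rand_one_way <- function(n_groups = sample(2:4, 1L)) {
  sizes <- sample(2:6, n_groups, replace = TRUE)
  data.frame(
    pd = round(rnorm(sum(sizes), 5, 3), 2),
    sex = factor(rep(LETTERS[seq_len(n_groups)], sizes))
  )
}

rand_two_way <- function() {
  repeat {
    sizes <- matrix(sample(2:5, 4L, replace = TRUE), 2L)
    if (all(sizes >= 2L)) break
  }
  d <- expand.grid(sex = c("F", "M"), region = c("NW", "rest"))
  d <- d[rep(seq_len(4L), as.vector(sizes)), ]
  d$pd <- round(rnorm(nrow(d), 5, 3), 2)
  d$sex <- factor(d$sex)
  d$region <- factor(d$region)
  d
}

# random recoded-allele vectors sharing a schema; N is excluded because a
# pairwise-skipped missing state is outside the metric state space
rand_recoded_pair <- function(n_snp = 12L, n_rep = 2L, n_ind = 1L) {
  mk <- function() {
    list(snp = sample(c("A", "C", "G", "T", "-"), n_snp, replace = TRUE,
                      prob = c(rep(0.225, 4), 0.1)),
         repeats = sample(0:9, n_rep, replace = TRUE),
         indels = sample(0:1, n_ind, replace = TRUE))
  }
  list(mk(), mk(), mk())
}

# build a tiny aligned_marker from plain strings
mk_marker <- function(seqs, labels, name = "toy") {
  aligned_marker(seqs, labels, name)
}

toy_regions <- function() {
  region_map(1:30, c(rep("SE_refugia", 10), rep("Pannonian", 9),
                     rep("NW_Europe", 11)))
}

# small, fast simulator settings for Monte-Carlo loops (overridable)
fast_params <- function(seed, ...) {
  base <- list(seq_len = 200L, sub_rate = 8e-5, t_burnin = 80L,
               t_pann_gap = 30L, t_split = 40L, deme_females = 12L,
               deme_males = 12L, pann_founders = 6L, bottleneck = 4L,
               repeat_step_rate = 1e-3, indel_rate = 0,
               n_sample = list(SE_refugia = c(F = 4L, M = 4L),
                               Pannonian = c(F = 4L, M = 4L),
                               NW_Europe = c(F = 4L, M = 4L)),
               seed = seed)
  over <- list(...)
  base[names(over)] <- over
  do.call(sim_params, base)
}
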