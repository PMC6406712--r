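# Independent brute-force oracles used across the suite. These stay
# deliberately naive: textbook formulas and exhaustive enumeration, never
# calls into the code paths they check.

# Pearson r by the raw textbook formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# Spearman rho via rank-then-Pearson
oracle_spearman_rho <- function(x, y) oracle_pearson(rank(x), rank(y))

# Hypergeometric upper tail P(X >= k) by exhaustive enumeration of all
# C(|U|, n) possible draws; exact for small universes.
oracle_hyper_enum <- function(universe, pathway, query) {
  n <- length(query)
  k_obs <- length(intersect(query, pathway))
  draws <- combn(universe, n)
  hits <- apply(draws, 2, function(d) length(intersect(d, pathway)))
  mean(hits >= k_obs)
}

# Betweenness centrality by brute-force enumeration of all simple paths:
# for each unordered pair (s, t), count shortest paths and the fraction
# passing through each interior vertex.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  bc <- numeric(n)
  all_paths <- function(s, t, visited) {
    if (s == t) return(list(t))
    out <- list()
    for (v in which(adj[s, ] == 1)) {
      if (v %in% visited) next
      for (p in all_paths(v, t, c(visited, v)))
        out[[length(out) + 1L]] <- c(s, p)
    }
    out
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- all_paths(s, t, s)
    if (length(paths) == 0) next
    lens <- vapply(paths, length, 0L)
    sp <- paths[lens == min(lens)]
    for (p in sp) {
      interior <- setdiff(p, c(s, t))
      bc[interior] <- bc[interior] + 1 / length(sp)
    }
  }
  bc
}

# Minimal hand-built injection table: `blocks` is a named list of
# intensity matrices (features x injections) keyed by type.
manual_table <- function(study = NULL, qc = NULL, blank = NULL,
                         dilution = NULL, volumes = NULL, log2 = FALSE) {
  blocks <- list(study = study, qc = qc, blank = blank, dilution = dilution)
  blocks <- blocks[!vapply(blocks, is.null, TRUE)]
  M <- do.call(cbind, blocks)
  P <- nrow(M)
  types <- rep(names(blocks), vapply(blocks, ncol, 0L))
  O <- length(types)
  n_study <- sum(types == "study")
  inj <- data.frame(injection_id = sprintf("I%03d", seq_len(O)),
                    type = types, injection_order = seq_len(O),
                    sample_id = ifelse(types == "study",
                                       sprintf("S%03d", cumsum(types == "study")),
                                       NA_character_),
                    volume = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(dilution)) inj$volume[types == "dilution"] <- volumes
  colnames(M) <- inj$injection_id
  rownames(M) <- sprintf("F%03d", seq_len(P))
  injection_table(M, inj,
                  data.frame(feature_id = rownames(M),
                             mz = seq(100, 200, length.out = P),
                             rt = seq(60, 600, length.out = P)),
                  log2 = log2)
}

# A small, fast simulation config for tests
small_cfg <- function(seed = 1, ...) {
  sim_config(n_per_group = c(control = 6L, RRMS = 12L, SPMS = 8L),
             n_features = 60L, qc_interval = 5L, seed = seed, ...)
}

table2_fixture <- function() read.delim(
  system.file("extdata", "table_sprr_altered.tsv", package = "csfmet"),
  stringsAsFactors = FALSE)

table4_fixture <- function() read.delim(
  system.file("extdata", "table_spc_altered.tsv", package = "csfmet"),
  stringsAsFactors = FALSE)
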