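# Small in-code fixtures and independent oracles shared across tests.

toy_community <- function() {
  m <- matrix(c(300, 200,   0,   0,
                100, 250, 150,   0,
                  0,  50, 200, 250),
              nrow = 3, byrow = TRUE,
              dimnames = list(paste0("site", 1:3), paste0("sp", 1:4)))
  storage.mode(m) <- "double"
  m
}

toy_traits <- function() {
  data.frame(
    size          = c("large", "small", "small", "large"),
    mobility      = c("mobile", "non-mobile", "mobile", "non-mobile"),
    attachment    = c("adnate", "pedunculate", "non-attached", "pedunculate"),
    peduncle_type = c("not-applicable", "pad", "not-applicable", "stalk"),
    colonization  = c("colonial", "non-colonial", "non-colonial", "colonial"),
    growth_form   = c("low-profile", "high-profile", "motile", "planktonic"),
    nitrogen_fixation = c("fixer", "non-fixer", "non-fixer", "non-fixer"),
    row.names = paste0("sp", 1:4))
}

toy_env <- function() {
  set.seed(42)
  vars <- c("salinity", "pH", "temperature", "fetch", "stone_volume",
            "NO2_NO3", "NH4", "PO4", "Si", "total_N", "total_P")
  e <- as.data.frame(setNames(lapply(vars, function(v) runif(3, 1, 10)), vars))
  e$distance_from_site1 <- c(0, 10, 25)
  rownames(e) <- paste0("site", 1:3)
  e
}

# one small simulated dataset per seed, cached for the session
small_sim <- local({
  cache <- list()
  function(seed = 1, n_sites = 20, n_species = 80, n_trait_syndromes = 8) {
    key <- paste(seed, n_sites, n_species, n_trait_syndromes)
    if (is.null(cache[[key]]))
      cache[[key]] <<- simulate_dataset(gradient_spec(
        n_sites = n_sites, n_species = n_species,
        n_trait_syndromes = n_trait_syndromes, seed = seed))
    cache[[key]]
  }
})

# brute-force UPGMA by naive repeated matrix update (independent of hclust)
upgma_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  sizes <- rep(1, n)
  coph <- matrix(0, n, n)
  active <- seq_len(n)
  dd <- d
  while (length(active) > 1) {
    pairs <- t(combn(active, 2))
    vals <- dd[pairs]
    k <- which.min(vals)
    i <- pairs[k, 1]; j <- pairs[k, 2]
    h <- dd[i, j]
    for (a in clusters[[i]]) for (b in clusters[[j]])
      coph[a, b] <- coph[b, a] <- h
    # average-linkage update into slot i
    for (m in setdiff(active, c(i, j)))
      dd[i, m] <- dd[m, i] <-
        (sizes[i] * dd[i, m] + sizes[j] * dd[j, m]) / (sizes[i] + sizes[j])
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  dimnames(coph) <- dimnames(d)
  coph
}

# brute-force pairwise Sorensen/Simpson dissimilarity components
pairwise_sor_oracle <- function(x, y) {
  a <- sum(x & y); b <- sum(x & !y); c <- sum(!x & y)
  list(sor = (b + c) / (2 * a + b + c),
       sim = min(b, c) / (a + min(b, c)))
}

# random incidence matrix with no empty site and no empty species
random_incidence <- function(n, s) {
  repeat {
    m <- matrix(rbinom(n * s, 1, 0.4), n, s)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}
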