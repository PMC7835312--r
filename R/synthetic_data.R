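#' Specification of a simulated sampling gradient
#'
#' Parameters of the community simulator: a linear sampling gradient
#' (river to open sea) with equally spaced sites, Gaussian species niches
#' along it, fixed counting effort per site, and trait syndromes controlling
#' functional redundancy (redundancy = n_species / n_trait_syndromes).
#'
#' @param n_sites number of sites (default 51).
#' @param gradient_length_km gradient extent in km (default 60).
#' @param n_species size of the species pool (default 408).
#' @param valves_per_site counting effort: valves identified per site
#'   (default 500).
#' @param niche_width_range range (km) of the uniform draw of Gaussian
#'   niche widths (default c(1, 10)).
#' @param abundance_sdlog sd-log of the log-normal species abundance
#'   multipliers that create dominance structure (default 2). Together with
#'   the niche widths this is calibrated so per-site richness falls in the
#'   observed band while some widespread generalist species remain.
#' @param n_trait_syndromes number of distinct trait syndromes (default 25,
#'   i.e. redundancy about 16 species per syndrome).
#' @param env_noise_sd site-level Gaussian noise on each environmental
#'   variable, as a fraction of the variable's deterministic range
#'   (default 0.05).
#' @param seed integer seed; every generated number is a function of it.
#' @return list of class `gradient_spec`.
#' @export
gradient_spec <- function(n_sites = 51, gradient_length_km = 60,
                          n_species = 408, valves_per_site = 500,
                          niche_width_range = c(1, 10),
                          abundance_sdlog = 2,
                          n_trait_syndromes = 25,
                          env_noise_sd = 0.05, seed = 1) {
  stopifnot(n_sites >= 2, gradient_length_km > 0, n_species >= 2,
            valves_per_site > 0, all(niche_width_range > 0),
            abundance_sdlog >= 0,
            n_trait_syndromes >= 1, n_trait_syndromes <= n_species,
            env_noise_sd >= 0)
  structure(list(n_sites = n_sites, gradient_length_km = gradient_length_km,
                 n_species = n_species, valves_per_site = valves_per_site,
                 niche_width_range = sort(niche_width_range),
                 abundance_sdlog = abundance_sdlog,
                 n_trait_syndromes = n_trait_syndromes,
                 env_noise_sd = env_noise_sd, seed = seed),
            class = "gradient_spec")
}

#' Simulate the environmental gradient
#'
#' Eleven variables with the trends typical of a river-to-sea transition:
#' salinity, fetch, pH and phosphate increase seawards; temperature,
#' nitrate+nitrite, ammonium and total nitrogen decrease; stone volume is
#' unimodal; silicate and total phosphorus vary non-monotonically. Each is a
#' deterministic shape of gradient position plus Gaussian noise
#' (`env_noise_sd` x shape range). Salinity runs from about 0 (river) to
#' about 6 (sea).
#'
#' @param spec `gradient_spec`.
#' @return environment table with `distance_from_site1` (km).
#' @export
generate_environment <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_sites
  L <- spec$gradient_length_km
  pos <- seq(0, L, length.out = n)
  u <- pos / L                     # 0..1 along the gradient
  shapes <- list(
    salinity     = 6 / (1 + exp(-(pos - 0.42 * L) / (0.1 * L))),
    pH           = 7.2 + 1.0 * u,
    temperature  = 22 - 7 * u,
    fetch        = 50 * exp(6 * u),
    stone_volume = 500 + 1500 * exp(-(u - 0.5)^2 / (2 * 0.2^2)),
    NO2_NO3      = 150 * exp(-3.3 * u),
    NH4          = 30 * exp(-1.8 * u),
    PO4          = 5 + 25 * u,
    Si           = 1500 + 600 * sin(2 * pi * u),
    total_N      = 900 - 600 * u,
    total_P      = 20 + 10 * cos(2 * pi * u + 1)
  )
  env <- data.frame(lapply(shapes, function(s) {
    noise <- rnorm(n, 0, spec$env_noise_sd * diff(range(s)))
    pmax(s + noise, 0.001 * max(s))   # keep strictly positive
  }))
  env$distance_from_site1 <- pos
  rownames(env) <- paste0("site", seq_len(n))
  as_environment_table(env)
}

## One categorical trait row per syndrome, all distinct, respecting the
## attachment/peduncle hierarchy.
generate_syndromes <- function(k) {
  if (k > 512) stop("at most 512 distinct trait syndromes exist")
  rows <- list(); seen <- character(0)
  while (length(rows) < k) {
    r <- lapply(TRAIT_LEVELS, function(lv) sample(setdiff(lv, "not-applicable"), 1))
    r$peduncle_type <- if (r$attachment == "pedunculate")
      sample(c("pad", "stalk"), 1) else "not-applicable"
    key <- paste(unlist(r), collapse = "|")
    if (!key %in% seen) { seen <- c(seen, key); rows[[length(rows) + 1]] <- r }
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Simulate communities and traits along the gradient
#'
#' Species i responds to gradient position with a Gaussian niche: optimum
#' mu_i uniform on (-10, gradient_length + 10) (extending beyond the ends to
#' avoid edge-richness artifacts) and width sigma_i uniform on
#' `niche_width_range`. Expected relative abundance at a site is
#' proportional to exp(-(pos - mu_i)^2 / (2 sigma_i^2)) and counts are drawn
#' multinomially with the fixed counting effort, mirroring a
#' fixed-number-of-valves protocol. Species additionally differ in overall
#' commonness through log-normal abundance multipliers (`abundance_sdlog`),
#' which produces the dominance structure of real counts: moderate per-site
#' richness together with a set of widespread generalists. Each species
#' carries one of
#' `n_trait_syndromes` complete trait rows; species are assigned to
#' syndromes round-robin in order of niche optimum, so every syndrome
#' persists along the whole gradient.
#'
#' @param spec `gradient_spec`.
#' @param env environment table from [generate_environment()] (provides the
#'   site positions).
#' @return list with `community` (matrix) and `traits` (data.frame).
#' @export
generate_communities <- function(spec, env) {
  set.seed(spec$seed + 1L)
  n <- spec$n_sites; S <- spec$n_species
  L <- spec$gradient_length_km
  pos <- env$distance_from_site1
  draw_niches <- function() list(
    mu = runif(S, -10, L + 10),
    sigma = runif(S, spec$niche_width_range[1], spec$niche_width_range[2]),
    h = exp(rnorm(S, 0, spec$abundance_sdlog)))
  expected <- function(ni)
    t(t(exp(-outer(pos, ni$mu, "-")^2 /
              (2 * matrix(ni$sigma^2, n, S, byrow = TRUE)))) * ni$h)
  ni <- draw_niches()
  p <- expected(ni)
  if (any(rowSums(p) == 0)) {        # degenerate site: resample once
    ni <- draw_niches()
    p <- expected(ni)
    if (any(rowSums(p) == 0)) stop("site with zero expected abundance for all species")
  }
  counts <- t(vapply(seq_len(n),
                     function(s) rmultinom(1, spec$valves_per_site, p[s, ])[, 1],
                     integer(S)))
  dimnames(counts) <- list(paste0("site", seq_len(n)), paste0("sp", seq_len(S)))

  synd <- generate_syndromes(spec$n_trait_syndromes)
  assignment <- integer(S)
  assignment[order(ni$mu)] <- rep_len(seq_len(spec$n_trait_syndromes), S)
  traits <- synd[assignment, , drop = FALSE]
  rownames(traits) <- colnames(counts)
  storage.mode(counts) <- "double"
  list(community = counts, traits = as_trait_table(traits))
}

#' Simulate a full paper-like dataset
#'
#' @param spec `gradient_spec` (default: the paper-like preset).
#' @return list with `community`, `traits`, `environment`, `spec`. Species
#'   never observed anywhere are dropped from both community and traits.
#' @export
simulate_dataset <- function(spec = gradient_spec()) {
  env <- generate_environment(spec)
  ct <- generate_communities(spec, env)
  cm <- suppressMessages(as_community_matrix(ct$community))  # drop never-observed
  list(community = cm, traits = ct$traits[colnames(cm), ],
       environment = env, spec = spec)
}
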