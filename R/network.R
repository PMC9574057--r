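#' Structured-network configuration
#'
#' Describes the architecture of the working-memory network: `N_E`
#' excitatory and `N_I` inhibitory neurons, `n_pops` selective populations
#' of `pop_size` excitatory neurons each (the remaining excitatory neurons
#' form the non-selective population), fixed in-degree random connectivity
#' with connection probability `c` per source class, and the weight classes.
#' Connections within a selective population are potentiated (`J_p`,
#' emulating prior long-term Hebbian learning); connections between
#' different selective populations or touching the non-selective population
#' carry the baseline `J_b`, except that a fraction
#' `frac_potentiated_background` of the non-selective-to-non-selective
#' connections is potentiated. All excitatory-to-excitatory connections are
#' plastic (short-term facilitation/depression); connections involving
#' inhibitory neurons are static, with inhibitory efficacies given as
#' negative mV.
#'
#' @param N_E,N_I numbers of excitatory / inhibitory neurons.
#' @param n_pops number of selective populations.
#' @param pop_size excitatory neurons per selective population.
#' @param overlap if `TRUE`, each selective population is drawn uniformly
#'   from the whole excitatory population (memberships may overlap); if
#'   `FALSE` the populations tile the first `n_pops * pop_size` neurons.
#' @param c connection probability per source-target population pair; each
#'   neuron receives exactly `round(c * N_E)` excitatory and
#'   `round(c * N_I)` inhibitory connections.
#' @param J_p,J_b potentiated / baseline E-to-E efficacy (mV).
#' @param J_EI efficacy of E-to-I connections (mV).
#' @param J_IE,J_II efficacies of I-to-E and I-to-I connections (mV,
#'   negative).
#' @param frac_potentiated_background fraction of non-selective E-to-E
#'   connections set to `J_p`.
#' @param delay_range synaptic-delay range (ms), uniform.
#' @param allow_multapses draw sources with replacement (several synapses
#'   may join the same pair, each with its own delay and plastic state).
#' @param allow_autapses permit self-connections.
#' @param J_p_overlap_factor multiplier on `J_p` applied in overlap mode
#'   (population spikes are less synchronized there and need slightly
#'   stronger intra-population coupling).
#' @param K_E,K_I explicit per-neuron in-degrees from the excitatory /
#'   inhibitory population, overriding `round(c * N)`; used by scaled test
#'   fixtures to preserve the input statistics of the full network.
#' @return An object of class `"network_config"`.
#' @export
network_config <- function(N_E = 8000, N_I = 2000, n_pops = 5,
                           pop_size = 800, overlap = FALSE, c = 0.2,
                           J_p = 0.45, J_b = 0.10, J_EI = 0.135,
                           J_IE = -0.25, J_II = -0.20,
                           frac_potentiated_background = 0.10,
                           delay_range = c(0.1, 1.0),
                           allow_multapses = TRUE, allow_autapses = TRUE,
                           J_p_overlap_factor = 1.05,
                           K_E = NULL, K_I = NULL) {
  if (N_E < 1 || N_I < 1) stop("N_E and N_I must be positive", call. = FALSE)
  if (n_pops < 0 || pop_size < 0)
    stop("n_pops and pop_size must be non-negative", call. = FALSE)
  if (!overlap && n_pops * pop_size > N_E)
    stop("n_pops * pop_size exceeds N_E with overlap = FALSE", call. = FALSE)
  if (overlap && pop_size > N_E)
    stop("pop_size exceeds N_E", call. = FALSE)
  if (c <= 0 || c > 1) stop("c must lie in (0, 1]", call. = FALSE)
  if (frac_potentiated_background < 0 || frac_potentiated_background > 1)
    stop("frac_potentiated_background must lie in [0, 1]", call. = FALSE)
  if (length(delay_range) != 2 || delay_range[1] <= 0 ||
      delay_range[2] < delay_range[1])
    stop("delay_range must be positive and increasing", call. = FALSE)
  if (J_IE > 0 || J_II > 0)
    stop("inhibitory efficacies J_IE, J_II must be <= 0", call. = FALSE)
  structure(list(N_E = as.integer(N_E), N_I = as.integer(N_I),
                 n_pops = as.integer(n_pops), pop_size = as.integer(pop_size),
                 overlap = isTRUE(overlap), c = c, J_p = J_p, J_b = J_b,
                 J_EI = J_EI, J_IE = J_IE, J_II = J_II,
                 frac_potentiated_background = frac_potentiated_background,
                 delay_range = delay_range,
                 allow_multapses = isTRUE(allow_multapses),
                 allow_autapses = isTRUE(allow_autapses),
                 J_p_overlap_factor = J_p_overlap_factor,
                 K_E = if (is.null(K_E)) NULL else as.integer(K_E),
                 K_I = if (is.null(K_I)) NULL else as.integer(K_I)),
            class = "network_config")
}

#' Assign neurons to selective populations
#'
#' Excitatory neurons are numbered `1..N_E`, inhibitory neurons
#' `N_E+1 .. N_E+N_I`. Without overlap, selective population `p` occupies
#' the `p`-th block of `pop_size` excitatory neurons; with overlap each
#' population draws `pop_size` excitatory neurons uniformly without
#' replacement, independently across populations. Uses R's global RNG.
#'
#' @param cfg a [network_config()] object.
#' @return An object of class `"population_map"`: list with `members` (list
#'   of integer vectors, one per selective population), `pop_of` (for
#'   non-overlap mode, integer vector over E neurons: population id or 0 for
#'   non-selective), `membership` (N_E x n_pops logical matrix in overlap
#'   mode, else NULL), plus `N_E`, `N_I`, `n_pops`.
#' @export
assign_populations <- function(cfg) {
  members <- vector("list", cfg$n_pops)
  pop_of <- integer(cfg$N_E)
  membership <- NULL
  if (cfg$n_pops > 0) {
    if (cfg$overlap) {
      membership <- matrix(FALSE, cfg$N_E, cfg$n_pops)
      for (p in seq_len(cfg$n_pops)) {
        members[[p]] <- sort(sample.int(cfg$N_E, cfg$pop_size))
        membership[members[[p]], p] <- TRUE
      }
      pop_of <- ifelse(rowSums(membership) > 0,
                       max.col(membership, ties.method = "first"), 0L)
      pop_of[rowSums(membership) == 0] <- 0L
    } else {
      for (p in seq_len(cfg$n_pops)) {
        members[[p]] <- ((p - 1L) * cfg$pop_size + 1L):(p * cfg$pop_size)
        pop_of[members[[p]]] <- p
      }
    }
  }
  structure(list(members = members, pop_of = as.integer(pop_of),
                 membership = membership, N_E = cfg$N_E, N_I = cfg$N_I,
                 n_pops = cfg$n_pops),
            class = "population_map")
}

#' Build the synapse table
#'
#' Every neuron (excitatory and inhibitory) receives exactly
#' `round(c * N_E)` excitatory and `round(c * N_I)` inhibitory connections,
#' with sources drawn uniformly — with replacement when multapses are
#' allowed — and i.i.d. uniform delays. Weights are then assigned by
#' [assign_weights()]. Uses R's global RNG; the realized table is exactly
#' reproducible from (config, seed).
#'
#' @param cfg a [network_config()] object.
#' @param popmap the matching [assign_populations()] result.
#' @return An object of class `"connection_table"`: list of parallel vectors
#'   `src`, `tgt` (integer ids), `J` (mV, signed), `delay` (ms), `plastic`
#'   (logical; `TRUE` iff E-to-E).
#' @export
build_connections <- function(cfg, popmap) {
  N <- cfg$N_E + cfg$N_I
  K_E <- if (is.null(cfg$K_E)) as.integer(round(cfg$c * cfg$N_E)) else cfg$K_E
  K_I <- if (is.null(cfg$K_I)) as.integer(round(cfg$c * cfg$N_I)) else cfg$K_I
  draw <- function(n_src, K, offset) {
    tgt <- rep(seq_len(N), each = K)
    if (cfg$allow_multapses) {
      if (!cfg$allow_autapses && n_src == 1 && any(tgt == 1L + offset))
        stop("cannot avoid autapses: a neuron is the sole source of its class",
             call. = FALSE)
      src <- sample.int(n_src, K * N, replace = TRUE) + offset
      if (!cfg$allow_autapses) {
        bad <- which(src == tgt)
        while (length(bad) > 0) {
          src[bad] <- sample.int(n_src, length(bad), replace = TRUE) + offset
          bad <- bad[src[bad] == tgt[bad]]
        }
      }
    } else {
      src <- integer(K * N)
      for (j in seq_len(N)) {
        pool <- seq_len(n_src) + offset
        if (!cfg$allow_autapses) pool <- pool[pool != j]
        if (K > length(pool))
          stop("in-degree exceeds available sources with allow_multapses = FALSE",
               call. = FALSE)
        src[((j - 1L) * K + 1L):(j * K)] <- pool[sample.int(length(pool), K)]
      }
    }
    list(src = src, tgt = tgt)
  }
  e <- draw(cfg$N_E, K_E, 0L)
  i <- draw(cfg$N_I, K_I, cfg$N_E)
  tab <- list(src = c(e$src, i$src), tgt = c(e$tgt, i$tgt))
  n <- length(tab$src)
  tab$delay <- stats::runif(n, cfg$delay_range[1], cfg$delay_range[2])
  tab$plastic <- tab$src <= cfg$N_E & tab$tgt <= cfg$N_E
  class(tab) <- "connection_table"
  tab <- assign_weights(tab, popmap, cfg)
  # group by source neuron: the engine walks outbound synapses per emission
  ord <- order(tab$src)
  for (f in c("src", "tgt", "J", "delay", "plastic")) tab[[f]] <- tab[[f]][ord]
  tab
}

#' Assign weight classes to a synapse table
#'
#' Applies the Hebbian weight structure: potentiated `J_p` within a
#' selective population (in overlap mode: whenever source and target share
#' at least one population, with `J_p` scaled by `J_p_overlap_factor`),
#' baseline `J_b` for other E-to-E connections touching a selective
#' population, `J_p` with probability `frac_potentiated_background` (else
#' `J_b`) among non-selective pairs, and the static `J_EI`/`J_IE`/`J_II`
#' values for connections involving inhibitory neurons. Decided per
#' connection (multapses draw independently).
#'
#' @param tab a `"connection_table"` (weights may be absent or stale).
#' @param popmap the [assign_populations()] result.
#' @param cfg the [network_config()].
#' @return the table with its `J` field (re)filled.
#' @export
assign_weights <- function(tab, popmap, cfg) {
  N_E <- cfg$N_E
  src_E <- tab$src <= N_E
  tgt_E <- tab$tgt <= N_E
  J <- numeric(length(tab$src))
  # rows involving inhibitory neurons: static classes
  J[src_E & !tgt_E] <- cfg$J_EI
  J[!src_E & tgt_E] <- cfg$J_IE
  J[!src_E & !tgt_E] <- cfg$J_II
  ee <- which(tab$plastic)
  if (length(ee)) {
    s <- tab$src[ee]; t <- tab$tgt[ee]
    if (cfg$overlap && !is.null(popmap$membership)) {
      shared <- rowSums(popmap$membership[s, , drop = FALSE] &
                          popmap$membership[t, , drop = FALSE]) > 0
      sel_s <- rowSums(popmap$membership[s, , drop = FALSE]) > 0
      sel_t <- rowSums(popmap$membership[t, , drop = FALSE]) > 0
      J_p_eff <- cfg$J_p * cfg$J_p_overlap_factor
    } else {
      ps <- popmap$pop_of[s]; pt <- popmap$pop_of[t]
      shared <- ps > 0 & ps == pt
      sel_s <- ps > 0; sel_t <- pt > 0
      J_p_eff <- cfg$J_p
    }
    w <- ifelse(shared, J_p_eff, cfg$J_b)
    bg <- !sel_s & !sel_t
    n_bg <- sum(bg)
    if (n_bg > 0 && cfg$frac_potentiated_background > 0)
      w[bg][stats::runif(n_bg) < cfg$frac_potentiated_background] <- J_p_eff
    J[ee] <- w
  }
  tab$J <- J
  tab
}

#' Build population map and synapse table in one call
#'
#' @param cfg a [network_config()] object.
#' @param seed integer seed for R's RNG (population draw, wiring, delays,
#'   background potentiation).
#' @return list with `popmap` and `connections`, class `"wm_network"`.
#' @export
build_network <- function(cfg, seed = 1) {
  set.seed(seed)
  popmap <- assign_populations(cfg)
  conn <- build_connections(cfg, popmap)
  structure(list(cfg = cfg, popmap = popmap, connections = conn,
                 seed = as.integer(seed)),
            class = "wm_network")
}

#' @export
print.wm_network <- function(x, ...) {
  cat(sprintf("wm_network: %d E + %d I neurons, %d selective populations of %d%s\n",
              x$cfg$N_E, x$cfg$N_I, x$cfg$n_pops, x$cfg$pop_size,
              if (x$cfg$overlap) " (overlapping)" else ""))
  cat(sprintf("  %d synapses (%d plastic E-to-E), seed %d\n",
              length(x$connections$src), sum(x$connections$plastic), x$seed))
  invisible(x)
}

#' Export / import a realized synapse table as a columnar text file
#'
#' Deterministic rebuild from (config, seed) is the primary persistence
#' path; the text export exists for interoperability and audits.
#'
#' @param tab a `"connection_table"`.
#' @param path file path (tab-separated, header
#'   `source target weight_mV delay_ms plastic`).
#' @return `write_connections`: `path`, invisibly. `read_connections`: a
#'   `"connection_table"`.
#' @export
write_connections <- function(tab, path) {
  df <- data.frame(source = tab$src, target = tab$tgt, weight_mV = tab$J,
                   delay_ms = tab$delay, plastic = tab$plastic)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_connections
#' @param path file path.
#' @export
read_connections <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  structure(list(src = as.integer(df$source), tgt = as.integer(df$target),
                 J = df$weight_mV, delay = df$delay_ms,
                 plastic = as.logical(df$plastic)),
            class = "connection_table")
}
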