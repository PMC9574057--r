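#' Stimulation protocol: a timeline of Gaussian noise-current epochs
#'
#' A protocol is an ordered set of epochs; during each epoch every neuron of
#' the epoch's target set receives an independent piecewise-constant
#' Gaussian current (mean `mu`, SD `sigma`, redrawn every 1 ms).
#' Overlapping epochs add. Targets are given as strings:
#' `"all"`, `"exc"`, `"inh"`, `"pop:<id>"` (one selective population) or
#' `"frac:<f>"` (a random fraction `f` of the excitatory neurons, drawn once
#' per epoch).
#'
#' @param epochs a data.frame with columns `t_start`, `t_end` (ms),
#'   `target` (character), `mu`, `sigma`.
#' @return An object of class `"wm_protocol"`.
#' @examples
#' wm_protocol(data.frame(t_start = 0, t_end = 1000, target = "exc",
#'                        mu = 22, sigma = 1))
#' @export
wm_protocol <- function(epochs) {
  need <- c("t_start", "t_end", "target", "mu", "sigma")
  if (!all(need %in% names(epochs)))
    stop("epochs must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  epochs <- as.data.frame(epochs)[need]
  if (any(epochs$t_start >= epochs$t_end))
    stop("every epoch needs t_start < t_end", call. = FALSE)
  if (any(epochs$sigma < 0)) stop("sigma must be non-negative", call. = FALSE)
  structure(epochs, class = c("wm_protocol", "data.frame"))
}

#' Append an epoch to a protocol
#'
#' @param proto a [wm_protocol()] (or `NULL` to start one).
#' @param t_start,t_end epoch bounds (ms).
#' @param target target selector string (see [wm_protocol()]).
#' @param mu,sigma mean and SD of the epoch's noise current.
#' @return the extended protocol.
#' @export
protocol_epoch <- function(proto, t_start, t_end, target, mu, sigma) {
  row <- data.frame(t_start = t_start, t_end = t_end, target = target,
                    mu = mu, sigma = sigma, stringsAsFactors = FALSE)
  if (is.null(proto)) return(wm_protocol(row))
  wm_protocol(rbind(as.data.frame(proto), row))
}

#' Resolve protocol targets against a population map
#'
#' Turns the target selector of each epoch into an explicit neuron set.
#' Random-fraction targets (`"frac:<f>"`) are drawn once per epoch from R's
#' global RNG, so resolution is reproducible under `set.seed()`.
#'
#' @param proto a [wm_protocol()].
#' @param popmap an [assign_populations()] result.
#' @return list with numeric vectors `t_start`, `t_end`, `mu`, `sigma` and
#'   `members`, a list of integer neuron-id vectors (1-based).
#' @export
compile_protocol <- function(proto, popmap) {
  N_E <- popmap$N_E
  N <- N_E + popmap$N_I
  members <- lapply(as.character(proto$target), function(tg) {
    if (tg == "all") return(seq_len(N))
    if (tg == "exc") return(seq_len(N_E))
    if (tg == "inh") return((N_E + 1L):N)
    if (startsWith(tg, "pop:")) {
      p <- as.integer(sub("^pop:", "", tg))
      if (is.na(p) || p < 1 || p > popmap$n_pops)
        stop("epoch references unknown population: ", tg, call. = FALSE)
      return(popmap$members[[p]])
    }
    if (startsWith(tg, "frac:")) {
      f <- as.numeric(sub("^frac:", "", tg))
      if (is.na(f) || f < 0 || f > 1)
        stop("invalid fraction target: ", tg, call. = FALSE)
      return(sort(sample.int(N_E, round(f * N_E))))
    }
    stop("unknown protocol target: ", tg, call. = FALSE)
  })
  list(t_start = as.numeric(proto$t_start), t_end = as.numeric(proto$t_end),
       mu = as.numeric(proto$mu), sigma = as.numeric(proto$sigma),
       members = members)
}
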