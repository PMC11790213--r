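## Forward simulation of trees with a Markov-evolving state: lineages
## speciate, go extinct and switch states at state-dependent rates; the
## run stops when the target number of extant lineages is reached, extinct
## subtrees are pruned and the reconstructed ultrametric tree is returned
## with observed tip states.  Used to generate test fixtures for the SSE
## module.

#' Simulate a tree and tip states under an SSE model
#'
#' Gillespie simulation of a birth-death process with a Markov character:
#' each lineage in state `s` speciates at `lambda[s]`, dies at `mu[s]` and
#' moves to state `j` at `Q[s, j]`.  The simulation starts from a single
#' lineage and stops at the moment the number of extant lineages reaches
#' `ntip`; runs that die out (or exceed `max_events`) are redrawn up to
#' `max_tries` times.  Extinct side branches are pruned, so the returned
#' tree is ultrametric with exactly `ntip` tips.
#'
#' @param spec an [sse_model_spec()]; together with `params` defines the
#'   rates.  Alternatively supply `lambda`, `mu`, `Q`, `obs_map` directly.
#' @param params named parameter vector for `spec`.
#' @param ntip number of extant tips.
#' @param lambda,mu,Q,obs_map explicit rates (used when `spec` is `NULL`):
#'   per-state speciation/extinction, transition matrix, and the observed
#'   state of each model state.
#' @param root_state starting state index; default is drawn from the
#'   stationary distribution of `Q`.
#' @param max_tries redraw budget for runs that die out.
#' @param max_events safety cap on events per try.
#' @return list with `tree` (ape `phylo`), `tip_states` (named factor of
#'   observed bands), `tip_model_states` (named integer, full model
#'   states) and `root_state`.
#' @examples
#' spec <- sse_model_spec("a", "CR")
#' set.seed(1)
#' sim <- simulate_sse_tree(spec, c(lambda = 0.3, mu = 0.1, q = 0.1),
#'                          ntip = 25)
#' table(sim$tip_states)
#' @export
simulate_sse_tree <- function(spec = NULL, params = NULL, ntip = 50,
                              lambda = NULL, mu = NULL, Q = NULL,
                              obs_map = NULL, root_state = NULL,
                              max_tries = 100, max_events = 1e6) {
  if (!is.null(spec)) {
    rates <- sse_build_rates(spec, params)
    lambda <- rates$lambda; mu <- rates$mu; Q <- rates$Q
    obs_map <- rates$obs_map
  }
  stopifnot(!is.null(lambda), !is.null(mu), !is.null(Q))
  S <- length(lambda)
  if (is.null(obs_map)) obs_map <- seq_len(S)
  qout <- rowSums(Q) - diag(Q) * 0
  diag(Q) <- 0
  qout <- rowSums(Q)

  for (try in seq_len(max_tries)) {
    rs <- if (is.null(root_state))
      sample.int(S, 1, prob = .stationary_dist(Q)) else root_state
    out <- .simulate_tree_once(lambda, mu, Q, qout, rs, ntip, max_events)
    if (!is.null(out)) {
      st <- factor(BAND_LEVELS[obs_map[out$tip_states]],
                   levels = BAND_LEVELS)
      names(st) <- names(out$tip_states)
      return(list(tree = out$tree, tip_states = st,
                  tip_model_states = out$tip_states, root_state = rs))
    }
  }
  stop("no surviving tree with ", ntip, " tips in ", max_tries, " tries")
}

.simulate_tree_once <- function(lambda, mu, Q, qout, root_state, ntip,
                                max_events) {
  ## lineage records, grown geometrically
  cap <- 2 * ntip + 16
  parent <- integer(cap); t_birth <- numeric(cap); t_end <- numeric(cap)
  state <- integer(cap); status <- integer(cap)  # 0 alive 1 dead 2 split
  kid1 <- integer(cap); kid2 <- integer(cap)
  n_lin <- 1L
  parent[1] <- 0L; t_birth[1] <- 0; state[1] <- root_state; status[1] <- 0L
  alive <- 1L
  t <- 0
  ev <- 0L
  while (TRUE) {
    ev <- ev + 1L
    if (ev > max_events) return(NULL)
    na <- length(alive)
    if (na == 0L) return(NULL)
    st_al <- state[alive]
    rate_l <- lambda[st_al]; rate_m <- mu[st_al]; rate_q <- qout[st_al]
    per_lin <- rate_l + rate_m + rate_q
    tot <- sum(per_lin)
    t <- t + rexp(1, tot)
    i_al <- sample.int(na, 1, prob = per_lin)
    lin <- alive[i_al]
    s <- state[lin]
    u <- runif(1) * per_lin[i_al]
    if (u < rate_l[i_al]) {
      ## speciation: lineage splits into two daughters
      if (n_lin + 2L > cap) {
        cap <- cap * 2L
        length(parent) <- cap; length(t_birth) <- cap; length(t_end) <- cap
        length(state) <- cap; length(status) <- cap
        length(kid1) <- cap; length(kid2) <- cap
      }
      t_end[lin] <- t; status[lin] <- 2L
      for (d in 1:2) {
        n_lin <- n_lin + 1L
        parent[n_lin] <- lin; t_birth[n_lin] <- t; t_end[n_lin] <- NA
        state[n_lin] <- s; status[n_lin] <- 0L
        if (d == 1) kid1[lin] <- n_lin else kid2[lin] <- n_lin
      }
      alive <- c(alive[-i_al], n_lin - 1L, n_lin)
      if (length(alive) == ntip) break
    } else if (u < rate_l[i_al] + rate_m[i_al]) {
      t_end[lin] <- t; status[lin] <- 1L
      alive <- alive[-i_al]
    } else {
      j <- sample.int(length(lambda), 1, prob = Q[s, ])
      state[lin] <- j
    }
  }
  T_ <- t
  t_end[alive] <- T_
  extant <- logical(n_lin); extant[alive] <- TRUE

  ## keep lineages with extant descendants
  keep <- extant[seq_len(n_lin)]
  for (i in seq(n_lin, 1L)) {
    if (status[i] == 2L) keep[i] <- keep[kid1[i]] || keep[kid2[i]]
  }
  if (!keep[1L]) return(NULL)

  ## recursive newick over kept lineages, suppressing unifurcations
  tip_count <- 0L
  tip_states <- integer(0)
  build <- function(i) {
    blen <- t_end[i] - t_birth[i]
    repeat {
      if (status[i] == 2L) {
        kk <- c(kid1[i], kid2[i])
        kk <- kk[keep[kk]]
        if (length(kk) == 2L) {
          return(paste0("(", build(kk[1]), ",", build(kk[2]), "):",
                        format(blen, digits = 12)))
        }
        blen <- blen + t_end[kk] - t_birth[kk]
        i <- kk
      } else {
        tip_count <<- tip_count + 1L
        lab <- paste0("t", tip_count)
        tip_states[lab] <<- state[i]
        return(paste0(lab, ":", format(blen, digits = 12)))
      }
    }
  }
  nwk <- paste0(build(1L), ";")
  tree <- ape::read.tree(text = nwk)
  list(tree = tree, tip_states = tip_states)
}
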