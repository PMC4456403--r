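# Desk-scale stochastic simulation of compiled programs: the mixture is an
# explicit population of ground agents, rule activities are rate constants
# times exact embedding counts (KaSim's convention: no automorphism
# division), and events are drawn with Gillespie's direct method.

lbsk_sim_error <- function(msg) {
  stop(errorCondition(paste0("simulation error: ", msg),
                      class = c("lbsk_sim_error", "lbsk_error")))
}

# --- mixture -----------------------------------------------------------------

# agents: list indexed by id; an agent is list(name, internal = named chr,
# partner = named list siteName -> c(agentId, partnerSite) or NULL).
# Deleted agents are set to NULL and their ids never reused.

#' Build the initial mixture of a compiled program
#'
#' Instantiates every initial condition; bonds come from the link labels of
#' each init complex.  Sites a ground complex leaves unmentioned do not
#' occur (inits are rejected as non-ground upstream).
#'
#' @param k A `kappa_program`.
#' @param max_agents Hard cap on the mixture size.
#' @return A mixture object (list of agent instances).
#' @export
kappa_mixture <- function(k, max_agents = 1e5) {
  agents <- list()
  total <- sum(vapply(k$inits, function(i) i$count * length(i$agents), 0))
  if (total > max_agents) {
    lbsk_sim_error(sprintf(
      "initial mixture has %d agents; the cap is %d", total, max_agents))
  }
  for (ini in k$inits) {
    for (copy in seq_len(ini$count)) {
      base <- length(agents)
      ends <- list() # label -> c(agent index, site)
      for (j in seq_along(ini$agents)) {
        a <- ini$agents[[j]]
        internal <- character()
        for (s in a$sites) {
          internal[[s$name]] <- s$internal
          if (s$link$kind == "label") {
            key <- as.character(s$link$k)
            if (is.null(ends[[key]])) {
              ends[[key]] <- list(c(base + j, NA), s$name)
              ends[[key]] <- list(idx = base + j, site = s$name)
            } else {
              ends[[key]]$other <- list(idx = base + j, site = s$name)
            }
          }
        }
        agents[[base + j]] <- list(name = a$name, internal = internal,
                                   partner = list())
      }
      for (key in names(ends)) {
        e <- ends[[key]]
        agents[[e$idx]]$partner[[e$site]] <- c(e$other$idx, e$other$site)
        agents[[e$other$idx]]$partner[[e$other$site]] <- c(e$idx, e$site)
      }
    }
  }
  structure(list(agents = agents), class = "kappa_mixture")
}

#' @export
print.kappa_mixture <- function(x, ...) {
  live <- sum(!vapply(x$agents, is.null, TRUE))
  cat(sprintf("<kappa mixture: %d agents>\n", live))
  invisible(x)
}

mixture_counts <- function(mix) {
  live <- Filter(Negate(is.null), mix$agents)
  table(vapply(live, function(a) a$name, ""))
}

# --- embedding enumeration ---------------------------------------------------

site_matches <- function(ps, agent) {
  # ps: pattern site (name, internal chr|NA, link); agent: mixture agent
  if (!ps$name %in% names(agent$internal)) return(FALSE)
  if (!is.na(ps$internal) && !identical(agent$internal[[ps$name]], ps$internal)) {
    return(FALSE)
  }
  bonded <- !is.null(agent$partner[[ps$name]])
  switch(ps$link$kind,
    free = !bonded,
    bound = bonded,
    any = TRUE,
    label = bonded, # partner consistency checked against the assignment
    FALSE
  )
}

agent_matches <- function(pa, agent) {
  if (!identical(pa$name, agent$name)) return(FALSE)
  for (ps in pa$sites) {
    if (!site_matches(ps, agent)) return(FALSE)
  }
  TRUE
}

# label -> list of (pattern agent index, site name); each label has exactly
# two endpoints in a well-typed pattern
pattern_bonds <- function(pattern) {
  bonds <- list()
  for (i in seq_along(pattern)) {
    for (s in pattern[[i]]$sites) {
      if (s$link$kind == "label") {
        key <- as.character(s$link$k)
        bonds[[key]] <- c(bonds[[key]], list(list(idx = i, site = s$name)))
      }
    }
  }
  bonds
}

#' Count and enumerate embeddings of a pattern into a mixture
#'
#' An embedding is an injective map from pattern agents to mixture agents
#' respecting agent names, internal states (wildcards match anything) and
#' link constraints: a free site must be unbound, `!_` bound to anything,
#' `?` unconstrained, and sites sharing a link label must be bound to each
#' other.
#'
#' @param pattern List of Kappa agents (e.g. a rule LHS, or from
#'   [parse_pattern()]).
#' @param mix A mixture from [kappa_mixture()].
#' @return `list(count, matches)`; each match is an integer vector of
#'   mixture agent ids, one per pattern agent.
#' @export
find_embeddings <- function(pattern, mix) {
  np <- length(pattern)
  if (np == 0L) return(list(count = 0L, matches = list()))
  live_ids <- which(!vapply(mix$agents, is.null, TRUE))
  bonds <- pattern_bonds(pattern)
  # peer[(i, site)] -> c(peer pattern index, peer site)
  peer <- list()
  for (key in names(bonds)) {
    e <- bonds[[key]]
    if (length(e) != 2L) {
      lbsk_sim_error(sprintf("pattern link label %s does not occur twice", key))
    }
    peer[[paste0(e[[1L]]$idx, ".", e[[1L]]$site)]] <-
      list(idx = e[[2L]]$idx, site = e[[2L]]$site)
    peer[[paste0(e[[2L]]$idx, ".", e[[2L]]$site)]] <-
      list(idx = e[[1L]]$idx, site = e[[1L]]$site)
  }
  matches <- list()
  assign_next <- function(i, phi) {
    if (i > np) {
      matches[[length(matches) + 1L]] <<- phi
      return(invisible(NULL))
    }
    # a labelled site whose peer is already placed forces the candidate
    forced <- NULL
    for (s in pattern[[i]]$sites) {
      if (s$link$kind != "label") next
      pr <- peer[[paste0(i, ".", s$name)]]
      if (pr$idx < i) {
        partner <- mix$agents[[phi[[pr$idx]]]]$partner[[pr$site]]
        if (is.null(partner)) return(invisible(NULL))
        cand <- as.integer(partner[[1L]])
        want_site <- s$name
        if (!identical(partner[[2L]], want_site)) return(invisible(NULL))
        if (!is.null(forced) && forced != cand) return(invisible(NULL))
        forced <- cand
      }
    }
    cands <- if (!is.null(forced)) forced else live_ids
    for (id in cands) {
      if (id %in% phi) next
      if (!agent_matches(pattern[[i]], mix$agents[[id]])) next
      ok <- TRUE
      # bonds whose both endpoints are now placed must agree
      for (s in pattern[[i]]$sites) {
        if (s$link$kind != "label") next
        pr <- peer[[paste0(i, ".", s$name)]]
        if (pr$idx < i) {
          partner <- mix$agents[[id]]$partner[[s$name]]
          if (is.null(partner) || as.integer(partner[[1L]]) != phi[[pr$idx]] ||
              !identical(partner[[2L]], pr$site)) {
            ok <- FALSE
            break
          }
        }
      }
      if (ok) assign_next(i + 1L, c(phi, id))
    }
    invisible(NULL)
  }
  assign_next(1L, integer())
  list(count = length(matches), matches = matches)
}

#' Parse a flat observable pattern
#'
#' Accepts the flat curly-brace dialect, e.g. `"MEK{S222~p}"` or
#' `"A{s!1}-B{t!1}"`.  An omitted internal state matches anything; an
#' omitted link is unconstrained (`?`), so `MEK{S222~p}` counts
#' phosphorylated MEK whether bound or not — write `S222~p!_` or an explicit
#' free site to constrain the link.
#'
#' @param text Pattern text.
#' @param comp Compartment path token to require (default none: the pattern
#'   matches agents in any compartment).
#' @return A list of Kappa agents usable with [find_embeddings()].
#' @export
parse_pattern <- function(text, comp = NULL) {
  st <- new_stream(tokenize(text))
  agents <- list()
  repeat {
    id <- expect(st, "ident", "agent name")$value
    sites <- list()
    if (cur_type(st) == "lbrace") sites <- parse_site_block(st)
    ksites <- lapply(sites, function(s) {
      internal <- if (is.null(s$internal)) {
        NA_character_
      } else if (s$internal$kind == "value") {
        s$internal$v
      } else {
        NA_character_
      }
      link <- s$link %||% link_any()
      if (link$kind == "identity") {
        lbsk_sim_error("identity links are not allowed in observables")
      }
      list(name = s$name, internal = internal, link = link)
    })
    if (!is.null(comp)) {
      ksites[[length(ksites) + 1L]] <- list(name = "comp", internal = comp,
                                            link = link_any())
    }
    agents[[length(agents) + 1L]] <- list(name = id, sites = ksites)
    if (cur_type(st) == "dash") advance(st) else break
  }
  expect(st, "eof", "end of pattern")
  agents
}

# --- event application -------------------------------------------------------

first_internal <- function(signatures, agent_name, site) {
  sig <- signatures[[agent_name]]
  if (!is.null(sig) && !is.null(sig[[site]])) sig[[site]][[1L]] else "u"
}

apply_event <- function(mix, rule, phi, signatures) {
  nl <- length(rule$lhs)
  nr <- length(rule$rhs)
  # reactants and products correspond positionally while their agent names
  # agree; the remainder is deleted (left) or created (right), so e.g.
  # `mRNA -> MEK` deletes the mRNA and creates a MEK
  nmatch <- 0L
  while (nmatch < min(nl, nr) &&
         identical(rule$lhs[[nmatch + 1L]]$name, rule$rhs[[nmatch + 1L]]$name)) {
    nmatch <- nmatch + 1L
  }
  unbind <- function(id, site) {
    partner <- mix$agents[[id]]$partner[[site]]
    if (!is.null(partner)) {
      pid <- as.integer(partner[[1L]])
      psite <- partner[[2L]]
      if (!is.null(mix$agents[[pid]])) {
        mix$agents[[pid]]$partner[[psite]] <- NULL
      }
      mix$agents[[id]]$partner[[site]] <- NULL
    }
    mix
  }
  # deletions (unmatched reactants)
  if (nl > nmatch) {
    for (i in (nmatch + 1L):nl) {
      id <- phi[[i]]
      for (site in names(mix$agents[[id]]$partner)) {
        mix <- unbind(id, site)
      }
      mix$agents[id] <- list(NULL)
    }
  }
  # creations (unmatched products); ids recorded for bonds
  created <- integer()
  if (nr > nmatch) {
    for (j in (nmatch + 1L):nr) {
      a <- rule$rhs[[j]]
      internal <- character()
      sig <- signatures[[a$name]]
      for (s in names(sig)) {
        internal[[s]] <- sig[[s]][[1L]]
      }
      for (s in a$sites) {
        internal[[s$name]] <- if (!is.na(s$internal)) s$internal
                              else first_internal(signatures, a$name, s$name)
      }
      mix$agents[[length(mix$agents) + 1L]] <-
        list(name = a$name, internal = internal, partner = list())
      created[[j - nmatch]] <- length(mix$agents)
    }
  }
  resolve_id <- function(j) if (j <= nmatch) phi[[j]] else created[[j - nmatch]]
  # internal states and link frees on matched agents
  for (j in seq_len(nmatch)) {
    id <- phi[[j]]
    for (s in rule$rhs[[j]]$sites) {
      if (!is.na(s$internal)) mix$agents[[id]]$internal[[s$name]] <- s$internal
      if (s$link$kind == "free") mix <- unbind(id, s$name)
    }
  }
  # bonds named on the right hand side
  rbonds <- pattern_bonds(rule$rhs)
  for (key in names(rbonds)) {
    e <- rbonds[[key]]
    if (length(e) != 2L) {
      lbsk_sim_error(sprintf(
        "rule '%s' would create a dangling bond (label %s)", rule$label, key))
    }
    id1 <- resolve_id(e[[1L]]$idx)
    id2 <- resolve_id(e[[2L]]$idx)
    mix <- unbind(id1, e[[1L]]$site)
    mix <- unbind(id2, e[[2L]]$site)
    mix$agents[[id1]]$partner[[e[[1L]]$site]] <- c(id2, e[[2L]]$site)
    mix$agents[[id2]]$partner[[e[[2L]]$site]] <- c(id1, e[[1L]]$site)
  }
  mix
}

# --- Gillespie direct method -------------------------------------------------

#' Stochastic simulation of a compiled program
#'
#' Gillespie's direct method over the compiled rule set: each rule's
#' activity is its rate constant times its current number of embeddings
#' (no automorphism correction, as in KaSim); waiting times are
#' exponential and the applied embedding is drawn uniformly.  With a fixed
#' seed the trajectory is reproducible bit for bit.
#'
#' @param k A `kappa_program` with non-empty initial conditions.
#' @param tmax Simulated time horizon (arbitrary units).
#' @param seed Integer seed for the run.
#' @param observables Named list/vector of pattern strings (see
#'   [parse_pattern()]) or pre-parsed patterns; counted after every event.
#' @param max_events Safety cap on the number of events.
#' @param max_agents Mixture size cap.
#' @return A `data.frame` with column `time` and one column per observable;
#'   attributes `seed` and `status` ("tmax", "exhausted" for zero total
#'   activity, or "max_events").
#' @export
ssa <- function(k, tmax, seed = 1L, observables = list(),
                max_events = 1e5, max_agents = 1e5) {
  if (length(k$inits) == 0L) {
    lbsk_sim_error("cannot simulate a program without initial conditions")
  }
  seed <- as.integer(seed)
  obs <- lapply(observables, function(o) {
    if (is.character(o)) parse_pattern(o) else o
  })
  if (is.null(names(obs)) && length(obs)) {
    names(obs) <- vapply(seq_along(obs), function(i) {
      if (is.character(observables[[i]])) observables[[i]]
      else paste0("obs", i)
    }, "")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)

  mix <- kappa_mixture(k, max_agents = max_agents)
  t <- 0
  rows <- list()
  record <- function(t) {
    counts <- vapply(obs, function(p) find_embeddings(p, mix)$count, 0L)
    rows[[length(rows) + 1L]] <<- c(time = t, counts)
  }
  record(0)
  status <- "tmax"
  events <- 0L
  while (t < tmax) {
    embeds <- lapply(k$rules, function(r) find_embeddings(r$lhs, mix))
    acts <- vapply(seq_along(k$rules), function(i) {
      k$rules[[i]]$rate * embeds[[i]]$count
    }, 0)
    total <- sum(acts)
    if (total <= 0) {
      status <- "exhausted"
      break
    }
    dt <- stats::rexp(1L, rate = total)
    if (t + dt > tmax) break
    t <- t + dt
    ri <- sample.int(length(acts), 1L, prob = acts)
    m <- embeds[[ri]]$matches
    phi <- m[[sample.int(length(m), 1L)]]
    mix <- apply_event(mix, k$rules[[ri]], phi, k$signatures)
    live <- sum(!vapply(mix$agents, is.null, TRUE))
    if (live > max_agents) {
      lbsk_sim_error(sprintf("mixture exceeded the cap of %d agents",
                             max_agents))
    }
    record(t)
    events <- events + 1L
    if (events >= max_events) {
      status <- "max_events"
      break
    }
  }
  traj <- as.data.frame(do.call(rbind, rows))
  names(traj) <- c("time", names(obs))
  attr(traj, "seed") <- seed
  attr(traj, "status") <- status
  attr(traj, "final_mixture") <- mix
  traj
}

# Debug-grade invariant check on a mixture: partner pointers are mutual and
# every internal value is declared by the agent's signature.
check_mixture <- function(mix, signatures) {
  for (id in seq_along(mix$agents)) {
    a <- mix$agents[[id]]
    if (is.null(a)) next
    sig <- signatures[[a$name]]
    for (s in names(a$internal)) {
      if (!is.null(sig[[s]]) && !a$internal[[s]] %in% sig[[s]]) {
        lbsk_sim_error(sprintf(
          "agent %d (%s) has undeclared internal state '%s' on site '%s'",
          id, a$name, a$internal[[s]], s))
      }
    }
    for (s in names(a$partner)) {
      p <- a$partner[[s]]
      pid <- as.integer(p[[1L]])
      back <- mix$agents[[pid]]$partner[[p[[2L]]]]
      if (is.null(back) || as.integer(back[[1L]]) != id ||
          !identical(back[[2L]], s)) {
        lbsk_sim_error(sprintf(
          "bond %s.%s <-> %s.%s is not mutual", id, s, pid, p[[2L]]))
      }
    }
  }
  invisible(TRUE)
}
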